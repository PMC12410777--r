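test_that("bipolar derivation subtracts common mode exactly", {
  a <- rnorm(100)
  expect_equal(derive_bipolar(a, a), rep(0, 100))
  cm <- rnorm(100)
  s <- sin(seq(0, 10, length.out = 100))
  expect_equal(derive_bipolar(s + cm, cm), s)
  expect_error(derive_bipolar(a, a[-1]), "equal-length")
})

test_that("bipolar ECG derivation recovers the beat train", {
  set.seed(41)
  e <- synth_ecg(70, 20, 60, 500)
  d <- derive_bipolar(e$stream$data[, 1], e$stream$data[, 2])
  # rebuild the clean template train from ground-truth beat times
  tgrid <- (seq_len(30000)) / 500
  train <- numeric(30000)
  for (b in e$beat_times_s) train <- train + exp(-((tgrid - b)^2) / (2 * 0.008^2))
  # compare inside the cardiac analysis band, where the QRS energy lives
  bp <- default_config()$filters$cardiac
  expect_gt(cor(zero_phase_filter(d, bp, 500), zero_phase_filter(train, bp, 500)),
            0.9)
})

test_that("mastoid re-referencing drops the reference pair", {
  n <- 500
  eeg <- matrix(rnorm(n * 27), n, 27, dimnames = list(NULL, eeg_montage()))
  out <- rereference_to_mastoids(eeg)
  expect_equal(ncol(out), 25)
  expect_false(any(c("TP9", "TP10") %in% colnames(out)))

  eeg2 <- eeg
  eeg2[, c("TP9", "TP10")] <- 0
  out2 <- rereference_to_mastoids(eeg2)
  expect_equal(out2, eeg2[, setdiff(eeg_montage(), mastoid_labels())])

  const <- matrix(4.2, n, 27, dimnames = list(NULL, eeg_montage()))
  expect_equal(max(abs(rereference_to_mastoids(const))), 0)

  bad <- eeg[, colnames(eeg) != "TP10"]
  expect_error(rereference_to_mastoids(bad), "TP10")
})

test_that("common average reference zeroes the cross-channel mean and is idempotent", {
  set.seed(42)
  x <- matrix(rnorm(1000 * 5), 1000, 5)
  y <- common_average_reference(x)
  expect_equal(max(abs(rowMeans(y))), 0, tolerance = 1e-12)
  expect_equal(common_average_reference(y), y)
  same <- matrix(rep(rnorm(100), 4), 100, 4)
  expect_equal(max(abs(common_average_reference(same))), 0, tolerance = 1e-12)
  expect_error(common_average_reference(x[, 1, drop = FALSE]), "2 channels")
})

test_that("EOG regression removes the mixed-in component and recovers the clean signal", {
  set.seed(43)
  n <- 30000 # 300 s at 100 Hz
  clean <- matrix(rnorm(n * 3), n, 3)
  veog <- as.numeric(stats::filter(rnorm(n), rep(1 / 20, 20), circular = TRUE))
  heog <- as.numeric(stats::filter(rnorm(n), rep(1 / 20, 20), circular = TRUE))
  mixed <- clean
  mixed[, 1] <- clean[, 1] + 0.3 * veog
  mixed[, 2] <- clean[, 2] + 0.5 * heog
  out <- regress_out_eog(mixed, veog, heog)
  expect_lt(abs(cor(out[, 1], veog)), 0.01)
  expect_lt(abs(cor(out[, 2], heog)), 0.01)
  expect_gt(cor(out[, 1], clean[, 1]), 0.99)
  expect_gt(cor(out[, 2], clean[, 2]), 0.99)
  # untouched channel barely changes; contaminated channel changes materially
  deltas <- sqrt(colMeans((out - clean)^2)) / apply(clean, 2, sd)
  expect_lt(deltas[3], 0.05)
})

test_that("clean EEG passes through EOG regression nearly unchanged", {
  set.seed(44)
  n <- 10000
  eeg <- matrix(rnorm(n * 4), n, 4)
  veog <- rnorm(n)
  heog <- rnorm(n)
  out <- regress_out_eog(eeg, veog, heog)
  expect_lt(sqrt(mean((out - eeg)^2)) / sd(eeg), 0.02)
})

test_that("constant EOG regressors pass EEG through with a warning", {
  eeg <- matrix(rnorm(200 * 3), 200, 3)
  expect_warning(out <- regress_out_eog(eeg, rep(0, 200), rep(0, 200)), "constant")
  expect_identical(out, eeg)
})

test_that("preprocessing a full recording yields the seven processed streams at 100 Hz", {
  spec <- cohort_spec(n_participants = 4, duration_s = 30, seed = 45)
  co <- generate_cohort(spec)
  pr <- preprocess_recording(co$recordings[[1]])
  expect_setequal(names(pr$streams),
                  c("hr_raw", "tonic", "phasic", "pupil", "resp", "roll", "eeg25"))
  for (s in pr$streams) expect_equal(s$fs, 100)
  expect_equal(ncol(pr$streams$eeg25$data), 25)
  expect_equal(max(abs(rowMeans(pr$streams$eeg25$data))), 0, tolerance = 1e-9)
  expect_error(preprocess_recording(co$recordings[[1]], require = "nonexistent"),
               "nonexistent")
})

test_that("EEG pipeline suppresses powerline and decorrelates EOG on long data", {
  set.seed(46)
  e <- synth_eeg(c(delta = 2, theta = 1.2, alpha = 1, beta = 0.5, gamma = 0.2),
                 eog_gain = 0.3, powerline_amp_uV = 5, duration_s = 120, fs = 500)
  rec <- recording("T", list(eeg = e$eeg, eog = e$eog))
  pr <- preprocess_recording(rec)
  eeg <- pr$streams$eeg25$data
  # residual correlation with the EOG ground truth (at the common rate)
  v100 <- resample_to_common(stream("v", 500, e$veog_truth), 100)$data[, 1]
  h100 <- resample_to_common(stream("h", 500, e$heog_truth), 100)$data[, 1]
  rs <- apply(eeg, 2, function(ch) c(cor(ch, v100), cor(ch, h100)))
  expect_lt(max(abs(rs)), 0.05)
  # powerline: the notched EEG path suppresses the 50 Hz bin >= 20 dB
  # relative to the identical path without the notch (compared at the
  # native rate, where the 50 Hz bin is still interior)
  fl <- default_config()$filters
  unnotched <- zero_phase_filter(rereference_to_mastoids(e$eeg$data)[, 1],
                                 fl$eeg, 500)
  notched <- zero_phase_filter(unnotched, fl$notch, 500)
  # lock-in amplitude at exactly 50 Hz (full-length demodulation resolves
  # the narrow notch, unlike 1 Hz Welch bins)
  tt <- (seq_along(unnotched) - 1) / 500
  amp50 <- function(x) Mod(mean(x * exp(-2i * pi * 50 * tt)))
  expect_gt(20 * log10(amp50(unnotched) / amp50(notched)), 20)
  # and the fully processed stream shows no 50 Hz elevation over its neighbors
  w_proc <- welch_psd(eeg[, 1], 100)
  expect_lt(w_proc$psd[w_proc$freq == 50],
            3 * max(w_proc$psd[w_proc$freq %in% 45:49]))
})
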