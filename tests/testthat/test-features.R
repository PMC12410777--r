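ecg_epochs_at <- function(bpm, jitter_ms, duration_s = 300, seed = 51) {
  set.seed(seed)
  e <- synth_ecg(bpm, jitter_ms, duration_s, 500)
  rec <- recording("T", list(ecg = e$stream))
  pr <- preprocess_recording(rec)
  make_epochs(pr$streams$hr_raw)
}

test_that("heart rate is recovered from synthetic ECG through the pipeline", {
  ep <- ecg_epochs_at(60, 0, 120)
  hrs <- vapply(seq_len(ep$n_epochs),
                function(k) extract_hr(epoch_matrix(ep, k)[, 1], ep$fs), numeric(1))
  expect_equal(mean(hrs), 60, tolerance = 0.5 / 60)

  ep <- ecg_epochs_at(79.445, 10, 120)
  hrs <- vapply(seq_len(ep$n_epochs),
                function(k) extract_hr(epoch_matrix(ep, k)[, 1], ep$fs), numeric(1))
  expect_equal(mean(hrs, na.rm = TRUE), 79.445, tolerance = 1 / 79.445)
})

test_that("degenerate cardiac epochs are flagged missing", {
  set.seed(52)
  for (i in 1:5) expect_true(is.na(extract_hr(rnorm(3000), 100)))
  expect_true(is.na(extract_hr(rep(0, 3000), 100)))
})

test_that("rate extractors recover generator settings across the physiological range", {
  for (bpm in c(50, 80, 110)) {
    ep <- ecg_epochs_at(bpm, 20, 60, seed = bpm)
    hrs <- vapply(seq_len(ep$n_epochs),
                  function(k) extract_hr(epoch_matrix(ep, k)[, 1], ep$fs), numeric(1))
    expect_equal(mean(hrs, na.rm = TRUE), bpm, tolerance = 1 / bpm,
                 info = paste("bpm", bpm))
  }
  for (brpm in c(10, 15, 20, 25)) {
    set.seed(brpm)
    r <- synth_resp(brpm, 60, 500)
    pr <- preprocess_recording(recording("T", list(resp = r$stream)))
    ep <- make_epochs(pr$streams$resp)
    rr <- vapply(seq_len(ep$n_epochs),
                 function(k) extract_resp_rate(epoch_matrix(ep, k)[, 1], ep$fs),
                 numeric(1))
    expect_equal(mean(rr, na.rm = TRUE), brpm, tolerance = 0.5 / brpm,
                 info = paste("brpm", brpm))
  }
})

test_that("HRV ratio matches hand arithmetic and its invariances", {
  # beats at 0, 0.5, 1.5 -> intervals {0.5, 1.0}: sd 0.35355, rms 0.79057
  expect_equal(extract_hrv(c(0, 0.5, 1.5)), 0.4472136, tolerance = 1e-6)
  # perfectly regular rhythm -> exactly 0
  expect_equal(extract_hrv(seq(0, 29, by = 0.8)), 0)
  # scale invariance
  b <- cumsum(c(0, runif(20, 0.5, 1.2)))
  expect_equal(extract_hrv(b * 3), extract_hrv(b), tolerance = 1e-12)
  # too few beats
  expect_true(is.na(extract_hrv(c(0, 1))))
})

test_that("epoch mean and baseline zeroing follow their definitions", {
  expect_equal(epoch_mean(rep(8.099, 3000)), 8.099)
  t <- (0:2999) / 100
  expect_equal(epoch_mean(sin(2 * pi * 1 * t)), 0, tolerance = 1e-12)
  expect_equal(epoch_mean(seq(2, 4, length.out = 1000)), 3)
  expect_equal(zero_baseline(c(3.1, 3.0, 2.9)), c(0, -0.1, -0.2))
  expect_equal(zero_baseline(rep(5, 10)), rep(0, 10))
  s <- c(0, 1, 2)
  expect_equal(zero_baseline(s), s)
})

test_that("respiratory rate extraction handles sinusoids and degenerate input", {
  t <- (0:2999) / 100
  x <- sin(2 * pi * 0.25 * t)
  expect_equal(extract_resp_rate(x, 100), 15, tolerance = 0.5 / 15)
  expect_true(is.na(extract_resp_rate(rep(1, 3000), 100)))
})

test_that("roll variance is the sample variance", {
  expect_equal(roll_variance(rep(2, 100)), 0)
  sq <- rep(c(-1, 1), 500)
  expect_equal(roll_variance(sq), 1, tolerance = 2e-3)
  set.seed(53)
  r <- synth_imu_roll(2.104, 300, 110)
  pr <- preprocess_recording(recording("T", list(imu_roll = r$stream)))
  ep <- make_epochs(pr$streams$roll)
  rv <- vapply(seq_len(ep$n_epochs),
               function(k) roll_variance(epoch_matrix(ep, k)[, 1]), numeric(1))
  expect_equal(mean(rv), 2.104, tolerance = 0.10)
})

test_that("Welch PSD satisfies Parseval and localizes sinusoids", {
  t <- (0:2999) / 100
  w <- welch_psd(sin(2 * pi * 10 * t), 100)
  expect_equal(w$freq, 0:50)
  expect_equal(w$freq[which.max(w$psd)], 10)
  expect_equal(sum(w$psd) * 1, 0.5, tolerance = 0.02) # integrated power of unit sine
  set.seed(54)
  for (sdev in c(1, 3)) {
    x <- rnorm(3000, sd = sdev)
    w <- welch_psd(x, 100)
    expect_equal(sum(w$psd), var(x), tolerance = 0.10)
  }
  w0 <- welch_psd(rep(2.5, 3000), 100)
  expect_lt(max(w0$psd[-1]), 1e-20)
  expect_error(welch_psd(rnorm(50), 100), "segment")
})

test_that("band power averages the right bins", {
  freq <- 0:50
  flat <- rep(2, 51)
  for (b in names(eeg_bands())) expect_equal(band_power(flat, freq, b), 2)
  one <- numeric(51)
  one[freq == 10] <- 5
  expect_gt(band_power(one, freq, "alpha"), 0)
  for (b in c("delta", "theta", "beta", "gamma")) {
    expect_equal(band_power(one, freq, b), 0)
  }
  # half-open bands: the 50 Hz Nyquist bin is outside gamma
  nyq <- numeric(51)
  nyq[freq == 50] <- 100
  expect_equal(band_power(nyq, freq, "gamma"), 0)
  expect_error(band_power(flat, freq, c(60, 70)), "no PSD bins")
})

test_that("theta-boosted EEG shows the boost in extracted band power", {
  set.seed(55)
  base <- c(delta = 2, theta = 1.2, alpha = 1, beta = 0.5, gamma = 0.2)
  mk <- function(bands) {
    e <- synth_eeg(bands, eog_gain = 0, powerline_amp_uV = 0,
                   duration_s = 30, fs = 500)
    pr <- preprocess_recording(recording("T", list(eeg = e$eeg, eog = e$eog)))
    ep <- make_epochs(pr$streams$eeg25)
    mean(vapply(1:25, function(ch) {
      w <- welch_psd(ep$data[1, , ch], 100)
      band_power(w$psd, w$freq, "theta")
    }, numeric(1)))
  }
  boosted <- base; boosted["theta"] <- base["theta"] * 2
  ratio <- mk(boosted) / mk(base)
  expect_equal(ratio, 2, tolerance = 0.25)
})

test_that("feature matrices carry participants x epochs with labels", {
  spec <- cohort_spec(n_participants = 4, duration_s = 40, seed = 56,
                      streams = "gsr")
  co <- generate_cohort(spec)
  pr <- lapply(co$recordings, preprocess_recording)
  fm <- feature_matrix(pr, "tonic", epoch_mean, measure = "Tonic GSR", units = "uS")
  expect_equal(dim(fm), c(4L, 3L)) # floor((40-30)/5)+1 = 3 epochs
  expect_equal(rownames(fm), sprintf("P%02d", 1:4))
  expect_equal(attr(fm, "measure"), "Tonic GSR")
  truth <- co$truth$tonic_level_uS
  expect_equal(unname(rowMeans(fm)), truth, tolerance = 0.05)
})
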