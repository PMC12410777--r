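# Synthetic cohort generator.
#
# Emulates the statistical structure the downstream analysis consumes — not
# realistic physiology. Every generator stores its ground truth (beat times,
# tonic trace, EOG traces, clean per-band PSD levels) on the recording so
# feature extractors can be validated by parameter recovery.

band_limited_noise <- function(n, fs, lo, hi) {
  # Gaussian noise with flat spectrum in [lo, hi), zero outside, unit variance.
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f) # two-sided frequency magnitude
  X[f < lo | f >= hi] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  sdy <- stats::sd(y)
  if (sdy == 0) rep(0, n) else y / sdy
}

#' Simulate a two-electrode ECG
#'
#' Beats occur at inter-beat intervals of `60/hr_bpm` seconds with additive
#' Gaussian jitter. Each beat contributes a narrow Gaussian deflection
#' (QRS-like, width about 20 ms) of amplitude 1 split antisymmetrically
#' across the two electrodes, so the bipolar difference carries the full
#' beat train over broadband noise (SD 0.05 per electrode).
#'
#' @param hr_bpm Heart rate in beats/min (30-200).
#' @param hr_jitter_sd_ms SD of inter-beat-interval jitter in milliseconds.
#' @param duration_s Duration in seconds.
#' @param fs Sampling rate in Hz (>= 100).
#' @return List: `stream` (2-channel `anx_stream` named "ecg") and
#'   `beat_times_s` (ground-truth beat times).
#' @export
synth_ecg <- function(hr_bpm, hr_jitter_sd_ms = 0, duration_s = 300, fs = 500) {
  if (hr_bpm < 30 || hr_bpm > 200) stop("hr_bpm must be in [30, 200]")
  if (fs < 100) stop("fs must be at least 100 Hz")
  ibi <- 60 / hr_bpm
  n_beats <- ceiling(duration_s / ibi) + 2L
  ibis <- ibi + stats::rnorm(n_beats, 0, hr_jitter_sd_ms / 1000)
  ibis <- pmax(ibis, 0.25)
  beats <- cumsum(c(ibi / 2, ibis))
  beats <- beats[beats < duration_s - 0.05]
  n <- round(duration_s * fs)
  train <- numeric(n)
  sigma <- 0.008 # seconds; ~20 ms wide QRS-like pulse
  hw <- ceiling(4 * sigma * fs)
  tgrid <- seq_len(n) / fs
  for (b in beats) {
    i0 <- max(1L, floor(b * fs) - hw)
    i1 <- min(n, floor(b * fs) + hw)
    idx <- i0:i1
    train[idx] <- train[idx] + exp(-((tgrid[idx] - b)^2) / (2 * sigma^2))
  }
  e1 <- 0.5 * train + stats::rnorm(n, 0, 0.05)
  e2 <- -0.5 * train + stats::rnorm(n, 0, 0.05)
  list(stream = stream("ecg", fs, cbind(e1, e2), c("ecg1", "ecg2")),
       beat_times_s = beats)
}

#' Simulate electrodermal activity with tonic and phasic components
#'
#' Tonic: baseline level plus a linear drift (all energy far below the
#' 0.05 Hz tonic/phasic split). Phasic: sparse skin-conductance-response
#' bursts with instantaneous rise and exponential decay (tau = 3 s), energy
#' above the split. Additive measurement noise SD 0.01 uS.
#'
#' @param tonic_level_uS Baseline conductance in microsiemens (> 0).
#' @param tonic_slope_uS_per_s Linear drift in uS/s.
#' @param phasic_rate_per_min Mean burst rate (Poisson, events/min).
#' @param duration_s,fs Duration (s) and rate (Hz).
#' @param burst_amp_uS Mean burst amplitude in uS (exponentially distributed).
#' @return List: `stream` (1-channel "gsr"), `tonic_truth`, `phasic_truth`.
#' @export
synth_eda <- function(tonic_level_uS, tonic_slope_uS_per_s = 0,
                      phasic_rate_per_min = 2, duration_s = 300, fs = 500,
                      burst_amp_uS = 0.3) {
  if (tonic_level_uS <= 0) stop("tonic_level_uS must be positive")
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  tonic <- tonic_level_uS + tonic_slope_uS_per_s * t
  phasic <- numeric(n)
  n_ev <- stats::rpois(1, phasic_rate_per_min * duration_s / 60)
  if (n_ev > 0) {
    onsets <- sort(stats::runif(n_ev, 0, duration_s))
    amps <- stats::rexp(n_ev, 1 / burst_amp_uS)
    for (i in seq_len(n_ev)) {
      idx <- which(t >= onsets[i])
      phasic[idx] <- phasic[idx] + amps[i] * exp(-(t[idx] - onsets[i]) / 3)
    }
  }
  x <- tonic + phasic + stats::rnorm(n, 0, 0.01)
  list(stream = stream("gsr", fs, x, "gsr"),
       tonic_truth = tonic, phasic_truth = phasic)
}

#' Simulate a respiration trace
#'
#' A sinusoid at `resp_brpm / 60` Hz with unit amplitude plus broadband
#' noise (SD 0.1). Rates outside 6-30 breaths/min trigger a warning because
#' they fall outside the 0.1-0.5 Hz analysis band-pass.
#'
#' @param resp_brpm Respiratory rate in breaths/min.
#' @param duration_s,fs Duration (s) and rate (Hz).
#' @return List with `stream` (1-channel "resp").
#' @export
synth_resp <- function(resp_brpm, duration_s = 300, fs = 500) {
  if (resp_brpm < 6 || resp_brpm > 30) {
    warning("respiratory rate ", resp_brpm,
            " brpm lies outside the 0.1-0.5 Hz analysis band")
  }
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  phase <- stats::runif(1, 0, 2 * pi)
  x <- sin(2 * pi * resp_brpm / 60 * t + phase) + stats::rnorm(n, 0, 0.1)
  list(stream = stream("resp", fs, x, "resp"))
}

#' Simulate a two-eye pupil-size trace
#'
#' Per eye: baseline diameter plus linear trend plus slow (< 0.5 Hz)
#' correlated fluctuations, mimicking arousal-driven pupil drift.
#'
#' @param base_mm Baseline diameter in mm.
#' @param trend_mm_per_s Linear trend in mm/s.
#' @param duration_s,fs Duration (s) and rate (Hz, default 200).
#' @return List with `stream` (2-channel "pupil": left, right).
#' @export
synth_pupil <- function(base_mm = 3.5, trend_mm_per_s = 0, duration_s = 300, fs = 200) {
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  common <- 0.1 * band_limited_noise(n, fs, 0.01, 0.5)
  mk <- function() base_mm + trend_mm_per_s * t + common +
    0.03 * band_limited_noise(n, fs, 0.01, 0.5) + stats::rnorm(n, 0, 0.005)
  list(stream = stream("pupil", fs, cbind(mk(), mk()),
                       c("pupil_left", "pupil_right")))
}

#' Simulate head-roll angular velocity
#'
#' Zero-mean stationary Gaussian noise band-limited to 0.5-45 Hz (inside
#' the preprocessing low-pass and below the 55 Hz Nyquist of the 110 Hz
#' gyroscope stream) with sample variance normalized exactly to
#' `variance_dps2`.
#'
#' @param variance_dps2 Target variance in (deg/s)^2 (>= 0).
#' @param duration_s,fs Duration (s) and rate (Hz, default 110).
#' @return List with `stream` (1-channel "imu_roll").
#' @export
synth_imu_roll <- function(variance_dps2, duration_s = 300, fs = 110) {
  if (variance_dps2 < 0) stop("variance_dps2 must be non-negative")
  n <- round(duration_s * fs)
  if (variance_dps2 == 0) {
    x <- numeric(n)
  } else {
    x <- band_limited_noise(n, fs, 0.5, min(45, 0.45 * fs)) * sqrt(variance_dps2)
  }
  list(stream = stream("imu_roll", fs, x, "roll"))
}

#' Simulate 27-channel EEG with ocular and powerline contamination
#'
#' Each EEG channel is a sum of independent band-limited noise processes
#' with per-band one-sided PSD levels given by `band_power` (uV^2/Hz over
#' delta/theta/alpha/beta/gamma), plus `eog_gain[ch]` times the vertical and
#' horizontal EOG ground truth, plus a 50 Hz powerline sinusoid. The four
#' EOG electrodes are returned separately; their pairwise differences
#' (upper - lower, left - right) recover the ground-truth EOG traces.
#'
#' @param band_power Named numeric vector/list of PSD levels per band
#'   (names delta, theta, alpha, beta, gamma), or a 27 x 5 matrix (rows =
#'   montage channels) for per-channel levels.
#' @param eog_gain Numeric length 1 or 27: mixing gain of the EOG ground
#'   truth into each EEG channel.
#' @param powerline_amp_uV Nominal amplitude of the 50 Hz contamination in
#'   uV; each channel picks up 0.7-1.3x this amplitude (line pickup varies
#'   with electrode impedance, so re-referencing alone cannot cancel it).
#' @param duration_s,fs Duration (s) and rate (Hz, default 500).
#' @param channel_labels Montage labels; must equal [eeg_montage()].
#' @return List: `eeg` (27-channel stream), `eog` (4-channel stream:
#'   veog_up, veog_lo, heog_l, heog_r), `veog_truth`, `heog_truth`,
#'   `band_power_truth` (27 x 5 matrix of clean PSD levels).
#' @export
synth_eeg <- function(band_power, eog_gain = 0, powerline_amp_uV = 0,
                      duration_s = 300, fs = 500,
                      channel_labels = eeg_montage()) {
  if (!identical(channel_labels, eeg_montage())) {
    stop("channel labels must match the 27-electrode montage exactly")
  }
  bands <- eeg_bands()
  nch <- length(channel_labels)
  if (is.matrix(band_power)) {
    stopifnot(nrow(band_power) == nch, ncol(band_power) == length(bands))
    bp <- band_power
  } else {
    band_power <- unlist(band_power)
    stopifnot(all(names(bands) %in% names(band_power)))
    bp <- matrix(band_power[names(bands)], nrow = nch, ncol = length(bands),
                 byrow = TRUE)
  }
  colnames(bp) <- names(bands)
  rownames(bp) <- channel_labels
  if (length(eog_gain) == 1) eog_gain <- rep(eog_gain, nch)
  stopifnot(length(eog_gain) == nch)
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  # EOG ground truth: slow large-amplitude ocular activity, band 0.3-8 Hz
  veog <- 60 * band_limited_noise(n, fs, 0.3, 8)
  heog <- 40 * band_limited_noise(n, fs, 0.3, 8)
  pline <- powerline_amp_uV * sin(2 * pi * 50 * t)
  pline_gain <- stats::runif(nch, 0.7, 1.3)
  dat <- matrix(0, n, nch)
  for (j in seq_len(nch)) {
    x <- numeric(n)
    for (b in seq_along(bands)) {
      lo <- bands[[b]][1]; hi <- min(bands[[b]][2], 0.98 * fs / 2)
      lvl <- bp[j, b]
      if (lvl > 0) {
        # flat one-sided PSD `lvl` over [lo, hi) has variance lvl * (hi - lo)
        x <- x + band_limited_noise(n, fs, lo, hi) * sqrt(lvl * (hi - lo))
      }
    }
    dat[, j] <- x + eog_gain[j] * (veog + 0.6 * heog) + pline_gain[j] * pline
  }
  # EOG electrodes: antisymmetric pair per axis plus shared common mode
  cm_v <- 5 * band_limited_noise(n, fs, 0.5, 30)
  cm_h <- 5 * band_limited_noise(n, fs, 0.5, 30)
  eog <- cbind(0.5 * veog + cm_v, -0.5 * veog + cm_v,
               0.5 * heog + cm_h, -0.5 * heog + cm_h)
  list(eeg = stream("eeg", fs, dat, channel_labels),
       eog = stream("eog", fs, eog, c("veog_up", "veog_lo", "heog_l", "heog_r")),
       veog_truth = veog, heog_truth = heog, band_power_truth = bp)
}

#' Decompose questionnaire totals into seven item scores
#'
#' Produces seven continuous visual-analogue item scores in [0, 3] summing
#' exactly to the requested pre and post totals (0-21 each).
#'
#' @param pre_total,post_total Requested totals on the 0-21 scale.
#' @param spread Fraction (0-1) of the maximal feasible item dispersion.
#' @return List with `pre` and `post`, numeric length 7 each.
#' @export
synth_gad7 <- function(pre_total, post_total, spread = 0.5) {
  one <- function(total) {
    if (total < 0 || total > 21) stop("GAD-7 total must be in [0, 21], got ", total)
    m <- total / 7
    d <- stats::runif(7, -1, 1)
    d <- d - mean(d)
    if (max(abs(d)) < 1e-12) return(rep(m, 7))
    up <- if (max(d) > 0) (3 - m) / max(d) else Inf
    dn <- if (min(d) < 0) (0 - m) / min(d) else Inf
    m + d * spread * min(up, dn)
  }
  list(pre = one(pre_total), post = one(post_total))
}

#' Group-level generator templates
#'
#' Default per-group generator parameters. Group means follow the study's
#' descriptive group statistics (heart rate 79.4 vs 66.8 bpm, respiratory
#' rate 17.9 vs 15.4 brpm, tonic level 8.10 vs 4.84 uS, roll variance 8.26
#' vs 2.10 dps^2), with between-subject SDs from the same table. Anxious
#' participants get elevated theta/beta/gamma EEG levels and higher
#' questionnaire change scores.
#'
#' @return Named list with `anxious` and `non_anxious` template lists.
#' @export
group_templates <- function() {
  base_bands <- c(delta = 2, theta = 1.2, alpha = 1.0, beta = 0.5, gamma = 0.2)
  anx_bands <- base_bands * c(1, 1.8, 1, 1.8, 1.8)
  list(
    anxious = list(
      hr_bpm = 79.445, hr_sd = 13.424, hr_jitter_sd_ms = 50,
      resp_brpm = 17.879, resp_sd = 3.229,
      tonic_level_uS = 8.099, tonic_sd = 3.89, tonic_slope_uS_per_s = 0,
      phasic_event_rate_per_min = 2,
      roll_noise_variance_dps2 = 8.261, roll_sd = 5,
      eeg_band_power = anx_bands,
      pupil_base_mm = 3.6, pupil_trend_mm_per_s = -0.001,
      eog_gain_frontal = 0.4, eog_gain_other = 0.1, powerline_amp_uV = 5,
      gad7_change_range = c(1.0, 2.5)
    ),
    non_anxious = list(
      hr_bpm = 66.75, hr_sd = 7.184, hr_jitter_sd_ms = 50,
      resp_brpm = 15.37, resp_sd = 2.622,
      tonic_level_uS = 4.84, tonic_sd = 2.035, tonic_slope_uS_per_s = 0,
      phasic_event_rate_per_min = 2,
      roll_noise_variance_dps2 = 2.104, roll_sd = 1.5,
      eeg_band_power = base_bands,
      pupil_base_mm = 3.4, pupil_trend_mm_per_s = -0.001,
      eog_gain_frontal = 0.4, eog_gain_other = 0.1, powerline_amp_uV = 5,
      gad7_change_range = c(-0.5, 0.8)
    )
  )
}

#' Specify a synthetic cohort
#'
#' @param n_participants Number of participants (>= 4; default 17, split
#'   ceiling(n/2) anxious / floor(n/2) non-anxious).
#' @param duration_s Recording duration in seconds (>= 30; default 300).
#' @param seed Integer RNG seed; the cohort is bit-reproducible given it.
#' @param streams Which modalities to generate (subset of
#'   `c("ecg","gsr","resp","pupil","imu_roll","eeg")`; EEG implies EOG).
#' @param group_params Per-group templates, see [group_templates()].
#' @param between_subject Logical: draw per-participant parameters around
#'   the group means (TRUE, default) or fix them at the means (FALSE).
#' @return An `anx_cohort_spec` list.
#' @export
cohort_spec <- function(n_participants = 17, duration_s = 300, seed = 1,
                        streams = c("ecg", "gsr", "resp", "pupil", "imu_roll", "eeg"),
                        group_params = group_templates(),
                        between_subject = TRUE) {
  if (n_participants < 4) stop("need at least 4 participants")
  if (duration_s < 30) {
    stop("duration_s must cover at least one 30 s analysis window, got ", duration_s)
  }
  streams <- match.arg(streams, several.ok = TRUE)
  structure(list(n_participants = as.integer(n_participants),
                 duration_s = duration_s, seed = as.integer(seed),
                 streams = streams, group_params = group_params,
                 between_subject = between_subject,
                 native_rates = native_rates()),
            class = "anx_cohort_spec")
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a synthetic cohort
#'
#' Draws per-participant generator parameters from the group templates,
#' synthesizes every requested stream at its native rate with a shared time
#' origin, and builds questionnaire scores whose change scores are distinct
#' and separate the two intended groups. Deterministic given `spec$seed`.
#'
#' @param spec An [cohort_spec()] object.
#' @return An `anx_cohort`: list with `recordings` (list of
#'   [recording()]), `gad7` (data.frame of per-item pre/post scores),
#'   `truth` (data.frame of per-participant generator parameters and group),
#'   and `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "anx_cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_participants
  n_anx <- ceiling(n / 2)
  groups <- rep(c("anxious", "non_anxious"), c(n_anx, n - n_anx))
  ids <- sprintf("P%02d", seq_len(n))
  rates <- spec$native_rates
  # distinct questionnaire change scores, disjoint between groups
  repeat {
    chg <- vapply(groups, function(g) {
      r <- spec$group_params[[g]]$gad7_change_range
      stats::runif(1, r[1], r[2])
    }, numeric(1))
    if (!anyDuplicated(signif(chg, 10))) break
  }
  recs <- vector("list", n)
  truth_rows <- list()
  gad_rows <- list()
  montage <- eeg_montage()
  frontal <- montage %in% c("Fp1", "FP2", "F7", "F8", "F3", "F4", "Fz")
  for (i in seq_len(n)) {
    g <- spec$group_params[[groups[i]]]
    bs <- spec$between_subject
    p <- list(
      hr_bpm = clip(g$hr_bpm + if (bs) stats::rnorm(1, 0, g$hr_sd) else 0, 45, 180),
      hr_jitter_sd_ms = g$hr_jitter_sd_ms,
      resp_brpm = clip(g$resp_brpm + if (bs) stats::rnorm(1, 0, g$resp_sd) else 0, 8, 28),
      tonic_level_uS = clip(g$tonic_level_uS + if (bs) stats::rnorm(1, 0, g$tonic_sd) else 0, 0.5, 25),
      tonic_slope_uS_per_s = g$tonic_slope_uS_per_s,
      phasic_event_rate_per_min = g$phasic_event_rate_per_min,
      roll_noise_variance_dps2 = clip(g$roll_noise_variance_dps2 +
        if (bs) stats::rnorm(1, 0, g$roll_sd) else 0, 0.05, 60),
      pupil_base_mm = g$pupil_base_mm, pupil_trend_mm_per_s = g$pupil_trend_mm_per_s,
      powerline_amp_uV = g$powerline_amp_uV
    )
    streams <- list()
    gt <- list()
    if ("ecg" %in% spec$streams) {
      e <- synth_ecg(p$hr_bpm, p$hr_jitter_sd_ms, spec$duration_s, rates[["ecg"]])
      streams$ecg <- e$stream
      gt$beat_times_s <- e$beat_times_s
    }
    if ("gsr" %in% spec$streams) {
      e <- synth_eda(p$tonic_level_uS, p$tonic_slope_uS_per_s,
                     p$phasic_event_rate_per_min, spec$duration_s, rates[["gsr"]])
      streams$gsr <- e$stream
      gt$tonic_truth <- e$tonic_truth
      gt$phasic_truth <- e$phasic_truth
    }
    if ("resp" %in% spec$streams) {
      streams$resp <- synth_resp(p$resp_brpm, spec$duration_s, rates[["resp"]])$stream
    }
    if ("pupil" %in% spec$streams) {
      streams$pupil <- synth_pupil(p$pupil_base_mm, p$pupil_trend_mm_per_s,
                                   spec$duration_s, rates[["pupil"]])$stream
    }
    if ("imu_roll" %in% spec$streams) {
      streams$imu_roll <- synth_imu_roll(p$roll_noise_variance_dps2,
                                         spec$duration_s, rates[["imu_roll"]])$stream
    }
    if ("eeg" %in% spec$streams) {
      gains <- ifelse(frontal, g$eog_gain_frontal, g$eog_gain_other)
      e <- synth_eeg(g$eeg_band_power, gains, p$powerline_amp_uV,
                     spec$duration_s, rates[["eeg"]])
      streams$eeg <- e$eeg
      streams$eog <- e$eog
      gt$veog_truth <- e$veog_truth
      gt$heog_truth <- e$heog_truth
      gt$band_power_truth <- e$band_power_truth
      gt$eog_gains <- gains
    }
    pre_total <- stats::runif(1, 3, 9)
    post_total <- clip(pre_total + chg[i] * 7, 0, 21)
    gad <- synth_gad7(pre_total, post_total)
    recs[[i]] <- recording(ids[i], streams, gad$pre, gad$post,
                           ground_truth = gt,
                           meta = c(list(group = groups[i], seed = spec$seed), p))
    truth_rows[[i]] <- data.frame(participant_id = ids[i], group = groups[i],
                                  hr_bpm = p$hr_bpm, resp_brpm = p$resp_brpm,
                                  tonic_level_uS = p$tonic_level_uS,
                                  roll_noise_variance_dps2 = p$roll_noise_variance_dps2,
                                  gad7_change = (sum(gad$post) - sum(gad$pre)) / 7)
    row <- as.list(c(gad$pre, gad$post))
    names(row) <- c(paste0("item", 1:7, "_pre"), paste0("item", 1:7, "_post"))
    gad_rows[[i]] <- data.frame(participant_id = ids[i], row)
  }
  structure(list(recordings = recs,
                 gad7 = do.call(rbind, gad_rows),
                 truth = do.call(rbind, truth_rows),
                 spec = spec),
            class = "anx_cohort")
}

#' @export
print.anx_cohort <- function(x, ...) {
  cat(sprintf("<anx_cohort> %d participants, %g s, streams: %s\n",
              length(x$recordings), x$spec$duration_s,
              paste(x$spec$streams, collapse = ", ")))
  invisible(x)
}
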