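# Per-epoch feature extractors. Each operates on one 30 s epoch of one
# processed stream at the common rate and returns a scalar (or a PSD bin
# vector); epoch-level failures are returned as NA and propagate into the
# group statistics as missing values.

#' Detect peaks with an adaptive threshold and refractory period
#'
#' The working signal is z-normalized; for cardiac signals the detector
#' runs on the negated first difference (the "normalized negative
#' derivative"), for respiration on the signal itself. Candidate peaks are
#' local maxima above `threshold_frac` times the in-epoch maximum, accepted
#' greedily in order of amplitude subject to a minimum spacing.
#'
#' @param x Numeric vector (one epoch).
#' @param fs Sampling rate in Hz.
#' @param refractory_s Minimum spacing between accepted peaks in seconds.
#' @param threshold_frac Fraction of the in-epoch maximum (default 0.5).
#' @param use_neg_deriv Run on `-diff(x)` (default FALSE).
#' @return Numeric vector of peak times in seconds relative to epoch start.
#' @export
detect_peaks <- function(x, fs, refractory_s, threshold_frac = 0.5,
                         use_neg_deriv = FALSE) {
  if (stats::sd(x) == 0) return(numeric(0))
  z <- (x - mean(x)) / stats::sd(x)
  w <- if (use_neg_deriv) -diff(z) else z
  n <- length(w)
  if (n < 3) return(numeric(0))
  thr <- threshold_frac * max(w)
  if (thr <= 0) return(numeric(0))
  cand <- which(w[2:(n - 1)] > w[1:(n - 2)] & w[2:(n - 1)] >= w[3:n] &
                  w[2:(n - 1)] > thr) + 1L
  if (!length(cand)) return(numeric(0))
  cand <- cand[order(w[cand], decreasing = TRUE)]
  min_gap <- refractory_s * fs
  accepted <- integer(0)
  for (i in cand) {
    if (!length(accepted) || all(abs(accepted - i) >= min_gap)) {
      accepted <- c(accepted, i)
    }
  }
  sort(accepted - 1L) / fs
}

rate_from_peaks <- function(peaks_s, lo, hi, max_cv = 0.3) {
  if (length(peaks_s) < 2) return(NA_real_)
  iv <- diff(peaks_s)
  rate <- 60 * length(iv) / sum(iv)
  if (rate < lo || rate > hi) return(NA_real_)
  # irregular spacing (high interval CV) marks spurious noise detections
  if (length(iv) >= 3 && stats::sd(iv) / mean(iv) > max_cv) return(NA_real_)
  rate
}

#' Heart rate of one epoch
#'
#' Peak detection on the normalized negative derivative of the processed
#' cardiac signal (refractory 250 ms), then
#' `60 * n_intervals / sum(intervals)`. Epochs without a credible beat
#' train — fewer than 2 beats, a rate outside 30-240 bpm, grossly irregular
#' spacing, or inconsistent beat amplitudes (both hallmarks of detections
#' on noise rather than on QRS complexes) — are flagged `NA`.
#'
#' @param x One epoch of the processed cardiac stream.
#' @param fs Sampling rate in Hz (default 100).
#' @return Heart rate in beats/min, or `NA`.
#' @export
extract_hr <- function(x, fs = 100) {
  p <- detect_peaks(x, fs, refractory_s = 0.25, use_neg_deriv = TRUE)
  if (length(p) >= 2 && peak_amplitude_cv(x, p, fs) > 0.11) return(NA_real_)
  rate_from_peaks(p, 30, 240)
}

# CV of the detection-signal amplitude at the accepted peaks: QRS trains
# have near-identical beat amplitudes, noise detections do not.
peak_amplitude_cv <- function(x, peaks_s, fs) {
  z <- (x - mean(x)) / stats::sd(x)
  w <- -diff(z)
  idx <- pmin(pmax(round(peaks_s * fs) + 1L, 1L), length(w))
  a <- w[idx]
  stats::sd(a) / mean(a)
}

#' Epoch beat times from the processed cardiac signal
#' @inheritParams extract_hr
#' @return Beat times in seconds relative to epoch start.
#' @export
extract_beats <- function(x, fs = 100) {
  detect_peaks(x, fs, refractory_s = 0.25, use_neg_deriv = TRUE)
}

#' Heart-rate variability of one epoch
#'
#' Defined here as the standard deviation of the inter-beat intervals
#' divided by their root mean square: a dimensionless ratio that is exactly
#' 0 for a perfectly regular rhythm and invariant under rescaling all
#' intervals. Sample (n-1) standard deviation is used.
#'
#' @param beat_times_s Beat times within the epoch (from [extract_beats()]).
#' @return SD(intervals) / RMS(intervals), or `NA` with fewer than 3 beats.
#' @export
extract_hrv <- function(beat_times_s) {
  if (length(beat_times_s) < 3) return(NA_real_)
  iv <- diff(beat_times_s)
  stats::sd(iv) / sqrt(mean(iv^2))
}

#' Mean of one epoch
#' @param x One epoch (numeric vector).
#' @return Arithmetic mean over samples.
#' @export
epoch_mean <- function(x) {
  if (!length(x)) stop("empty epoch")
  mean(x)
}

#' Zero the first epoch of a per-participant feature series
#'
#' Subtracts the first epoch's value from the whole series so every
#' participant's trace starts at exactly zero (used for pupil size, where
#' absolute diameter depends on viewing geometry).
#'
#' @param series Numeric vector of per-epoch values.
#' @return Series with `series[1]` subtracted.
#' @export
zero_baseline <- function(series) {
  if (!length(series)) stop("empty series")
  series - series[1]
}

#' Respiratory rate of one epoch
#'
#' Peak detection on the z-normalized respiration signal with a 2 s
#' refractory period (bounding detectable rates at 30 breaths/min), then
#' `60 * n_intervals / sum(intervals)`. Constant or peak-poor epochs are
#' flagged `NA`.
#'
#' @param x One epoch of the processed respiration stream.
#' @param fs Sampling rate in Hz (default 100).
#' @return Respiratory rate in breaths/min, or `NA`.
#' @export
extract_resp_rate <- function(x, fs = 100) {
  p <- detect_peaks(x, fs, refractory_s = 2, use_neg_deriv = FALSE)
  rate_from_peaks(p, 4, 30)
}

#' Sample variance of one epoch
#' @param x One epoch (numeric vector).
#' @return Sample (n-1) variance.
#' @export
roll_variance <- function(x) {
  if (!length(x)) stop("empty epoch")
  stats::var(x)
}

#' Welch power spectral density with 1 Hz bins
#'
#' Averaged modified periodograms: Hann-windowed segments of `1/bin_width`
#' seconds with 50% overlap and per-segment constant detrend, one-sided
#' density scaling (power per Hz). At the default 100 Hz rate and 1 Hz bins
#' this yields bins centred at 0, 1, ..., 50 Hz.
#'
#' @param x One epoch (numeric vector).
#' @param fs Sampling rate in Hz (default 100).
#' @param bin_width_hz Frequency resolution in Hz (default 1).
#' @return List with `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs = 100, bin_width_hz = 1) {
  seg <- round(fs / bin_width_hz)
  n <- length(x)
  if (n < seg) stop("epoch shorter than one Welch segment (", seg, " samples)")
  step <- seg %/% 2
  starts <- seq(1, n - seg + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg) / seg) # periodic Hann
  wnorm <- sum(w^2)
  segm <- vapply(starts, function(i) {
    s <- x[i:(i + seg - 1)]
    (s - mean(s)) * w # constant detrend per segment
  }, numeric(seg))
  spec <- Mod(stats::mvfft(segm))^2
  nf <- seg %/% 2 + 1
  p <- rowMeans(spec[seq_len(nf), , drop = FALSE]) / (fs * wnorm)
  scale2 <- rep(2, nf)
  scale2[1] <- 1
  if (seg %% 2 == 0) scale2[nf] <- 1
  list(freq = (seq_len(nf) - 1) * bin_width_hz, psd = p * scale2)
}

#' Mean band power from PSD bins
#'
#' Mean of the PSD bins whose centre frequency falls in the half-open
#' interval `[lo, hi)`.
#'
#' @param psd PSD values (from [welch_psd()]).
#' @param freq Bin centre frequencies in Hz.
#' @param band `c(lo, hi)` in Hz, or a band name from [eeg_bands()].
#' @return Mean PSD over the band's bins.
#' @export
band_power <- function(psd, freq, band) {
  if (is.character(band)) band <- eeg_bands()[[match.arg(band, names(eeg_bands()))]]
  sel <- freq >= band[1] & freq < band[2]
  if (!any(sel)) stop("no PSD bins inside band [", band[1], ", ", band[2], ")")
  mean(psd[sel])
}

#' Per-epoch feature matrix for one measure across a cohort
#'
#' Applies a scalar epoch feature to every epoch of one processed stream
#' for every participant.
#'
#' @param processed List of preprocessed recordings.
#' @param stream_name Which processed stream to use.
#' @param feature_fn Function(epoch vector, fs) or function(epoch vector).
#' @param channel Channel index within the stream (default 1).
#' @param window_s,step_s Epoching parameters.
#' @param baseline_zero Apply [zero_baseline()] per participant.
#' @param measure,units Labels stored as attributes.
#' @return participants x epochs numeric matrix (rownames participant ids)
#'   with attributes `measure` and `units`.
#' @export
feature_matrix <- function(processed, stream_name, feature_fn, channel = 1,
                           window_s = 30, step_s = 5, baseline_zero = FALSE,
                           measure = stream_name, units = "") {
  takes_fs <- length(formals(feature_fn)) >= 2
  rows <- lapply(processed, function(rec) {
    s <- rec$streams[[stream_name]]
    if (is.null(s)) stop("recording ", rec$participant_id,
                         " lacks processed stream '", stream_name, "'")
    ep <- make_epochs(s, window_s, step_s)
    v <- vapply(seq_len(ep$n_epochs), function(k) {
      x <- epoch_matrix(ep, k)[, channel]
      if (takes_fs) feature_fn(x, ep$fs) else feature_fn(x)
    }, numeric(1))
    if (baseline_zero) v <- zero_baseline(v)
    v
  })
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(processed, function(r) r$participant_id, character(1))
  attr(m, "measure") <- measure
  attr(m, "units") <- units
  m
}

#' Whole-task average PSD per participant
#'
#' Welch PSD per epoch and channel, averaged across epochs, for one
#' processed stream of every participant.
#'
#' @param processed List of preprocessed recordings.
#' @param stream_name Which processed stream (e.g. "roll", "eeg25").
#' @param window_s,step_s Epoching parameters.
#' @param bin_width_hz Welch bin width (default 1 Hz).
#' @return List with `freq` and `psd`, an array participants x channels x
#'   bins (dimnames: participant ids, channel labels, frequencies).
#' @export
cohort_psd <- function(processed, stream_name, window_s = 30, step_s = 5,
                       bin_width_hz = 1) {
  ids <- vapply(processed, function(r) r$participant_id, character(1))
  first <- processed[[1]]$streams[[stream_name]]
  if (is.null(first)) stop("no processed stream '", stream_name, "'")
  probe <- welch_psd(first$data[seq_len(round(window_s * first$fs)), 1],
                     first$fs, bin_width_hz)
  nb <- length(probe$freq)
  nch <- ncol(first$data)
  out <- array(NA_real_, dim = c(length(processed), nch, nb),
               dimnames = list(ids, first$channel_labels, probe$freq))
  for (i in seq_along(processed)) {
    s <- processed[[i]]$streams[[stream_name]]
    ep <- make_epochs(s, window_s, step_s)
    for (ch in seq_len(nch)) {
      acc <- numeric(nb)
      for (k in seq_len(ep$n_epochs)) {
        acc <- acc + welch_psd(ep$data[k, , ch], ep$fs, bin_width_hz)$psd
      }
      out[i, ch, ] <- acc / ep$n_epochs
    }
  }
  list(freq = probe$freq, psd = out)
}
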