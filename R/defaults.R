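#' Standard 27-electrode EEG montage
#'
#' Electrode labels for the 27-channel wet-electrode cap used throughout the
#' package (International 10-20 positions), including the two mastoid
#' reference electrodes TP9 and TP10. After mastoid re-referencing the two
#' reference electrodes are dropped, leaving 25 analysis channels.
#'
#' @return Character vector of 27 electrode labels.
#' @export
eeg_montage <- function() {
  c("Fp1", "F7", "Fz", "F3", "FC5", "T7", "C3", "Cz", "TP9", "CP1",
    "P7", "CP5", "P3", "O1", "FP2", "F8", "F4", "FC6", "T8", "C4",
    "CP2", "TP10", "P8", "CP6", "P4", "Pz", "O2")
}

#' Mastoid reference electrode labels
#' @return Character vector `c("TP9", "TP10")`.
#' @export
mastoid_labels <- function() c("TP9", "TP10")

#' Canonical EEG frequency bands
#'
#' Band edges in Hz; each band is half-open `[lo, hi)` so adjacent bands do
#' not share bins and the Nyquist bin of a 100 Hz stream never enters gamma.
#'
#' @return Named list of `c(lo, hi)` pairs: delta 1-4, theta 4-8, alpha 8-13,
#'   beta 13-30, gamma 30-50 Hz.
#' @export
eeg_bands <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13),
       beta = c(13, 30), gamma = c(30, 50))
}

#' Native sampling rates of the acquisition setup
#'
#' Electrophysiology (EEG, ECG, EOG, GSR, respiration) at 500 Hz, pupil size
#' at 200 Hz, head gyroscope at 110 Hz.
#'
#' @return Named numeric vector of Hz per stream name.
#' @export
native_rates <- function() {
  c(eeg = 500, ecg = 500, eog = 500, gsr = 500, resp = 500,
    pupil = 200, imu_roll = 110)
}

#' Default analysis configuration
#'
#' All numeric settings of the analysis in one serializable list: epoch
#' window and step, common resampling rate, per-modality filter
#' specifications, EEG band edges, and the significance level.
#'
#' @return Named list with elements `window_s` (30), `step_s` (5),
#'   `common_fs` (100), `alpha` (0.05), `bands`, and `filters` (named list of
#'   [filter_spec()] objects keyed by modality).
#' @export
default_config <- function() {
  list(
    window_s = 30,
    step_s = 5,
    common_fs = 100,
    alpha = 0.05,
    bands = eeg_bands(),
    filters = list(
      cardiac = filter_spec("bandpass", c(2, 30)),
      tonic = filter_spec("lowpass", 0.05),
      phasic = filter_spec("highpass", 0.05),
      pupil = filter_spec("lowpass", 50),
      resp = filter_spec("bandpass", c(0.1, 0.5)),
      # nominal 50 Hz low-pass; on the 110 Hz gyroscope stream the effective
      # cutoff is 45 Hz to stay clear of the 55 Hz Nyquist
      roll = filter_spec("lowpass", 45),
      eeg = filter_spec("bandpass", c(0.5, 50)),
      notch = filter_spec("notch", 50)
    )
  )
}
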