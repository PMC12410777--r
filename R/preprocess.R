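#' Bipolar derivation of two electrode channels
#'
#' @param a,b Numeric vectors of equal length (electrode signals).
#' @return `a - b`, elementwise.
#' @export
derive_bipolar <- function(a, b) {
  if (length(a) != length(b)) {
    stop("bipolar derivation needs equal-length channels (", length(a),
         " vs ", length(b), ")")
  }
  a - b
}

#' Re-reference EEG to the mastoid average
#'
#' Subtracts the samplewise mean of TP9 and TP10 from every other channel
#' and drops the two reference electrodes, turning the 27-channel montage
#' into 25 analysis channels.
#'
#' @param eeg Samples x channels matrix with montage column names.
#' @param reference_labels Labels of the reference pair (default TP9/TP10).
#' @return Samples x (channels - 2) matrix.
#' @export
rereference_to_mastoids <- function(eeg, reference_labels = mastoid_labels()) {
  stopifnot(is.matrix(eeg))
  labs <- colnames(eeg)
  if (!all(reference_labels %in% labs)) {
    stop("missing reference electrode(s): ",
         paste(setdiff(reference_labels, labs), collapse = ", "))
  }
  ref <- rowMeans(eeg[, reference_labels, drop = FALSE])
  keep <- setdiff(labs, reference_labels)
  eeg[, keep, drop = FALSE] - ref
}

#' Remove ocular artifacts by EOG regression
#'
#' For each EEG channel, ordinary least squares regresses the channel on
#' the vertical and horizontal EOG traces (with intercept) over the full
#' recording, and the fitted EOG contribution is subtracted. Residual
#' correlation of every output channel with both regressors is zero by
#' construction (up to numerical precision).
#'
#' @param eeg Samples x channels matrix.
#' @param veog,heog Vertical / horizontal EOG regressors, same length.
#' @return Matrix of the same shape with the EOG contribution removed.
#' @export
regress_out_eog <- function(eeg, veog, heog) {
  stopifnot(is.matrix(eeg), nrow(eeg) == length(veog), nrow(eeg) == length(heog))
  if (stats::sd(veog) == 0 && stats::sd(heog) == 0) {
    warning("EOG regressors are constant; EEG passed through unchanged")
    return(eeg)
  }
  X <- cbind(1, veog, heog)
  coefs <- qr.coef(qr(X), eeg) # 3 x channels
  eeg - X[, 2:3, drop = FALSE] %*% coefs[2:3, , drop = FALSE]
}

#' Common average reference
#'
#' Subtracts the instantaneous cross-channel mean from every channel; the
#' cross-channel mean of the output is exactly zero at every sample, and
#' the operation is idempotent (a projection).
#'
#' @param eeg Samples x channels matrix (>= 2 channels).
#' @return Re-referenced matrix of the same shape.
#' @export
common_average_reference <- function(eeg) {
  stopifnot(is.matrix(eeg))
  if (ncol(eeg) < 2) stop("common average reference needs at least 2 channels")
  eeg - rowMeans(eeg)
}

#' Preprocess a recording into the seven analysis streams
#'
#' Applies the per-modality pipeline at each stream's native rate and then
#' resamples everything to the common rate:
#' \itemize{
#'   \item cardiac (`hr_raw`): bipolar ECG derivation, band-pass 2-30 Hz;
#'   \item `tonic`: GSR low-pass 0.05 Hz; `phasic`: GSR high-pass 0.05 Hz;
#'   \item `pupil`: low-pass 50 Hz (both eyes);
#'   \item `resp`: band-pass 0.1-0.5 Hz;
#'   \item `roll`: low-pass (45 Hz effective on the 110 Hz gyroscope);
#'   \item `eeg25`: mastoid re-reference (27 to 25 channels), band-pass
#'     0.5-50 Hz plus 50 Hz notch, EOG regression (bipolar EOG derivations
#'     filtered identically), and finally common average reference.
#' }
#'
#' @param rec An [recording()] with streams `ecg`, `gsr`, `resp`, `pupil`,
#'   `imu_roll`, and optionally `eeg` + `eog` (any subset; only present
#'   modalities are processed, but a modality listed in `require` must
#'   exist).
#' @param config Analysis configuration, see [default_config()].
#' @param require Character vector of stream names that must be present.
#' @return A new `anx_recording` whose streams are the processed ones, all
#'   at `config$common_fs`.
#' @export
preprocess_recording <- function(rec, config = default_config(), require = NULL) {
  stopifnot(inherits(rec, "anx_recording"))
  miss <- setdiff(require, names(rec$streams))
  if (length(miss)) stop("missing required stream(s): ", paste(miss, collapse = ", "))
  fl <- config$filters
  fs100 <- config$common_fs
  out <- list()
  if ("ecg" %in% names(rec$streams)) {
    s <- rec$streams$ecg
    x <- derive_bipolar(s$data[, 1], s$data[, 2])
    x <- zero_phase_filter(x, fl$cardiac, s$fs)
    out$hr_raw <- resample_to_common(stream("hr_raw", s$fs, x, "hr_raw"), fs100)
  }
  if ("gsr" %in% names(rec$streams)) {
    s <- rec$streams$gsr
    tonic <- zero_phase_filter(s$data[, 1], fl$tonic, s$fs)
    phasic <- zero_phase_filter(s$data[, 1], fl$phasic, s$fs)
    out$tonic <- resample_to_common(stream("tonic", s$fs, tonic, "tonic"), fs100)
    out$phasic <- resample_to_common(stream("phasic", s$fs, phasic, "phasic"), fs100)
  }
  if ("pupil" %in% names(rec$streams)) {
    s <- rec$streams$pupil
    x <- zero_phase_filter(s$data, fl$pupil, s$fs)
    out$pupil <- resample_to_common(stream("pupil", s$fs, x, s$channel_labels), fs100)
  }
  if ("resp" %in% names(rec$streams)) {
    s <- rec$streams$resp
    x <- zero_phase_filter(s$data[, 1], fl$resp, s$fs)
    out$resp <- resample_to_common(stream("resp", s$fs, x, "resp"), fs100)
  }
  if ("imu_roll" %in% names(rec$streams)) {
    s <- rec$streams$imu_roll
    x <- zero_phase_filter(s$data[, 1], fl$roll, s$fs)
    out$roll <- resample_to_common(stream("roll", s$fs, x, "roll"), fs100)
  }
  if ("eeg" %in% names(rec$streams)) {
    if (!"eog" %in% names(rec$streams)) stop("EEG present but EOG stream missing")
    s <- rec$streams$eeg
    eeg <- rereference_to_mastoids(s$data)
    eeg <- zero_phase_filter(eeg, fl$eeg, s$fs)
    for (j in seq_len(ncol(eeg))) {
      eeg[, j] <- zero_phase_filter(eeg[, j], fl$notch, s$fs)
    }
    eo <- rec$streams$eog$data
    veog <- derive_bipolar(eo[, "veog_up"], eo[, "veog_lo"])
    heog <- derive_bipolar(eo[, "heog_l"], eo[, "heog_r"])
    veog <- zero_phase_filter(veog, fl$eeg, s$fs)
    heog <- zero_phase_filter(heog, fl$eeg, s$fs)
    eeg <- regress_out_eog(eeg, veog, heog)
    eeg <- common_average_reference(eeg)
    out$eeg25 <- resample_to_common(stream("eeg25", s$fs, eeg, colnames(eeg)), fs100)
  }
  recording(rec$participant_id, out, rec$gad7_pre, rec$gad7_post,
            ground_truth = rec$ground_truth, meta = rec$meta)
}
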