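#' Construct a uniformly sampled signal stream
#'
#' A stream is one named, uniformly sampled multichannel signal: a samples x
#' channels matrix plus its rate and time origin. All streams of a recording
#' share the time origin so multi-device data stay aligned after resampling.
#'
#' @param name Stream name (e.g. "ecg", "eeg", "gsr").
#' @param fs Sampling rate in Hz.
#' @param data Numeric vector (one channel) or samples x channels matrix.
#' @param channel_labels Character vector, one per column of `data`.
#' @param t0 Time of the first sample in seconds (default 0).
#' @return An object of class `anx_stream`.
#' @export
stream <- function(name, fs, data, channel_labels = NULL, t0 = 0) {
  if (is.vector(data)) data <- matrix(data, ncol = 1)
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("stream data must be a numeric vector or matrix")
  }
  if (nrow(data) == 0) stop("stream '", name, "' is empty")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stop("fs must be a positive scalar")
  if (is.null(channel_labels)) {
    channel_labels <- if (ncol(data) == 1) name else paste0(name, seq_len(ncol(data)))
  }
  if (length(channel_labels) != ncol(data)) {
    stop("stream '", name, "': ", length(channel_labels), " channel labels for ",
         ncol(data), " channels")
  }
  colnames(data) <- channel_labels
  structure(list(name = name, fs = fs, t0 = t0,
                 channel_labels = channel_labels, data = data),
            class = "anx_stream")
}

#' @export
print.anx_stream <- function(x, ...) {
  cat(sprintf("<anx_stream '%s'> %d ch x %d samples @ %g Hz (%.1f s)\n",
              x$name, ncol(x$data), nrow(x$data), x$fs, nrow(x$data) / x$fs))
  invisible(x)
}

#' Duration of a stream in seconds
#' @param s An `anx_stream`.
#' @return Seconds spanned by the samples (n / fs).
#' @export
stream_duration <- function(s) nrow(s$data) / s$fs

#' Sample timestamps of a stream
#' @param s An `anx_stream`.
#' @return Numeric vector `t0 + (0:(n-1))/fs`.
#' @export
stream_times <- function(s) s$t0 + (seq_len(nrow(s$data)) - 1) / s$fs

#' Construct a participant recording
#'
#' Bundles a participant's streams with their pre/post questionnaire item
#' scores (seven continuous items each, 0-3 per item) and optional generator
#' ground truth.
#'
#' @param participant_id Identifier string.
#' @param streams Named list of [stream()] objects.
#' @param gad7_pre,gad7_post Numeric vectors of 7 item scores each.
#' @param ground_truth Optional list of generator ground truth (beat times,
#'   tonic trace, EOG traces and gains, clean band powers).
#' @param meta Optional list of generator parameters / provenance.
#' @return An object of class `anx_recording`.
#' @export
recording <- function(participant_id, streams, gad7_pre = NULL, gad7_post = NULL,
                      ground_truth = list(), meta = list()) {
  stopifnot(is.list(streams))
  if (is.null(names(streams)) || any(names(streams) == "")) {
    stop("streams must be a named list")
  }
  for (g in list(gad7_pre, gad7_post)) {
    if (!is.null(g) && length(g) != 7) stop("GAD-7 item vectors must have length 7")
  }
  structure(list(participant_id = participant_id, streams = streams,
                 gad7_pre = gad7_pre, gad7_post = gad7_post,
                 ground_truth = ground_truth, meta = meta),
            class = "anx_recording")
}

#' @export
print.anx_recording <- function(x, ...) {
  cat(sprintf("<anx_recording '%s'> %d streams: %s\n", x$participant_id,
              length(x$streams), paste(names(x$streams), collapse = ", ")))
  invisible(x)
}
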