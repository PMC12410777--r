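# Fourier resampling of one uniformly sampled channel. The signal is
# extended to an even (mirror) extension, so both ends are continuous and
# spectral leakage at the edges stays negligible; the spectrum is then
# truncated (or zero-padded) at the new Nyquist and inverted at the new
# length. Exact for band-limited content: DC is preserved bit-for-bit and a
# sinusoid below both Nyquists keeps its amplitude.
fourier_resample <- function(x, fs, target_fs) {
  n <- length(x)
  m <- round(n * target_fs / fs)
  if (abs(m - n * target_fs / fs) > 1e-8) {
    stop(sprintf("duration %g s is not an integer number of samples at %g Hz",
                 n / fs, target_fs))
  }
  if (m == n) return(x)
  xe <- c(x, rev(x))                       # even extension, length 2n
  X <- stats::fft(xe)
  M <- 2L * m
  Y <- complex(length.out = M)
  half <- min(n - 1L, m - 1L)
  Y[1] <- X[1]
  if (half > 0) {
    Y[2:(half + 1)] <- X[2:(half + 1)]
    Y[(M - half + 1):M] <- X[(2L * n - half + 1):(2L * n)]
  }
  y <- Re(stats::fft(Y, inverse = TRUE)) / (2L * n)
  y[seq_len(m)]
}

#' Resample a stream to the common analysis rate
#'
#' Downsamples every channel to `target_fs` on the shared timebase using
#' Fourier resampling, which is zero-phase and implicitly anti-aliasing
#' (content above the new Nyquist is removed; content below it is preserved
#' in amplitude). A stream already at `target_fs` is returned unchanged, so
#' the operation is idempotent.
#'
#' @param s An [stream()] object with uniform sampling.
#' @param target_fs Target rate in Hz (default 100); must not exceed the
#'   stream's native rate.
#' @return A new `anx_stream` at `target_fs`.
#' @export
resample_to_common <- function(s, target_fs = 100) {
  stopifnot(inherits(s, "anx_stream"))
  if (nrow(s$data) == 0) stop("cannot resample an empty stream")
  if (target_fs > s$fs) {
    stop(sprintf("stream '%s': target rate %g Hz exceeds native rate %g Hz",
                 s$name, target_fs, s$fs))
  }
  if (target_fs == s$fs) return(s)
  out <- apply(s$data, 2, fourier_resample, fs = s$fs, target_fs = target_fs)
  stream(s$name, target_fs, out, s$channel_labels, t0 = s$t0)
}

#' Segment a stream into overlapping epochs
#'
#' Slides a `window_s`-second window in `step_s`-second steps over the
#' stream. Epoch k (1-based) covers the half-open interval
#' `[(k-1)*step_s, (k-1)*step_s + window_s)` seconds, so a 300 s recording
#' at a 30 s window and 5 s step yields 55 epochs and consecutive epochs
#' never share a boundary sample.
#'
#' @param s An [stream()] object (any rate; typically the 100 Hz common rate).
#' @param window_s Window length in seconds (default 30).
#' @param step_s Step between epoch starts in seconds (default 5).
#' @return An `anx_epochs` object: list with `window_s`, `step_s`, `fs`,
#'   `n_epochs`, `starts_s`, `channel_labels`, and `data`, an array of
#'   dimension n_epochs x samples-per-window x channels.
#' @export
make_epochs <- function(s, window_s = 30, step_s = 5) {
  stopifnot(inherits(s, "anx_stream"))
  dur <- stream_duration(s)
  if (dur < window_s) {
    stop(sprintf("stream '%s' lasts %.3f s, shorter than the %g s analysis window",
                 s$name, dur, window_s))
  }
  spw <- round(window_s * s$fs)
  sps <- step_s * s$fs
  n_epochs <- as.integer(floor((dur - window_s) / step_s + 1e-9)) + 1L
  nch <- ncol(s$data)
  arr <- array(NA_real_, dim = c(n_epochs, spw, nch))
  for (k in seq_len(n_epochs)) {
    i0 <- round((k - 1) * sps)
    arr[k, , ] <- s$data[(i0 + 1):(i0 + spw), , drop = FALSE]
  }
  structure(list(window_s = window_s, step_s = step_s, fs = s$fs,
                 n_epochs = n_epochs, starts_s = (seq_len(n_epochs) - 1) * step_s,
                 channel_labels = s$channel_labels, data = arr),
            class = "anx_epochs")
}

#' @export
print.anx_epochs <- function(x, ...) {
  cat(sprintf("<anx_epochs> %d epochs of %g s (step %g s) x %d ch @ %g Hz\n",
              x$n_epochs, x$window_s, x$step_s, dim(x$data)[3], x$fs))
  invisible(x)
}

#' Extract one epoch as a samples x channels matrix
#' @param ep An `anx_epochs` object.
#' @param k Epoch index (1-based).
#' @return Numeric matrix samples x channels.
#' @export
epoch_matrix <- function(ep, k) {
  m <- ep$data[k, , , drop = TRUE]
  if (is.null(dim(m))) m <- matrix(m, ncol = 1)
  colnames(m) <- ep$channel_labels
  m
}
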