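#' Specify a zero-phase filter
#'
#' Filters are described declaratively and realized at apply time for the
#' stream's sampling rate, so one specification serves streams at different
#' native rates. All filters in this package are zero-phase: the designed
#' IIR filter is applied forward and backward over a reflection-padded
#' signal, which squares the magnitude response and cancels the phase.
#'
#' @param kind One of "lowpass", "highpass", "bandpass", "notch".
#' @param cutoffs_hz One cutoff (lowpass/highpass/notch centre) or two
#'   ascending cutoffs (bandpass), in Hz.
#' @param order Butterworth order (default 4; ignored for notch, which is a
#'   second-order section with quality factor `q`).
#' @param q Notch quality factor (default 30).
#' @return An object of class `anx_filter_spec`.
#' @export
filter_spec <- function(kind = c("lowpass", "highpass", "bandpass", "notch"),
                        cutoffs_hz, order = 4, q = 30) {
  kind <- match.arg(kind)
  cutoffs_hz <- as.numeric(cutoffs_hz)
  nc <- if (kind == "bandpass") 2L else 1L
  if (length(cutoffs_hz) != nc) {
    stop(kind, " filter needs ", nc, " cutoff(s), got ", length(cutoffs_hz))
  }
  if (any(cutoffs_hz <= 0)) stop("cutoffs must be positive")
  if (kind == "bandpass" && diff(cutoffs_hz) <= 0) stop("bandpass cutoffs must ascend")
  structure(list(kind = kind, cutoffs_hz = cutoffs_hz, order = order,
                 q = q, zero_phase = TRUE),
            class = "anx_filter_spec")
}

#' @export
print.anx_filter_spec <- function(x, ...) {
  cat(sprintf("<anx_filter_spec> %s %s Hz (order %d, zero-phase)\n",
              x$kind, paste(x$cutoffs_hz, collapse = "-"), x$order))
  invisible(x)
}

# Butterworth design as cascaded second-order sections via bilinear
# transform. Transfer-function (b, a) realizations of high-order designs are
# numerically unusable at the very low normalized cutoffs this pipeline
# needs (0.05 Hz at 500 Hz); biquad cascades are stable there.
butter_sos <- function(kind, cutoffs_hz, order, fs) {
  if (any(cutoffs_hz >= fs / 2)) {
    stop(sprintf("cutoff %g Hz is at or above the Nyquist frequency (%g Hz)",
                 max(cutoffs_hz), fs / 2))
  }
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order)) # LHP prototype poles
  w <- tan(pi * cutoffs_hz / fs)                            # prewarped
  if (kind == "lowpass") {
    apoles <- w * proto
  } else if (kind == "highpass") {
    apoles <- w / proto
  } else if (kind == "bandpass") {
    B <- w[2] - w[1]
    w0sq <- w[1] * w[2]
    apoles <- unlist(lapply(proto, function(p) {
      disc <- sqrt((p * B)^2 / 4 - w0sq + 0i)
      c(p * B / 2 + disc, p * B / 2 - disc)
    }))
  } else stop("unsupported kind: ", kind)
  zpoles <- (1 + apoles) / (1 - apoles)
  # pair conjugate poles into biquads
  zpoles <- zpoles[order(Re(zpoles), abs(Im(zpoles)))]
  used <- rep(FALSE, length(zpoles))
  sections <- list()
  for (i in seq_along(zpoles)) {
    if (used[i]) next
    used[i] <- TRUE
    j <- which(!used & Mod(zpoles - Conj(zpoles[i])) < 1e-9)[1]
    if (!is.na(j)) {
      used[j] <- TRUE
      a <- c(1, -Re(zpoles[i] + zpoles[j]), Re(zpoles[i] * zpoles[j]))
    } else {
      a <- c(1, -Re(zpoles[i]), 0)
    }
    sections[[length(sections) + 1]] <- list(a = a)
  }
  nsec <- length(sections)
  zero_at <- switch(kind,
    lowpass = rep(-1, 2 * nsec),
    highpass = rep(1, 2 * nsec),
    bandpass = rep(c(1, -1), nsec))
  for (i in seq_len(nsec)) {
    z1 <- zero_at[2 * i - 1]; z2 <- zero_at[2 * i]
    sections[[i]]$b <- c(1, -(z1 + z2), z1 * z2)
  }
  # unit gain at a reference frequency inside the passband
  fref <- switch(kind, lowpass = 0, highpass = fs / 2,
                 bandpass = sqrt(prod(cutoffs_hz)))
  zref <- exp(-1i * 2 * pi * fref / fs)
  g <- 1 + 0i
  for (s in sections) {
    g <- g * sum(s$b * zref^(0:2)) / sum(s$a * zref^(0:2))
  }
  sections[[1]]$b <- sections[[1]]$b / Mod(g)
  sections
}

# Second-order IIR notch (constrained pole-zero placement), quality factor q.
notch_sos <- function(f0, fs, q = 30) {
  if (f0 >= fs / 2) {
    stop(sprintf("notch frequency %g Hz is at or above the Nyquist frequency (%g Hz)",
                 f0, fs / 2))
  }
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  list(list(b = b, a = a))
}

filter_sections <- function(spec, fs) {
  if (spec$kind == "notch") notch_sos(spec$cutoffs_hz, fs, spec$q)
  else butter_sos(spec$kind, spec$cutoffs_hz, spec$order, fs)
}

sos_apply <- function(sections, x) {
  for (s in sections) x <- as.numeric(signal::filter(s$b, s$a, x))
  x
}

# Reflection-pad length: several times the settling constant of the slowest
# pole, which scales with the inverse of the lowest cutoff frequency.
pad_samples <- function(spec, fs, n) {
  flo <- min(spec$cutoffs_hz)
  pad <- ceiling(fs * max(1, 4 / flo))
  min(pad, n - 1L)
}

#' Apply a zero-phase filter
#'
#' Realizes `spec` as a cascade of second-order sections at the given rate
#' and applies it forward and backward (zero phase, squared magnitude). The
#' signal is extended by end-point reflection before filtering and the mean
#' is removed first (and restored for mean-preserving kinds), which removes
#' start-up transients: a constant signal passes a low-pass exactly and maps
#' to exactly zero under a high-pass.
#'
#' @param x Numeric vector or samples x channels matrix.
#' @param spec An [filter_spec()] object.
#' @param fs Sampling rate of `x` in Hz.
#' @return Filtered signal, same shape as `x`.
#' @export
zero_phase_filter <- function(x, spec, fs) {
  stopifnot(inherits(spec, "anx_filter_spec"))
  if (any(spec$cutoffs_hz >= fs / 2)) {
    stop(sprintf("filter cutoff %g Hz not below Nyquist (%g Hz) at fs = %g Hz",
                 max(spec$cutoffs_hz), fs / 2, fs))
  }
  if (is.matrix(x)) {
    out <- x
    for (j in seq_len(ncol(x))) out[, j] <- zero_phase_filter(x[, j], spec, fs)
    return(out)
  }
  n <- length(x)
  if (n < 4) stop("signal too short to filter")
  sections <- filter_sections(spec, fs)
  keep_mean <- spec$kind %in% c("lowpass", "notch")
  mu <- mean(x)
  xc <- x - mu
  npad <- pad_samples(spec, fs, n)
  xp <- c(2 * xc[1] - xc[(npad + 1):2], xc, 2 * xc[n] - xc[(n - 1):(n - npad)])
  y <- sos_apply(sections, xp)
  y <- rev(sos_apply(sections, rev(y)))
  y <- y[(npad + 1):(npad + n)]
  if (keep_mean) y + mu else y
}
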