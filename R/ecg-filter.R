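#' Single-lead ECG signal container
#'
#' @param samples numeric sample vector (raw ADC units or mV).
#' @param fs sampling rate in Hz.
#' @param role `"experimental"` (chair electrodes) or `"reference"`
#'   (pre-gelled electrodes).
#' @return object of class `ecg_signal`.
#' @export
ecg_signal <- function(samples, fs, role = c("experimental", "reference")) {
  role <- match.arg(role)
  if (!is.numeric(fs) || fs <= 0) stop_sc("fs must be > 0")
  structure(list(samples = as.numeric(samples), fs = fs, role = role),
            class = "ecg_signal")
}

#' @export
print.ecg_signal <- function(x, ...) {
  cat(sprintf("<ecg_signal> %s, n=%d, fs=%g Hz (%.1f s)\n", x$role,
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

as_ecg <- function(x, fs = NULL, role = "experimental") {
  if (inherits(x, "ecg_signal")) x else ecg_signal(x, fs, role)
}

# Hamming-windowed linear-phase band-pass design; order taps + 1
# coefficients, unit gain at the passband centre.
fir_bandpass_design <- function(order, band, fs) {
  if (order %% 2 != 0) order <- order + 1  # even order -> symmetric, type I
  n <- 0:order
  m <- order / 2
  f1 <- band[1] / fs
  f2 <- band[2] / fs
  h <- ifelse(n == m, 2 * (f2 - f1),
              (sin(2 * pi * f2 * (n - m)) - sin(2 * pi * f1 * (n - m))) /
                (pi * (n - m)))
  w <- 0.54 - 0.46 * cos(2 * pi * n / order)
  h <- h * w
  h <- h - mean(h)  # exact null at DC (window leakage otherwise ~ -14 dB)
  fc <- mean(band) / fs
  gain <- Mod(sum(h * exp(-2i * pi * fc * n)))
  h / gain
}

# Causal FIR filtering via FFT convolution.
fir_apply <- function(x, h) {
  z <- stats::convolve(x, rev(h), type = "open")
  z[seq_along(x)]
}

#' Zero-phase FIR band-pass filter
#'
#' Linear-phase Hamming-window FIR band-pass of the given order, applied
#' forward and backward so the net group delay is zero (all processing is
#' offline). Output length equals input length; edge transients are
#' absorbed by odd-reflection padding of length `3 * (order + 1)`.
#'
#' @param sig an [ecg_signal()] or numeric vector.
#' @param order filter order (default 150).
#' @param band passband in Hz (default `c(3, 45)`, the QRS-preserving
#'   range).
#' @param fs sampling rate, required when `sig` is a bare vector.
#' @return filtered signal, same class as the input.
#' @export
bandpass_fir <- function(sig, order = 150, band = c(3, 45), fs = NULL) {
  s <- as_ecg(sig, fs)
  if (s$fs <= 2 * band[2]) {
    stop_sc("fs = %g Hz cannot represent the %g Hz band edge", s$fs, band[2])
  }
  x <- s$samples
  p <- 3L * (order + 1L)
  if (length(x) < p) {
    stop_sc("signal too short for order-%d filtering (%d < %d samples)",
            order, length(x), p)
  }
  h <- fir_bandpass_design(order, band, s$fs)
  n <- length(x)
  ext <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  y <- fir_apply(ext, h)
  y <- rev(fir_apply(rev(y), h))
  y <- y[(p + 1):(p + n)]
  if (inherits(sig, "ecg_signal")) {
    out <- sig
    out$samples <- y
    out
  } else y
}
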