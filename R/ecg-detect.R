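#' Hamilton-style R-peak detection
#'
#' Classical QRS detection pipeline implemented from scratch: band-limit to
#' the QRS band (8-16 Hz), differentiate, rectify, smooth with an ~80 ms
#' centred moving window, then pick peaks with an adaptive detection
#' threshold maintained from running QRS-peak and noise-peak buffers
#' (length 8), a 200 ms refractory period, and a search-back pass that
#' rescues beats whenever an inter-peak interval exceeds 1.5x the running
#' average RR. Detected positions are refined to the local extremum of the
#' 3-45 Hz filtered signal within +/- 40 ms.
#'
#' @param sig an [ecg_signal()] or numeric vector (raw or filtered).
#' @param fs sampling rate, required for bare vectors; must be >= 100 Hz.
#' @param threshold_coef detection threshold position between the noise and
#'   QRS running means (default 0.3125).
#' @param refractory_ms dead time after an accepted beat (default 200).
#' @param searchback_factor RR multiple that triggers search-back
#'   (default 1.5).
#' @param buffer_len length of the running peak/noise/RR buffers
#'   (default 8).
#' @return increasing integer vector of R-peak sample indices (1-based);
#'   empty when no QRS-like activity is found.
#' @export
detect_rpeaks <- function(sig, fs = NULL, threshold_coef = 0.3125,
                          refractory_ms = 200, searchback_factor = 1.5,
                          buffer_len = 8L) {
  s <- as_ecg(sig, fs)
  fs <- s$fs
  if (fs < 100) stop_sc("fs = %g Hz too low to resolve QRS (< 100 Hz)", fs)
  x <- s$samples
  if (length(x) < 2 * fs) stop_sc("need at least 2 s of signal")
  if (all(x == x[1])) return(integer(0))

  # feature signal: 8-16 Hz band, derivative, rectify, 80 ms centred MA
  ord <- min(150L, 2L * (floor(length(x) / 6) - 1L))
  bp <- bandpass_fir(x, order = ord, band = c(8, 16), fs = fs)
  dx <- abs(c(0, diff(bp)))
  w <- max(3L, round(0.08 * fs))
  if (w %% 2 == 0) w <- w + 1L
  ma <- as.numeric(stats::filter(dx, rep(1 / w, w), sides = 2))
  ma[is.na(ma)] <- 0

  n <- length(ma)
  pk <- which(diff(sign(diff(ma))) < 0) + 1L  # local maxima
  pk <- pk[ma[pk] > 0]
  if (!length(pk)) return(integer(0))
  refr <- round(refractory_ms / 1000 * fs)
  # non-maximum suppression: a candidate must dominate its own
  # refractory-wide neighbourhood, so satellite bumps (P/T energy) do not
  # pre-empt the QRS peak
  pk <- pk[vapply(pk, function(p) {
    lo <- max(1L, as.integer(p - refr))
    hi <- min(n, as.integer(p + refr))
    ma[p] >= max(ma[lo:hi])
  }, logical(1))]
  if (!length(pk)) return(integer(0))
  init <- seq_len(min(2L * round(fs), n))
  qbuf <- max(ma[init])
  nbuf <- mean(ma[init])
  rrbuf <- numeric(0)
  qrs <- integer(0)

  push <- function(buf, v) c(tail(buf, buffer_len - 1L), v)
  for (p in pk) {
    thr <- mean(nbuf) + threshold_coef * (mean(qbuf) - mean(nbuf))
    is_beat <- ma[p] > thr &&
      (!length(qrs) || p - qrs[length(qrs)] > refr)
    if (is_beat) {
      if (length(qrs)) {
        rr <- p - qrs[length(qrs)]
        if (length(rrbuf) && rr > searchback_factor * mean(rrbuf)) {
          # search-back: the largest missed peak above half threshold
          gap <- pk[pk > qrs[length(qrs)] + refr & pk < p - refr]
          if (length(gap)) {
            cand <- gap[which.max(ma[gap])]
            if (ma[cand] > 0.5 * thr) {
              qrs <- c(qrs, cand)
              qbuf <- push(qbuf, ma[cand])
              rr <- p - cand
            }
          }
        }
        rrbuf <- push(rrbuf, rr)
      }
      qrs <- c(qrs, p)
      qbuf <- push(qbuf, ma[p])
    } else if (!length(qrs) || p - qrs[length(qrs)] > refr) {
      # sub-threshold and outside the refractory window: noise estimate
      nbuf <- push(nbuf, ma[p])
    }
  }
  if (!length(qrs)) return(integer(0))

  # refine each detection to the dominant deflection of the 3-45 Hz signal
  wide <- bandpass_fir(x, order = ord, band = c(3, 45), fs = fs)
  half <- round(0.04 * fs)
  ref <- vapply(qrs, function(p) {
    lo <- max(1L, as.integer(p - half))
    hi <- min(length(wide), as.integer(p + half))
    lo + which.max(abs(wide[lo:hi])) - 1L
  }, integer(1))
  ref <- sort(unique(ref))
  # enforce refractory after refinement
  if (length(ref) > 1L) {
    keep <- c(TRUE, diff(ref) > refr)
    ref <- ref[keep]
  }
  sc_log("detect_rpeaks: %d beats in %.1f s", length(ref), length(x) / fs)
  ref
}
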