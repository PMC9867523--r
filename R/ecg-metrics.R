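#' Segment fixed-length heartbeat waveforms
#'
#' Cuts one window around every R-peak. Beats whose window would cross a
#' signal boundary are dropped (and logged); all retained beats have equal
#' length `round((pre_ms + post_ms) / 1000 * fs)`.
#'
#' @param sig an [ecg_signal()] or numeric vector.
#' @param rpeaks increasing R-peak sample indices.
#' @param window `c(pre_ms, post_ms)` window extent around the R-peak;
#'   default 200 ms before to 400 ms after.
#' @param fs sampling rate for bare vectors.
#' @return object of class `beat_matrix`: `beats` (n x L matrix),
#'   `r_indices` (original sample index of each retained beat), `window`,
#'   `fs`, `r_offset` (column of the R sample within a beat).
#' @export
segment_beats <- function(sig, rpeaks, window = c(200, 400), fs = NULL) {
  s <- as_ecg(sig, fs)
  if (is.unsorted(rpeaks, strictly = TRUE)) {
    stop_sc("rpeaks must be strictly increasing")
  }
  pre <- round(window[1] / 1000 * s$fs)
  len <- round(sum(window) / 1000 * s$fs)
  starts <- rpeaks - pre
  ok <- starts >= 1 & starts + len - 1 <= length(s$samples)
  if (any(!ok)) {
    sc_log("segment_beats: %d boundary beat(s) dropped", sum(!ok))
  }
  kept <- rpeaks[ok]
  beats <- t(vapply(starts[ok], function(st) {
    s$samples[st:(st + len - 1)]
  }, numeric(len)))
  if (!sum(ok)) beats <- matrix(numeric(0), 0, len)
  structure(list(beats = beats, r_indices = kept, window = window,
                 fs = s$fs, r_offset = pre + 1L),
            class = "beat_matrix")
}

#' @export
print.beat_matrix <- function(x, ...) {
  cat(sprintf("<beat_matrix> %d beats x %d samples (%g ms pre, %g ms post)\n",
              nrow(x$beats), ncol(x$beats), x$window[1], x$window[2]))
  invisible(x)
}

#' Heart rate from R-peak intervals
#'
#' Computes `bpm = 60 * fs / RR` for every pair of *consecutive* retained
#' peaks. When `rpeaks` carries chain bookkeeping from [apply_mask()],
#' intervals spanning a removed beat are not used. Physiologically
#' implausible intervals (outside 40-200 bpm) are excluded and logged.
#'
#' @param rpeaks increasing R-peak indices, or the object returned by
#'   [apply_mask()].
#' @param fs sampling rate in Hz.
#' @param bpm_range plausibility bounds, default `c(40, 200)`.
#' @return list with `bpm` (per-interval values), `mean`, `sd` and
#'   `n_excluded`; all empty/NA when fewer than two consecutive peaks
#'   exist.
#' @export
heart_rate <- function(rpeaks, fs, bpm_range = c(40, 200)) {
  if (is.list(rpeaks)) {
    idx <- rpeaks$rpeaks
    chain <- rpeaks$chain
  } else {
    idx <- rpeaks
    chain <- rep(1L, length(idx))
  }
  if (length(idx) < 2) {
    return(list(bpm = numeric(0), mean = NA_real_, sd = NA_real_,
                n_excluded = 0L))
  }
  consec <- diff(chain) == 0L
  rr <- diff(idx)[consec]
  bpm <- 60 * fs / rr
  keep <- bpm >= bpm_range[1] & bpm <= bpm_range[2]
  if (any(!keep)) {
    sc_log("heart_rate: %d implausible interval(s) excluded", sum(!keep))
  }
  bpm <- bpm[keep]
  list(bpm = bpm,
       mean = if (length(bpm)) mean(bpm) else NA_real_,
       sd = if (length(bpm) > 1) stats::sd(bpm) else NA_real_,
       n_excluded = sum(!keep))
}

#' Match experimental against reference R-peaks
#'
#' Greedy one-to-one nearest matching within a tolerance: candidate pairs
#' are ordered by absolute time difference and accepted while both peaks
#' are unmatched. Unmatched experimental peaks count as false positives,
#' unmatched reference peaks as false negatives.
#'
#' @param ref,exp increasing R-peak indices of the reference and
#'   experimental signals.
#' @param tol_ms matching tolerance in milliseconds (default 100).
#' @param fs sampling rate in Hz.
#' @return object of class `match_result` with `TP`, `FP`, `FN`, `N_ref`
#'   and the matched index pairs.
#' @export
match_rpeaks <- function(ref, exp, tol_ms = 100, fs) {
  if (is.unsorted(ref) || is.unsorted(exp)) {
    stop_sc("peak index lists must be increasing")
  }
  tol <- tol_ms / 1000 * fs
  pairs <- NULL
  if (length(ref) && length(exp)) {
    dt <- abs(outer(ref, exp, "-"))
    cand <- which(dt <= tol, arr.ind = TRUE)
    if (nrow(cand)) {
      ord <- order(dt[cand], cand[, 1], cand[, 2])
      cand <- cand[ord, , drop = FALSE]
      used_r <- logical(length(ref))
      used_e <- logical(length(exp))
      keep <- logical(nrow(cand))
      for (i in seq_len(nrow(cand))) {
        r <- cand[i, 1]; e <- cand[i, 2]
        if (!used_r[r] && !used_e[e]) {
          used_r[r] <- used_e[e] <- TRUE
          keep[i] <- TRUE
        }
      }
      pairs <- cand[keep, , drop = FALSE]
    }
  }
  tp <- if (is.null(pairs)) 0L else nrow(pairs)
  structure(list(TP = tp, FP = length(exp) - tp, FN = length(ref) - tp,
                 N_ref = length(ref), pairs = pairs),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> TP=%d FP=%d FN=%d (N_ref=%d)\n", x$TP, x$FP,
              x$FN, x$N_ref))
  invisible(x)
}

#' R-peak detection performance and accuracy
#'
#' \deqn{Performance(\%) = 100 \cdot TP / N_{R\mathrm{-}peaks,REF}}
#' \deqn{Accuracy(\%) = 100 \cdot TP / (TP + FP)}
#' Accuracy is reported as `NA` (absent, not zero) when no peaks were
#' detected at all.
#'
#' @param m a [match_rpeaks()] result.
#' @return list with `performance` and `accuracy`, both in percent.
#' @export
performance_accuracy <- function(m) {
  stopifnot(inherits(m, "match_result"))
  if (m$N_ref == 0) stop_sc("reference signal has no R-peaks")
  list(performance = 100 * m$TP / m$N_ref,
       accuracy = if (m$TP + m$FP == 0) NA_real_
                  else 100 * m$TP / (m$TP + m$FP))
}

#' SNR and cosine similarity between experimental and reference signals
#'
#' The reference is first amplitude-scaled to the experimental signal by
#' least squares (`alpha = <exp, ref> / <ref, ref>`); then
#' `SNR = 10 log10(sum((alpha ref)^2) / sum((exp - alpha ref)^2))` in dB,
#' capped at 100 dB for (near-)identical signals, and the cosine
#' similarity is `<exp, alpha ref> / (|exp| |alpha ref|)`.
#'
#' @param exp,ref equal-length [ecg_signal()]s or numeric vectors at the
#'   same rate (align/resample upstream).
#' @param snr_cap sentinel for a zero-residual comparison (default 100 dB).
#' @return list with `snr_db`, `cosine` and `alpha` (the fitted scale).
#' @export
compare_signals <- function(exp, ref, snr_cap = 100) {
  e <- if (inherits(exp, "ecg_signal")) exp$samples else exp
  r <- if (inherits(ref, "ecg_signal")) ref$samples else ref
  if (length(e) != length(r)) stop_sc("signals must have equal length")
  if (sum(e^2) == 0 || sum(r^2) == 0) stop_sc("zero-norm input signal")
  alpha <- sum(e * r) / sum(r * r)
  sr <- alpha * r
  resid <- sum((e - sr)^2)
  snr <- if (resid <= .Machine$double.eps * sum(sr^2)) snr_cap
         else min(snr_cap, 10 * log10(sum(sr^2) / resid))
  cosine <- sum(e * sr) / sqrt(sum(e^2) * sum(sr^2))
  list(snr_db = snr, cosine = cosine, alpha = alpha)
}

#' R-peak amplitude over a beat matrix
#'
#' Amplitude of a beat is its value at the R sample minus the beat's
#' baseline, estimated as the median of the first 40 ms of the window
#' (iso-electric segment before the QRS).
#'
#' @param beats a [segment_beats()] result with at least one beat.
#' @param scale optional units-conversion factor (e.g. ADC-to-mV).
#' @return list with `amplitudes`, `mean` and `sd` (input units times
#'   `scale`).
#' @export
r_amplitude <- function(beats, scale = 1) {
  stopifnot(inherits(beats, "beat_matrix"))
  if (nrow(beats$beats) == 0L) stop_sc("beat matrix is empty")
  nb <- max(1L, round(0.04 * beats$fs))
  base <- apply(beats$beats[, seq_len(nb), drop = FALSE], 1, stats::median)
  amp <- (beats$beats[, beats$r_offset] - base) * scale
  list(amplitudes = amp, mean = mean(amp),
       sd = if (length(amp) > 1) stats::sd(amp) else 0)
}
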