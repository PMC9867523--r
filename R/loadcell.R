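#' Repair over-capacity readings
#'
#' Replaces extreme outliers (readings above the cell's rated capacity or
#' non-finite samples) with the most recent valid reading. Leading invalid
#' samples, for which no previous valid reading exists, are backfilled from
#' the first valid one. Output length equals input length and the operation
#' is idempotent.
#'
#' @param series numeric weight sequence in grams.
#' @param max_capacity_g rated cell capacity in grams; values strictly above
#'   it are treated as invalid.
#' @return repaired numeric vector, every value `<= max_capacity_g`.
#' @export
#' @examples
#' repair_extreme_outliers(c(100, 200, 9e9, 300), 50000)
repair_extreme_outliers <- function(series, max_capacity_g = 50000) {
  if (!length(series)) stop_sc("empty series")
  valid <- is.finite(series) & series <= max_capacity_g
  if (!any(valid)) {
    stop_sc("all %d samples are invalid; no valid reference value exists",
            length(series))
  }
  if (all(valid)) return(series)
  n_bad <- sum(!valid)
  idx <- ifelse(valid, seq_along(series), NA_integer_)
  # forward-fill index of last valid sample
  idx <- cummax(ifelse(is.na(idx), 0L, idx))
  first_valid <- which(valid)[1]
  idx[idx == 0L] <- first_valid
  out <- series[idx]
  sc_log("repair_extreme_outliers: replaced %d/%d samples", n_bad,
         length(series))
  out
}

#' Moving-average smoothing with 1-s non-overlapping windows
#'
#' Averages consecutive windows of `fs` samples, smoothing jitter and
#' downsampling to one value per second. The trailing partial window is
#' discarded.
#'
#' @param series numeric sequence sampled at `fs` Hz.
#' @param fs sampling rate in Hz (>= 1). Non-integer rates are floored to an
#'   integer window length, with a log notice.
#' @return numeric vector of length `floor(length(series) / floor(fs))`.
#' @export
smooth_downsample <- function(series, fs) {
  if (fs < 1) stop_sc("fs must be >= 1 (got %g)", fs)
  win <- floor(fs)
  if (win != fs) sc_log("smooth_downsample: window floored to %d samples", win)
  if (length(series) < win) {
    stop_sc("series shorter than one window (%d < %d)", length(series), win)
  }
  n_out <- floor(length(series) / win)
  m <- matrix(series[seq_len(n_out * win)], nrow = win)
  out <- colMeans(m)
  sc_log("smooth_downsample: %d samples -> %d windows", length(series), n_out)
  out
}

#' Center of mass in the seat plane
#'
#' Maps the three weight readings to the 2-D balance point of the seated
#' load:
#' \deqn{CM_x = (d_{RL} LB + d_{RF} F) / (RB + LB + F)}
#' \deqn{CM_y = d_{BF} F / (RB + LB + F)}
#' in the frame with origin at the RB cell.
#'
#' @param F,LB,RB weights (grams) at the front, left-back and right-back
#'   cells; vectors of equal length are accepted.
#' @param geometry a [chair_geometry()].
#' @return data.frame with columns `CMx`, `CMy` (cm).
#' @export
#' @examples
#' compute_cm(20000, 15000, 25000, chair_geometry())
compute_cm <- function(F, LB, RB, geometry = chair_geometry()) {
  tot <- F + LB + RB
  if (any(tot <= 0)) {
    stop_sc("unoccupied chair: total weight <= 0 in %d window(s)",
            sum(tot <= 0))
  }
  data.frame(CMx = (geometry$dRL * LB + geometry$dRF * F) / tot,
             CMy = (geometry$dBF * F) / tot)
}

#' Split a session into labeled static bouts
#'
#' The pushbutton channel goes HIGH at the start and at the end of each
#' static sitting bout. Press onsets (0 -> 1 transitions) are paired in
#' order: odd presses open a bout, even presses close it. Samples between
#' bouts form the transition periods.
#'
#' @param button 0/1 vector at the load-cell sampling rate.
#' @param labels posture labels, one per bout, in temporal order.
#' @return data.frame with columns `start`, `end`, `label`; `start` is the
#'   1-based sample index of the opening press onset and the bout covers the
#'   half-open interval `[start, end)`.
#' @export
split_static_bouts <- function(button, labels) {
  if (!all(button %in% c(0, 1))) stop_sc("button channel must be 0/1")
  onsets <- which(diff(c(0, button)) == 1)
  if (length(onsets) %% 2L != 0L) {
    stop_sc("odd number of button presses (%d); bouts must be start/end pairs",
            length(onsets))
  }
  n_bouts <- length(onsets) %/% 2L
  if (n_bouts == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      label = character(0)))
  }
  if (length(labels) < n_bouts) {
    stop_sc("%d bouts found but only %d labels supplied", n_bouts,
            length(labels))
  }
  data.frame(start = onsets[seq(1, by = 2, length.out = n_bouts)],
             end = onsets[seq(2, by = 2, length.out = n_bouts)],
             label = as.character(labels[seq_len(n_bouts)]),
             stringsAsFactors = FALSE)
}

#' Full load-cell feature pipeline
#'
#' Runs repair -> bout splitting -> per-bout 1-s smoothing -> center-of-mass
#' computation, producing one labeled `(CMx, CMy)` feature vector per second
#' of static sitting. Windows are aligned to bout starts, so a 60-s bout
#' yields exactly 60 windows. Transition periods between bouts are returned
#' too (label `NA`, segment `"T<k>"`) so classifier behaviour during
#' position changes can be analysed.
#'
#' @param stream a [session_stream()] with `F_g`, `LB_g`, `RB_g` and
#'   `button` channels.
#' @param labels posture label per bout, temporal order.
#' @param geometry a [chair_geometry()].
#' @param include_transitions keep transition-period windows (label `NA`)?
#' @return data.frame of class `cm_dataset`: `window_index`, `CMx`, `CMy`,
#'   `label`, `segment` (`"B<k>"` for bout k, `"T<k>"` for the transition
#'   after bout k).
#' @export
extract_cm_dataset <- function(stream, labels, geometry = chair_geometry(),
                               include_transitions = FALSE) {
  stopifnot(inherits(stream, "session_stream"))
  ch <- stream$channels
  need <- c("F_g", "LB_g", "RB_g", "button")
  if (!all(need %in% names(ch))) {
    stop_sc("stream lacks channel(s): %s",
            paste(setdiff(need, names(ch)), collapse = ", "))
  }
  fs <- stream$fs_loadcell
  rep_ch <- lapply(ch[c("F_g", "LB_g", "RB_g")], repair_extreme_outliers,
                   max_capacity_g = geometry$max_capacity_g)
  bouts <- split_static_bouts(ch$button, labels)
  if (nrow(bouts) == 0L) stop_sc("no bouts found in session")

  segment_cm <- function(from, to, seg, lab) {
    len <- to - from
    if (len < floor(fs)) return(NULL)
    sm <- lapply(rep_ch, function(v) smooth_downsample(v[from:(to - 1)], fs))
    tot <- sm$F_g + sm$LB_g + sm$RB_g
    occ <- tot > 0
    if (!all(occ)) sc_log("segment %s: %d unoccupied window(s) dropped",
                          seg, sum(!occ))
    if (!any(occ)) return(NULL)
    cm <- compute_cm(sm$F_g[occ], sm$LB_g[occ], sm$RB_g[occ], geometry)
    cm$label <- lab
    cm$segment <- seg
    cm$window_index <- which(occ) - 1L
    cm
  }

  out <- list()
  for (i in seq_len(nrow(bouts))) {
    out[[length(out) + 1L]] <-
      segment_cm(bouts$start[i], bouts$end[i], paste0("B", i),
                 bouts$label[i])
    if (include_transitions && i < nrow(bouts)) {
      out[[length(out) + 1L]] <-
        segment_cm(bouts$end[i], bouts$start[i + 1], paste0("T", i),
                   NA_character_)
    }
  }
  res <- do.call(rbind, out)
  res <- res[, c("window_index", "CMx", "CMy", "label", "segment")]
  rownames(res) <- NULL
  attr(res, "bout_labels") <- bouts$label
  class(res) <- c("cm_dataset", "data.frame")
  sc_log("extract_cm_dataset: %d windows from %d bouts", nrow(res),
         nrow(bouts))
  res
}
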