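# Synthetic posture sessions and ECG signals with ground truth, so every
# pipeline stage is testable at desk scale without subject recordings.

#' Per-posture center-of-mass cluster statistics
#'
#' Loads the packaged per-class CM statistics (mean, SD, min, max on each
#' axis, in cm, for P1-P8) measured on the reference chair, or a
#' user-supplied file with the same columns.
#'
#' @param path CSV with columns `class, mean_x, sd_x, max_x, min_x,
#'   mean_y, sd_y, max_y, min_y`; `NULL` loads the packaged fixture.
#' @return data.frame of class `posture_stats`, row-named by class.
#' @export
posture_stats <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "posture_cm_stats.csv",
                        package = "smartchair", mustWork = TRUE)
  }
  st <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("class", "mean_x", "sd_x", "max_x", "min_x", "mean_y", "sd_y",
            "max_y", "min_y")
  if (!all(need %in% names(st))) {
    stop_sc("stats file lacks column(s): %s",
            paste(setdiff(need, names(st)), collapse = ", "))
  }
  bad <- with(st, min_x > mean_x | mean_x > max_x | min_y > mean_y |
                mean_y > max_y | sd_x <= 0 | sd_y <= 0)
  if (any(bad)) stop_sc("inconsistent stats for class %s", st$class[bad][1])
  rownames(st) <- st$class
  class(st) <- c("posture_stats", "data.frame")
  st
}

#' Sample synthetic CM points for one posture
#'
#' Independent draws from the class's axis-aligned 2-D Gaussian
#' (`mean_x/sd_x`, `mean_y/sd_y`). With `truncate = TRUE`, draws outside
#' the class's observed `[min, max]` box are redrawn (rejection sampling);
#' note truncation shrinks the realised SDs below the nominal ones.
#'
#' @param stats a [posture_stats()] table.
#' @param class posture label present in `stats`.
#' @param n number of points.
#' @param seed RNG seed (restored afterwards); `NULL` uses the current
#'   stream.
#' @param truncate reject draws outside the class box?
#' @return a `cm_dataset` with `n` labeled points.
#' @export
gen_cm_samples <- function(stats, class, n, seed = NULL, truncate = FALSE) {
  if (!class %in% rownames(stats)) stop_sc("unknown class %s", class)
  if (n < 1) stop_sc("n must be >= 1")
  s <- stats[class, ]
  with_seed(seed, {
    x <- stats::rnorm(n, s$mean_x, s$sd_x)
    y <- stats::rnorm(n, s$mean_y, s$sd_y)
    if (truncate) {
      repeat {
        bad <- x < s$min_x | x > s$max_x | y < s$min_y | y > s$max_y
        if (!any(bad)) break
        x[bad] <- stats::rnorm(sum(bad), s$mean_x, s$sd_x)
        y[bad] <- stats::rnorm(sum(bad), s$mean_y, s$sd_y)
      }
    }
    cm_dataset(x, y, rep(class, n))
  })
}

#' Sample a multi-class CM dataset
#'
#' @param stats a [posture_stats()] table.
#' @param classes posture labels to sample.
#' @param n_per_class points per class.
#' @param seed RNG seed for the whole dataset (classes drawn sequentially
#'   from one stream).
#' @param truncate see [gen_cm_samples()].
#' @return a `cm_dataset` with `length(classes) * n_per_class` points.
#' @export
gen_cm_dataset <- function(stats, classes, n_per_class, seed = NULL,
                           truncate = FALSE) {
  parts <- with_seed(seed, lapply(classes, function(cl) {
    gen_cm_samples(stats, cl, n_per_class, seed = NULL,
                   truncate = truncate)
  }))
  out <- do.call(rbind, parts)
  out$window_index <- seq_len(nrow(out)) - 1L
  class(out) <- c("cm_dataset", "data.frame")
  out
}

#' Invert the CM equations to load-cell weights
#'
#' Solves the center-of-mass equations for the three weights given a CM
#' point and a total seated weight: `F = W CMy / dBF`,
#' `LB = (W CMx - dRF F) / dRL`, `RB = W - LB - F`. The CM must lie inside
#' the triangle spanned by the cells, else a weight would be negative.
#'
#' @param CMx,CMy CM coordinates (cm); vectors allowed.
#' @param total_weight_g total seated weight W in grams.
#' @param geometry a [chair_geometry()].
#' @return data.frame with columns `F`, `LB`, `RB` (grams).
#' @export
invert_cm <- function(CMx, CMy, total_weight_g,
                      geometry = chair_geometry()) {
  W <- total_weight_g
  Fw <- W * CMy / geometry$dBF
  LB <- (W * CMx - geometry$dRF * Fw) / geometry$dRL
  RB <- W - LB - Fw
  tol <- -1e-9 * W
  if (any(Fw < tol | LB < tol | RB < tol)) {
    stop_sc("CM outside the sensor triangle: a weight would be negative")
  }
  data.frame(F = pmax(Fw, 0), LB = pmax(LB, 0), RB = pmax(RB, 0))
}

# clip a CM point into the (slightly shrunk) sensor triangle
clip_to_triangle <- function(x, y, geometry, margin = 1e-6) {
  w <- invert_cm_weights_raw(x, y, geometry)
  if (all(w >= 0)) return(c(x, y))
  w <- pmax(w, margin)
  w <- w / sum(w)
  cm <- compute_cm(w[1], w[2], w[3], geometry)
  c(cm$CMx, cm$CMy)
}

invert_cm_weights_raw <- function(x, y, geometry) {
  Fw <- y / geometry$dBF
  LB <- (x - geometry$dRF * Fw) / geometry$dRL
  c(Fw, LB, 1 - LB - Fw)
}

#' Session plan for the posture generator
#'
#' @param classes posture label per bout, in order.
#' @param duration_s static-bout duration(s) in seconds (recycled).
#' @param transition_s seconds between consecutive bouts.
#' @param body_weight_g total seated weight in grams.
#' @param noise_sd_g per-cell Gaussian sensor noise SD in grams.
#' @param spike_rate per-sample probability of an over-capacity spike per
#'   cell.
#' @param walk_sd_cm SD per step of the within-bout CM random walk.
#' @param seed RNG seed.
#' @return object of class `session_plan`.
#' @export
session_plan <- function(classes, duration_s = 60, transition_s = 5,
                         body_weight_g = 65000, noise_sd_g = 30,
                         spike_rate = 0, walk_sd_cm = 0.01, seed = 1L) {
  if (any(duration_s <= 0) || transition_s < 0) {
    stop_sc("durations must be positive")
  }
  if (body_weight_g <= 0) stop_sc("body_weight_g must be > 0")
  if (walk_sd_cm > 0.05) stop_sc("walk_sd_cm must be <= 0.05 cm")
  structure(list(classes = as.character(classes),
                 duration_s = rep_len(duration_s, length(classes)),
                 transition_s = transition_s,
                 body_weight_g = body_weight_g, noise_sd_g = noise_sd_g,
                 spike_rate = spike_rate, walk_sd_cm = walk_sd_cm,
                 seed = seed), class = "session_plan")
}

#' Generate a synthetic posture session with ground truth
#'
#' Emulates the acquisition protocol: alternating static sitting bouts and
#' transitions, with continuous recording. Within a bout the CM performs a
#' slow random walk around one draw from the class cluster; transitions
#' interpolate the CM linearly between bout endpoints. Weights are
#' obtained by inverting the CM equations for the planned body weight,
#' plus Gaussian sensor noise and optional over-capacity spikes. The
#' pushbutton channel pulses at every bout start and end.
#'
#' @param plan a [session_plan()].
#' @param stats a [posture_stats()] table covering the planned classes.
#' @param geometry a [chair_geometry()].
#' @param fs load-cell sampling rate in Hz.
#' @return list with `stream` (a [session_stream()]) and `truth`: `bouts`
#'   (start/end/label, 1-based half-open sample intervals), `cm` (true CM
#'   per sample, before sensor noise), `class` (per-sample label, `NA` in
#'   transitions), `spikes` (sample/channel of every injected spike).
#' @export
gen_posture_session <- function(plan, stats = posture_stats(),
                                geometry = chair_geometry(), fs = 20) {
  stopifnot(inherits(plan, "session_plan"))
  missing <- setdiff(plan$classes, rownames(stats))
  if (length(missing)) {
    stop_sc("class(es) %s absent from stats", paste(missing, collapse = ","))
  }
  with_seed(plan$seed, {
    n_b <- as.integer(round(plan$duration_s * fs))
    n_t <- as.integer(round(plan$transition_s * fs))
    pw <- max(1L, round(0.05 * fs))  # button pulse width
    # one cluster draw per bout; each bout's walk starts at its draw and
    # transitions interpolate linearly to the next bout's draw
    centers <- lapply(plan$classes, function(cl) {
      gen_cm_samples(stats, cl, 1, truncate = TRUE)
    })
    cm <- list(); lab <- list()
    bout_start <- integer(0); bout_end <- integer(0)
    pos <- 1L
    n_clipped <- 0L
    for (i in seq_along(plan$classes)) {
      cl <- plan$classes[i]
      # mean-reverting walk: slow jitter that stays around the bout draw
      ou <- function(n, sd) {
        if (n <= 1 || sd == 0) return(numeric(n))
        as.numeric(stats::filter(c(0, stats::rnorm(n - 1, 0, sd)), 0.99,
                                 method = "recursive"))
      }
      bx <- centers[[i]]$CMx + ou(n_b[i], plan$walk_sd_cm)
      by <- centers[[i]]$CMy + ou(n_b[i], plan$walk_sd_cm)
      for (j in seq_along(bx)) {
        p <- clip_to_triangle(bx[j], by[j], geometry)
        if (p[1] != bx[j] || p[2] != by[j]) n_clipped <- n_clipped + 1L
        bx[j] <- p[1]; by[j] <- p[2]
      }
      bout_start <- c(bout_start, pos)
      bout_end <- c(bout_end, pos + n_b[i])
      cm[[length(cm) + 1L]] <- cbind(bx, by)
      lab[[length(lab) + 1L]] <- rep(cl, n_b[i])
      pos <- pos + n_b[i]
      if (i < length(plan$classes) && n_t > 0) {
        frac <- seq_len(n_t) / (n_t + 1)
        tx <- bx[length(bx)] + frac * (centers[[i + 1]]$CMx - bx[length(bx)])
        ty <- by[length(by)] + frac * (centers[[i + 1]]$CMy - by[length(by)])
        cm[[length(cm) + 1L]] <- cbind(tx, ty)
        lab[[length(lab) + 1L]] <- rep(NA_character_, n_t)
        pos <- pos + n_t
      }
    }
    # tail so the final end-press pulse fits
    tail_n <- pw + 1L
    last_cm <- cm[[length(cm)]]
    cm[[length(cm) + 1L]] <- matrix(rep(last_cm[nrow(last_cm), ], tail_n),
                                    ncol = 2, byrow = TRUE)
    lab[[length(lab) + 1L]] <- rep(NA_character_, tail_n)
    cm <- do.call(rbind, cm)
    lab <- unlist(lab)
    n <- nrow(cm)

    w <- invert_cm(cm[, 1], cm[, 2], plan$body_weight_g, geometry)
    chans <- list(F_g = w$F, LB_g = w$LB, RB_g = w$RB)
    spikes <- NULL
    for (ch in names(chans)) {
      if (plan$noise_sd_g > 0) {
        chans[[ch]] <- chans[[ch]] + stats::rnorm(n, 0, plan$noise_sd_g)
      }
      if (plan$spike_rate > 0) {
        hit <- which(stats::runif(n) < plan$spike_rate)
        if (length(hit)) {
          chans[[ch]][hit] <- geometry$max_capacity_g *
            (2 + stats::runif(length(hit)))
          spikes <- rbind(spikes, data.frame(sample = hit, channel = ch))
        }
      }
    }
    button <- numeric(n)
    for (sidx in c(bout_start, bout_end)) {
      button[sidx:min(n, sidx + pw - 1L)] <- 1
    }
    chans$button <- button
    if (n_clipped) sc_log("gen_posture_session: %d CM point(s) clipped",
                          n_clipped)
    list(stream = session_stream(chans, fs_loadcell = fs),
         truth = list(bouts = data.frame(start = bout_start,
                                         end = bout_end,
                                         label = plan$classes,
                                         stringsAsFactors = FALSE),
                      cm = cm, class = lab,
                      spikes = spikes %||%
                        data.frame(sample = integer(0),
                                   channel = character(0))))
  })
}

#' Generate a synthetic single-lead ECG with known R-peaks
#'
#' Each beat is a sum of Gaussian bumps (P, Q, R, S, T waves) with fixed
#' widths and offsets and configurable R amplitude; RR intervals are drawn
#' from a truncated Gaussian. Optional additive baseline wander (0.3 Hz),
#' powerline hum (50 Hz) and white noise.
#'
#' @param fs sampling rate in Hz (>= 250).
#' @param duration_s signal length in seconds (long enough for >= 2
#'   beats).
#' @param hr_bpm target heart rate, within \[30, 220\].
#' @param hr_sd SD of the RR intervals in seconds.
#' @param noise `c(baseline, powerline, white)` amplitudes/SD in signal
#'   units.
#' @param seed RNG seed.
#' @param r_amp R-wave amplitude (arbitrary units, default 0.8).
#' @return list with `signal` (an [ecg_signal()]), `rpeaks` (true R sample
#'   indices) and `r_amp`.
#' @export
gen_ecg <- function(fs = 500, duration_s = 60, hr_bpm = 60, hr_sd = 0,
                    noise = c(baseline = 0, powerline = 0, white = 0),
                    seed = NULL, r_amp = 0.8) {
  if (fs < 250) stop_sc("fs must be >= 250 Hz")
  if (hr_bpm < 30 || hr_bpm > 220) {
    stop_sc("hr_bpm %g outside the supported [30, 220] range", hr_bpm)
  }
  with_seed(seed, {
    n <- round(duration_s * fs)
    t <- (seq_len(n) - 1) / fs
    rr_mean <- 60 / hr_bpm
    beat_t <- numeric(0)
    tb <- 0.5
    while (tb < duration_s - 0.35) {
      beat_t <- c(beat_t, tb)
      rr <- if (hr_sd > 0) stats::rnorm(1, rr_mean, hr_sd) else rr_mean
      tb <- tb + max(0.3, rr)
    }
    if (length(beat_t) < 2) stop_sc("duration too short for 2 beats")
    # PQRST as Gaussian bumps: offset (s), width sigma (s), relative amp
    bumps <- rbind(P = c(-0.13, 0.015, 0.15),
                   Q = c(-0.035, 0.009, -0.12),
                   R = c(0.0, 0.011, 1.0),
                   S = c(0.035, 0.009, -0.20),
                   T = c(0.25, 0.055, 0.35))
    x <- numeric(n)
    for (tb in beat_t) {
      for (b in seq_len(nrow(bumps))) {
        off <- bumps[b, 1]; sg <- bumps[b, 2]; am <- bumps[b, 3] * r_amp
        lo <- max(1L, floor((tb + off - 5 * sg) * fs) + 1L)
        hi <- min(n, ceiling((tb + off + 5 * sg) * fs) + 1L)
        if (lo > hi) next
        seg <- lo:hi
        x[seg] <- x[seg] + am * exp(-((t[seg] - tb - off)^2) / (2 * sg^2))
      }
    }
    if (is.null(names(noise)) || !any(nzchar(names(noise)))) {
      noise <- stats::setNames(rep_len(as.numeric(noise), 3),
                               c("baseline", "powerline", "white"))
    }
    noise <- c(noise, baseline = 0, powerline = 0, white = 0)[
      c("baseline", "powerline", "white")]
    if (noise["baseline"] > 0) {
      x <- x + noise["baseline"] * sin(2 * pi * 0.3 * t +
                                       stats::runif(1, 0, 2 * pi))
    }
    if (noise["powerline"] > 0) {
      x <- x + noise["powerline"] * sin(2 * pi * 50 * t +
                                        stats::runif(1, 0, 2 * pi))
    }
    if (noise["white"] > 0) x <- x + stats::rnorm(n, 0, noise["white"])
    list(signal = ecg_signal(x, fs), rpeaks = round(beat_t * fs) + 1L,
         r_amp = r_amp)
  })
}

#' Inject localized broadband artifact bursts
#'
#' Adds 0.5-2 s high-amplitude white-noise bursts at Poisson-distributed
#' times, emulating contact noise that induces false R-peak detections.
#'
#' @param sig an [ecg_signal()].
#' @param burst_rate expected bursts per minute.
#' @param burst_amp burst noise SD as a multiple of `ref_amp`.
#' @param seed RNG seed.
#' @param ref_amp R-wave amplitude the multiple refers to (default 0.8).
#' @return list with `signal` (contaminated copy) and `bursts`
#'   (data.frame of start/end sample indices).
#' @export
inject_artifacts <- function(sig, burst_rate, burst_amp = 3, seed = NULL,
                             ref_amp = 0.8) {
  stopifnot(inherits(sig, "ecg_signal"))
  if (burst_amp <= 0) stop_sc("burst_amp must be > 0")
  n <- length(sig$samples)
  dur_min <- n / sig$fs / 60
  with_seed(seed, {
    k <- stats::rpois(1, burst_rate * dur_min)
    if (k == 0) {
      return(list(signal = sig,
                  bursts = data.frame(start = integer(0),
                                      end = integer(0))))
    }
    starts <- sort(round(stats::runif(k, 1, n)))
    lens <- round(stats::runif(k, 0.5, 2) * sig$fs)
    ends <- pmin(n, starts + lens - 1L)
    x <- sig$samples
    for (i in seq_len(k)) {
      seg <- starts[i]:ends[i]
      x[seg] <- x[seg] + stats::rnorm(length(seg), 0,
                                      burst_amp * ref_amp / 2)
    }
    out <- sig
    out$samples <- x
    list(signal = out, bursts = data.frame(start = starts, end = ends))
  })
}
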