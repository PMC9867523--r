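# Beat-level outlier rejection: the three detectors compared for cleaning
# armrest ECG — DBSCAN over cosine distances, DMEAN (distance to the mean
# template with adaptive thresholds), and NCCC (greedy admission to a
# cluster seeded by the beats with highest average normalised
# cross-correlation).

outlier_mask <- function(flags, method, params) {
  structure(list(flags = flags, method = method, params = params),
            class = "outlier_mask")
}

#' @export
print.outlier_mask <- function(x, ...) {
  cat(sprintf("<outlier_mask> %s: %d/%d flagged\n", x$method,
              sum(x$flags), length(x$flags)))
  invisible(x)
}

beat_rows <- function(beats) {
  if (inherits(beats, "beat_matrix")) beats$beats else as.matrix(beats)
}

#' Pairwise cosine distance between beats
#'
#' `d(i, j) = 1 - <b_i, b_j> / (|b_i| |b_j|)`; symmetric with zero
#' diagonal.
#'
#' @param beats a [segment_beats()] result or numeric matrix (one beat per
#'   row) with at least two beats, each of nonzero norm.
#' @return symmetric distance matrix.
#' @export
cosine_distance_matrix <- function(beats) {
  B <- beat_rows(beats)
  if (nrow(B) < 2) stop_sc("need at least 2 beats")
  nrm <- sqrt(rowSums(B^2))
  zero <- which(nrm == 0)
  if (length(zero)) stop_sc("beat %d has zero norm", zero[1])
  D <- 1 - tcrossprod(B / nrm)
  D[D < 0] <- 0  # numerical fuzz
  diag(D) <- 0
  (D + t(D)) / 2
}

#' DBSCAN beat outliers
#'
#' Full density-based clustering implemented from scratch on the cosine
#' distance matrix: a core beat has at least `min_pts` neighbours within
#' `epsilon` (itself included); clusters are the density-reachable
#' closures of core beats. "Normal" beats are the members of the largest
#' cluster; noise beats and members of any smaller cluster are flagged.
#' Deterministic given input order.
#'
#' @param beats a [segment_beats()] result or beat matrix.
#' @param epsilon cosine-distance neighbourhood radius (default 0.45).
#' @param min_pts neighbour count defining a core beat (default 10).
#' @return an `outlier_mask`.
#' @export
dbscan_outliers <- function(beats, epsilon = 0.45, min_pts = 10) {
  B <- beat_rows(beats)
  n <- nrow(B)
  params <- list(epsilon = epsilon, min_pts = min_pts, metric = "cosine")
  if (n < 2) {
    return(outlier_mask(rep(n < min_pts, n), "dbscan", params))
  }
  D <- cosine_distance_matrix(B)
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= epsilon))
  core <- lengths(nb) >= min_pts
  labels <- rep(0L, n)  # 0 = unvisited/noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nb[[i]]
    while (length(queue)) {
      j <- queue[1]
      queue <- queue[-1]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) queue <- c(queue, nb[[j]][labels[nb[[j]]] == 0L])
      }
    }
  }
  if (cl == 0L) {
    flags <- rep(TRUE, n)  # no core point: everything is noise
  } else {
    sizes <- tabulate(labels[labels > 0L], nbins = cl)
    main <- which.max(sizes)  # ties: first-formed cluster
    flags <- labels != main
  }
  outlier_mask(flags, "dbscan", params)
}

#' DMEAN beat outliers
#'
#' Flags a beat when its cosine distance to the mean beat template exceeds
#' the adaptive threshold `min(c1 * median(d), mean(d) + c2 * sd(d))`, or
#' when its R amplitude deviates from the median amplitude by more than
#' `c3` robust standard deviations (1.4826 * MAD).
#'
#' @param beats a [segment_beats()] result (needed for the amplitude rule)
#'   or beat matrix with at least three beats.
#' @param c1,c2,c3 threshold coefficients, defaults 1.5, 2.0, 2.0.
#' @return an `outlier_mask`.
#' @export
dmean_outliers <- function(beats, c1 = 1.5, c2 = 2.0, c3 = 2.0) {
  B <- beat_rows(beats)
  if (nrow(B) < 3) stop_sc("DMEAN needs at least 3 beats")
  template <- colMeans(B)
  tn <- sqrt(sum(template^2))
  if (tn == 0) stop_sc("degenerate (zero) mean template")
  nrm <- sqrt(rowSums(B^2))
  zero <- which(nrm == 0)
  if (length(zero)) stop_sc("beat %d has zero norm", zero[1])
  d <- 1 - as.numeric(B %*% template) / (nrm * tn)
  thr <- min(c1 * stats::median(d), mean(d) + c2 * stats::sd(d))
  flags <- d > thr + 1e-12  # fuzz floor: identical beats are never flagged
  if (inherits(beats, "beat_matrix")) {
    amp <- r_amplitude(beats)$amplitudes
    rsd <- stats::mad(amp)
    if (rsd > 0) flags <- flags | abs(amp - stats::median(amp)) > c3 * rsd
  }
  outlier_mask(flags, "dmean",
               list(c1 = c1, c2 = c2, c3 = c3, threshold = thr))
}

# Zero-lag normalised cross-correlation between mean-removed beats; beats
# are R-aligned by segmentation, so no lag search is needed.
ncc_matrix <- function(B) {
  Bc <- B - rowMeans(B)
  nrm <- sqrt(rowSums(Bc^2))
  nrm[nrm == 0] <- .Machine$double.eps
  tcrossprod(Bc / nrm)
}

#' NCCC beat outliers
#'
#' Greedy quality clustering: each beat's score `A` is its average
#' zero-lag normalised cross-correlation with every other beat; the
#' `init_size` highest-A beats seed the cluster, and the remaining beats
#' are visited in descending A. A beat is admitted while its correlation
#' with the current cluster's mean template is at least `theta`; at the
#' first failure that beat and all unvisited beats are flagged.
#'
#' @param beats a [segment_beats()] result or beat matrix.
#' @param init_size size of the seed cluster (default 20). When the beat
#'   count does not exceed it, nothing is flagged and a warning is issued.
#' @param theta admission correlation threshold (default 0.8).
#' @return an `outlier_mask`.
#' @export
nccc_outliers <- function(beats, init_size = 20, theta = 0.8) {
  B <- beat_rows(beats)
  n <- nrow(B)
  params <- list(init_size = init_size, theta = theta)
  if (n <= init_size) {
    warning(sprintf("only %d beats (<= init_size %d); nothing flagged", n,
                    init_size), call. = FALSE)
    return(outlier_mask(rep(FALSE, n), "nccc", params))
  }
  R <- ncc_matrix(B)
  A <- (rowSums(R) - diag(R)) / (n - 1)
  ord <- order(A, decreasing = TRUE)
  cluster <- ord[seq_len(init_size)]
  flags <- rep(FALSE, n)
  rest <- ord[(init_size + 1):n]
  corr_to_template <- function(i, members) {
    tmpl <- colMeans(B[members, , drop = FALSE])
    tc <- tmpl - mean(tmpl)
    bi <- B[i, ] - mean(B[i, ])
    den <- sqrt(sum(tc^2) * sum(bi^2))
    if (den == 0) 0 else sum(tc * bi) / den
  }
  for (j in seq_along(rest)) {
    i <- rest[j]
    if (corr_to_template(i, cluster) >= theta) {
      cluster <- c(cluster, i)
    } else {
      flags[rest[j:length(rest)]] <- TRUE
      break
    }
  }
  outlier_mask(flags, "nccc", params)
}

#' Apply an outlier mask to R-peak indices
#'
#' Drops flagged beats and returns the retained indices with chain
#' bookkeeping: removals split the sequence into runs of originally
#' consecutive beats, and [heart_rate()] only forms intervals within a
#' run, so an interval spanning a removed beat is never used.
#'
#' @param rpeaks R-peak indices, one per beat in the mask.
#' @param mask an `outlier_mask` of the same length.
#' @return list with `rpeaks` (retained indices) and `chain` (run id per
#'   retained index), consumable by [heart_rate()].
#' @export
apply_mask <- function(rpeaks, mask) {
  stopifnot(inherits(mask, "outlier_mask"))
  if (length(rpeaks) != length(mask$flags)) {
    stop_sc("rpeaks (%d) and mask (%d) lengths differ", length(rpeaks),
            length(mask$flags))
  }
  keep <- !mask$flags
  idx <- which(keep)
  chain <- if (length(idx)) cumsum(c(1L, diff(idx) != 1L)) else integer(0)
  list(rpeaks = rpeaks[keep], chain = chain)
}
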