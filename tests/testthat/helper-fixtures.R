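# Shared fixtures and independent oracles, all built in code at test time.

# small well-separated two-cluster dataset
two_cluster_cm <- function(n = 50, sd = 0.1, seed = 1) {
  set.seed(seed)
  cm_dataset(CMx = c(rnorm(n, 5, sd), rnorm(n, 25, sd)),
             CMy = c(rnorm(n, 5, sd), rnorm(n, 5, sd)),
             label = rep(c("P1", "P5"), each = n))
}

# standardized artifact-burst ECG fixture: heavy background noise (the
# armrest regime) plus localized broadband bursts; ground truth retained
burst_fixture <- function(seed = 42, duration_s = 120) {
  g <- gen_ecg(fs = 500, duration_s = duration_s, hr_bpm = 70,
               hr_sd = 0.05, noise = c(0.05, 0.02, 0.25), seed = seed)
  inj <- inject_artifacts(g$signal, burst_rate = 6, burst_amp = 3,
                          seed = seed + 1L)
  list(truth = g, noisy = inj$signal, bursts = inj$bursts)
}

# beats matrix fixture: near-identical template beats plus arbitrary rows
template_beats <- function(n, len = 300, jitter = 0, seed = 1) {
  set.seed(seed)
  t <- seq_len(len)
  tmpl <- 0.8 * exp(-((t - 100)^2) / (2 * 5.5^2)) +
    0.3 * exp(-((t - 220)^2) / (2 * 27^2))
  m <- matrix(rep(tmpl, n), nrow = n, byrow = TRUE)
  if (jitter > 0) m <- m + matrix(rnorm(n * len, 0, jitter), n, len)
  m
}

# independent DBSCAN oracle built from the definition: core points, then
# connected components of the core-core epsilon graph; border points may
# attach to any cluster holding a core neighbour; the rest is noise.
dbscan_oracle <- function(D, eps, min_pts) {
  n <- nrow(D)
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- which(lengths(nb) >= min_pts)
  comp <- rep(0L, n)
  cl <- 0L
  for (c0 in core) {
    if (comp[c0] != 0L) next
    cl <- cl + 1L
    todo <- c0
    while (length(todo)) {
      v <- todo[[1]]
      todo <- todo[-1]
      if (comp[v] != 0L) next
      comp[v] <- cl
      todo <- c(todo, intersect(nb[[v]], core)[comp[intersect(nb[[v]],
                                                              core)] == 0L])
    }
  }
  border <- lapply(seq_len(n), function(i) {
    if (comp[i] != 0L || i %in% core) return(integer(0))
    unique(comp[intersect(nb[[i]], core)])
  })
  list(core = core, comp = comp, border_options = border)
}

# brute-force optimal bipartite matching (max cardinality) within
# tolerance, for <= 12 peaks per side
match_oracle_count <- function(ref, exp, tol) {
  ok <- abs(outer(ref, exp, "-")) <= tol
  best <- 0L
  recurse <- function(i, used) {
    if (i > length(ref)) return(0L)
    top <- recurse(i + 1L, used)  # skip ref i
    for (j in which(ok[i, ])) {
      if (!used[j]) {
        used2 <- used
        used2[j] <- TRUE
        top <- max(top, 1L + recurse(i + 1L, used2))
      }
    }
    top
  }
  if (!length(ref) || !length(exp)) return(0L)
  recurse(1L, logical(length(exp)))
}
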