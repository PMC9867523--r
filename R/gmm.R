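# Gaussian mixture model, fitted unsupervised by EM with one component per
# posture class. Covariance structures follow the usual taxonomy: "full"
# (one covariance per component), "tied" (shared), "diagonal", "spherical".
# Initialisation is deterministic k-means under a fixed seed so repeated
# fits agree.

gmm_log_dens <- function(X, mu, sigma) {
  # log N(x; mu, sigma) for a 2-D Gaussian, via Cholesky
  ch <- chol(sigma)
  z <- forwardsolve(t(ch), t(X) - mu)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - log(2 * pi)
}

gmm_cov_shape <- function(S, covariance) {
  switch(covariance,
    full = S,
    tied = S,  # pooling handled by caller
    diagonal = diag(diag(S), nrow = nrow(S)),
    spherical = diag(rep(mean(diag(S)), nrow(S))))
}

gmm_em <- function(X, K, covariance, init_seed = 1L, max_iter = 200L,
                   tol = 1e-7, reg = 1e-6) {
  n <- nrow(X); d <- ncol(X)
  km <- with_seed(init_seed, stats::kmeans(X, centers = K, nstart = 10,
                                           iter.max = 100))
  mu <- km$centers
  pi_k <- as.numeric(table(factor(km$cluster, levels = seq_len(K)))) / n
  resp <- matrix(0, n, K)
  resp[cbind(seq_len(n), km$cluster)] <- 1
  sigma <- vector("list", K)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    # M-step
    nk <- colSums(resp)
    pi_k <- nk / n
    mu <- t(vapply(seq_len(K), function(k) {
      colSums(X * resp[, k]) / nk[k]
    }, numeric(d)))
    covs <- lapply(seq_len(K), function(k) {
      Xc <- t(t(X) - mu[k, ])
      S <- crossprod(Xc * resp[, k], Xc) / nk[k]
      S + diag(reg, d)
    })
    if (covariance == "tied") {
      pooled <- Reduce(`+`, Map(function(S, w) S * w, covs, pi_k))
      sigma <- rep(list(pooled), K)
    } else {
      sigma <- lapply(covs, gmm_cov_shape, covariance = covariance)
    }
    # E-step
    logd <- vapply(seq_len(K), function(k) {
      log(pi_k[k]) + gmm_log_dens(X, mu[k, ], sigma[[k]])
    }, numeric(n))
    m <- apply(logd, 1, max)
    lse <- m + log(rowSums(exp(logd - m)))
    resp <- exp(logd - lse)
    ll <- sum(lse)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll)) break
    ll_old <- ll
  }
  list(pi = pi_k, mu = mu, sigma = sigma, loglik = ll, resp = resp,
       covariance = covariance)
}

gmm_posterior <- function(fit, Q) {
  K <- length(fit$pi)
  logd <- vapply(seq_len(K), function(k) {
    log(fit$pi[k]) + gmm_log_dens(Q, fit$mu[k, ], fit$sigma[[k]])
  }, numeric(nrow(Q)))
  if (nrow(Q) == 1L) logd <- matrix(logd, nrow = 1)
  logd
}

gmm_fit_classifier <- function(X, y, spec) {
  classes <- levels(y)
  counts <- table(y)
  if (spec$covariance %in% c("full", "diagonal") && any(counts < 2)) {
    stop_sc(paste0("class %s has a single point; %s covariance is ",
                   "degenerate - use tied or spherical covariance"),
            names(counts)[counts < 2][1], spec$covariance)
  }
  fit <- gmm_em(X, K = length(classes), covariance = spec$covariance,
                init_seed = spec$init_seed)
  # component -> class by majority true label among hard-assigned points
  hard <- max.col(fit$resp, ties.method = "first")
  mapping <- vapply(seq_along(fit$pi), function(k) {
    claimed <- y[hard == k]
    if (!length(claimed)) return(NA_character_)
    tab <- table(claimed)
    names(tab)[which.max(tab)]
  }, character(1))
  unmapped <- setdiff(classes, mapping)
  if (length(unmapped)) {
    sc_log("GMM: class(es) %s claimed by no component",
           paste(unmapped, collapse = ","))
  }
  fit$mapping <- mapping
  fit
}

gmm_predict_classifier <- function(fit, Q) {
  logd <- gmm_posterior(fit, Q)
  comp <- max.col(logd, ties.method = "first")
  fit$mapping[comp]
}
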