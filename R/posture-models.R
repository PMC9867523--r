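#' Posture classifier specification
#'
#' Describes one classifier family and its hyperparameters. Families mirror
#' the four model types trained on the center-of-mass feature space:
#' weighted k-nearest neighbours, nearest centroid, support vector machine
#' and Gaussian mixture model.
#'
#' @param family one of `"knn"`, `"nc"`, `"svm"`, `"gmm"`.
#' @param k neighbour count (kNN; brute-force search, inverse-distance
#'   vote weighting).
#' @param metric `"euclidean"` or `"cityblock"` (NC).
#' @param kernel `"linear"` or `"rbf"` (SVM).
#' @param C SVM regularisation weight.
#' @param gamma RBF kernel width (SVM).
#' @param covariance `"tied"`, `"full"`, `"diagonal"` or `"spherical"`
#'   (GMM).
#' @param init_seed deterministic seed for the GMM k-means initialisation.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(family = c("knn", "nc", "svm", "gmm"),
                       k = 1000L, metric = "euclidean",
                       kernel = "linear", C = 1e-3, gamma = 0.5,
                       covariance = "tied", init_seed = 1L) {
  family <- match.arg(family)
  metric <- match.arg(metric, c("euclidean", "cityblock"))
  kernel <- match.arg(kernel, c("linear", "rbf"))
  covariance <- match.arg(covariance,
                          c("tied", "full", "diagonal", "spherical"))
  if (family == "knn" && (!is.numeric(k) || k < 1)) {
    stop_sc("k must be a positive integer")
  }
  structure(list(family = family, k = as.integer(k), metric = metric,
                 kernel = kernel, C = C, gamma = gamma,
                 covariance = covariance, init_seed = init_seed),
            class = "model_spec")
}

#' Reference hyperparameters for the five- and seven-class tasks
#'
#' The tuned settings for each family: five classes use k-NN
#' (inverse-distance), NC with the Euclidean metric, a linear SVM with
#' `C = 0.001` and a tied-covariance GMM; seven classes use NC with the
#' cityblock metric, an RBF SVM with `C = 0.1`, `gamma = 0.5` and a
#' full-covariance GMM.
#'
#' @param n_classes 5 or 7.
#' @param knn_k neighbour count to use for the k-NN entry.
#' @return named list of [model_spec()]s (`knn`, `nc`, `svm`, `gmm`).
#' @export
reference_model_specs <- function(n_classes = 5, knn_k = 1000L) {
  if (n_classes == 5) {
    list(knn = model_spec("knn", k = knn_k),
         nc = model_spec("nc", metric = "euclidean"),
         svm = model_spec("svm", kernel = "linear", C = 1e-3),
         gmm = model_spec("gmm", covariance = "tied"))
  } else if (n_classes == 7) {
    list(knn = model_spec("knn", k = knn_k),
         nc = model_spec("nc", metric = "cityblock"),
         svm = model_spec("svm", kernel = "rbf", C = 0.1, gamma = 0.5),
         gmm = model_spec("gmm", covariance = "full"))
  } else {
    stop_sc("n_classes must be 5 or 7")
  }
}

#' Assemble a labeled CM dataset
#'
#' @param CMx,CMy coordinates in cm.
#' @param label posture label per point (P1..P8, excluding P4 for training).
#' @return data.frame of class `cm_dataset`.
#' @export
cm_dataset <- function(CMx, CMy, label) {
  stopifnot(length(CMx) == length(CMy), length(CMx) == length(label))
  structure(data.frame(window_index = seq_along(CMx) - 1L, CMx = CMx,
                       CMy = CMy, label = as.character(label),
                       segment = NA_character_, stringsAsFactors = FALSE),
            class = c("cm_dataset", "data.frame"))
}

cm_matrix <- function(dataset) {
  as.matrix(dataset[, c("CMx", "CMy")])
}

check_training_set <- function(dataset) {
  lab <- dataset$label
  if (anyNA(lab)) stop_sc("training set contains unlabeled points")
  if ("P4" %in% lab) {
    stop_sc("P4 is excluded from training class sets (no coherent cluster)")
  }
  classes <- unique(lab)
  if (length(classes) < 2) stop_sc("training set needs >= 2 classes")
  # preserve canonical posture order when labels look like P<k>
  classes[order(classes)]
}

#' Train a posture classifier
#'
#' Fits one of the four model families to a labeled CM dataset. The GMM is
#' fitted unsupervised (one mixture component per class, EM) and its
#' components are then mapped to posture classes by the majority true label
#' of the training points each component claims; a component that claims no
#' class, or a class claimed by no component, simply degrades accuracy
#' rather than erroring, so the model reports its own failure.
#'
#' @param dataset a `cm_dataset` with labels.
#' @param spec a [model_spec()].
#' @return object of class `posture_model`; use `predict()` with a
#'   data.frame holding `CMx`, `CMy` to obtain labels.
#' @export
posture_train <- function(dataset, spec) {
  stopifnot(inherits(spec, "model_spec"))
  classes <- check_training_set(dataset)
  X <- cm_matrix(dataset)
  y <- factor(dataset$label, levels = classes)
  if (any(table(y) < 1)) stop_sc("every class needs >= 1 point")
  fit <- switch(spec$family,
    knn = {
      if (spec$k > nrow(X)) {
        stop_sc("k = %d exceeds training-set size %d", spec$k, nrow(X))
      }
      list(X = X, y = y)
    },
    nc = {
      cent <- do.call(rbind, lapply(classes, function(cl) {
        colMeans(X[y == cl, , drop = FALSE])
      }))
      rownames(cent) <- classes
      list(centroids = cent)
    },
    svm = svm_fit_multiclass(X, y, spec),
    gmm = gmm_fit_classifier(X, y, spec))
  structure(list(spec = spec, classes = classes, fit = fit,
                 n_train = nrow(X)),
            class = "posture_model")
}

#' @export
print.posture_model <- function(x, ...) {
  cat(sprintf("<posture_model> family=%s classes={%s} n_train=%d\n",
              x$spec$family, paste(x$classes, collapse = ","), x$n_train))
  invisible(x)
}

#' Predict posture labels
#'
#' @param object a fitted `posture_model`.
#' @param newdata data.frame with `CMx` and `CMy` columns, or a 2-column
#'   matrix.
#' @param ... unused.
#' @return character vector of predicted class labels.
#' @export
predict.posture_model <- function(object, newdata, ...) {
  Q <- if (is.matrix(newdata)) newdata else
    as.matrix(newdata[, c("CMx", "CMy")])
  switch(object$spec$family,
    knn = knn_predict(object, Q, object$spec$k),
    nc = nc_predict(object, Q),
    svm = svm_predict_multiclass(object$fit, Q, object$classes),
    gmm = gmm_predict_classifier(object$fit, Q))
}

# ---- weighted kNN ---------------------------------------------------------

# Neighbour search is delegated to FNN (brute force, per the reference
# configuration); the inverse-distance vote and the coincident-point
# convention (a query on top of a training point takes that point's label,
# i.e. infinite weight) are implemented here.
knn_neighbors <- function(model, Q, k) {
  FNN::get.knnx(model$fit$X, Q, k = k, algorithm = "brute")
}

knn_vote <- function(nn_index, nn_dist, y, classes) {
  n <- nrow(nn_index)
  lab <- matrix(as.integer(y)[nn_index], nrow = n)
  w <- 1 / pmax(nn_dist, .Machine$double.eps)
  exact <- nn_dist < 1e-12
  hit <- rowSums(exact) > 0
  if (any(hit)) {
    # zero-distance neighbours get infinite weight: vote only among them
    w[hit, ] <- exact[hit, , drop = FALSE] * 1
  }
  scores <- vapply(seq_along(classes), function(ci) {
    rowSums(w * (lab == ci))
  }, numeric(n))
  if (n == 1L) scores <- matrix(scores, nrow = 1)
  classes[max.col(scores, ties.method = "first")]
}

knn_predict <- function(model, Q, k, chunk = 2000L) {
  out <- character(nrow(Q))
  for (from in seq(1, nrow(Q), by = chunk)) {
    to <- min(from + chunk - 1L, nrow(Q))
    nn <- knn_neighbors(model, Q[from:to, , drop = FALSE], k)
    out[from:to] <- knn_vote(nn$nn.index, nn$nn.dist, model$fit$y,
                             model$classes)
  }
  out
}

# Evaluate several neighbour counts from one search (used by the k sweep).
knn_predict_multi_k <- function(model, Q, ks, chunk = 2000L) {
  kmax <- max(ks)
  out <- matrix(character(1), nrow(Q), length(ks),
                dimnames = list(NULL, paste0("k", ks)))
  for (from in seq(1, nrow(Q), by = chunk)) {
    to <- min(from + chunk - 1L, nrow(Q))
    nn <- knn_neighbors(model, Q[from:to, , drop = FALSE], kmax)
    for (j in seq_along(ks)) {
      k <- ks[j]
      out[from:to, j] <- knn_vote(nn$nn.index[, seq_len(k), drop = FALSE],
                                  nn$nn.dist[, seq_len(k), drop = FALSE],
                                  model$fit$y, model$classes)
    }
  }
  out
}

# ---- nearest centroid -----------------------------------------------------

nc_predict <- function(model, Q) {
  cent <- model$fit$centroids
  d <- vapply(seq_len(nrow(cent)), function(i) {
    dx <- Q[, 1] - cent[i, 1]
    dy <- Q[, 2] - cent[i, 2]
    if (model$spec$metric == "euclidean") sqrt(dx^2 + dy^2)
    else abs(dx) + abs(dy)
  }, numeric(nrow(Q)))
  if (nrow(Q) == 1L) d <- matrix(d, nrow = 1)
  model$classes[max.col(-d, ties.method = "first")]
}

# ---- SVM (one-vs-one, dual coordinate descent) ----------------------------

svm_fit_multiclass <- function(X, y, spec) {
  classes <- levels(y)
  kern <- if (spec$kernel == "linear") 0L else 1L
  pairs <- utils::combn(seq_along(classes), 2)
  fits <- vector("list", ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    sel <- y == classes[i] | y == classes[j]
    Xp <- X[sel, , drop = FALSE]
    yp <- ifelse(y[sel] == classes[i], 1, -1)
    sol <- svm_smo_train(Xp, yp, C = spec$C, kernel = kern,
                         gamma = spec$gamma)
    sv <- sol$alpha > 1e-12 * spec$C
    fits[[p]] <- list(i = i, j = j, X = Xp[sv, , drop = FALSE],
                      coef = (sol$alpha * yp)[sv], b = sol$b)
  }
  list(pairs = fits, kernel = kern, gamma = spec$gamma)
}

svm_predict_multiclass <- function(fit, Q, classes) {
  votes <- matrix(0L, nrow(Q), length(classes))
  for (p in fit$pairs) {
    f <- svm_decision(p$X, p$coef, p$b, Q, fit$kernel, fit$gamma)
    win <- ifelse(f >= 0, p$i, p$j)
    votes[cbind(seq_len(nrow(Q)), win)] <-
      votes[cbind(seq_len(nrow(Q)), win)] + 1L
  }
  classes[max.col(votes, ties.method = "first")]
}
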