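#' Deterministic stratified folds
#'
#' Assigns fold ids per class in round-robin order of appearance, so each
#' fold's class proportions differ from the global proportions by at most
#' one sample and repeated calls agree.
#'
#' @param labels class label per point.
#' @param folds number of folds.
#' @return integer fold id per point (1..folds).
#' @export
stratified_folds <- function(labels, folds = 5L) {
  counts <- table(labels)
  short <- names(counts)[counts < folds]
  if (length(short)) {
    stop_sc("class %s has %d point(s), fewer than %d folds", short[1],
            counts[short[1]], folds)
  }
  ids <- integer(length(labels))
  for (cl in names(counts)) {
    idx <- which(labels == cl)
    ids[idx] <- rep_len(seq_len(folds), length(idx))
  }
  ids
}

grid_specs <- function(family, grid, k = 1000L) {
  specs <- list()
  add <- function(...) specs[[length(specs) + 1L]] <<- model_spec(...)
  switch(family,
    knn = add("knn", k = k),
    nc = for (m in grid$metric) add("nc", metric = m),
    svm = for (kern in grid$kernel) for (C in grid$C) {
      if (kern == "linear") add("svm", kernel = "linear", C = C)
      else for (g in grid$gamma) add("svm", kernel = "rbf", C = C,
                                     gamma = g)
    },
    gmm = for (cv in grid$covariance) add("gmm", covariance = cv),
    stop_sc("unknown family %s", family))
  specs
}

#' Hyperparameter tuning by stratified cross-validation
#'
#' Exhaustive grid search over a family's hyperparameter space, scoring
#' each grid point by stratified k-fold CV accuracy; ties are broken
#' deterministically in favour of the first grid point. The kNN neighbour
#' count is deliberately *not* tuned: it is fixed externally via `k`
#' (validation accuracy decreases monotonically with k while held-out
#' accuracy does not, so CV would always pick the smallest k).
#'
#' @param dataset labeled `cm_dataset`; every class needs at least `folds`
#'   points.
#' @param family model family to tune (`"knn"`, `"nc"`, `"svm"`, `"gmm"`).
#' @param grid hyperparameter space for the family; defaults to the
#'   package grid in [load_config()].
#' @param folds number of CV folds (default 5).
#' @param k fixed neighbour count for kNN.
#' @return list with `best_spec`, `cv_accuracy`, and `results` (one row per
#'   grid point with its CV accuracy).
#' @export
posture_tune <- function(dataset, family, grid = NULL, folds = 5L,
                         k = 1000L) {
  if (is.null(grid)) {
    cfg <- default_config()$grids
    grid <- switch(family, knn = list(), nc = cfg$nc, svm = cfg$svm,
                   gmm = cfg$gmm)
  }
  specs <- grid_specs(family, grid, k = k)
  fold_id <- stratified_folds(dataset$label, folds)
  acc <- vapply(specs, function(sp) {
    correct <- 0L
    for (f in seq_len(folds)) {
      tr <- dataset[fold_id != f, , drop = FALSE]
      te <- dataset[fold_id == f, , drop = FALSE]
      m <- posture_train(tr, sp)
      correct <- correct + sum(predict(m, te) == te$label)
    }
    correct / nrow(dataset)
  }, numeric(1))
  best <- which.max(acc)  # which.max returns the first maximum
  desc <- vapply(specs, function(sp) {
    switch(sp$family,
           knn = sprintf("knn k=%d", sp$k),
           nc = sprintf("nc %s", sp$metric),
           svm = if (sp$kernel == "linear")
             sprintf("svm linear C=%g", sp$C)
           else sprintf("svm rbf C=%g gamma=%g", sp$C, sp$gamma),
           gmm = sprintf("gmm %s", sp$covariance))
  }, character(1))
  sc_log("posture_tune(%s): best %s (CV acc %.4f)", family, desc[best],
         acc[best])
  list(best_spec = specs[[best]], cv_accuracy = acc[best],
       results = data.frame(spec = desc, cv_accuracy = acc))
}
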