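#' Evaluate a posture classifier
#'
#' Computes the confusion matrix, per-label precision/recall/F1, their
#' macro (unweighted per-label) means with across-label standard
#' deviations, and overall accuracy. A label never predicted gets precision
#' 0 (and F1 0 when precision + recall is 0), the usual convention for
#' undefined ratios.
#'
#' @param model a fitted `posture_model`, or any function mapping a
#'   data.frame with `CMx`,`CMy` to labels.
#' @param testset a `cm_dataset` with labels drawn from the model's class
#'   set.
#' @return object of class `evaluation_report`: `confusion` (true x
#'   predicted counts), `per_label` (precision/recall/f1 per class),
#'   `precision`, `recall`, `f1` (each `c(mean, sd)`), `accuracy`, `n`.
#' @export
posture_evaluate <- function(model, testset) {
  if (nrow(testset) == 0L) stop_sc("empty test set")
  pred <- if (inherits(model, "posture_model")) {
    predict(model, testset)
  } else {
    model(testset)
  }
  classes <- if (inherits(model, "posture_model")) model$classes else
    sort(unique(c(testset$label, pred)))
  extra <- setdiff(unique(testset$label), classes)
  if (length(extra)) {
    stop_sc("test labels outside the classifier's class set: %s",
            paste(extra, collapse = ","))
  }
  classification_report(truth = testset$label, pred = pred,
                        classes = classes)
}

#' Classification metrics from label vectors
#'
#' @param truth,pred true and predicted labels.
#' @param classes label set `L`; defaults to the union of observed labels.
#' @return an `evaluation_report` (see [posture_evaluate()]).
#' @export
classification_report <- function(truth, pred,
                                  classes = sort(unique(c(truth, pred)))) {
  truth <- factor(truth, levels = classes)
  pred <- factor(pred, levels = classes)
  if (anyNA(pred)) pred[is.na(pred)] <- classes[1]  # unmapped GMM component
  conf <- table(truth = truth, predicted = pred)
  tp <- diag(conf)
  p_den <- colSums(conf)  # predicted-as-i counts
  r_den <- rowSums(conf)  # true-i counts
  prec <- ifelse(p_den > 0, tp / p_den, 0)
  rec <- ifelse(r_den > 0, tp / r_den, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  per_label <- data.frame(label = classes, precision = as.numeric(prec),
                          recall = as.numeric(rec), f1 = as.numeric(f1))
  structure(list(
    confusion = conf,
    per_label = per_label,
    precision = c(mean = mean(prec), sd = stats::sd(prec)),
    recall = c(mean = mean(rec), sd = stats::sd(rec)),
    f1 = c(mean = mean(f1), sd = stats::sd(f1)),
    accuracy = sum(tp) / length(truth),
    n = length(truth),
    label_set = classes), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> n=%d classes={%s}\n", x$n,
              paste(x$label_set, collapse = ",")))
  cat(sprintf("  accuracy  %.3f\n", x$accuracy))
  for (m in c("precision", "recall", "f1")) {
    cat(sprintf("  %-9s %.3f +/- %.3f\n", m, x[[m]]["mean"], x[[m]]["sd"]))
  }
  invisible(x)
}

#' Decision map over the seat plane
#'
#' Predicts the posture label on a regular grid covering
#' `[0, dRL] x [0, dBF]` (inclusive) at the given step, mirroring the
#' decision-boundary evaluation of the classifier over the whole seat.
#'
#' @param model a fitted `posture_model`.
#' @param geometry a [chair_geometry()].
#' @param step grid step in cm (default 0.1).
#' @return object of class `decision_map`: `x`, `y` (grid axes) and
#'   `labels`, a `length(x) x length(y)` character matrix.
#' @export
decision_map <- function(model, geometry = chair_geometry(), step = 0.1) {
  if (step <= 0) stop_sc("step must be > 0")
  x <- seq(0L, floor(geometry$dRL / step + 1e-9)) * step
  y <- seq(0L, floor(geometry$dBF / step + 1e-9)) * step
  grid <- as.matrix(expand.grid(CMx = x, CMy = y))
  lab <- predict(model, grid)
  structure(list(x = x, y = y,
                 labels = matrix(lab, nrow = length(x), ncol = length(y)),
                 classes = model$classes, step = step),
            class = "decision_map")
}

#' @export
print.decision_map <- function(x, ...) {
  cat(sprintf("<decision_map> %d x %d cells, step %g cm\n",
              length(x$x), length(x$y), x$step))
  invisible(x)
}

#' @describeIn decision_map flatten to a data.frame (`CMx`, `CMy`, `label`)
#'   suitable for CSV export.
#' @param row.names,optional,... passed conventions; unused.
#' @export
as.data.frame.decision_map <- function(x, row.names = NULL,
                                       optional = FALSE, ...) {
  data.frame(CMx = rep(x$x, times = length(x$y)),
             CMy = rep(x$y, each = length(x$x)),
             label = as.vector(x$labels), stringsAsFactors = FALSE)
}

#' Count connected decision regions
#'
#' Counts 4-connected components of constant label in a decision map; small
#' "islands" inside another class's region are the overfitting signature
#' that grows as the kNN neighbour count shrinks.
#'
#' @param map a [decision_map()].
#' @return integer component count.
#' @export
count_label_islands <- function(map) {
  lab <- map$labels
  nr <- nrow(lab); nc <- ncol(lab)
  comp <- matrix(0L, nr, nc)
  n_comp <- 0L
  for (start in seq_len(nr * nc)) {
    if (comp[start] != 0L) next
    n_comp <- n_comp + 1L
    stack <- start
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (comp[cur] != 0L) next
      comp[cur] <- n_comp
      r <- (cur - 1L) %% nr + 1L
      c <- (cur - 1L) %/% nr + 1L
      for (nb in c(if (r > 1L) cur - 1L, if (r < nr) cur + 1L,
                   if (c > 1L) cur - nr, if (c < nc) cur + nr)) {
        if (comp[nb] == 0L && lab[nb] == lab[cur]) stack <- c(stack, nb)
      }
    }
  }
  n_comp
}

#' Predicted-label frequencies in transition periods
#'
#' For every pair of consecutive bouts, predicts the posture label of each
#' 1-s transition window between them and tabulates the relative frequency
#' (%) of each class, plus an average row across transitions. Rows sum to
#' 100.
#'
#' @param model a fitted `posture_model`.
#' @param dataset output of [extract_cm_dataset()] with
#'   `include_transitions = TRUE`.
#' @return data.frame, one row per transition (named `"P1-P2"` style) plus
#'   `"Average"`, one column per model class, values in percent.
#' @export
transition_frequencies <- function(model, dataset) {
  bl <- attr(dataset, "bout_labels")
  if (is.null(bl) || length(bl) < 2) {
    stop_sc("dataset must come from a session with >= 2 bouts")
  }
  classes <- model$classes
  rows <- list()
  for (i in seq_len(length(bl) - 1)) {
    seg <- dataset[dataset$segment == paste0("T", i), , drop = FALSE]
    nm <- paste0(bl[i], "-", bl[i + 1])
    if (nrow(seg) == 0L) {
      warning(sprintf("no transition samples between bouts %d and %d; row %s omitted",
                      i, i + 1, nm), call. = FALSE)
      next
    }
    pred <- factor(predict(model, seg), levels = classes)
    rows[[nm]] <- 100 * as.numeric(table(pred)) / length(pred)
  }
  if (!length(rows)) stop_sc("no transition rows could be computed")
  out <- do.call(rbind, rows)
  out <- rbind(out, Average = colMeans(out))
  out <- as.data.frame(out)
  names(out) <- classes
  out
}
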