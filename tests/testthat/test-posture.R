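test_that("every family separates two tight clusters perfectly", {
  train <- two_cluster_cm(n = 60, sd = 0.1, seed = 1)
  test <- two_cluster_cm(n = 40, sd = 0.1, seed = 2)
  for (spec in list(model_spec("knn", k = 5), model_spec("nc"),
                    model_spec("svm", kernel = "linear", C = 1e-3),
                    model_spec("svm", kernel = "rbf", C = 0.1,
                               gamma = 0.5),
                    model_spec("gmm", covariance = "tied"),
                    model_spec("gmm", covariance = "full"))) {
    m <- posture_train(train, spec)
    expect_equal(posture_evaluate(m, test)$accuracy, 1.0,
                 info = spec$family)
  }
})

test_that("kNN k=1 returns a training point's own label", {
  train <- two_cluster_cm(n = 30, seed = 4)
  m <- posture_train(train, model_spec("knn", k = 1))
  expect_equal(predict(m, train[17, ]), train$label[17])
  # inverse-distance zero-distance convention with k > 1 too
  m5 <- posture_train(train, model_spec("knn", k = 5))
  expect_equal(predict(m5, train[17, ]), train$label[17])
})

test_that("training-set validation catches bad inputs", {
  train <- two_cluster_cm(n = 10)
  expect_error(posture_train(train, model_spec("knn", k = 100)),
               "exceeds")
  bad <- cm_dataset(c(1, 2), c(1, 2), c("P4", "P1"))
  expect_error(posture_train(bad, model_spec("nc")), "P4")
  one <- cm_dataset(c(1, 2, 3), c(1, 2, 3), c("P1", "P1", "P2"))
  expect_error(posture_train(one, model_spec("gmm", covariance = "full")),
               "tied or spherical")
})

test_that("NC fits class centroids (sample-mean oracle)", {
  st <- posture_stats()
  five <- c("P1", "P2", "P3", "P5", "P6")
  train <- gen_cm_dataset(st, five, 400, seed = 31)
  m <- posture_train(train, model_spec("nc", metric = "euclidean"))
  for (cl in five) {
    se_x <- st[cl, "sd_x"] / sqrt(400)
    se_y <- st[cl, "sd_y"] / sqrt(400)
    expect_lt(abs(m$fit$centroids[cl, 1] - st[cl, "mean_x"]), 3 * se_x)
    expect_lt(abs(m$fit$centroids[cl, 2] - st[cl, "mean_y"]), 3 * se_y)
  }
})

test_that("evaluation metrics match hand-computed values", {
  # y=[1,1,0,0], yhat=[1,0,0,0]
  r <- classification_report(truth = c("1", "1", "0", "0"),
                             pred = c("1", "0", "0", "0"))
  expect_equal(r$accuracy, 0.75)
  expect_equal(unname(r$precision["mean"]), 5 / 6)
  expect_equal(unname(r$recall["mean"]), 0.75)
  expect_equal(unname(r$f1["mean"]),
               mean(c(2 * (2 / 3 * 1) / (5 / 3), 2 * (1 * 0.5) / 1.5)))
  expect_equal(sum(r$confusion), r$n)
  expect_equal(sum(diag(r$confusion)) / r$n, r$accuracy)

  perfect <- classification_report(c("a", "b", "b"), c("a", "b", "b"))
  expect_equal(perfect$accuracy, 1)
  expect_equal(unname(perfect$f1["mean"]), 1)
  expect_true(all(r$per_label$precision >= 0 & r$per_label$precision <= 1))

  # constant predictor on a balanced 2-class set
  const <- classification_report(rep(c("a", "b"), 10), rep("a", 20))
  expect_equal(const$accuracy, 0.5)
  expect_equal(unname(const$recall["mean"]), 0.5)
  # macro metrics are unweighted means of the per-label values
  expect_equal(unname(const$precision["mean"]),
               mean(const$per_label$precision))
})

test_that("posture_evaluate guards its contract", {
  train <- two_cluster_cm(30)
  m <- posture_train(train, model_spec("nc"))
  expect_error(posture_evaluate(m, train[0, ]), "empty")
  alien <- cm_dataset(1, 1, "P9")
  expect_error(posture_evaluate(m, alien), "outside")
})

test_that("stratified folds keep class proportions within one sample", {
  set.seed(8)
  labels <- sample(rep(c("P1", "P2", "P5"), times = c(23, 41, 17)))
  ids <- stratified_folds(labels, 5)
  tab <- table(labels, ids)
  for (cl in rownames(tab)) {
    expect_lte(max(tab[cl, ]) - min(tab[cl, ]), 1)
  }
  expect_error(stratified_folds(c("a", "a", "b"), 5), "fewer than 5")
})

test_that("grid search is exhaustive with deterministic first-max ties", {
  train <- two_cluster_cm(n = 25, sd = 0.1, seed = 6)
  tuned <- posture_tune(train, "svm",
                        grid = list(kernel = c("linear", "rbf"),
                                    C = c(0.01, 1), gamma = c(0.5)))
  expect_equal(nrow(tuned$results), 4)  # 2 linear C + 2 rbf C x 1 gamma
  expect_equal(tuned$cv_accuracy, 1.0)
  # separable data: every grid point ties at 1.0, first one wins
  expect_equal(tuned$best_spec$kernel, "linear")
  expect_equal(tuned$best_spec$C, 0.01)

  single <- posture_tune(train, "nc", grid = list(metric = "cityblock"))
  expect_equal(single$best_spec$metric, "cityblock")
  expect_equal(nrow(single$results), 1)
})

test_that("decision_map covers the seat grid and is total", {
  train <- two_cluster_cm(40)
  m <- posture_train(train, model_spec("nc"))
  dm <- decision_map(m, chair_geometry(), step = 0.1)
  expect_equal(dim(dm$labels), c(304, 262))
  expect_true(all(dm$labels %in% m$classes))
  expect_error(decision_map(m, step = 0), "step")
})

test_that("NC decision boundary is the perpendicular bisector", {
  train <- two_cluster_cm(200, sd = 0.05, seed = 9)
  m <- posture_train(train, model_spec("nc", metric = "euclidean"))
  dm <- decision_map(m, chair_geometry(), step = 0.1)
  cent <- m$fit$centroids
  # boundary cells: 4-neighbour label changes along x
  change <- which(dm$labels[-1, ] != dm$labels[-nrow(dm$labels), ],
                  arr.ind = TRUE)
  xs <- (dm$x[change[, 1]] + dm$x[change[, 1] + 1]) / 2
  ys <- dm$y[change[, 2]]
  d1 <- sqrt((xs - cent[1, 1])^2 + (ys - cent[1, 2])^2)
  d2 <- sqrt((xs - cent[2, 1])^2 + (ys - cent[2, 2])^2)
  expect_true(all(abs(d1 - d2) < 2 * dm$step))
})

test_that("larger k smooths away decision islands (monotone trend)", {
  st <- posture_stats()
  seven <- c("P1", "P2", "P3", "P5", "P6", "P7", "P8")
  train <- gen_cm_dataset(st, seven, 500, seed = 1)
  m <- posture_train(train, model_spec("knn", k = 3000))
  islands <- vapply(c(250, 1000, 3000), function(k) {
    mk <- m
    mk$spec$k <- as.integer(k)
    count_label_islands(decision_map(mk, chair_geometry(), step = 0.5))
  }, numeric(1))
  expect_true(all(diff(islands) <= 0))
  expect_gte(islands[1], 7)  # at least one region per class
})

test_that("GMM five-class accuracy exceeds seven-class (cluster shape)", {
  st <- posture_stats()
  five <- c("P1", "P2", "P3", "P5", "P6")
  seven <- c(five, "P7", "P8")
  acc <- vapply(list(five, seven), function(cls) {
    tr <- gen_cm_dataset(st, cls, 500, seed = 1)
    te <- gen_cm_dataset(st, cls, 300, seed = 2)
    sp <- if (length(cls) == 5) model_spec("gmm", covariance = "tied")
          else model_spec("gmm", covariance = "full")
    posture_evaluate(posture_train(tr, sp), te)$accuracy
  }, numeric(1))
  expect_gt(acc[1], acc[2])
})

test_that("transition frequencies are normalized rows over bout pairs", {
  st <- posture_stats()
  plan <- session_plan(c("P1", "P3", "P5"), duration_s = 30,
                       transition_s = 5, seed = 21)
  sess <- gen_posture_session(plan, fs = 20)
  ds <- extract_cm_dataset(sess$stream, plan$classes,
                           include_transitions = TRUE)
  train <- gen_cm_dataset(st, c("P1", "P2", "P3", "P5", "P6"), 500,
                          seed = 3)
  m <- posture_train(train, model_spec("nc"))
  tf <- transition_frequencies(m, ds)
  expect_equal(rownames(tf), c("P1-P3", "P3-P5", "Average"))
  expect_true(all(abs(rowSums(tf) - 100) < 0.01))
  expect_true(all(tf >= 0))
  # the P1 -> P3 path crosses P2's decision region (centroid ordering)
  expect_gt(tf["P1-P3", "P2"], 0)

  # constant classifier (all centroids identical -> first class wins)
  mc <- m
  mc$fit$centroids[] <- 1
  tfc <- transition_frequencies(mc, ds)
  expect_true(all(tfc[, m$classes[1]] == 100))
  expect_true(all(tfc[, m$classes[-1]] == 0))

  nobouts <- ds[ds$segment == "B1", ]
  attr(nobouts, "bout_labels") <- attr(ds, "bout_labels")[1]
  expect_error(transition_frequencies(m, nobouts), "bouts")
})
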