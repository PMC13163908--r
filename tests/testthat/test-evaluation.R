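# Confusion matrices, classification metrics, baselines, benchmark grid.

# per-sample brute-force oracle for all metrics
metrics_oracle <- function(y_true, y_pred, K) {
  acc <- mean(y_true == y_pred)
  per <- lapply(0:(K - 1), function(k) {
    tp <- sum(y_true == k & y_pred == k)
    fp <- sum(y_true != k & y_pred == k)
    fn <- sum(y_true == k & y_pred != k)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(p = p, r = r, f = f)
  })
  M <- do.call(rbind, per)
  list(accuracy = acc, precision = M[, "p"], recall = M[, "r"], f1 = M[, "f"])
}

test_that("confusion_matrix counts truth/prediction pairs", {
  expect_equal(confusion_matrix(c(0, 1, 2), c(0, 1, 2), 3), diag(3),
               ignore_attr = TRUE)
  expect_equal(confusion_matrix(c(0, 0, 1), c(0, 1, 1), 2),
               matrix(c(1, 0, 1, 1), 2), ignore_attr = TRUE)
  set.seed(61)
  yt <- sample(0:3, 57, replace = TRUE)
  yp <- sample(0:3, 57, replace = TRUE)
  expect_equal(sum(confusion_matrix(yt, yp, 4)), 57)
  expect_error(confusion_matrix(c(0, 4), c(0, 1), 3), "out of range")
  expect_error(confusion_matrix(c(0, 1), c(0), 2), "lengths")
})

test_that("metrics match the hand-derived worked confusion matrix", {
  cm <- matrix(c(8, 2, 0,
                 1, 9, 0,
                 0, 0, 10), 3, byrow = TRUE)
  m <- metrics_from_cm(cm)
  expect_equal(m$accuracy, 27 / 30)
  expect_equal(m$precision, c(8 / 9, 9 / 11, 1))
  expect_equal(m$recall, c(0.8, 0.9, 1))
  f1_expected <- 2 * m$precision * m$recall / (m$precision + m$recall)
  expect_equal(m$f1, f1_expected)
  expect_equal(m$macro_precision, mean(c(8 / 9, 9 / 11, 1)))
  expect_equal(m$macro_recall, mean(c(0.8, 0.9, 1)))
  expect_equal(m$macro_f1, mean(f1_expected))
})

test_that("degenerate classes report 0 with a warning", {
  cm <- matrix(c(5, 0, 0,
                 0, 5, 0,
                 0, 0, 0), 3, byrow = TRUE)   # class 2 absent, never predicted
  expect_warning(m <- metrics_from_cm(cm), "class")
  expect_equal(m$precision[3], 0)
  expect_equal(m$recall[3], 0)
  expect_equal(m$f1[3], 0)
  expect_equal(m$accuracy, 1)
})

test_that("metrics agree with the per-sample oracle on random fixtures", {
  set.seed(62)
  for (i in 1:20) {
    K <- sample(2:5, 1)
    n <- sample(20:80, 1)
    yt <- sample(0:(K - 1), n, replace = TRUE)
    yp <- ifelse(runif(n) < 0.7, yt, sample(0:(K - 1), n, replace = TRUE))
    m <- suppressWarnings(metrics_from_cm(confusion_matrix(yt, yp, K)))
    o <- metrics_oracle(yt, yp, K)
    expect_equal(m$accuracy, o$accuracy)
    expect_equal(m$precision, o$precision, ignore_attr = TRUE)
    expect_equal(m$recall, o$recall, ignore_attr = TRUE)
    expect_equal(m$f1, o$f1, ignore_attr = TRUE)
  }
})

test_that("balanced test sets make macro recall equal mean per-class accuracy", {
  set.seed(63)
  yt <- rep(0:2, each = 30)
  yp <- ifelse(runif(90) < 0.8, yt, sample(0:2, 90, replace = TRUE))
  m <- metrics_from_cm(confusion_matrix(yt, yp, 3))
  per_class_acc <- vapply(0:2, function(k) mean(yp[yt == k] == k), numeric(1))
  expect_equal(m$macro_recall, mean(per_class_acc))
})

test_that("LDA and KNN baselines separate the easy synthetic preset", {
  sp <- small_split(n_per_class = 40)
  for (method in c("lda", "knn")) {
    fit <- fit_classical(method, sp$train$reflectance, sp$train$labels)
    rep_ <- evaluate_model(function(X) predict_classical(fit, X), sp)
    expect_gt(rep_$test_accuracy, 0.9)
  }
})

test_that("scikit-learn-backed RF and SVM baselines run on small data", {
  sp <- small_split(n_per_class = 15)
  for (method in c("rf", "svm")) {
    fit <- fit_classical(method, sp$train$reflectance, sp$train$labels, seed = 1)
    pred <- predict_classical(fit, sp$test$reflectance)
    expect_length(pred, n_samples(sp$test))
    expect_gt(mean(pred == sp$test$labels), 0.8)
  }
})

test_that("benchmark grid produces one mean/sd cell per model and dataset", {
  sp1 <- small_split(n_per_class = 20, seed = 1)
  sp2 <- small_split(n_per_class = 20, seed = 2)
  grid <- benchmark_grid(
    models = list(lda = "lda", knn = "knn"),
    datasets = list(a = sp1, b = sp2),
    cfg = fast_cfg(seeds = c(1L, 2L))
  )
  acc <- grid$table[grid$table$metric == "test_accuracy", ]
  expect_equal(nrow(acc), 4L)
  expect_true(all(is.finite(acc$mean)))
  # reproducible given the seed list
  grid2 <- benchmark_grid(list(lda = "lda", knn = "knn"),
                          list(a = sp1, b = sp2), fast_cfg(seeds = c(1L, 2L)))
  expect_identical(grid$table, grid2$table)
})

test_that("a failing grid cell is reported without aborting the grid", {
  sp <- small_split(n_per_class = 20)
  broken <- function(nb, nc) stop("boom")
  grid <- benchmark_grid(list(bad = broken, lda = "lda"),
                         list(d = sp), fast_cfg())
  expect_match(grid$cells[["bad|d"]]$error, "boom")
  acc <- grid$table[grid$table$metric == "test_accuracy", ]
  expect_true(is.na(acc$mean[acc$model == "bad"]))
  expect_true(is.finite(acc$mean[acc$model == "lda"]))
})

test_that("models clear 0.95 on the high-separation Vis-NIR preset", {
  # scaled-down analogue of the full-spectrum benchmark: every baseline
  # should be near-perfect when class separation is high
  sp <- pp_split(small_split(n_per_class = 40, delta = 0.08), "sg:5:3,snv")
  grid <- benchmark_grid(list(lda = "lda", knn = "knn"),
                         list(visnir = sp), fast_cfg(seeds = c(1L, 2L, 3L)))
  acc <- grid$table[grid$table$metric == "test_accuracy", ]
  expect_true(all(acc$mean >= 0.95))
})
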