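# Evaluation: confusion matrices, accuracy and per-class / macro
# precision-recall-F1, classical baselines on the same splits, and the
# model x dataset benchmark grid with multi-seed aggregation.

#' Confusion matrix
#'
#' @param y_true,y_pred integer vectors of 0-based class ids, equal
#'   length.
#' @param K number of classes.
#' @return `K x K` integer matrix of counts; rows are true classes,
#'   columns predicted classes.
#' @export
confusion_matrix <- function(y_true, y_pred, K) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred)) stop_fmt("y_true and y_pred lengths differ")
  if (length(y_true) && (min(y_true, y_pred) < 0L || max(y_true, y_pred) >= K)) {
    stop_fmt("labels out of range 0..%d", K - 1L)
  }
  cm <- matrix(0L, K, K)
  for (i in seq_along(y_true)) {
    cm[y_true[i] + 1L, y_pred[i] + 1L] <- cm[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  }
  cm
}

#' Classification metrics from a confusion matrix
#'
#' Computes accuracy (trace over total) and, per class i, precision
#' `TP_i / (TP_i + FP_i)`, recall `TP_i / (TP_i + FN_i)` and their
#' harmonic-mean F1; macro metrics are unweighted means over classes.
#' A degenerate denominator (class never predicted, absent, or both)
#' yields 0 for that class's metric with a warning.
#'
#' @param cm square confusion matrix (rows true, columns predicted).
#' @return list with `accuracy`, vectors `precision`, `recall`, `f1`, and
#'   `macro_precision`, `macro_recall`, `macro_f1`, plus the matrix.
#' @export
metrics_from_cm <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop_fmt("confusion matrix must be square")
  total <- sum(cm)
  if (total <= 0) stop_fmt("empty confusion matrix")
  K <- nrow(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe_div <- function(num, den, what) {
    out <- numeric(K)
    ok <- den > 0
    out[ok] <- num[ok] / den[ok]
    if (any(!ok)) {
      warning(sprintf("%s undefined for class(es) %s; reported as 0", what,
                      paste(which(!ok) - 1L, collapse = ", ")), call. = FALSE)
    }
    out
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- numeric(K)
  pos <- (precision + recall) > 0
  f1[pos] <- 2 * precision[pos] * recall[pos] / (precision[pos] + recall[pos])
  list(accuracy = sum(tp) / total,
       precision = precision, recall = recall, f1 = f1,
       macro_precision = mean(precision), macro_recall = mean(recall),
       macro_f1 = mean(f1), confusion = cm)
}

#' Evaluate a classifier on the validation and test partitions
#'
#' @param predict_fn function taking a spectra matrix and returning
#'   0-based predicted class ids.
#' @param splits a `split_result`.
#' @return list with `val_accuracy`, `test_accuracy` and the full `test`
#'   metrics of [metrics_from_cm()].
#' @export
evaluate_model <- function(predict_fn, splits) {
  K <- length(splits$train$class_names)
  acc_of <- function(ds) {
    if (n_samples(ds) == 0L) return(NA_real_)
    mean(predict_fn(ds$reflectance) == ds$labels)
  }
  val_acc <- acc_of(splits$val)
  pred_test <- predict_fn(splits$test$reflectance)
  cm <- confusion_matrix(splits$test$labels, pred_test, K)
  list(val_accuracy = val_acc,
       test_accuracy = mean(pred_test == splits$test$labels),
       test = metrics_from_cm(cm))
}

#' Write a labelled confusion matrix as delimited text
#'
#' @param cm confusion matrix.
#' @param class_names class names for row/column labels.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_confusion <- function(cm, class_names, path) {
  df <- as.data.frame(cm)
  names(df) <- paste0("pred_", class_names)
  df <- cbind(true = class_names, df)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- classical baselines ---------------------------------------------

standardize_fit <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0] <- 1
  list(mu = mu, sd = sd)
}
standardize_apply <- function(st, X) sweep(sweep(X, 2, st$mu), 2, st$sd, "/")

sklearn_available <- function() {
  py <- Sys.which("python")
  if (!nzchar(py)) return(FALSE)
  ok <- suppressWarnings(system2(py, c("-c", shQuote("import sklearn")),
                                 stdout = FALSE, stderr = FALSE))
  identical(ok, 0L)
}

# Random forest and RBF-SVM are delegated to scikit-learn through a small
# subprocess bridge (no R implementation of either is assumed installed).
sklearn_fit_predict <- function(method, X_train, y_train, X_list, seed) {
  script <- system.file("python", "classical_baselines.py", package = "specorigin")
  if (script == "") script <- file.path("inst", "python", "classical_baselines.py")
  if (!file.exists(script)) stop_fmt("classical_baselines.py bridge script not found")
  if (!sklearn_available()) {
    stop_fmt(paste("the '%s' baseline needs python with scikit-learn on PATH;",
                   "use the 'lda' or 'knn' baselines instead"), method)
  }
  dir <- tempfile("sk")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  utils::write.table(cbind(y_train, X_train), file.path(dir, "train.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  for (i in seq_along(X_list)) {
    utils::write.table(X_list[[i]], file.path(dir, sprintf("pred%d.csv", i)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  status <- system2(Sys.which("python"),
                    c(script, method, shQuote(dir), length(X_list), seed),
                    stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(status, "status"))) {
    stop_fmt("scikit-learn bridge failed:\n%s", paste(status, collapse = "\n"))
  }
  lapply(seq_along(X_list), function(i) {
    as.integer(readLines(file.path(dir, sprintf("out%d.txt", i))))
  })
}

#' Fit a classical baseline classifier
#'
#' Baselines with fixed, documented hyperparameters: `"lda"` (MASS, no
#' shrinkage), `"knn"` (FNN, 5 neighbours), `"rf"` (scikit-learn random
#' forest, 100 trees) and `"svm"` (scikit-learn RBF kernel, unit cost).
#' KNN and SVM standardize features with train-fitted statistics.
#'
#' @param method one of `"lda"`, `"knn"`, `"rf"`, `"svm"`.
#' @param X_train training feature matrix.
#' @param y_train 0-based training labels.
#' @param seed seed for the stochastic forest.
#' @return a `classical_model`; predict with [predict_classical()].
#' @export
fit_classical <- function(method = c("lda", "knn", "rf", "svm"),
                          X_train, y_train, seed = 1L) {
  method <- match.arg(method)
  X_train <- check_matrix(X_train, "X_train")
  y_train <- as.integer(y_train)
  model <- switch(method,
    lda = MASS::lda(X_train, grouping = factor(y_train)),
    knn = {
      st <- standardize_fit(X_train)
      list(st = st, X = standardize_apply(st, X_train), y = y_train, k = 5L)
    },
    rf = ,
    svm = {
      st <- if (method == "svm") standardize_fit(X_train)
      list(st = st,
           X = if (is.null(st)) X_train else standardize_apply(st, X_train),
           y = y_train, seed = as.integer(seed))
    }
  )
  structure(list(method = method, model = model), class = "classical_model")
}

#' Predict 0-based class ids from a classical baseline
#'
#' @param fit a `classical_model` from [fit_classical()].
#' @param X feature matrix.
#' @return integer vector of predicted class ids.
#' @export
predict_classical <- function(fit, X) {
  stopifnot(inherits(fit, "classical_model"))
  X <- check_matrix(X)
  switch(fit$method,
    lda = as.integer(as.character(stats::predict(fit$model, X)$class)),
    knn = {
      Xs <- standardize_apply(fit$model$st, X)
      as.integer(as.character(
        FNN::knn(fit$model$X, Xs, factor(fit$model$y), k = fit$model$k)))
    },
    {
      Xs <- if (is.null(fit$model$st)) X else standardize_apply(fit$model$st, X)
      sklearn_fit_predict(fit$method, fit$model$X, fit$model$y, list(Xs),
                          fit$model$seed)[[1]]
    }
  )
}

# ---- benchmark grid ---------------------------------------------------

classical_methods <- c("lda", "knn", "rf", "svm")

eval_classical_multiseed <- function(method, splits, seeds) {
  accs <- vapply(seeds, function(s) {
    fit <- with_seed(s, fit_classical(method, splits$train$reflectance,
                                      splits$train$labels, seed = s))
    rep <- evaluate_model(function(X) predict_classical(fit, X), splits)
    c(rep$val_accuracy, rep$test_accuracy, rep$test$macro_precision,
      rep$test$macro_recall, rep$test$macro_f1)
  }, numeric(5))
  accs
}

#' Run a model x dataset benchmark grid
#'
#' Evaluates every model on every dataset split, aggregating metrics as
#' mean +/- sample sd over `cfg$seeds`. Deep models (network specs or
#' builder functions) go through [run_multiseed()]; classical baselines
#' (method name strings) are re-fitted per seed on the same splits. A
#' failing cell is recorded (with its error message) without aborting the
#' rest of the grid.
#'
#' @param models named list; each element a `network_spec`, a builder
#'   `function(n_bands, n_classes)`, or one of `"lda"`, `"knn"`, `"rf"`,
#'   `"svm"`.
#' @param datasets named list of `split_result` objects (e.g. the
#'   full-spectrum, PCA-20 and UMAP-20 variants of both band regimes).
#' @param cfg a [train_config()].
#' @return a `benchmark_grid` object: long-format data frame in `$table`
#'   (model, dataset, metric, mean, sd) plus per-cell details in
#'   `$cells`.
#' @export
benchmark_grid <- function(models, datasets, cfg = train_config()) {
  stopifnot(length(names(models)) == length(models),
            length(names(datasets)) == length(datasets))
  metrics <- c("val_accuracy", "test_accuracy", "macro_precision",
               "macro_recall", "macro_f1")
  rows <- list()
  cells <- list()
  for (mn in names(models)) {
    for (dn in names(datasets)) {
      key <- paste(mn, dn, sep = "|")
      res <- tryCatch({
        if (is.character(models[[mn]])) {
          vals <- eval_classical_multiseed(models[[mn]], datasets[[dn]], cfg$seeds)
          list(mean = rowMeans(vals), sd = apply(vals, 1, stats::sd), detail = NULL)
        } else {
          rep <- run_multiseed(models[[mn]], datasets[[dn]], cfg)
          list(mean = rep$summary$mean, sd = rep$summary$sd, detail = rep)
        }
      }, error = function(e) e)
      if (inherits(res, "error")) {
        cells[[key]] <- list(error = conditionMessage(res))
        rows[[key]] <- data.frame(model = mn, dataset = dn, metric = metrics,
                                  mean = NA_real_, sd = NA_real_)
      } else {
        cells[[key]] <- res
        rows[[key]] <- data.frame(model = mn, dataset = dn, metric = metrics,
                                  mean = res$mean, sd = res$sd)
      }
    }
  }
  structure(list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 cells = cells, seeds = cfg$seeds),
            class = "benchmark_grid")
}

#' @export
print.benchmark_grid <- function(x, ...) {
  acc <- x$table[x$table$metric == "test_accuracy", ]
  cat("benchmark grid (test accuracy, mean +/- sd over seeds):\n")
  for (i in seq_len(nrow(acc))) {
    cat(sprintf("  %-12s %-14s %s\n", acc$model[i], acc$dataset[i],
                if (is.na(acc$mean[i])) "FAILED"
                else sprintf("%.4f +/- %.4f", acc$mean[i], acc$sd[i])))
  }
  invisible(x)
}

#' Write benchmark grid results as delimited text
#'
#' @param grid a `benchmark_grid`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_benchmark <- function(grid, path) {
  utils::write.table(grid$table, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
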