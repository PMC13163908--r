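# Training protocol: AdamW, cross-entropy, early stopping on validation
# accuracy with best-checkpoint restoration, repeated over several seeds
# and aggregated as mean +/- sample standard deviation.

#' Training configuration
#'
#' Defaults follow the deep-learning protocol used throughout this
#' package: batch size 8, initial learning rate 5e-4, weight decay 1e-5,
#' AdamW, at most 50 epochs with patience 10 on validation accuracy, and
#' five random seeds. The learning rate is held constant (no schedule).
#'
#' @param batch_size minibatch size (>= 1).
#' @param learning_rate AdamW step size.
#' @param weight_decay decoupled weight-decay coefficient.
#' @param max_epochs maximum number of epochs.
#' @param patience epochs without validation-accuracy improvement before
#'   stopping (`<= max_epochs`).
#' @param seeds distinct integer seeds for the repeated runs.
#' @return a `train_config` object.
#' @export
train_config <- function(batch_size = 8L, learning_rate = 5e-4,
                         weight_decay = 1e-5, max_epochs = 50L,
                         patience = 10L, seeds = 1:5) {
  batch_size <- as.integer(batch_size)
  max_epochs <- as.integer(max_epochs)
  patience <- as.integer(patience)
  seeds <- as.integer(seeds)
  if (batch_size < 1L) stop_fmt("batch_size must be >= 1")
  if (patience > max_epochs) stop_fmt("patience (%d) must be <= max_epochs (%d)", patience, max_epochs)
  if (anyDuplicated(seeds)) stop_fmt("seeds must be distinct")
  structure(list(batch_size = batch_size, learning_rate = learning_rate,
                 weight_decay = weight_decay, max_epochs = max_epochs,
                 patience = patience, seeds = seeds,
                 loss = "cross-entropy", optimizer = "AdamW"),
            class = "train_config")
}

# ---- AdamW ------------------------------------------------------------

adamw_init <- function(params) {
  zero <- function(p) tree_map2(p, p, function(a, b) a * 0)
  list(m = zero(params), v = zero(params), t = 0L)
}

adamw_step <- function(params, grads, state, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- tree_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  c1 <- 1 / (1 - beta1^state$t)
  c2 <- 1 / (1 - beta2^state$t)
  upd <- tree_map2(state$m, state$v,
                   function(m, v) (m * c1) / (sqrt(v * c2) + eps))
  params <- tree_map2(params, upd,
                      function(p, u) p - lr * u - lr * weight_decay * p)
  list(params = params, state = state)
}

# ---- early-stopping driver -------------------------------------------

#' Epoch at which early stopping halts for a validation-accuracy sequence
#'
#' Pure implementation of the stopping rule: training halts at the first
#' epoch `e` such that no strict improvement of the running best
#' validation accuracy occurred in the last `patience` epochs (i.e.
#' `e - best_epoch >= patience`), or at the end of the sequence.
#'
#' @param val_acc numeric vector of per-epoch validation accuracies.
#' @param patience patience in epochs.
#' @return list with `stop_epoch`, `best_epoch` (earliest epoch attaining
#'   the running maximum) and `stopped_early` flag.
#' @export
early_stop_epoch <- function(val_acc, patience) {
  best <- -Inf; best_epoch <- 0L
  for (e in seq_along(val_acc)) {
    if (val_acc[e] > best) {   # strict improvement
      best <- val_acc[e]; best_epoch <- e
    }
    if (e - best_epoch >= patience) {
      return(list(stop_epoch = e, best_epoch = best_epoch, stopped_early = TRUE))
    }
  }
  list(stop_epoch = length(val_acc), best_epoch = best_epoch,
       stopped_early = FALSE)
}

# Generic epoch loop shared by the real trainer and by stub-model tests.
# step_fn(epoch) runs one training epoch and returns list(train_loss=);
# eval_fn(epoch) returns list(val_loss=, val_acc=); snapshot_fn() captures
# the current model state; the best snapshot is returned.
run_training_loop <- function(step_fn, eval_fn, snapshot_fn, max_epochs,
                              patience) {
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), val_acc = numeric())
  best <- -Inf; best_epoch <- 0L; best_snap <- NULL
  stopped_early <- FALSE
  for (e in seq_len(max_epochs)) {
    tr <- step_fn(e)
    ev <- eval_fn(e)
    if (!is.finite(tr$train_loss)) {
      stop_fmt("non-finite training loss at epoch %d; aborting", e)
    }
    hist <- rbind(hist, data.frame(epoch = e, train_loss = tr$train_loss,
                                   val_loss = ev$val_loss, val_acc = ev$val_acc))
    if (ev$val_acc > best) {
      best <- ev$val_acc; best_epoch <- e; best_snap <- snapshot_fn()
    }
    if (e - best_epoch >= patience) {
      stopped_early <- TRUE
      break
    }
  }
  list(history = hist, best_epoch = best_epoch, best_snapshot = best_snap,
       stopped_early = stopped_early)
}

# ---- real trainer -----------------------------------------------------

cross_entropy_grad <- function(logits_t, y) {
  # logits_t: (K, B); y: 0-based labels, length B
  B <- ncol(logits_t)
  P <- t(softmax_rows(logits_t))          # (K, B)
  idx <- cbind(y + 1L, seq_len(B))
  loss <- -mean(log(pmax(P[idx], 1e-12)))
  G <- P
  G[idx] <- G[idx] - 1
  list(loss = loss, dlogits = G / B)
}

eval_loss_acc <- function(net, X, y, batch_size = 256L) {
  n <- nrow(X)
  loss <- 0; correct <- 0L
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    r <- network_forward(net, input_tensor(X[i:j, , drop = FALSE]), train = FALSE)
    P <- softmax_rows(r$logits)
    yy <- y[i:j]
    loss <- loss - sum(log(pmax(P[cbind(seq_along(yy), yy + 1L)], 1e-12)))
    correct <- correct + sum(max.col(P, ties.method = "first") - 1L == yy)
    i <- j + 1L
  }
  list(loss = loss / n, acc = correct / n)
}

#' Train a network once on a data split
#'
#' Minibatch AdamW training with cross-entropy loss. After every epoch the
#' validation accuracy is measured; training halts at the first epoch with
#' no strict improvement over the last `patience` epochs (or at
#' `max_epochs`), and the weights of the earliest best-validation epoch
#' are restored. Fully reproducible: weight initialization, batch
#' shuffling and dropout are all keyed to `seed`.
#'
#' @param spec a `network_spec` matching the split's band count.
#' @param splits a `split_result` with non-empty train and validation
#'   partitions.
#' @param cfg a [train_config()].
#' @param seed integer run seed.
#' @return list with `net` (the restored best network), `history`
#'   (per-epoch data frame), `best_epoch` and `stopped_early`.
#' @export
train_once <- function(spec, splits, cfg = train_config(), seed = 1L) {
  stopifnot(inherits(spec, "network_spec"), inherits(cfg, "train_config"))
  Xtr <- splits$train$reflectance; ytr <- splits$train$labels
  Xva <- splits$val$reflectance; yva <- splits$val$labels
  if (nrow(Xtr) == 0L) stop_fmt("empty training set")
  if (nrow(Xva) == 0L) stop_fmt("empty validation set; early stopping needs one")
  if (ncol(Xtr) != spec$n_bands) {
    stop_fmt("spec expects %d bands, data has %d", spec$n_bands, ncol(Xtr))
  }

  net <- init_network(spec, seed = seed)
  params <- net_params(net)
  opt <- adamw_init(params)
  n <- nrow(Xtr)
  bs <- cfg$batch_size

  res <- with_seed(derive_seed(seed, "trainloop"), {
    step_fn <- function(epoch) {
      ord <- sample.int(n)
      total <- 0
      i <- 1L
      while (i <= n) {
        take <- ord[i:min(i + bs - 1L, n)]
        fw <- network_forward(net, input_tensor(Xtr[take, , drop = FALSE]), train = TRUE)
        net <<- fw$net   # batch-norm running stats
        ce <- cross_entropy_grad(fw$logits, ytr[take])
        grads <- network_backward(net, ce$dlogits, fw$caches)
        st <- adamw_step(params, grads, opt, cfg$learning_rate, cfg$weight_decay)
        params <<- st$params; opt <<- st$state
        net <<- net_set_params(net, params)
        total <- total + ce$loss * length(take)
        i <- i + bs
      }
      list(train_loss = total / n)
    }
    eval_fn <- function(epoch) {
      ev <- eval_loss_acc(net, Xva, yva)
      list(val_loss = ev$loss, val_acc = ev$acc)
    }
    snapshot_fn <- function() list(params = params, buffers = net_buffers(net))
    run_training_loop(step_fn, eval_fn, snapshot_fn, cfg$max_epochs, cfg$patience)
  })

  net <- net_set_params(net, res$best_snapshot$params)
  net <- net_set_buffers(net, res$best_snapshot$buffers)
  list(net = net, history = res$history, best_epoch = res$best_epoch,
       stopped_early = res$stopped_early, seed = as.integer(seed))
}

#' Train and evaluate a network across several seeds
#'
#' Runs one full train/evaluate cycle per seed in `cfg$seeds`, evaluating
#' the restored best model on validation and test partitions, and
#' aggregates every metric as mean and sample standard deviation over
#' seeds.
#'
#' @param spec a `network_spec` (or a builder `function(n_bands,
#'   n_classes)`).
#' @param splits a `split_result`.
#' @param cfg a [train_config()].
#' @return a `multiseed_report`: list with `runs` (per-seed list of
#'   [evaluate_model()] reports plus histories) and `summary` (data frame
#'   of metric mean/sd across seeds).
#' @export
run_multiseed <- function(spec, splits, cfg = train_config()) {
  if (is.function(spec)) {
    spec <- spec(ncol(splits$train$reflectance), length(splits$train$class_names))
  }
  runs <- lapply(cfg$seeds, function(s) {
    fit <- train_once(spec, splits, cfg, seed = s)
    rep <- evaluate_model(function(X) predict_classes(fit$net, X), splits)
    list(seed = s, fit = fit, report = rep)
  })
  metrics <- c("val_accuracy", "test_accuracy", "macro_precision",
               "macro_recall", "macro_f1")
  vals <- vapply(runs, function(r) {
    c(r$report$val_accuracy, r$report$test_accuracy,
      r$report$test$macro_precision, r$report$test$macro_recall,
      r$report$test$macro_f1)
  }, numeric(5))
  summary <- data.frame(
    metric = metrics,
    mean = apply(matrix(vals, nrow = 5), 1, mean),
    sd = apply(matrix(vals, nrow = 5), 1, stats::sd)
  )
  structure(list(architecture = spec$architecture, runs = runs,
                 summary = summary, seeds = cfg$seeds),
            class = "multiseed_report")
}

#' @export
print.multiseed_report <- function(x, ...) {
  cat(sprintf("%s over %d seed(s):\n", x$architecture, length(x$seeds)))
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-16s %.4f +/- %.4f\n", x$summary$metric[i],
                x$summary$mean[i], x$summary$sd[i]))
  }
  invisible(x)
}
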