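# Dimensionality reduction: PCA implemented via singular-value
# decomposition of the train-mean-centred matrix, and a contract wrapper
# around uwot's UMAP for nonlinear embedding (3-D visualization, 20-D
# reduced-feature modelling). Both reducers fit on the training partition
# only and transform held-out data out-of-sample.

#' Fit a PCA model on training spectra
#'
#' Components are the right singular vectors of the centred training
#' matrix, ordered by singular value. The sign of each component is fixed
#' deterministically: the loading of largest magnitude is made positive.
#'
#' @param X_train numeric matrix `n x p`.
#' @param n_components number of components,
#'   `<= min(n_samples - 1, n_bands)`.
#' @return a `pca_model`: list with `mean` (train mean vector), `loadings`
#'   (`n_components x p`, orthonormal rows) and `explained_ratio`
#'   (fractions of total variance, non-increasing).
#' @export
pca_fit <- function(X_train, n_components = 20L) {
  X <- check_matrix(X_train, "X_train")
  n <- nrow(X); p <- ncol(X)
  rmax <- min(n - 1L, p)
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > rmax) {
    stop_fmt("n_components must be in 1..min(n_samples-1, n_bands) = %d", rmax)
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0, nv = rmax)
  var_all <- sv$d[seq_len(rmax)]^2 / (n - 1)
  load <- t(sv$v[, seq_len(n_components), drop = FALSE])
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(n_components)) {
    i <- which.max(abs(load[j, ]))
    if (load[j, i] < 0) load[j, ] <- -load[j, ]
  }
  structure(
    list(mean = mu, loadings = load,
         explained_ratio = var_all[seq_len(n_components)] / sum(var_all),
         n_components = n_components),
    class = "pca_model"
  )
}

#' Project spectra onto fitted principal components
#'
#' @param model a `pca_model` from [pca_fit()].
#' @param X spectra matrix with the same band grid as the training data.
#' @return scores matrix `n x n_components` (columns `PC1..PCk`).
#' @export
pca_transform <- function(model, X) {
  stopifnot(inherits(model, "pca_model"))
  X <- check_matrix(X)
  if (ncol(X) != length(model$mean)) stop_fmt("band count mismatch with fitted model")
  S <- sweep(X, 2, model$mean) %*% t(model$loadings)
  colnames(S) <- paste0("PC", seq_len(ncol(S)))
  S
}

#' Nonlinear manifold embedding (UMAP, delegated)
#'
#' Thin contract wrapper around `uwot::umap`: fit on the training matrix,
#' embed held-out rows with `uwot::umap_transform`. Deterministic for a
#' fixed `seed` (single-threaded). The neighbourhood size is capped at
#' `n_train - 1` so small fixtures embed cleanly.
#'
#' @param X_train training spectra matrix.
#' @param X_other optional matrix to embed out-of-sample.
#' @param n_components embedding dimension (3 for visualization, 20 for
#'   reduced-feature modelling).
#' @param seed integer seed.
#' @param n_neighbors UMAP neighbourhood size (default 15, capped).
#' @return list with `train` (`n_train x n_components` matrix) and `other`
#'   (matrix or NULL).
#' @export
nonlinear_embed <- function(X_train, X_other = NULL, n_components = 3L,
                            seed = 1L, n_neighbors = 15L) {
  if (!requireNamespace("uwot", quietly = TRUE)) {
    stop_fmt(paste("the uwot package is required for nonlinear embedding;",
                   "this stage is optional - use PCA instead"))
  }
  X_train <- check_matrix(X_train, "X_train")
  nb <- min(as.integer(n_neighbors), nrow(X_train) - 1L)
  if (nb < 2L) stop_fmt("need at least 3 training samples for embedding")
  fit <- with_seed(seed, uwot::umap(X_train, n_components = as.integer(n_components),
                                    n_neighbors = nb, n_threads = 1,
                                    n_sgd_threads = 0, ret_model = TRUE,
                                    verbose = FALSE))
  other <- NULL
  if (!is.null(X_other)) {
    X_other <- check_matrix(X_other, "X_other")
    other <- with_seed(derive_seed(seed, "umap-transform"),
                       uwot::umap_transform(X_other, fit, n_threads = 1,
                                            verbose = FALSE))
  }
  list(train = unname(fit$embedding), other = if (!is.null(other)) unname(other))
}

#' Reduce all partitions of a split to a feature space
#'
#' Fits the reducer on the training reflectance only and transforms every
#' partition, returning a `split_result` whose `reflectance` slots hold the
#' reduced features (the wavelength grid is replaced by feature indices).
#'
#' @param split a `split_result`.
#' @param method `"pca"` or `"umap"`.
#' @param n_components target dimension (20 for modelling, 3 for plots).
#' @param seed seed for the stochastic embedding (ignored for PCA).
#' @return a `split_result` in feature space.
#' @export
reduce_split <- function(split, method = c("pca", "umap"), n_components = 20L,
                         seed = 1L) {
  method <- match.arg(method)
  Xtr <- split$train$reflectance
  parts <- c("val", "test")
  if (method == "pca") {
    model <- pca_fit(Xtr, n_components)
    feats <- list(train = pca_transform(model, Xtr))
    for (p in parts) {
      feats[[p]] <- if (n_samples(split[[p]]) > 0) {
        pca_transform(model, split[[p]]$reflectance)
      } else {
        matrix(0, 0, n_components)
      }
    }
  } else {
    rows <- lapply(parts, function(p) split[[p]]$reflectance)
    Xother <- do.call(rbind, rows)
    emb <- nonlinear_embed(Xtr, if (nrow(Xother) > 0) Xother,
                           n_components = n_components, seed = seed)
    feats <- list(train = emb$train)
    off <- 0L
    for (i in seq_along(parts)) {
      ni <- nrow(rows[[i]])
      feats[[parts[i]]] <- if (ni > 0) {
        emb$other[off + seq_len(ni), , drop = FALSE]
      } else {
        matrix(0, 0, n_components)
      }
      off <- off + ni
    }
  }
  out <- split
  for (p in c("train", "val", "test")) {
    ds <- split[[p]]
    ds$reflectance <- feats[[p]]
    ds$wavelengths <- seq_len(n_components)  # feature indices, not nm
    out[[p]] <- ds
  }
  out
}
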