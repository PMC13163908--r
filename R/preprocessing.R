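# Chemometric spectral pretreatments: Savitzky-Golay smoothing, standard
# normal variate (SNV) and multiplicative scatter correction (MSC), plus a
# composable fit/apply pipeline. All transforms preserve matrix shape.

# Build the p x p Savitzky-Golay smoother matrix for a grid of p bands.
# Interior points use the centred window's least-squares polynomial
# evaluated at its centre; the first/last (window-1)/2 points evaluate the
# polynomial fitted to the first/last full window at the edge offsets
# (standard SG edge extension), so polynomials of degree <= order are
# reproduced exactly everywhere.
sg_matrix <- function(p, window, order) {
  h <- (window - 1L) %/% 2L
  offs <- -h:h
  A <- outer(offs, 0:order, `^`)
  H <- A %*% solve(crossprod(A), t(A))  # window hat matrix
  S <- matrix(0, p, p)
  for (i in seq_len(p)) {
    if (i <= h) {
      S[i, 1:window] <- H[i, ]
    } else if (i > p - h) {
      S[i, (p - window + 1L):p] <- H[window - (p - i), ]
    } else {
      S[i, (i - h):(i + h)] <- H[h + 1L, ]
    }
  }
  S
}

#' Savitzky-Golay smoothing
#'
#' Replaces each spectrum by local least-squares polynomial evaluations
#' over a sliding window (default: window 5, third-order polynomial).
#'
#' @param X numeric matrix, one spectrum per row.
#' @param window odd window length, `> order`.
#' @param order polynomial order.
#' @return smoothed matrix, same shape as `X`.
#' @export
sg_smooth <- function(X, window = 5L, order = 3L) {
  X <- check_matrix(X)
  window <- as.integer(window); order <- as.integer(order)
  if (window %% 2L == 0L) stop_fmt("SG window must be odd (got %d)", window)
  if (order >= window) stop_fmt("SG order (%d) must be < window (%d)", order, window)
  if (ncol(X) < window) stop_fmt("need at least %d bands for window %d", window, window)
  X %*% t(sg_matrix(ncol(X), window, order))
}

#' Standard normal variate transform
#'
#' Standardizes each spectrum to mean 0 and unit sample standard deviation
#' (n-1 denominator).
#'
#' @param X numeric matrix, one spectrum per row.
#' @return transformed matrix, same shape.
#' @export
snv <- function(X) {
  X <- check_matrix(X)
  m <- rowMeans(X)
  s <- apply(X, 1, stats::sd)
  bad <- which(s == 0 | !is.finite(s))
  if (length(bad)) stop_fmt("snv: constant spectrum in row %d", bad[1])
  (X - m) / s
}

#' Fit the MSC reference spectrum
#'
#' The reference is the column mean of the training spectra; it is fitted
#' on the training partition only and reused for validation/test.
#'
#' @param X_train numeric matrix of training spectra.
#' @return numeric vector of length `n_bands`.
#' @export
msc_fit <- function(X_train) {
  X_train <- check_matrix(X_train, "X_train")
  colMeans(X_train)
}

#' Apply multiplicative scatter correction
#'
#' Regresses each spectrum `x` on the reference by ordinary least squares,
#' `x ~ a * ref + b`, and returns the corrected spectrum `(x - b) / a`.
#'
#' @param X numeric matrix of spectra.
#' @param reference reference spectrum from [msc_fit()]; must be
#'   non-constant.
#' @return corrected matrix, same shape as `X`.
#' @export
msc_apply <- function(X, reference) {
  X <- check_matrix(X)
  reference <- as.numeric(reference)
  if (length(reference) != ncol(X)) stop_fmt("reference length != n_bands")
  rc <- reference - mean(reference)
  ss <- sum(rc^2)
  if (ss < 1e-24) stop_fmt("msc_apply: reference spectrum is constant")
  a <- as.vector(X %*% rc) / ss               # row-wise OLS slope
  b <- rowMeans(X) - a * mean(reference)      # row-wise OLS intercept
  bad <- which(abs(a) < 1e-12)
  if (length(bad)) stop_fmt("msc_apply: near-zero slope for row %d", bad[1])
  (X - b) / a
}

#' Build a preprocessing pipeline
#'
#' Steps are applied in order; supported kinds are `"sg"` (params `window`,
#' `order`), `"snv"` and `"msc"`. MSC acquires its reference during
#' [pp_fit()] from the training matrix (after all preceding steps), so
#' applying the fitted pipeline never reads statistics from the data it
#' transforms. Steps can also be given compactly as a string such as
#' `"sg:5:3,snv"`.
#'
#' @param steps list of steps, each either a kind string or
#'   `list(kind=, ...params)`, or a single comma-separated spec string.
#' @return an unfitted `pp_pipeline` object.
#' @export
pp_pipeline <- function(steps) {
  if (is.character(steps) && length(steps) == 1L) {
    steps <- lapply(strsplit(steps, ",", fixed = TRUE)[[1]], function(tok) {
      parts <- strsplit(trimws(tok), ":", fixed = TRUE)[[1]]
      if (parts[1] == "sg") {
        list(kind = "sg",
             window = if (length(parts) >= 2) as.integer(parts[2]) else 5L,
             order = if (length(parts) >= 3) as.integer(parts[3]) else 3L)
      } else {
        list(kind = parts[1])
      }
    })
  }
  steps <- lapply(steps, function(s) if (is.character(s)) list(kind = s) else s)
  kinds <- vapply(steps, `[[`, "", "kind")
  if (!all(kinds %in% c("sg", "snv", "msc"))) {
    stop_fmt("unknown preprocessing step kind: %s",
             paste(setdiff(kinds, c("sg", "snv", "msc")), collapse = ", "))
  }
  structure(list(steps = steps, fitted = FALSE), class = "pp_pipeline")
}

#' Fit a preprocessing pipeline on training spectra
#'
#' @param pipeline a [pp_pipeline()].
#' @param X_train training spectra matrix (fit scope for MSC references).
#' @return the fitted pipeline.
#' @export
pp_fit <- function(pipeline, X_train) {
  stopifnot(inherits(pipeline, "pp_pipeline"))
  X <- check_matrix(X_train, "X_train")
  for (i in seq_along(pipeline$steps)) {
    st <- pipeline$steps[[i]]
    if (st$kind == "msc") {
      pipeline$steps[[i]]$reference <- msc_fit(X)
    }
    X <- pp_apply_step(pipeline$steps[[i]], X)
  }
  pipeline$fitted <- TRUE
  pipeline
}

pp_apply_step <- function(st, X) {
  switch(st$kind,
    sg = sg_smooth(X, st$window %||% 5L, st$order %||% 3L),
    snv = snv(X),
    msc = {
      if (is.null(st$reference)) stop_fmt("MSC step not fitted; call pp_fit() first")
      msc_apply(X, st$reference)
    }
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply a fitted preprocessing pipeline
#'
#' @param pipeline a fitted `pp_pipeline` (see [pp_fit()]); pipelines
#'   without fitted state (no MSC) may be applied directly.
#' @param X spectra matrix to transform.
#' @return transformed matrix, same shape.
#' @export
pp_apply <- function(pipeline, X) {
  stopifnot(inherits(pipeline, "pp_pipeline"))
  X <- check_matrix(X)
  has_msc <- any(vapply(pipeline$steps, `[[`, "", "kind") == "msc")
  if (has_msc && !pipeline$fitted) stop_fmt("pipeline contains MSC; fit it first")
  for (st in pipeline$steps) X <- pp_apply_step(st, X)
  X
}

#' Preprocess all partitions of a split
#'
#' Fits the pipeline on the training reflectance and applies it to train,
#' validation and test, returning a new `split_result` with transformed
#' reflectance matrices.
#'
#' @param split a `split_result`.
#' @param pipeline a [pp_pipeline()] (or step-spec string).
#' @return a `split_result` with preprocessed partitions.
#' @export
pp_split <- function(split, pipeline) {
  if (is.character(pipeline)) pipeline <- pp_pipeline(pipeline)
  fitted <- pp_fit(pipeline, split$train$reflectance)
  out <- split
  for (part in c("train", "val", "test")) {
    ds <- split[[part]]
    if (n_samples(ds) > 0) ds$reflectance <- pp_apply(fitted, ds$reflectance)
    out[[part]] <- ds
  }
  out
}
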