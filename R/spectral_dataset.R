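# Labelled reflectance-spectrum datasets: construction, IO, trimming,
# class summaries and stratified spectral-level splitting.

#' Construct a spectral dataset
#'
#' A `spectral_dataset` bundles a reflectance matrix (samples x bands) with
#' its wavelength grid, integer class labels and sample metadata. Labels are
#' stored zero-based (`0 .. K-1`) with `class_names` giving the display name
#' of each class in first-appearance order.
#'
#' @param reflectance numeric matrix, `n_samples x n_bands`, finite values.
#' @param wavelengths strictly increasing numeric vector (nm), length
#'   `n_bands`.
#' @param labels integer vector of class ids in `0 .. K-1`, or a character /
#'   factor vector which is converted using first-appearance order.
#' @param class_names character vector of K class names. Required when
#'   `labels` is already integer.
#' @param sample_ids unique character ids, one per sample. Generated when
#'   omitted.
#' @param fruit_ids optional per-sample group tag (spectra from the same
#'   fruit share a tag); used by the grouped split variant.
#' @return an object of class `spectral_dataset`.
#' @export
spectral_dataset <- function(reflectance, wavelengths, labels,
                             class_names = NULL, sample_ids = NULL,
                             fruit_ids = NULL) {
  reflectance <- check_matrix(reflectance, "reflectance")
  wavelengths <- as.numeric(wavelengths)
  n <- nrow(reflectance)
  p <- ncol(reflectance)
  if (length(wavelengths) != p) {
    stop_fmt("wavelengths length (%d) != number of bands (%d)", length(wavelengths), p)
  }
  if (any(!is.finite(wavelengths))) stop_fmt("wavelengths must be finite")
  if (p > 1 && any(diff(wavelengths) <= 0)) stop_fmt("wavelengths not increasing")

  if (is.character(labels) || is.factor(labels)) {
    lab_chr <- as.character(labels)
    if (is.null(class_names)) class_names <- unique(lab_chr)
    if (!all(lab_chr %in% class_names)) stop_fmt("labels contain values outside class_names")
    labels <- match(lab_chr, class_names) - 1L
  } else {
    labels <- as.integer(labels)
    if (is.null(class_names)) {
      stop_fmt("class_names is required when labels are integer ids")
    }
  }
  K <- length(class_names)
  if (length(labels) != n) stop_fmt("labels length (%d) != number of samples (%d)", length(labels), n)
  if (any(labels < 0L) || any(labels >= K)) stop_fmt("labels must lie in 0..K-1 (K=%d)", K)

  if (is.null(sample_ids)) sample_ids <- sprintf("s%04d", seq_len(n))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != n) stop_fmt("sample_ids length mismatch")
  if (anyDuplicated(sample_ids)) stop_fmt("sample_ids must be unique")
  if (!is.null(fruit_ids)) {
    fruit_ids <- as.character(fruit_ids)
    if (length(fruit_ids) != n) stop_fmt("fruit_ids length mismatch")
  }

  structure(
    list(reflectance = reflectance, wavelengths = wavelengths,
         labels = labels, class_names = as.character(class_names),
         sample_ids = sample_ids, fruit_ids = fruit_ids),
    class = "spectral_dataset"
  )
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf("spectral_dataset: %d spectra x %d bands (%.1f-%.1f nm)\n",
              nrow(x$reflectance), ncol(x$reflectance),
              min(x$wavelengths), max(x$wavelengths)))
  tab <- table(factor(x$labels, levels = seq_along(x$class_names) - 1L,
                      labels = x$class_names))
  cat("classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples / bands in a dataset
#' @param ds a `spectral_dataset`.
#' @return integer count.
#' @export
n_samples <- function(ds) nrow(ds$reflectance)

#' @rdname n_samples
#' @export
n_bands <- function(ds) ncol(ds$reflectance)

#' Subset a spectral dataset by sample index
#' @param x a `spectral_dataset`.
#' @param i integer or logical sample index.
#' @param ... ignored.
#' @export
`[.spectral_dataset` <- function(x, i, ...) {
  spectral_dataset(x$reflectance[i, , drop = FALSE], x$wavelengths,
                   x$labels[i], class_names = x$class_names,
                   sample_ids = x$sample_ids[i],
                   fruit_ids = if (!is.null(x$fruit_ids)) x$fruit_ids[i])
}

#' Read a labelled spectra table from delimited text
#'
#' The header row carries one numeric wavelength (nm) per spectral column,
#' plus a label column and optional `sample_id` / `fruit_id` columns.
#' Class names are recorded in first-appearance order so label ids are
#' stable across writes and reads.
#'
#' @param path file path of a delimited text table.
#' @param label_column name of the class-label column (default `"label"`).
#' @param sep field separator (default comma).
#' @return a [spectral_dataset()].
#' @export
load_spectra <- function(path, label_column = "label", sep = ",") {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!label_column %in% names(df)) {
    stop_fmt("label column '%s' not found in %s", label_column, path)
  }
  meta_cols <- c(label_column, "sample_id", "fruit_id")
  spec_cols <- setdiff(names(df), meta_cols)
  wl <- suppressWarnings(as.numeric(spec_cols))
  if (any(is.na(wl))) {
    stop_fmt("non-numeric wavelength header(s): %s",
             paste(utils::head(spec_cols[is.na(wl)], 3), collapse = ", "))
  }
  X <- as.matrix(df[, spec_cols, drop = FALSE])
  storage.mode(X) <- "double"
  dimnames(X) <- NULL
  if (any(!is.finite(X))) stop_fmt("non-finite reflectance value in %s", path)
  if (length(wl) > 1 && any(diff(wl) <= 0)) stop_fmt("wavelengths not increasing")
  spectral_dataset(X, wl, labels = as.character(df[[label_column]]),
                   sample_ids = if ("sample_id" %in% names(df)) df$sample_id,
                   fruit_ids = if ("fruit_id" %in% names(df)) df$fruit_id)
}

#' Write a spectral dataset as delimited text
#'
#' Inverse of [load_spectra()]: wavelengths as header, one row per spectrum.
#'
#' @param ds a `spectral_dataset`.
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(ds, path, sep = ",") {
  df <- as.data.frame(ds$reflectance)
  names(df) <- format(ds$wavelengths, trim = TRUE, scientific = FALSE)
  df$label <- ds$class_names[ds$labels + 1L]
  df$sample_id <- ds$sample_ids
  if (!is.null(ds$fruit_ids)) df$fruit_id <- ds$fruit_ids
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Trim a dataset to a closed wavelength interval
#'
#' Keeps exactly the bands with `lo <= wavelength <= hi` (closed interval,
#' nm). Used to drop the noisy sensor edges before modelling.
#'
#' @param ds a `spectral_dataset`.
#' @param lo,hi interval endpoints in nm, `lo < hi`.
#' @return the trimmed `spectral_dataset`.
#' @export
trim_bands <- function(ds, lo, hi) {
  if (!(lo < hi)) stop_fmt("trim_bands: lo (%g) must be < hi (%g)", lo, hi)
  keep <- ds$wavelengths >= lo & ds$wavelengths <= hi
  if (!any(keep)) stop_fmt("trim_bands: no bands inside [%g, %g] nm", lo, hi)
  spectral_dataset(ds$reflectance[, keep, drop = FALSE], ds$wavelengths[keep],
                   ds$labels, class_names = ds$class_names,
                   sample_ids = ds$sample_ids, fruit_ids = ds$fruit_ids)
}

#' Per-class mean spectra
#'
#' @param ds a `spectral_dataset` with every class non-empty.
#' @return numeric matrix `K x n_bands`, row k the arithmetic mean spectrum
#'   of class k; rownames are the class names.
#' @export
class_mean_spectra <- function(ds) {
  K <- length(ds$class_names)
  counts <- tabulate(ds$labels + 1L, nbins = K)
  if (any(counts == 0L)) {
    stop_fmt("class '%s' has no samples", ds$class_names[which(counts == 0L)[1]])
  }
  M <- matrix(0, K, ncol(ds$reflectance),
              dimnames = list(ds$class_names, NULL))
  for (k in seq_len(K)) {
    M[k, ] <- colMeans(ds$reflectance[ds$labels == k - 1L, , drop = FALSE])
  }
  M
}

# Largest-remainder allocation of n items to the given ratios; any leftover
# after flooring goes to the partitions with the largest fractional part,
# ties broken in partition order (train first).
allocate_counts <- function(n, ratios) {
  target <- n * ratios
  counts <- floor(target)
  left <- n - sum(counts)
  if (left > 0) {
    frac <- target - counts
    ord <- order(-frac, seq_along(ratios))
    counts[ord[seq_len(left)]] <- counts[ord[seq_len(left)]] + 1
  }
  as.integer(counts)
}

#' Stratified train/validation/test split at the spectral level
#'
#' Splits the dataset into three partitions preserving class proportions.
#' Per-class counts are allocated by largest-remainder rounding (remainder
#' preferentially to train), then samples are assigned at random under
#' `seed`. Splitting is at the spectral level: spectra from the same fruit
#' may land in different partitions. Use `by_fruit = TRUE` for a grouped
#' split that keeps every fruit's spectra in a single partition.
#'
#' @param ds a `spectral_dataset`; every class needs at least 3 samples
#'   (one per partition) unless `allow_empty = TRUE`.
#' @param ratios three non-negative fractions summing to 1 (default 6:2:2).
#' @param seed integer seed controlling the random assignment.
#' @param allow_empty permit zero-width partitions such as `c(1, 0, 0)`.
#' @param by_fruit split whole fruits (requires `fruit_ids`).
#' @return a `split_result`: list with `train`, `val`, `test`
#'   (`spectral_dataset`s), `ratios` and `seed`.
#' @export
stratified_split <- function(ds, ratios = c(0.6, 0.2, 0.2), seed = 1L,
                             allow_empty = FALSE, by_fruit = FALSE) {
  ratios <- as.numeric(ratios)
  if (length(ratios) != 3 || any(ratios < 0)) {
    stop_fmt("ratios must be three non-negative fractions")
  }
  if (abs(sum(ratios) - 1) > 1e-9) {
    stop_fmt("ratios must sum to 1 (got %g)", sum(ratios))
  }
  if (any(ratios == 0) && !allow_empty) {
    stop_fmt("zero ratio produces an empty partition; set allow_empty = TRUE to permit")
  }
  K <- length(ds$class_names)
  if (by_fruit && is.null(ds$fruit_ids)) stop_fmt("by_fruit split requires fruit_ids")

  units <- if (by_fruit) {
    # one unit per fruit; a fruit's class is the class of its spectra
    split(seq_len(n_samples(ds)), ds$fruit_ids)
  } else {
    as.list(seq_len(n_samples(ds)))
  }
  unit_class <- vapply(units, function(ix) ds$labels[ix[1]], integer(1))

  part_of_unit <- integer(length(units))
  with_seed(seed, {
    for (k in seq_len(K) - 1L) {
      in_k <- which(unit_class == k)
      if (length(in_k) < 3 && !allow_empty) {
        stop_fmt("class '%s' has only %d unit(s); need >= 3 to split",
                 ds$class_names[k + 1L], length(in_k))
      }
      counts <- allocate_counts(length(in_k), ratios)
      shuffled <- in_k[sample.int(length(in_k))]
      part_of_unit[shuffled] <- rep(1:3, times = counts)
    }
  })
  part_of_sample <- integer(n_samples(ds))
  for (u in seq_along(units)) part_of_sample[units[[u]]] <- part_of_unit[u]

  structure(
    list(train = ds[part_of_sample == 1L],
         val   = ds[part_of_sample == 2L],
         test  = ds[part_of_sample == 3L],
         ratios = ratios, seed = as.integer(seed)),
    class = "split_result"
  )
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("split_result (seed %d): train %d / val %d / test %d\n",
              x$seed, n_samples(x$train), n_samples(x$val), n_samples(x$test)))
  invisible(x)
}

#' Write split membership manifests
#'
#' Writes `train.txt`, `val.txt` and `test.txt` (one sample id per line)
#' under `dir`.
#'
#' @param split a `split_result`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_split_manifest <- function(split, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (part in c("train", "val", "test")) {
    writeLines(split[[part]]$sample_ids, file.path(dir, paste0(part, ".txt")))
  }
  invisible(dir)
}
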