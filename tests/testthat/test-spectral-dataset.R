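# spectral_dataset: IO, validation, trimming, class means, splitting.

test_that("load_spectra reads a minimal well-formed table", {
  ds <- load_spectra(write_tiny_csv())
  expect_s3_class(ds, "spectral_dataset")
  expect_equal(n_samples(ds), 2L)
  expect_equal(n_bands(ds), 3L)
  expect_equal(ds$class_names, c("A", "B"))  # first-appearance order
  expect_equal(ds$labels, c(0L, 1L))
  expect_equal(ds$wavelengths, c(500, 510, 520))
})

test_that("load_spectra rejects malformed tables with descriptive errors", {
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "nolabel.csv")
  writeLines(c("500,510,520", "0.1,0.2,0.3"), p1)
  expect_error(load_spectra(p1), "label")

  p2 <- file.path(dir, "badheader.csv")
  writeLines(c("500,abc,520,label", "0.1,0.2,0.3,A"), p2)
  expect_error(load_spectra(p2), "non-numeric wavelength")

  p3 <- file.path(dir, "notincreasing.csv")
  writeLines(c("500,400,600,label", "0.1,0.2,0.3,A"), p3)
  expect_error(load_spectra(p3), "wavelengths not increasing")

  p4 <- file.path(dir, "nonfinite.csv")
  writeLines(c("500,510,520,label", "0.1,NA,0.3,A"), p4)
  expect_error(load_spectra(p4), "non-finite")
})

test_that("write_spectra / load_spectra round trip preserves the dataset", {
  ds <- tiny_dataset()
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra(ds, path)
  back <- load_spectra(path)
  expect_equal(back$reflectance, ds$reflectance, tolerance = 1e-12)
  expect_equal(back$labels, ds$labels)
  expect_equal(back$class_names, ds$class_names)
  expect_equal(back$sample_ids, ds$sample_ids)
})

test_that("trim_bands keeps exactly the closed-interval bands", {
  grid <- seq(375, 1045, by = 5)
  n <- 4
  ds <- spectral_dataset(matrix(runif(n * length(grid)), n), grid,
                         labels = rep(0L, n), class_names = "A")
  tr <- trim_bands(ds, 381, 1016)
  # independent enumeration of grid points in the closed interval
  expect_equal(n_bands(tr), sum(grid >= 381 & grid <= 1016))
  expect_true(min(tr$wavelengths) >= 381 && max(tr$wavelengths) <= 1016)

  # trim to full range is the identity; trimming twice is idempotent
  expect_equal(trim_bands(ds, min(grid), max(grid))$reflectance, ds$reflectance)
  expect_equal(trim_bands(tr, 381, 1016), tr)

  expect_error(trim_bands(ds, 500, 501 - 2), "lo")
  expect_error(trim_bands(ds, 500.2, 500.4), "no bands")
})

test_that("class_mean_spectra matches a direct per-class loop oracle", {
  ds <- tiny_dataset(n = 10, p = 5, K = 2, seed = 7)
  M <- class_mean_spectra(ds)
  for (k in 0:1) {
    oracle <- colMeans(ds$reflectance[ds$labels == k, , drop = FALSE])
    expect_equal(unname(M[k + 1, ]), unname(oracle))
  }
  # one sample per class: means equal the samples
  one <- ds[c(1, 2)]
  expect_equal(unname(class_mean_spectra(one)), unname(one$reflectance))
  # empty class errors
  only_a <- ds[ds$labels == 0]
  expect_error(class_mean_spectra(only_a), "no samples")
})

test_that("stratified 6:2:2 split of 660 balanced samples gives 396/132/132", {
  ds <- balanced_dataset(220)
  sp <- stratified_split(ds, c(0.6, 0.2, 0.2), seed = 42)
  expect_equal(n_samples(sp$train), 396L)
  expect_equal(n_samples(sp$val), 132L)
  expect_equal(n_samples(sp$test), 132L)
  for (part in c("train", "val", "test")) {
    counts <- tabulate(sp[[part]]$labels + 1L, 3)
    expect_equal(counts, rep(c(train = 132L, val = 44L, test = 44L)[part], 3),
                 ignore_attr = TRUE)
  }
})

test_that("split partitions are disjoint and exhaustive across seeds", {
  ds <- balanced_dataset(11, K = 3)   # 33 samples, awkward remainders
  for (seed in 1:100) {
    sp <- stratified_split(ds, seed = seed)
    ids <- c(sp$train$sample_ids, sp$val$sample_ids, sp$test$sample_ids)
    expect_equal(sort(ids), sort(ds$sample_ids))
    expect_equal(anyDuplicated(ids), 0L)
  }
})

test_that("per-class partition counts deviate from ratios by at most 1", {
  set.seed(99)
  # unbalanced fixture
  ds <- spectral_dataset(matrix(rnorm(60 * 3), 60), c(1, 2, 3),
                         labels = rep(c(0L, 1L, 2L), times = c(31, 17, 12)),
                         class_names = c("a", "b", "c"))
  ratios <- c(0.6, 0.2, 0.2)
  for (seed in 1:20) {
    sp <- stratified_split(ds, ratios, seed = seed)
    for (k in 0:2) {
      nk <- sum(ds$labels == k)
      got <- vapply(c("train", "val", "test"),
                    function(p) sum(sp[[p]]$labels == k), numeric(1))
      expect_true(all(abs(got - nk * ratios) < 1))
    }
  }
})

test_that("split reproducibility and argument validation", {
  ds <- balanced_dataset(10)
  a <- stratified_split(ds, seed = 5)
  b <- stratified_split(ds, seed = 5)
  expect_identical(a$train$sample_ids, b$train$sample_ids)
  expect_identical(a$test$sample_ids, b$test$sample_ids)
  d2 <- stratified_split(ds, seed = 6)
  expect_false(identical(a$train$sample_ids, d2$train$sample_ids))

  expect_error(stratified_split(ds, c(0.5, 0.2, 0.2)), "sum to 1")
  expect_error(stratified_split(ds, c(1, 0, 0)), "allow_empty")
  whole <- stratified_split(ds, c(1, 0, 0), allow_empty = TRUE)
  expect_equal(n_samples(whole$train), n_samples(ds))
  expect_equal(n_samples(whole$val), 0L)

  few <- ds[1:4]  # class sizes 2/1/1
  expect_error(stratified_split(few), "need >= 3")
})

test_that("grouped (fruit-level) split keeps each fruit in one partition", {
  d <- generate_spectra(sim_spec("visnir", n_per_class = 12,
                                 spectra_per_fruit = 4, seed = 2))
  sp <- stratified_split(d, seed = 1, by_fruit = TRUE)
  parts <- rep(c("train", "val", "test"),
               times = c(n_samples(sp$train), n_samples(sp$val), n_samples(sp$test)))
  fruit <- c(sp$train$fruit_ids, sp$val$fruit_ids, sp$test$fruit_ids)
  expect_true(all(tapply(parts, fruit, function(x) length(unique(x))) == 1))
})
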