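# Shared fixture builders: everything is generated in code at test time.

# tiny hand-made dataset: n samples, p bands, K classes cycling 0..K-1
tiny_dataset <- function(n = 9, p = 5, K = 3, seed = 1) {
  set.seed(seed)
  spectral_dataset(matrix(runif(n * p), n, p),
                   wavelengths = seq(400, 400 + 10 * (p - 1), by = 10),
                   labels = rep(seq_len(K) - 1L, length.out = n),
                   class_names = LETTERS[seq_len(K)])
}

# balanced dataset with n_per_class samples per class
balanced_dataset <- function(n_per_class, K = 3, p = 4, seed = 1) {
  set.seed(seed)
  n <- n_per_class * K
  spectral_dataset(matrix(rnorm(n * p), n, p),
                   wavelengths = seq_len(p) * 100,
                   labels = rep(seq_len(K) - 1L, each = n_per_class),
                   class_names = paste0("c", seq_len(K)))
}

# write a small spectra csv and return its path
write_tiny_csv <- function(dir = tempdir()) {
  path <- file.path(dir, "tiny_spectra.csv")
  writeLines(c("500,510,520,label",
               "0.1,0.2,0.3,A",
               "0.4,0.5,0.6,B"), path)
  path
}

# fast training config for smoke tests
fast_cfg <- function(seeds = 1L, max_epochs = 5L) {
  train_config(max_epochs = max_epochs, patience = min(3L, max_epochs),
               seeds = seeds)
}

# small, quickly separable split for network smoke tests
small_split <- function(preset = "visnir", n_per_class = 30, delta = 0.08,
                        seed = 3) {
  d <- generate_spectra(sim_spec(preset, n_per_class = n_per_class,
                                 delta = delta, seed = seed))
  stratified_split(d, seed = seed)
}
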