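# ECA operator, architecture builders, serialization, gradients.

test_that("adaptive kernel size reproduces the stated worked values", {
  expect_identical(eca_kernel_size(16), 3L)
  expect_identical(eca_kernel_size(32), 3L)
  expect_identical(eca_kernel_size(64), 5L)
  expect_identical(eca_kernel_size(2), 1L)
  expect_identical(eca_kernel_size(128), 5L)  # tie resolved upward
  expect_error(eca_kernel_size(0), "positive")
  expect_error(eca_kernel_size(2.5), "positive")
})

test_that("kernel size is odd and non-decreasing over C = 1..4096", {
  k <- eca_kernel_size(1:4096)
  expect_true(all(k %% 2L == 1L))
  expect_true(all(k >= 1L))
  expect_true(all(diff(k) >= 0L))
})

test_that("zero filter taps gate every channel at exactly 0.5", {
  set.seed(41)
  x <- array(rnorm(2 * 6 * 9), c(2, 6, 9))   # (B, C, L)
  out <- eca_forward(x, c(0, 0, 0))
  expect_identical(out, 0.5 * x)
})

test_that("ECA forward matches a hand-computed example", {
  # B=1, C=4, L=2; channel means (1,2,3,4); identity tap (0,1,0)
  x <- array(0, c(1, 4, 2))
  x[1, , 1] <- c(0.5, 1.5, 2.5, 3.5)
  x[1, , 2] <- c(1.5, 2.5, 3.5, 4.5)
  out <- eca_forward(x, c(0, 1, 0))
  gates <- 1 / (1 + exp(-(1:4)))          # sigmoid of the channel means
  for (c_ in 1:4) {
    expect_equal(out[1, c_, ], x[1, c_, ] * gates[c_], tolerance = 1e-8)
  }
})

test_that("ECA preserves shape and produces gates strictly inside (0,1)", {
  set.seed(42)
  for (d in list(c(1, 4, 7), c(3, 16, 10), c(2, 8, 1))) {
    x <- array(rnorm(prod(d)), d)
    w <- rnorm(3)
    out <- eca_forward(x, w)
    expect_equal(dim(out), d)
    gate <- out / x
    expect_true(all(gate[is.finite(gate)] > 0 & gate[is.finite(gate)] < 1))
  }
  # saturated gates (huge tap on positive means) approach the identity
  x <- array(abs(rnorm(2 * 4 * 5)) + 1, c(2, 4, 5))
  expect_equal(eca_forward(x, c(0, 1e4, 0)), x, tolerance = 1e-7)
  expect_error(eca_forward(array(0, c(1, 2, 2)), c(1, 1)), "odd")
  expect_error(eca_forward(array(0, c(1, 2, 2)), rep(1, 5)), "2C-1")
})

test_that("ECNN-1D builder honours the block contract", {
  spec <- build_ecnn1d(123, 3)
  expect_equal(vapply(spec$blocks, `[[`, 0L, "out_channels"), c(16L, 32L, 64L))
  expect_equal(vapply(spec$blocks, `[[`, 0L, "eca_k"), c(3L, 3L, 5L))
  expect_true(all(vapply(spec$blocks, `[[`, TRUE, "eca")))
  expect_error(build_ecnn1d(7, 3), "n_bands")
  expect_error(build_ecnn1d(123, 3, channels = c(32, 16, 8)), "non-decreasing")
})

test_that("forward pass yields row-stochastic probabilities", {
  set.seed(43)
  for (nb in c(123L, 267L)) {
    net <- init_network(build_ecnn1d(nb, 3), seed = 1)
    P <- predict_network(net, matrix(runif(8 * nb), 8, nb))
    expect_equal(dim(P), c(8L, 3L))
    expect_true(all(P >= 0))
    expect_equal(rowSums(P), rep(1, 8), tolerance = 1e-6)
  }
})

test_that("CNN-1D differs from ECNN-1D only in the ECA flags", {
  e <- build_ecnn1d(123, 3)
  c_ <- build_cnn1d(123, 3)
  e_off <- e
  for (i in seq_along(e_off$blocks)) e_off$blocks[[i]]$eca <- FALSE
  e_off$architecture <- c_$architecture
  expect_identical(e_off, c_)
  expect_lt(count_parameters(c_), count_parameters(e))
})

test_that("VGG-1D builder follows the two-conv kernel-3 block design", {
  spec <- build_vgg1d(123, 3)
  expect_true(all(vapply(spec$blocks, `[[`, 0L, "kernel") == 3L))
  expect_false(any(vapply(spec$blocks, `[[`, TRUE, "eca")))
  with_eca <- build_vgg1d(123, 3, eca = TRUE)
  expect_true(all(vapply(with_eca$blocks, `[[`, TRUE, "eca")))
  n_eca <- function(spec) {
    net <- init_network(spec, seed = 1)
    sum(vapply(net$layers, function(l) l$type == "eca", TRUE))
  }
  expect_equal(n_eca(with_eca) - n_eca(spec), length(spec$blocks))
  P <- predict_network(init_network(spec, seed = 2), matrix(runif(4 * 123), 4))
  expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-6)
})

test_that("ResNet-1D blocks project only on width changes and skip cleanly", {
  spec <- build_resnet1d(64, 3, channels = c(16, 16, 32))
  net <- init_network(spec, seed = 5)
  blocks <- Filter(function(l) l$type == "resblock", net$layers)
  expect_null(blocks[[2]]$proj)          # 16 -> 16: identity skip
  expect_false(is.null(blocks[[1]]$proj)) # 1 -> 16: projection
  expect_false(is.null(blocks[[3]]$proj)) # 16 -> 32: projection

  # zeroing the conv path reduces the block to (projected) input + ReLU
  blk <- blocks[[2]]
  for (i in seq_along(blk$sub)) {
    if (blk$sub[[i]]$type == "conv1d") {
      blk$sub[[i]]$params$W[] <- 0
      blk$sub[[i]]$params$b[] <- 0
    }
    if (blk$sub[[i]]$type == "batchnorm") blk$sub[[i]]$params$beta[] <- 0
  }
  x <- array(abs(rnorm(16 * 10 * 2)), c(16, 10, 2))
  out <- specorigin:::layer_forward(blk, x, train = TRUE)$out
  expect_equal(out, x, tolerance = 1e-12)
})

test_that("network specs survive a JSON round trip", {
  dir <- withr::local_tempdir()
  for (spec in list(build_ecnn1d(123, 3), build_cnn1d(267, 3),
                    build_vgg1d(123, 3, eca = TRUE),
                    build_resnet1d(267, 3, eca = TRUE))) {
    path <- file.path(dir, "spec.json")
    network_spec_to_json(spec, path)
    back <- network_spec_from_json(path)
    expect_equal(back, spec)
  }
})

test_that("forward passes are deterministic given fixed weights", {
  net <- init_network(build_ecnn1d(64, 3), seed = 11)
  X <- matrix(runif(6 * 64), 6)
  expect_identical(predict_network(net, X), predict_network(net, X))
  net2 <- init_network(build_ecnn1d(64, 3), seed = 11)
  expect_identical(predict_network(net, X), predict_network(net2, X))
})

test_that("analytic gradients agree with finite differences", {
  # spot-check a few parameters of each architecture on tiny inputs
  gradcheck <- function(spec, n_probe = 3, eps = 1e-5) {
    set.seed(77)
    net <- init_network(spec, seed = 9)
    X <- matrix(runif(3 * spec$n_bands), 3)
    y <- c(0L, 1L, 2L)
    lossfun <- function(nt) {
      fw <- specorigin:::network_forward(nt, specorigin:::input_tensor(X), TRUE)
      specorigin:::cross_entropy_grad(fw$logits, y)$loss
    }
    fw <- specorigin:::network_forward(net, specorigin:::input_tensor(X), TRUE)
    ce <- specorigin:::cross_entropy_grad(fw$logits, y)
    grads <- specorigin:::network_backward(fw$net, ce$dlogits, fw$caches)
    params <- specorigin:::net_params(fw$net)
    maxerr <- 0
    for (i in seq_along(params)) {
      leaves <- names(params[[i]])
      if (is.null(leaves)) next
      for (nm in leaves) {
        g <- grads[[i]][[nm]]
        for (ii in sample(length(g), min(n_probe, length(g)))) {
          pa <- params
          pa[[i]][[nm]][ii] <- pa[[i]][[nm]][ii] + eps
          l1 <- lossfun(specorigin:::net_set_params(fw$net, pa))
          pa[[i]][[nm]][ii] <- pa[[i]][[nm]][ii] - 2 * eps
          l2 <- lossfun(specorigin:::net_set_params(fw$net, pa))
          num <- (l1 - l2) / (2 * eps)
          maxerr <- max(maxerr, abs(num - g[ii]) /
                          max(1e-4, abs(num) + abs(g[ii])))
        }
      }
    }
    maxerr
  }
  expect_lt(gradcheck(build_ecnn1d(16, 3)), 1e-3)
  expect_lt(gradcheck(build_vgg1d(16, 3, dropout = 0)), 1e-3)
})
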