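# Internal neural-network primitives for 1D spectral convnets.
#
# Activations use the layout (C, L, B): channels x spectral length x batch,
# so that slicing along L and reshaping to a (C, L*B) matrix needs no
# permutation and every convolution reduces to k dense matrix products.
# Each layer implements forward (returning the output plus a cache) and
# backward (returning the input gradient plus parameter gradients with the
# same shapes as the parameters). All of this is plain R on BLAS matmuls;
# batches are small (the protocol trains with batch size 8) so this is
# fast enough.

new_layer <- function(type, params = list(), buffers = list(), cfg = list()) {
  list(type = type, params = params, buffers = buffers, cfg = cfg)
}

layer_conv1d <- function(in_ch, out_ch, kernel) {
  stopifnot(kernel %% 2L == 1L)
  W <- array(stats::rnorm(out_ch * in_ch * kernel, 0,
                          sqrt(2 / (in_ch * kernel))),
             dim = c(out_ch, in_ch, kernel))
  new_layer("conv1d", params = list(W = W, b = numeric(out_ch)),
            cfg = list(in_ch = in_ch, out_ch = out_ch, kernel = kernel))
}

layer_batchnorm <- function(ch, momentum = 0.1, eps = 1e-5) {
  new_layer("batchnorm",
            params = list(gamma = rep(1, ch), beta = numeric(ch)),
            buffers = list(running_mean = numeric(ch), running_var = rep(1, ch)),
            cfg = list(ch = ch, momentum = momentum, eps = eps))
}

layer_relu <- function() new_layer("relu")

layer_eca <- function(ch, k = eca_kernel_size(ch)) {
  stopifnot(k %% 2L == 1L, k <= 2L * ch - 1L)
  new_layer("eca", params = list(w = stats::rnorm(k, 0, sqrt(1 / k))),
            cfg = list(ch = ch, k = as.integer(k)))
}

layer_maxpool <- function(size = 2L) new_layer("maxpool", cfg = list(size = as.integer(size)))
layer_gap <- function() new_layer("gap")
layer_flatten <- function() new_layer("flatten")
layer_dropout <- function(p) new_layer("dropout", cfg = list(p = p))

layer_dense <- function(in_f, out_f) {
  new_layer("dense",
            params = list(W = matrix(stats::rnorm(out_f * in_f, 0, sqrt(2 / in_f)),
                                     out_f, in_f),
                          b = numeric(out_f)),
            cfg = list(in_f = in_f, out_f = out_f))
}

layer_resblock <- function(in_ch, out_ch, kernel = 3L, eca = FALSE) {
  sub <- list(layer_conv1d(in_ch, out_ch, kernel),
              layer_batchnorm(out_ch),
              layer_relu(),
              layer_conv1d(out_ch, out_ch, kernel),
              layer_batchnorm(out_ch))
  if (eca) sub <- c(sub, list(layer_eca(out_ch)))
  proj <- if (in_ch != out_ch) layer_conv1d(in_ch, out_ch, 1L)
  lay <- new_layer("resblock", cfg = list(in_ch = in_ch, out_ch = out_ch,
                                          kernel = kernel, eca = eca))
  lay$sub <- sub
  lay$proj <- proj
  lay
}

# ---- forward/backward -------------------------------------------------

conv1d_forward <- function(lay, x) {
  k <- lay$cfg$kernel; h <- (k - 1L) %/% 2L
  d <- dim(x); C <- d[1]; L <- d[2]; B <- d[3]
  out_ch <- lay$cfg$out_ch
  xp <- array(0, c(C, L + 2L * h, B))
  xp[, h + seq_len(L), ] <- x
  acc <- matrix(0, out_ch, L * B)
  for (j in seq_len(k)) {
    sl <- xp[, j:(j + L - 1L), , drop = FALSE]
    dim(sl) <- c(C, L * B)
    acc <- acc + matrix(lay$params$W[, , j], out_ch, C) %*% sl
  }
  acc <- acc + lay$params$b
  dim(acc) <- c(out_ch, L, B)
  list(out = acc, cache = list(xp = xp, L = L))
}

conv1d_backward <- function(lay, dout, cache) {
  k <- lay$cfg$kernel; h <- (k - 1L) %/% 2L
  xp <- cache$xp; L <- cache$L
  C <- dim(xp)[1]; B <- dim(xp)[3]
  out_ch <- lay$cfg$out_ch
  dmat <- dout; dim(dmat) <- c(out_ch, L * B)
  dW <- array(0, dim(lay$params$W))
  dxp <- array(0, dim(xp))
  for (j in seq_len(k)) {
    sl <- xp[, j:(j + L - 1L), , drop = FALSE]
    dim(sl) <- c(C, L * B)
    dW[, , j] <- dmat %*% t(sl)
    dsl <- t(matrix(lay$params$W[, , j], out_ch, C)) %*% dmat
    dim(dsl) <- c(C, L, B)
    dxp[, j:(j + L - 1L), ] <- dxp[, j:(j + L - 1L), , drop = FALSE] + dsl
  }
  dx <- dxp[, h + seq_len(L), , drop = FALSE]
  list(dx = dx, grads = list(W = dW, b = rowSums(dmat)))
}

batchnorm_forward <- function(lay, x, train) {
  d <- dim(x); C <- d[1]; N <- d[2] * d[3]
  xm <- x; dim(xm) <- c(C, N)
  eps <- lay$cfg$eps
  if (train) {
    mu <- rowMeans(xm)
    v <- rowMeans(xm^2) - mu^2
    v[v < 0] <- 0
  } else {
    mu <- lay$buffers$running_mean
    v <- lay$buffers$running_var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- (xm - mu) * inv
  y <- lay$params$gamma * xhat + lay$params$beta
  dim(y) <- d
  upd <- NULL
  if (train) {
    mom <- lay$cfg$momentum
    upd <- list(running_mean = (1 - mom) * lay$buffers$running_mean + mom * mu,
                running_var = (1 - mom) * lay$buffers$running_var + mom * v)
  }
  list(out = y, cache = list(xhat = xhat, inv = inv, d = d), buffers = upd)
}

batchnorm_backward <- function(lay, dout, cache) {
  d <- cache$d; C <- d[1]; N <- d[2] * d[3]
  dm <- dout; dim(dm) <- c(C, N)
  xhat <- cache$xhat
  dgamma <- rowSums(dm * xhat)
  dbeta <- rowSums(dm)
  g <- lay$params$gamma * cache$inv
  dx <- g * (dm - dbeta / N - xhat * (dgamma / N))
  dim(dx) <- d
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

eca_channel_means <- function(x) {
  d <- dim(x)
  colMeans(aperm(x, c(2, 1, 3)))  # (C, B)
}

# Forward pass of the ECA gate on a (C, L, B) activation: channel-wise
# global average over L, a k-tap zero-padded 1D convolution along the
# channel axis (no bias), sigmoid, and channel-wise rescaling of the input.
eca_forward_internal <- function(w, x) {
  d <- dim(x); C <- d[1]; L <- d[2]; B <- d[3]
  k <- length(w); h <- (k - 1L) %/% 2L
  m <- eca_channel_means(x)              # (C, B)
  mp <- matrix(0, C + 2L * h, B)
  mp[h + seq_len(C), ] <- m
  s <- matrix(0, C, B)
  for (j in seq_len(k)) s <- s + w[j] * mp[j:(j + C - 1L), , drop = FALSE]
  g <- sigmoid(s)                        # (C, B) gates in (0,1)
  garr <- aperm(array(g, c(C, B, L)), c(1, 3, 2))
  list(out = x * garr, cache = list(x = x, mp = mp, g = g, garr = garr,
                                    k = k, h = h, C = C, L = L, B = B))
}

eca_backward_internal <- function(w, dout, cache) {
  x <- cache$x; g <- cache$g; garr <- cache$garr
  C <- cache$C; L <- cache$L; B <- cache$B; k <- cache$k; h <- cache$h
  # direct path
  dx <- dout * garr
  # gate path: dg[c,b] = sum_l dout * x
  dg <- colMeans(aperm(dout * x, c(2, 1, 3))) * L
  ds <- dg * g * (1 - g)
  dw <- numeric(k)
  dmp <- matrix(0, C + 2L * h, B)
  for (j in seq_len(k)) {
    dw[j] <- sum(ds * cache$mp[j:(j + C - 1L), , drop = FALSE])
    dmp[j:(j + C - 1L), ] <- dmp[j:(j + C - 1L), , drop = FALSE] + w[j] * ds
  }
  dmean <- dmp[h + seq_len(C), , drop = FALSE] / L   # (C, B)
  dx <- dx + aperm(array(dmean, c(C, B, L)), c(1, 3, 2))
  list(dx = dx, grads = list(w = dw))
}

maxpool_forward <- function(lay, x) {
  sz <- lay$cfg$size
  d <- dim(x); L <- d[2]; Lo <- L %/% sz
  if (Lo < 1L) stop_fmt("maxpool: spectral length %d shorter than pool size %d", L, sz)
  idx <- lapply(seq_len(sz), function(o) seq(o, by = sz, length.out = Lo))
  y <- x[, idx[[1]], , drop = FALSE]
  arg <- array(1L, dim(y))
  for (o in 2:sz) {
    cand <- x[, idx[[o]], , drop = FALSE]
    better <- cand > y
    y[better] <- cand[better]
    arg[better] <- o
  }
  list(out = y, cache = list(arg = arg, idx = idx, d = d))
}

maxpool_backward <- function(lay, dout, cache) {
  dx <- array(0, cache$d)
  for (o in seq_along(cache$idx)) {
    m <- (cache$arg == o) * dout
    dx[, cache$idx[[o]], ] <- dx[, cache$idx[[o]], , drop = FALSE] + m
  }
  list(dx = dx, grads = NULL)
}

layer_forward <- function(lay, x, train) {
  switch(lay$type,
    conv1d = conv1d_forward(lay, x),
    batchnorm = batchnorm_forward(lay, x, train),
    relu = list(out = pmax(x, 0), cache = list(mask = x > 0)),
    eca = eca_forward_internal(lay$params$w, x),
    maxpool = maxpool_forward(lay, x),
    gap = {
      m <- eca_channel_means(x)
      list(out = m, cache = list(d = dim(x)))
    },
    flatten = {
      d <- dim(x); y <- x; dim(y) <- c(d[1] * d[2], d[3])
      list(out = y, cache = list(d = d))
    },
    dense = list(out = lay$params$W %*% x + lay$params$b, cache = list(x = x)),
    dropout = {
      if (train && lay$cfg$p > 0) {
        mask <- array((stats::runif(length(x)) >= lay$cfg$p) / (1 - lay$cfg$p), dim(x))
        list(out = x * mask, cache = list(mask = mask))
      } else {
        list(out = x, cache = list(mask = NULL))
      }
    },
    resblock = {
      z <- x; caches <- vector("list", length(lay$sub)); bufupd <- vector("list", length(lay$sub))
      for (i in seq_along(lay$sub)) {
        r <- layer_forward(lay$sub[[i]], z, train)
        z <- r$out
        caches[i] <- list(r$cache)   # [i]<-list() keeps NULLs as elements
        bufupd[i] <- list(r$buffers)
      }
      if (!is.null(lay$proj)) {
        pr <- layer_forward(lay$proj, x, train)
        skip <- pr$out; pcache <- pr$cache
      } else {
        skip <- x; pcache <- NULL
      }
      s <- z + skip
      list(out = pmax(s, 0),
           cache = list(sub = caches, proj = pcache, mask = s > 0),
           buffers = list(sub = bufupd))
    },
    stop_fmt("unknown layer type '%s'", lay$type)
  )
}

layer_backward <- function(lay, dout, cache) {
  switch(lay$type,
    conv1d = conv1d_backward(lay, dout, cache),
    batchnorm = batchnorm_backward(lay, dout, cache),
    relu = list(dx = dout * cache$mask, grads = NULL),
    eca = eca_backward_internal(lay$params$w, dout, cache),
    maxpool = maxpool_backward(lay, dout, cache),
    gap = {
      d <- cache$d
      dm <- dout / d[2]
      list(dx = aperm(array(dm, c(d[1], d[3], d[2])), c(1, 3, 2)), grads = NULL)
    },
    flatten = {
      dx <- dout; dim(dx) <- cache$d
      list(dx = dx, grads = NULL)
    },
    dense = list(dx = t(lay$params$W) %*% dout,
                 grads = list(W = dout %*% t(cache$x), b = rowSums(dout))),
    dropout = {
      if (is.null(cache$mask)) list(dx = dout, grads = NULL)
      else list(dx = dout * cache$mask, grads = NULL)
    },
    resblock = {
      dsum <- dout * cache$mask
      gsub <- vector("list", length(lay$sub))
      dz <- dsum
      for (i in rev(seq_along(lay$sub))) {
        r <- layer_backward(lay$sub[[i]], dz, cache$sub[[i]])
        dz <- r$dx
        gsub[i] <- list(r$grads)
      }
      if (!is.null(lay$proj)) {
        rp <- layer_backward(lay$proj, dsum, cache$proj)
        dx <- dz + rp$dx
        gproj <- rp$grads
      } else {
        dx <- dz + dsum
        gproj <- NULL
      }
      list(dx = dx, grads = list(sub = gsub, proj = gproj))
    },
    stop_fmt("unknown layer type '%s'", lay$type)
  )
}

# ---- parameter trees --------------------------------------------------

layer_params <- function(lay) {
  if (lay$type == "resblock") {
    list(sub = lapply(lay$sub, layer_params),
         proj = if (!is.null(lay$proj)) layer_params(lay$proj))
  } else {
    lay$params
  }
}

layer_set_params <- function(lay, p) {
  if (lay$type == "resblock") {
    for (i in seq_along(lay$sub)) lay$sub[[i]] <- layer_set_params(lay$sub[[i]], p$sub[[i]])
    if (!is.null(lay$proj)) lay$proj <- layer_set_params(lay$proj, p$proj)
  } else if (length(lay$params)) {
    lay$params <- p
  }
  lay
}

layer_buffers <- function(lay) {
  if (lay$type == "resblock") {
    list(sub = lapply(lay$sub, layer_buffers))
  } else {
    lay$buffers
  }
}

layer_set_buffers <- function(lay, b) {
  if (lay$type == "resblock") {
    for (i in seq_along(lay$sub)) lay$sub[[i]] <- layer_set_buffers(lay$sub[[i]], b$sub[[i]])
  } else if (length(lay$buffers)) {
    lay$buffers <- b
  }
  lay
}

layer_apply_buffer_update <- function(lay, upd) {
  if (is.null(upd)) return(lay)
  if (lay$type == "resblock") {
    for (i in seq_along(lay$sub)) {
      lay$sub[[i]] <- layer_apply_buffer_update(lay$sub[[i]], upd$sub[[i]])
    }
  } else {
    lay$buffers <- upd
  }
  lay
}

# elementwise map over two parallel parameter trees
tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a)); names(out) <- names(a)
    for (i in seq_along(a)) {
      out[[i]] <- if (is.null(a[[i]])) NULL else tree_map2(a[[i]], b[[i]], f)
    }
    out
  } else if (is.null(a)) {
    NULL
  } else {
    f(a, b)
  }
}

tree_sum <- function(a, f) {
  if (is.list(a)) sum(vapply(a, function(x) if (is.null(x)) 0 else tree_sum(x, f), numeric(1)))
  else if (is.null(a)) 0
  else f(a)
}
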