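# Declarative 1D convnet architectures for spectral classification:
# ECNN-1D (the channel-attention model), its CNN-1D ablation, and the
# VGG-1D / ResNet-1D baselines, each with an ECA on/off switch.
#
# A network_spec is a plain declarative description (serializable to
# JSON); init_network() instantiates it into layers with randomly
# initialized weights.

#' Adaptive ECA kernel size
#'
#' Derives the channel-attention kernel length from the channel count:
#' `k = nearest odd integer to (log2(C) + 1) / 2`, ties resolved upward,
#' and never below 1. For the channel widths used in this package,
#' `C = 16` and `C = 32` give `k = 3`, and `C = 64` gives `k = 5`.
#'
#' @param C channel count, positive integer (vectorized).
#' @return odd positive integer kernel size(s).
#' @export
eca_kernel_size <- function(C) {
  C <- as.numeric(C)
  if (any(C < 1 | C != floor(C))) stop_fmt("C must be a positive integer")
  raw <- (log2(C) + 1) / 2
  # round half-up to an integer, then take the next odd when even: the
  # boundary between the two candidate odd values sits half a unit above
  # the lower one, so anything at or beyond the midpoint resolves upward
  # (2.5 -> 3, 3 -> 3, 3.5 -> 5, 4 -> 5)
  m <- floor(raw + 0.5)
  k <- m + (m %% 2 == 0)
  as.integer(pmax(k, 1))
}

#' ECA channel-attention forward pass
#'
#' Applies the efficient-channel-attention gate to a feature tensor of
#' shape `(B, C, L)`: (1) global average over the spectral axis gives a
#' per-channel descriptor; (2) the C descriptors are convolved along the
#' channel axis with a single `k`-tap filter (zero padding `(k-1)/2`, no
#' bias); (3) a sigmoid turns them into per-channel gates in (0, 1);
#' (4) the input is rescaled channel-wise by its gate.
#'
#' @param x numeric array of shape `(B, C, L)`.
#' @param weights numeric vector of `k` filter taps, `k` odd and
#'   `k <= 2C - 1`.
#' @return array of the same shape as `x`.
#' @export
eca_forward <- function(x, weights) {
  if (!is.array(x) || length(dim(x)) != 3L) stop_fmt("x must be a (B, C, L) array")
  k <- length(weights)
  C <- dim(x)[2]
  if (k %% 2L == 0L) stop_fmt("ECA kernel must be odd (got %d taps)", k)
  if (k > 2L * C - 1L) stop_fmt("ECA kernel (%d) exceeds 2C-1 (C=%d)", k, C)
  xi <- aperm(x, c(2, 3, 1))  # internal (C, L, B) layout
  out <- eca_forward_internal(as.numeric(weights), xi)$out
  aperm(out, c(3, 1, 2))
}

new_network_spec <- function(architecture, n_bands, n_classes, blocks, head) {
  structure(
    list(architecture = architecture, n_bands = as.integer(n_bands),
         n_classes = as.integer(n_classes), blocks = blocks, head = head),
    class = "network_spec"
  )
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("network_spec '%s': %d bands -> %d classes, %d block(s)\n",
              x$architecture, x$n_bands, x$n_classes, length(x$blocks)))
  for (b in x$blocks) {
    cat(sprintf("  %s: ch=%d k=%d pool=%d eca=%s\n", b$type, b$out_channels,
                b$kernel, b$pool, if (isTRUE(b$eca)) sprintf("k%d", b$eca_k) else "off"))
  }
  invisible(x)
}

check_bands_for_blocks <- function(n_bands, n_blocks, pool = 2L) {
  if (n_bands < pool^n_blocks) {
    stop_fmt("n_bands = %d too small: %d pooling halvings need >= %d bands",
             n_bands, n_blocks, pool^n_blocks)
  }
}

#' Build the ECNN-1D architecture
#'
#' Three convolutional blocks, each Conv1D (kernel 3) -> batch norm ->
#' ReLU -> ECA attention -> max pooling (2), with channel widths expanding
#' across blocks; the ECA kernel of each block follows
#' [eca_kernel_size()] of its width. The head is global average pooling
#' followed by one fully connected layer to `n_classes` (softmax at
#' inference).
#'
#' @param n_bands number of spectral bands (>= 8).
#' @param n_classes number of origin classes.
#' @param channels non-decreasing block widths (default `c(16, 32, 64)`).
#' @return a `network_spec`.
#' @export
build_ecnn1d <- function(n_bands, n_classes, channels = c(16L, 32L, 64L)) {
  channels <- as.integer(channels)
  if (any(channels <= 0L) || any(diff(channels) < 0L)) {
    stop_fmt("channels must be positive and non-decreasing")
  }
  check_bands_for_blocks(n_bands, length(channels))
  blocks <- lapply(channels, function(ch) {
    list(type = "conv_block", out_channels = ch, kernel = 3L, pool = 2L,
         eca = TRUE, eca_k = eca_kernel_size(ch), dropout = 0)
  })
  new_network_spec("ECNN-1D", n_bands, n_classes, blocks,
                   head = list(type = "gap_fc"))
}

#' Build the CNN-1D ablation (ECNN-1D without attention)
#'
#' Identical to [build_ecnn1d()] with every ECA flag switched off.
#'
#' @inheritParams build_ecnn1d
#' @return a `network_spec`.
#' @export
build_cnn1d <- function(n_bands, n_classes, channels = c(16L, 32L, 64L)) {
  spec <- build_ecnn1d(n_bands, n_classes, channels)
  spec$architecture <- "CNN-1D"
  # eca_k is kept (it is derived from the width) so the two specs differ
  # in the eca flags alone
  for (i in seq_along(spec$blocks)) spec$blocks[[i]]$eca <- FALSE
  spec
}

#' Build the VGG-1D baseline
#'
#' Three blocks of two Conv1D layers (kernel uniformly 3) with batch norm
#' and ReLU, followed by max pooling and dropout; head flattens into a
#' hidden fully connected layer (width 128, dropout) and the class layer.
#' `eca = TRUE` appends one ECA stage per block (the "+ECA" ablation
#' variant), placed after the block's activations and before pooling.
#'
#' @inheritParams build_ecnn1d
#' @param channels block widths (default `c(32, 64, 128)`).
#' @param eca append an ECA stage to every block.
#' @param dropout dropout rate after each block and hidden layer.
#' @return a `network_spec`.
#' @export
build_vgg1d <- function(n_bands, n_classes, channels = c(32L, 64L, 128L),
                        eca = FALSE, dropout = 0.3) {
  channels <- as.integer(channels)
  check_bands_for_blocks(n_bands, length(channels))
  blocks <- lapply(channels, function(ch) {
    b <- list(type = "vgg_block", out_channels = ch, kernel = 3L, pool = 2L,
              eca = eca, dropout = dropout)
    if (eca) b$eca_k <- eca_kernel_size(ch)
    b
  })
  new_network_spec("VGG-1D", n_bands, n_classes, blocks,
                   head = list(type = "flatten_fc", hidden = 128L,
                               dropout = dropout))
}

#' Build the ResNet-1D baseline
#'
#' Residual blocks (two Conv1D layers with batch norm, identity skip, 1x1
#' projection when channel widths differ) with stride-2 max pooling
#' between blocks, global average pooling and a fully connected head.
#' `eca = TRUE` inserts an ECA stage inside each block before the residual
#' sum (the "+ECA" ablation variant).
#'
#' @inheritParams build_ecnn1d
#' @param channels residual block widths (default `c(16, 32, 64)`).
#' @param eca insert ECA inside each residual block.
#' @return a `network_spec`.
#' @export
build_resnet1d <- function(n_bands, n_classes, channels = c(16L, 32L, 64L),
                           eca = FALSE) {
  channels <- as.integer(channels)
  check_bands_for_blocks(n_bands, length(channels))
  blocks <- lapply(channels, function(ch) {
    b <- list(type = "res_block", out_channels = ch, kernel = 3L, pool = 2L,
              eca = eca, dropout = 0)
    if (eca) b$eca_k <- eca_kernel_size(ch)
    b
  })
  new_network_spec("ResNet-1D", n_bands, n_classes, blocks,
                   head = list(type = "gap_fc"))
}

# ---- spec -> layers ---------------------------------------------------

compile_layers <- function(spec) {
  layers <- list()
  ch <- 1L
  len <- spec$n_bands
  for (b in spec$blocks) {
    if (b$type == "conv_block") {
      layers <- c(layers, list(layer_conv1d(ch, b$out_channels, b$kernel),
                               layer_batchnorm(b$out_channels),
                               layer_relu()))
      if (isTRUE(b$eca)) layers <- c(layers, list(layer_eca(b$out_channels, b$eca_k)))
      layers <- c(layers, list(layer_maxpool(b$pool)))
    } else if (b$type == "vgg_block") {
      layers <- c(layers, list(layer_conv1d(ch, b$out_channels, b$kernel),
                               layer_batchnorm(b$out_channels),
                               layer_relu(),
                               layer_conv1d(b$out_channels, b$out_channels, b$kernel),
                               layer_batchnorm(b$out_channels),
                               layer_relu()))
      if (isTRUE(b$eca)) layers <- c(layers, list(layer_eca(b$out_channels, b$eca_k)))
      layers <- c(layers, list(layer_maxpool(b$pool)))
      if (b$dropout > 0) layers <- c(layers, list(layer_dropout(b$dropout)))
    } else if (b$type == "res_block") {
      layers <- c(layers, list(layer_resblock(ch, b$out_channels, b$kernel,
                                              eca = isTRUE(b$eca)),
                               layer_maxpool(b$pool)))
    } else {
      stop_fmt("unknown block type '%s'", b$type)
    }
    ch <- b$out_channels
    len <- len %/% b$pool
    if (len < 1L) stop_fmt("spectral length collapsed to 0; n_bands too small")
  }
  if (spec$head$type == "gap_fc") {
    layers <- c(layers, list(layer_gap(), layer_dense(ch, spec$n_classes)))
  } else if (spec$head$type == "flatten_fc") {
    layers <- c(layers, list(layer_flatten(),
                             layer_dense(ch * len, spec$head$hidden),
                             layer_relu()))
    if (spec$head$dropout > 0) layers <- c(layers, list(layer_dropout(spec$head$dropout)))
    layers <- c(layers, list(layer_dense(spec$head$hidden, spec$n_classes)))
  } else {
    stop_fmt("unknown head type '%s'", spec$head$type)
  }
  layers
}

#' Instantiate a network spec with random weights
#'
#' @param spec a `network_spec`.
#' @param seed integer seed for weight initialization.
#' @return a `network` object (spec plus initialized layers).
#' @export
init_network <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  layers <- with_seed(derive_seed(seed, "init"), compile_layers(spec))
  structure(list(spec = spec, layers = layers), class = "network")
}

network_forward <- function(net, x, train = FALSE) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    r <- layer_forward(net$layers[[i]], x, train)
    x <- r$out
    caches[[i]] <- r$cache
    if (train && !is.null(r$buffers)) {
      net$layers[[i]] <- layer_apply_buffer_update(net$layers[[i]], r$buffers)
    }
  }
  list(logits = x, caches = caches, net = net)
}

network_backward <- function(net, dlogits, caches) {
  grads <- vector("list", length(net$layers))
  dx <- dlogits
  for (i in rev(seq_along(net$layers))) {
    r <- layer_backward(net$layers[[i]], dx, caches[[i]])
    dx <- r$dx
    grads[i] <- list(r$grads)  # [i]<-list() keeps NULL grads as elements
  }
  grads
}

net_params <- function(net) lapply(net$layers, layer_params)
net_set_params <- function(net, p) {
  for (i in seq_along(net$layers)) net$layers[[i]] <- layer_set_params(net$layers[[i]], p[[i]])
  net
}
net_buffers <- function(net) lapply(net$layers, layer_buffers)
net_set_buffers <- function(net, b) {
  for (i in seq_along(net$layers)) net$layers[[i]] <- layer_set_buffers(net$layers[[i]], b[[i]])
  net
}

#' Count trainable parameters of a network spec
#'
#' @param spec a `network_spec` (or an instantiated `network`).
#' @return integer parameter count.
#' @export
count_parameters <- function(spec) {
  net <- if (inherits(spec, "network")) spec else init_network(spec, seed = 1L)
  as.integer(tree_sum(net_params(net), length))
}

# rows of X (n x p) -> internal (1, L, B) tensor
input_tensor <- function(X) {
  arr <- array(0, c(1L, ncol(X), nrow(X)))
  arr[1L, , ] <- t(X)
  arr
}

softmax_rows <- function(logits_t) {
  # logits_t: (K, B); returns (B, K) probabilities
  z <- t(logits_t)
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Class probabilities for a matrix of spectra
#'
#' Runs the network in inference mode (batch-norm running statistics,
#' no dropout) and applies a softmax to the logits.
#'
#' @param net a trained `network`.
#' @param X spectra matrix `n x n_bands`.
#' @param batch_size evaluation batch size.
#' @return `n x n_classes` matrix of probabilities (rows sum to 1).
#' @export
predict_network <- function(net, X, batch_size = 128L) {
  X <- check_matrix(X)
  if (ncol(X) != net$spec$n_bands) {
    stop_fmt("X has %d bands but the network expects %d", ncol(X), net$spec$n_bands)
  }
  n <- nrow(X)
  out <- matrix(0, n, net$spec$n_classes)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    r <- network_forward(net, input_tensor(X[i:j, , drop = FALSE]), train = FALSE)
    out[i:j, ] <- softmax_rows(r$logits)
    i <- j + 1L
  }
  out
}

#' Predicted class ids (0-based) for a matrix of spectra
#'
#' @inheritParams predict_network
#' @return integer vector of class ids in `0 .. K-1`.
#' @export
predict_classes <- function(net, X, batch_size = 128L) {
  max.col(predict_network(net, X, batch_size), ties.method = "first") - 1L
}

# ---- serialization ----------------------------------------------------

#' Serialize a network spec to JSON
#'
#' @param spec a `network_spec`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
network_spec_to_json <- function(spec, path) {
  stopifnot(inherits(spec, "network_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a network spec back from JSON
#'
#' Inverse of [network_spec_to_json()]; the round trip is the identity.
#'
#' @param path JSON file written by [network_spec_to_json()].
#' @return a `network_spec`.
#' @export
network_spec_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  int_if <- function(x) if (is.numeric(x) && all(x == floor(x))) as.integer(x) else x
  blocks <- lapply(raw$blocks, function(b) {
    b <- lapply(b, function(v) if (is.numeric(v)) int_if(v) else v)
    if (!is.null(b$dropout)) b$dropout <- as.numeric(b$dropout)
    b
  })
  head <- lapply(raw$head, function(v) if (is.numeric(v)) int_if(v) else v)
  if (!is.null(head$dropout)) head$dropout <- as.numeric(head$dropout)
  new_network_spec(raw$architecture, raw$n_bands, raw$n_classes, blocks, head)
}
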