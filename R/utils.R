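# Internal helpers shared across modules.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so package functions never clobber the user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a secondary 31-bit seed from a base seed and a stream label,
# keeping independent stochastic stages decoupled but reproducible.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587) + 1L
}

stop_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_matrix <- function(X, what = "X") {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X)) {
    stop_fmt("%s must be a numeric matrix (samples x bands)", what)
  }
  if (any(!is.finite(X))) stop_fmt("%s contains non-finite values", what)
  X
}
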