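# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Derive `n` child seeds from a master seed; values stay below 2^31 - 1.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

check_symmetric <- function(W, tol = 1e-8, arg = "W") {
  if (!is.matrix(W) || nrow(W) != ncol(W)) {
    stop(sprintf("`%s` must be a square matrix", arg), call. = FALSE)
  }
  if (any(!is.finite(W))) {
    stop(sprintf("`%s` contains non-finite entries", arg), call. = FALSE)
  }
  if (max(abs(W - t(W))) > tol) {
    stop(sprintf("`%s` must be symmetric", arg), call. = FALSE)
  }
  invisible(W)
}

# Upper-triangle (i < j) values of a square matrix as a vector.
upper_pairs <- function(M) M[upper.tri(M)]
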