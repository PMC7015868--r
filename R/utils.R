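# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state so callers never observe a side effect on `.Random.seed`.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @noRd
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# draw `n` independent sub-seeds from a master seed (32-bit safe)
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_square_labeled <- function(x, what = "matrix") {
  if (!is.matrix(x) || nrow(x) != ncol(x))
    stopf("%s must be a square matrix", what)
  invisible(x)
}

# squared Euclidean distances between rows of X (dense, clamped at 0)
row_sqdist <- function(x) {
  n2 <- rowSums(x^2)
  d2 <- outer(n2, n2, "+") - 2 * tcrossprod(x)
  d2[d2 < 0] <- 0
  d2
}
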