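# shared in-code fixtures

# two diseases sharing one parent: closures X:{X,P}, Y:{Y,P}
forest_xy <- function() {
  dag_forest(c("X", "Y"), rbind(c("X", "P"), c("Y", "P")))
}

# adds an isolated third disease Z (its own root)
forest_xyz <- function() {
  dag_forest(c("X", "Y", "Z"), rbind(c("X", "P"), c("Y", "P")))
}

# small labeled binary matrix with full row/column coverage
tiny_assoc <- function(m = 6, n = 5, seed = 1, p = 0.4) {
  A <- with_seed_local(seed, matrix(stats::rbinom(m * n, 1, p), m, n))
  A[rowSums(A) == 0, 1] <- 1
  A[1, colSums(A) == 0] <- 1
  dimnames(A) <- list(sprintf("m%d", 1:m), sprintf("d%d", 1:n))
  A
}

# seed helper that does not disturb the ambient RNG stream
with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# random symmetric PSD matrix with unit-ish scale
random_psd <- function(p, seed) {
  with_seed_local(seed, {
    B <- matrix(stats::rnorm(p * p), p)
    crossprod(B) / p
  })
}

# small planted fixture reused across evaluation tests
small_fixture <- function(seed = 3) {
  generate_fixture(synthetic_spec(m = 18, n = 12, density = 0.12,
                                  seed = seed))
}

# fast config for evaluation tests (overridable defaults)
fast_config <- function(...) {
  do.call(ekrr_config, utils::modifyList(list(M = 3, seed = 42), list(...)))
}
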