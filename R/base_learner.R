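#' Pipeline dimensions implied by the feature-reduction rules
#'
#' Reports, for `m` miRNAs and `n` diseases, the number of features kept by
#' random subsampling (`m_s = floor(r * m)`, `n_s = floor(r * n)`), the
#' reduced dimensions after truncated SVD (`k_m = floor(trunc_fraction *
#' m_s)`, `k_d` likewise) and the Gaussian-kernel bandwidths `sigma`
#' implied by the default rule `2 * sigma^2 = k`.
#'
#' @param m number of miRNAs.
#' @param n number of diseases.
#' @param r feature-sampling fraction.
#' @param trunc_fraction fraction of singular values kept.
#' @return named list: `m_s`, `n_s`, `k_m`, `k_d`, `sigma_m`, `sigma_d`.
#' @export
feature_dims <- function(m, n, r = 0.2, trunc_fraction = 0.2) {
  m_s <- max(1L, floor(r * m))
  n_s <- max(1L, floor(r * n))
  k_m <- min(max(1L, floor(trunc_fraction * m_s)), m, m_s)
  k_d <- min(max(1L, floor(trunc_fraction * n_s)), n, n_s)
  list(m_s = m_s, n_s = n_s, k_m = k_m, k_d = k_d,
       sigma_m = sqrt(k_m / 2), sigma_d = sqrt(k_d / 2))
}

#' Randomly subsample similarity features (columns)
#'
#' Draws `floor(r * ncol)` distinct columns uniformly without replacement
#' (at least 1); rows are untouched. With `use_subsampling = FALSE` the
#' matrix passes through unchanged.
#'
#' @param sim square labeled similarity matrix (rows = entities,
#'   columns = features).
#' @param r sampling fraction in (0, 1).
#' @param use_subsampling disable to pass the full matrix through.
#' @return the column-subset matrix.
#' @export
subsample_features <- function(sim, r = 0.2, use_subsampling = TRUE) {
  if (!use_subsampling) return(sim)
  if (r <= 0 || r >= 1) stopf("r must lie in (0, 1), got %g", r)
  check_square_labeled(sim, "similarity matrix")
  ns <- max(1L, floor(r * ncol(sim)))
  idx <- sort(sample.int(ncol(sim), ns))
  sim[, idx, drop = FALSE]
}

#' Truncated-SVD feature reduction
#'
#' Decomposes the feature matrix `F = U S V'` and returns `U S` restricted
#' to the largest `k = floor(trunc_fraction * ncol(F))` singular values
#' (clamped to `[1, min(dim(F))]`), i.e. the coordinates of the rows in the
#' best rank-k approximation. Singular-vector signs are fixed by making
#' each left singular vector's largest-magnitude entry positive, so results
#' are reproducible across linear-algebra backends.
#'
#' @param x numeric feature matrix (entities x features).
#' @param trunc_fraction fraction of singular values kept, in (0, 1].
#' @param use_tsvd disable to pass the matrix through unchanged.
#' @return matrix with `nrow(x)` rows and `k` columns.
#' @export
tsvd_reduce <- function(x, trunc_fraction = 0.2, use_tsvd = TRUE) {
  if (!use_tsvd) return(x)
  if (length(x) == 0) stopf("empty feature matrix")
  k <- min(max(1L, floor(trunc_fraction * ncol(x))), nrow(x), ncol(x))
  sv <- svd(x, nu = k, nv = 0)
  u <- sv$u
  for (j in seq_len(k)) {
    i <- which.max(abs(u[, j]))
    if (u[i, j] < 0) u[, j] <- -u[, j]
  }
  out <- sweep(u, 2, sv$d[seq_len(k)], "*")
  rownames(out) <- rownames(x)
  out
}

#' Kernel matrix on reduced features
#'
#' Gaussian kernel `exp(-||x_i - x_j||^2 / bandwidth)` with the bandwidth
#' defaulting to the number of feature columns (i.e. `2 sigma^2 = k`), or
#' the polynomial kernels `1 + x'y` (`poly1`) and `(1 + x'y)^2` (`poly2`).
#'
#' @param x numeric feature matrix (entities x features).
#' @param kind `"gaussian"`, `"poly1"` or `"poly2"`.
#' @param bandwidth Gaussian denominator (`2 sigma^2`); defaults to
#'   `ncol(x)`.
#' @return symmetric kernel matrix, labeled from `rownames(x)`.
#' @export
kernel_matrix <- function(x, kind = c("gaussian", "poly1", "poly2"),
                          bandwidth = NULL) {
  kind <- match.arg(kind)
  K <- switch(kind,
    gaussian = {
      bw <- bandwidth %||% ncol(x)
      if (bw <= 0) stopf("bandwidth must be > 0")
      exp(-row_sqdist(x) / bw)
    },
    poly1 = 1 + tcrossprod(x),
    poly2 = (1 + tcrossprod(x))^2)
  K <- (K + t(K)) / 2
  dimnames(K) <- list(rownames(x), rownames(x))
  K
}

#' Closed-form kernel ridge regression scores
#'
#' Returns `K (K + lambda I)^-1 Y` via a linear solve (no explicit
#' inverse). The solve must meet the residual contract
#' `||(K + lambda I) X - Y||_F <= 1e-8 ||Y||_F`; a singular system with
#' `lambda = 0` raises an error asking for regularization.
#'
#' @param K symmetric positive semidefinite kernel matrix (p x p).
#' @param Y target matrix (p x q).
#' @param lam ridge regularizer >= 0.
#' @return score matrix of the same shape as `Y`.
#' @export
krr_scores <- function(K, Y, lam = 1) {
  if (lam < 0) stopf("lam must be >= 0")
  Y <- as.matrix(Y)
  if (nrow(Y) != nrow(K)) stopf("K and Y are not conformable")
  M <- K + diag(lam, nrow(K))
  X <- tryCatch(solve(M, Y),
                error = function(e)
                  stopf("regularization required: kernel system is singular (%s)",
                        conditionMessage(e)))
  resid <- norm(M %*% X - Y, "F")
  if (resid > 1e-8 * max(1, norm(Y, "F")))
    stopf("regularization required: solve residual %.3g exceeds tolerance", resid)
  out <- K %*% X
  dimnames(out) <- dimnames(Y)
  out
}

#' Propagate scores to entities with no training association
#'
#' A column of `scores` belonging to an entity outside `known` (no known
#' association in the training matrix) is replaced by the
#' similarity-weighted average of the known entities' columns:
#' `sum_u sim(t, u) * scores[, u] / sum_u sim(t, u)`, sums over known
#' entities only. Known entities are untouched. If an entity has zero
#' similarity to every known entity its column is set to 0 with a warning.
#'
#' @param scores score matrix whose columns index the entities of `sim`.
#' @param sim integrated similarity matrix over those entities.
#' @param known logical vector marking entities with at least one training
#'   association.
#' @return the score matrix with new-entity columns replaced.
#' @export
propagate_new_entities <- function(scores, sim, known) {
  if (!any(known)) stopf("no entity has a training association")
  if (ncol(scores) != ncol(sim) || length(known) != ncol(sim))
    stopf("scores, sim and known disagree in entity count")
  new <- which(!known)
  if (!length(new)) return(scores)
  W <- sim[new, known, drop = FALSE]          # |new| x |known|
  tot <- rowSums(W)
  dead <- tot == 0
  if (any(dead)) {
    warning(sprintf("%d entity(ies) have zero similarity to all known entities; scores set to 0",
                    sum(dead)))
    tot[dead] <- 1
    W[dead, ] <- 0
  }
  scores[, new] <- scores[, known, drop = FALSE] %*% t(W / tot)
  scores
}

#' One KRR-avg base learner
#'
#' Executes the full base-learning pipeline in both spaces: random feature
#' subsampling of the integrated similarity rows, truncated-SVD reduction,
#' kernel construction (Gaussian bandwidth = number of reduced features
#' unless overridden), closed-form KRR against the association matrix, and
#' similarity-based propagation for entities with no training association.
#' The two score matrices are averaged: `S = 0.5 S_M + 0.5 t(S_D)`.
#'
#' @param A binary association matrix (m x n) with dimnames.
#' @param SM integrated miRNA similarity (m x m).
#' @param SD integrated disease similarity (n x n).
#' @param config an [ekrr_config()].
#' @param seed optional integer; when given, the feature draws are made
#'   under this seed (RNG state is restored afterwards).
#' @return list of class `base_scores`: `S` (m x n), `S_M` (m x n, miRNA
#'   space), `S_D` (n x m, disease space).
#' @export
base_predict <- function(A, SM, SD, config = ekrr_config(), seed = NULL) {
  run <- function() {
    side_seeds <- if (config$link_subsets && config$use_subsampling)
      rep(sample.int(.Machine$integer.max - 1L, 1), 2) else NULL
    fm <- reduce_side(SM, config, side_seeds[1])
    fd <- reduce_side(SD, config, side_seeds[2])
    km <- side_kernel(fm, config)
    kd <- side_kernel(fd, config)
    s_m <- krr_scores(km, A, config$lam)
    s_d <- krr_scores(kd, t(A), config$lam)
    s_m <- propagate_new_entities(s_m, SD, colSums(A) > 0)
    s_d <- propagate_new_entities(s_d, SM, rowSums(A) > 0)
    structure(list(S = 0.5 * s_m + 0.5 * t(s_d), S_M = s_m, S_D = s_d),
              class = "base_scores")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# subsample + reduce one side's features
reduce_side <- function(sim, config, side_seed = NULL) {
  f1 <- if (!is.null(side_seed) && !is.na(side_seed))
    with_seed(side_seed, subsample_features(sim, config$r, config$use_subsampling))
  else subsample_features(sim, config$r, config$use_subsampling)
  tsvd_reduce(f1, config$trunc_fraction, config$use_tsvd)
}

side_kernel <- function(feat, config) {
  bw <- if (config$kernel == "gaussian")
    config$bandwidth_override %||% ncol(feat) else NULL
  kernel_matrix(feat, config$kernel, bandwidth = bw)
}
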