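#' Ensemble of KRR-avg base learners
#'
#' Runs [base_predict()] `M` times, each with its own sub-seed derived
#' deterministically from the master seed, and averages the score matrices
#' entrywise. With both subsampling and TSVD disabled the base learner is
#' deterministic, so the ensemble equals a single learner for any `M` (and
#' is computed once).
#'
#' @param A binary association matrix (m x n) with dimnames.
#' @param SM integrated miRNA similarity (m x m).
#' @param SD integrated disease similarity (n x n).
#' @param config an [ekrr_config()]; `config$M` learners are run with
#'   master seed `config$seed`.
#' @return list of class `mda_prediction`: `S` (mean score matrix),
#'   `learner_seeds`, `config`.
#' @export
ekrr_predict <- function(A, SM, SD, config = ekrr_config()) {
  deterministic <- !config$use_subsampling && !config$use_tsvd &&
    !config$link_subsets
  seeds <- derive_seeds(config$seed, config$M)
  if (deterministic) {
    S <- base_predict(A, SM, SD, config)$S
  } else {
    S <- matrix(0, nrow(A), ncol(A), dimnames = dimnames(A))
    for (s in seeds)
      S <- S + base_predict(A, SM, SD, config, seed = s)$S
    S <- S / config$M
  }
  structure(list(S = S, learner_seeds = seeds, config = config),
            class = "mda_prediction")
}

#' @export
print.mda_prediction <- function(x, ...) {
  cat(sprintf("<mda_prediction> %d x %d scores, M=%d, seed=%d\n",
              nrow(x$S), ncol(x$S), x$config$M, x$config$seed))
  invisible(x)
}

#' Kronecker product kernel ridge regression (single-KRR variant)
#'
#' Replaces the two per-space KRRs of the base learner by a single KRR on
#' the pairwise Kronecker kernel `K((m_i, d_j), (m_k, d_l)) =
#' KM(m_i, m_k) KD(d_j, d_l)`. The vectorized solve
#' `vec(S') = K (K + lambda I)^-1 vec(A')` is carried out through the
#' eigendecompositions `KM = V_m L_m V_m'`, `KD = V_d L_d V_d'`:
#' \deqn{vec(Z) = (L_m \otimes L_d)(L_m \otimes L_d + \lambda I)^{-1}
#'   vec(V_d' A' V_m), \quad S = V_m Z' V_d'}
#' so the n*m x n*m system is never formed. The per-learner kernels are
#' built by the same subsample + TSVD + kernel stages as [base_predict()],
#' and the variant is ensembled over `config$M` draws exactly like
#' [ekrr_predict()].
#'
#' @inheritParams ekrr_predict
#' @return list of class `mda_prediction` (see [ekrr_predict()]).
#' @export
ekkrr_predict <- function(A, SM, SD, config = ekrr_config()) {
  deterministic <- !config$use_subsampling && !config$use_tsvd &&
    !config$link_subsets
  seeds <- derive_seeds(config$seed, config$M)
  one <- function(seed) {
    run <- function() {
      side_seeds <- if (config$link_subsets && config$use_subsampling)
        rep(sample.int(.Machine$integer.max - 1L, 1), 2) else NULL
      km <- side_kernel(reduce_side(SM, config, side_seeds[1]), config)
      kd <- side_kernel(reduce_side(SD, config, side_seeds[2]), config)
      kron_krr(A, km, kd, config$lam)
    }
    if (is.null(seed)) run() else with_seed(seed, run())
  }
  if (deterministic) {
    S <- one(NULL)
  } else {
    S <- matrix(0, nrow(A), ncol(A), dimnames = dimnames(A))
    for (s in seeds) S <- S + one(s)
    S <- S / config$M
  }
  structure(list(S = S, learner_seeds = seeds, config = config),
            class = "mda_prediction")
}

# eigendecomposition path of the Kronecker KRR; A is m x n, km m x m,
# kd n x n; returns the m x n score matrix
kron_krr <- function(A, km, kd, lam) {
  em <- eigen(km, symmetric = TRUE)
  ed <- eigen(kd, symmetric = TRUE)
  for (pair in list(list(e = em, K = km), list(e = ed, K = kd))) {
    recon <- pair$e$vectors %*% (pair$e$values * t(pair$e$vectors))
    if (norm(recon - pair$K, "F") > 1e-6 * max(1, norm(pair$K, "F")))
      stopf("eigendecomposition residual above tolerance")
  }
  L <- outer(ed$values, em$values)            # n x m grid of l_d * l_m
  if (lam == 0 && any(abs(L) < 1e-12))
    stopf("regularization required: Kronecker kernel is singular")
  C <- t(ed$vectors) %*% t(A) %*% em$vectors  # V_d' A' V_m (n x m)
  Z <- (L / (L + lam)) * C
  S <- em$vectors %*% t(Z) %*% t(ed$vectors)
  dimnames(S) <- dimnames(A)
  S
}

#' Rank candidate miRNA-disease pairs by predicted score
#'
#' Returns every pair unknown in the training matrix, sorted by descending
#' score; ties are broken by (miRNA index, disease index) ascending so the
#' ordering is fully deterministic.
#'
#' @param result an `mda_prediction` (or a bare score matrix).
#' @param A_train the training association matrix; pairs with entry 1 are
#'   excluded from the output.
#' @return data frame with columns `mirna`, `disease`, `score`.
#' @export
rank_pairs <- function(result, A_train) {
  S <- if (inherits(result, "mda_prediction")) result$S else result
  idx <- which(A_train == 0, arr.ind = TRUE)
  sc <- S[idx]
  ord <- order(-sc, idx[, 1], idx[, 2])
  data.frame(mirna = rownames(A_train)[idx[ord, 1]],
             disease = colnames(A_train)[idx[ord, 2]],
             score = sc[ord],
             stringsAsFactors = FALSE)
}
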