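#' Model configuration
#'
#' Collects every tunable of the prediction pipeline in one validated list.
#'
#' @param r fraction of similarity features sampled per base learner,
#'   in (0, 1). Each learner keeps `floor(r * m)` miRNA features and
#'   `floor(r * n)` disease features (at least 1).
#' @param trunc_fraction fraction of singular values retained by the
#'   truncated SVD, in (0, 1]; the reduced dimension is
#'   `floor(trunc_fraction * sampled features)`, clamped to at least 1.
#' @param lam ridge regularizer lambda >= 0 of the kernel ridge regression.
#' @param kernel kernel on the reduced features: `"gaussian"`,
#'   `"poly1"` (1 + x'y) or `"poly2"` ((1 + x'y)^2).
#' @param M ensemble size (number of base learners), >= 1.
#' @param delta semantic contribution decay factor of the DAG similarity
#'   (model 1), in (0, 1).
#' @param beta_prime base bandwidth of the Gaussian interaction profile
#'   kernel, > 0 (used for both the miRNA and the disease side).
#' @param seed master seed; per-learner sub-seeds are derived from it.
#' @param use_subsampling if `FALSE`, base learners use all features
#'   (disables the random-subspace step).
#' @param use_tsvd if `FALSE`, base learners skip the SVD reduction.
#' @param bandwidth_override optional explicit Gaussian-kernel denominator
#'   (the `2 * sigma^2` of the kernel `exp(-d^2 / (2 sigma^2))`), replacing
#'   the default rule denominator = number of reduced features.
#' @param link_subsets if `TRUE`, the miRNA- and disease-side feature draws
#'   within one base learner are generated from the same sub-seed (coupled
#'   draws); default independent draws.
#' @param sim_mask how a pair qualifies for semantic/functional similarity
#'   during integration: `"pairwise"` (that pair's similarity > 0) or
#'   `"entity"` (both entities carry similarity information).
#' @param log_base base of the logarithm in the model-2 semantic
#'   contribution; natural log by default.
#' @return a validated list of class `ekrr_config`.
#' @export
ekrr_config <- function(r = 0.2, trunc_fraction = 0.2, lam = 1,
                        kernel = c("gaussian", "poly1", "poly2"),
                        M = 100L, delta = 0.5, beta_prime = 1,
                        seed = 1L, use_subsampling = TRUE, use_tsvd = TRUE,
                        bandwidth_override = NULL, link_subsets = FALSE,
                        sim_mask = c("pairwise", "entity"),
                        log_base = exp(1)) {
  kernel <- match.arg(kernel)
  sim_mask <- match.arg(sim_mask)
  if (use_subsampling && (r <= 0 || r >= 1))
    stopf("r must lie in (0, 1), got %g", r)
  if (trunc_fraction <= 0 || trunc_fraction > 1)
    stopf("trunc_fraction must lie in (0, 1], got %g", trunc_fraction)
  if (lam < 0) stopf("lam must be >= 0")
  if (M < 1) stopf("M must be >= 1")
  if (delta <= 0 || delta >= 1) stopf("delta must lie in (0, 1)")
  if (beta_prime <= 0) stopf("beta_prime must be > 0")
  if (!is.null(bandwidth_override) && bandwidth_override <= 0)
    stopf("bandwidth_override must be > 0")
  if (log_base <= 0 || log_base == 1) stopf("invalid log base")
  structure(list(r = r, trunc_fraction = trunc_fraction, lam = lam,
                 kernel = kernel, M = as.integer(M), delta = delta,
                 beta_prime = beta_prime, seed = as.integer(seed),
                 use_subsampling = isTRUE(use_subsampling),
                 use_tsvd = isTRUE(use_tsvd),
                 bandwidth_override = bandwidth_override,
                 link_subsets = isTRUE(link_subsets),
                 sim_mask = sim_mask, log_base = log_base),
            class = "ekrr_config")
}

#' @export
print.ekrr_config <- function(x, ...) {
  cat(sprintf(paste0("<ekrr_config> r=%g trunc=%g lambda=%g kernel=%s M=%d ",
                     "delta=%g beta'=%g seed=%d subsample=%s tsvd=%s\n"),
              x$r, x$trunc_fraction, x$lam, x$kernel, x$M, x$delta,
              x$beta_prime, x$seed, x$use_subsampling, x$use_tsvd))
  invisible(x)
}
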