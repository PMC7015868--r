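#' Semantic contribution of ancestor terms to one disease
#'
#' Model 1 assigns the disease itself a contribution of 1 and every ancestor
#' `t` the value `delta * max` over the contributions of t's children inside
#' the disease's DAG, so the contribution decays by `delta` per generation
#' along the most direct ancestry line. Model 2 weights a term by its
#' specificity across the whole disease set,
#' `-log(count(t) / n_diseases)`, where `count(t)` is the number of disease
#' DAGs containing `t`; it does not depend on the query disease.
#'
#' @param forest a [dag_forest()].
#' @param disease disease (node) identifier.
#' @param model 1 or 2.
#' @param delta decay factor in (0, 1) (model 1 only).
#' @param dag_counts named integer vector, node -> number of disease DAGs
#'   containing the node (model 2 only; must cover every ancestor).
#' @param n_diseases total number of diseases (model 2 only).
#' @param log_base logarithm base for model 2 (natural log by default).
#' @return named numeric vector of contributions over the ancestor closure
#'   `T(disease)`.
#' @export
disease_contributions <- function(forest, disease, model = 1, delta = 0.5,
                                  dag_counts = NULL, n_diseases = NULL,
                                  log_base = exp(1)) {
  closure <- dag_ancestors(forest, disease)
  if (model == 2) {
    if (is.null(dag_counts) || is.null(n_diseases))
      stopf("model 2 requires dag_counts and n_diseases")
    missing <- setdiff(closure, names(dag_counts))
    if (length(missing))
      stopf("node '%s' missing from dag_counts", missing[1])
    contrib <- -log(dag_counts[closure] / n_diseases, base = log_base)
    return(stats::setNames(as.numeric(contrib), closure))
  }
  if (model != 1) stopf("model must be 1 or 2")
  if (delta <= 0 || delta >= 1) stopf("delta must lie in (0, 1)")
  # children of each node restricted to the closure
  edges <- forest$edges
  keep <- edges[, "child"] %in% closure & edges[, "parent"] %in% closure
  edges <- edges[keep, , drop = FALSE]
  children <- split(edges[, "child"], edges[, "parent"])
  contrib <- stats::setNames(rep(NA_real_, length(closure)), closure)
  contrib[disease] <- 1
  # reverse topological sweep: a node is ready once all its in-closure
  # children have contributions
  while (anyNA(contrib)) {
    progressed <- FALSE
    for (t in closure[is.na(contrib)]) {
      ch <- children[[t]] %||% character(0)
      if (!anyNA(contrib[ch])) {
        contrib[t] <- delta * max(contrib[ch])
        progressed <- TRUE
      }
    }
    if (!progressed) stopf("DAG closure of '%s' is not acyclic", disease)
  }
  contrib
}

#' Disease semantic similarity matrix over a DAG forest
#'
#' For diseases `d_i`, `d_j` with ancestor closures `T_i`, `T_j`,
#' contribution maps `C_i`, `C_j` and semantic values `DV = sum(C)`:
#' \deqn{SS(i, j) = \sum_{t \in T_i \cap T_j} (C_i(t) + C_j(t)) / (DV_i + DV_j)}
#' The result is symmetric with values in \[0, 1\] and (whenever `DV > 0`)
#' a unit diagonal. Under model 2 a disease whose terms all appear in every
#' DAG has `DV = 0`; such pairs get similarity 0 with a warning.
#'
#' @inheritParams disease_contributions
#' @return labeled symmetric similarity matrix over `forest$disease_ids`.
#' @export
semantic_similarity <- function(forest, model = 1, delta = 0.5,
                                log_base = exp(1)) {
  ids <- forest$disease_ids
  closures <- lapply(ids, function(d) dag_ancestors(forest, d))
  names(closures) <- ids
  dag_counts <- n_diseases <- NULL
  if (model == 2) {
    tab <- table(unlist(closures, use.names = FALSE))
    dag_counts <- stats::setNames(as.integer(tab), names(tab))
    n_diseases <- length(ids)
  }
  contribs <- lapply(ids, function(d)
    disease_contributions(forest, d, model = model, delta = delta,
                          dag_counts = dag_counts, n_diseases = n_diseases,
                          log_base = log_base))
  names(contribs) <- ids
  dv <- vapply(contribs, sum, numeric(1))
  if (any(dv == 0))
    warning(sprintf("%d disease(s) have zero semantic value; their similarities are set to 0",
                    sum(dv == 0)))
  n <- length(ids)
  ss <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in i:n) {
      den <- dv[i] + dv[j]
      if (den == 0) next
      common <- intersect(closures[[i]], closures[[j]])
      if (length(common))
        ss[i, j] <- ss[j, i] <-
          sum(contribs[[i]][common] + contribs[[j]][common]) / den
    }
  }
  ss
}

#' Gaussian interaction profile (GIP) kernel similarity
#'
#' Treats each entity's row (miRNA side) or column (disease side) of the
#' association matrix as a binary interaction profile `IV` and computes
#' `K(i, j) = exp(-beta * ||IV_i - IV_j||^2)` with the bandwidth normalized
#' by the mean squared profile norm:
#' `beta = beta_prime / mean(||IV||^2)`.
#'
#' @param A binary association matrix (miRNAs x diseases) with dimnames.
#' @param side `"mirna"` (profiles = rows of A) or `"disease"` (columns).
#' @param beta_prime base bandwidth, > 0.
#' @return labeled symmetric kernel matrix with unit diagonal.
#' @export
gip_kernel <- function(A, side = c("mirna", "disease"), beta_prime = 1) {
  side <- match.arg(side)
  profiles <- if (side == "mirna") A else t(A)
  norms2 <- rowSums(profiles^2)
  if (all(norms2 == 0)) stopf("GIP bandwidth undefined: all-zero association matrix")
  beta <- beta_prime / mean(norms2)
  K <- exp(-beta * row_sqdist(profiles))
  dimnames(K) <- list(rownames(profiles), rownames(profiles))
  K
}

#' Integrate semantic/functional similarity with GIP kernel similarity
#'
#' Entry-wise combination: where a pair "has" primary similarity the primary
#' value is used, elsewhere the GIP kernel value fills the gap. For diseases
#' the primary similarity is the mean of the two semantic models
#' `(SS1 + SS2) / 2`; for miRNAs it is the functional similarity `FS`
#' (pass these as `primary`).
#'
#' Which pairs "have" primary similarity is ambiguous in pairwise data; two
#' readings are offered: `mask = "pairwise"` uses pairs whose primary value
#' is > 0, `mask = "entity"` uses pairs where both entities carry similarity
#' information (`has_info`; by default, entities with any positive
#' off-diagonal primary value).
#'
#' @param primary labeled primary similarity matrix (semantic mean or FS).
#' @param gip labeled GIP kernel matrix with identical labels.
#' @param mask `"pairwise"` or `"entity"`.
#' @param has_info optional logical vector (entity-level mask), only used
#'   with `mask = "entity"`.
#' @return labeled symmetric similarity matrix with unit diagonal.
#' @export
integrate_similarity <- function(primary, gip,
                                 mask = c("pairwise", "entity"),
                                 has_info = NULL) {
  mask <- match.arg(mask)
  check_square_labeled(primary, "primary similarity")
  check_square_labeled(gip, "GIP similarity")
  if (!identical(dim(primary), dim(gip)) ||
      !identical(rownames(primary), rownames(gip)))
    stopf("primary and GIP matrices disagree in shape or labels")
  use_primary <- if (mask == "pairwise") {
    primary > 0
  } else {
    if (is.null(has_info)) {
      off <- primary
      diag(off) <- 0
      has_info <- rowSums(off > 0) > 0
    }
    outer(has_info, has_info, "&")
  }
  out <- ifelse(use_primary, primary, gip)
  dimnames(out) <- dimnames(primary)
  diag(out) <- 1
  out
}

#' Build the integrated miRNA and disease similarity matrices
#'
#' Convenience wrapper around the full similarity stack: semantic similarity
#' models 1 and 2 from the DAG forest (if given), GIP kernels from the
#' association matrix, then integration. With no forest (or no functional
#' similarity) the corresponding side falls back to pure GIP similarity.
#'
#' @param A binary association matrix (miRNAs x diseases) with dimnames.
#' @param forest optional [dag_forest()] covering the diseases of `A`.
#' @param fs optional labeled miRNA functional similarity matrix.
#' @param config an [ekrr_config()].
#' @param semantic_mean optional precomputed `(SS1 + SS2) / 2` matrix; pass
#'   it to avoid recomputing the (A-independent) semantic part when only
#'   `A` changes, as in cross-validation.
#' @param keep_intermediates if `TRUE`, also return SS1, SS2, GM, GD.
#' @return list with `SM` (miRNA side) and `SD` (disease side), plus
#'   intermediates if requested.
#' @export
build_similarities <- function(A, forest = NULL, fs = NULL,
                               config = ekrr_config(),
                               semantic_mean = NULL,
                               keep_intermediates = FALSE) {
  gm <- gip_kernel(A, "mirna", config$beta_prime)
  gd <- gip_kernel(A, "disease", config$beta_prime)
  ss1 <- ss2 <- NULL
  if (is.null(semantic_mean) && !is.null(forest)) {
    ss1 <- semantic_similarity(forest, 1, config$delta)
    ss2 <- semantic_similarity(forest, 2, log_base = config$log_base)
    semantic_mean <- (ss1 + ss2) / 2
  }
  sd_mat <- if (is.null(semantic_mean)) gd else
    integrate_similarity(semantic_mean[colnames(A), colnames(A)], gd,
                         mask = config$sim_mask)
  sm_mat <- if (is.null(fs)) gm else
    integrate_similarity(fs[rownames(A), rownames(A)], gm,
                         mask = config$sim_mask)
  out <- list(SM = sm_mat, SD = sd_mat)
  if (keep_intermediates)
    out <- c(out, list(SS1 = ss1, SS2 = ss2, GM = gm, GD = gd,
                       semantic_mean = semantic_mean))
  out
}
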