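# Validation protocols: LOOCV (global/local), repeated k-fold CV, ROC/AUC,
# rank CDF, robustness to association removal, bandwidth sensitivity and
# per-disease case-study ranking.

# turn a model spec into a scoring function(A, SM, SD, config) -> matrix
resolve_model <- function(model) {
  if (is.function(model)) return(model)
  switch(model,
         ekrr = function(A, SM, SD, config) ekrr_predict(A, SM, SD, config)$S,
         ekkrr = function(A, SM, SD, config) ekkrr_predict(A, SM, SD, config)$S,
         stopf("unknown model '%s'", model))
}

# mid-rank of score s among the candidate scores neg (ties share ranks)
midrank <- function(s, neg) 1 + sum(neg > s) + 0.5 * sum(neg == s)

# similarity matrices for one training matrix; `sem` is the precomputed
# (A-independent) semantic mean, `static` an optional frozen similarity pair
fold_similarities <- function(A, sem, fs, config, static = NULL) {
  static %||% build_similarities(A, fs = fs, config = config,
                                 semantic_mean = sem)
}

loocv_engine <- function(dataset, config, model, mode, forest, fs,
                         static_similarity) {
  A <- dataset$A
  pos <- which(A == 1, arr.ind = TRUE)
  if (nrow(pos) == 0) stopf("dataset has no known association")
  model_fn <- resolve_model(model)
  sem <- if (!is.null(forest)) {
    ss1 <- semantic_similarity(forest, 1, config$delta)
    ss2 <- semantic_similarity(forest, 2, log_base = config$log_base)
    (ss1 + ss2) / 2
  }
  static <- if (static_similarity)
    build_similarities(A, fs = fs, config = config, semantic_mean = sem)
  cand_global <- which(A == 0)
  ranks <- cand_sizes <- numeric(nrow(pos))
  for (t in seq_len(nrow(pos))) {
    i <- pos[t, 1]; j <- pos[t, 2]
    Am <- A
    Am[i, j] <- 0
    sims <- fold_similarities(Am, sem, fs, config, static)
    S <- model_fn(Am, sims$SM, sims$SD, config)
    neg <- if (mode == "global") S[cand_global] else S[A[, j] == 0, j]
    ranks[t] <- midrank(S[i, j], neg)
    cand_sizes[t] <- length(neg)
  }
  res <- roc_auc(ranks, cand_sizes)
  structure(list(mode = mode, ranks = ranks, cand_sizes = cand_sizes,
                 auc = res$auc, roc = res$roc),
            class = "mda_eval")
}

#' @export
print.mda_eval <- function(x, ...) {
  cat(sprintf("<mda_eval> %s LOOCV: %d hidden positives, AUC = %.4f\n",
              x$mode, length(x$ranks), x$auc))
  invisible(x)
}

#' Global leave-one-out cross validation
#'
#' Each known association is hidden in turn (its entry set to 0), the GIP
#' and integrated similarities are rebuilt from the masked matrix, the
#' model is retrained, and the hidden pair is ranked against every pair
#' without association evidence in the original matrix. AUC is the pooled
#' Mann-Whitney statistic over the hidden-positive ranks.
#'
#' Rebuilding the GIP similarity inside every step matters: the GIP kernel
#' is a function of `A`, so computing it once from the full matrix would
#' leak the test label. Set `static_similarity = TRUE` to reproduce that
#' leaky shortcut for comparison.
#'
#' @param dataset an [association_dataset()].
#' @param config an [ekrr_config()].
#' @param model `"ekrr"`, `"ekkrr"`, or a function
#'   `(A, SM, SD, config) -> score matrix`.
#' @param forest optional [dag_forest()] for disease semantic similarity.
#' @param fs optional miRNA functional similarity matrix.
#' @param static_similarity if `TRUE`, similarities are built once from the
#'   full matrix instead of per fold (leaks the held-out label).
#' @return object of class `mda_eval` with elements `ranks`, `cand_sizes`,
#'   `auc` and `roc`.
#' @export
global_loocv <- function(dataset, config = ekrr_config(), model = "ekrr",
                         forest = NULL, fs = NULL,
                         static_similarity = FALSE) {
  loocv_engine(dataset, config, model, "global", forest, fs,
               static_similarity)
}

#' Local leave-one-out cross validation
#'
#' As [global_loocv()], but each hidden association is ranked only against
#' the miRNAs unassociated with its disease, and AUC is pooled across
#' diseases.
#'
#' @inheritParams global_loocv
#' @return object of class `mda_eval`.
#' @export
local_loocv <- function(dataset, config = ekrr_config(), model = "ekrr",
                        forest = NULL, fs = NULL,
                        static_similarity = FALSE) {
  loocv_engine(dataset, config, model, "local", forest, fs,
               static_similarity)
}

#' Repeated k-fold cross validation
#'
#' Per repeat, the known associations are randomly partitioned into `k`
#' folds of sizes differing by at most 1; each fold is hidden together, the
#' similarities are rebuilt from the masked matrix, and the hidden pairs
#' are ranked against the pairs without association evidence in the
#' original matrix. One pooled AUC is computed per repeat; the summary is
#' their mean and standard deviation.
#'
#' @inheritParams global_loocv
#' @param k number of folds, >= 2.
#' @param repeats number of random re-partitions.
#' @param seed master seed for the partitions (defaults to `config$seed`);
#'   each repeat uses a sub-seed derived from it.
#' @return object of class `mda_cv` with `auc_mean`, `auc_sd` and
#'   `repeat_aucs`.
#' @export
kfold_cv <- function(dataset, config = ekrr_config(), model = "ekrr",
                     k = 5, repeats = 10, seed = config$seed,
                     forest = NULL, fs = NULL, static_similarity = FALSE) {
  if (k < 2) stopf("k must be >= 2")
  A <- dataset$A
  pos <- which(A == 1, arr.ind = TRUE)
  if (nrow(pos) < k) stopf("fewer associations (%d) than folds (%d)",
                           nrow(pos), k)
  model_fn <- resolve_model(model)
  sem <- if (!is.null(forest)) {
    ss1 <- semantic_similarity(forest, 1, config$delta)
    ss2 <- semantic_similarity(forest, 2, log_base = config$log_base)
    (ss1 + ss2) / 2
  }
  static <- if (static_similarity)
    build_similarities(A, fs = fs, config = config, semantic_mean = sem)
  cand_global <- which(A == 0)
  rep_seeds <- derive_seeds(seed, repeats)
  repeat_aucs <- numeric(repeats)
  for (rp in seq_len(repeats)) {
    folds <- with_seed(rep_seeds[rp],
                       sample(rep_len(seq_len(k), nrow(pos))))
    ranks <- cand_sizes <- numeric(nrow(pos))
    for (f in seq_len(k)) {
      test <- which(folds == f)
      Am <- A
      Am[pos[test, , drop = FALSE]] <- 0
      sims <- fold_similarities(Am, sem, fs, config, static)
      S <- model_fn(Am, sims$SM, sims$SD, config)
      neg <- S[cand_global]
      for (t in test) {
        ranks[t] <- midrank(S[pos[t, 1], pos[t, 2]], neg)
        cand_sizes[t] <- length(neg)
      }
    }
    repeat_aucs[rp] <- roc_auc(ranks, cand_sizes)$auc
  }
  structure(list(auc_mean = mean(repeat_aucs),
                 auc_sd = stats::sd(repeat_aucs),
                 repeat_aucs = repeat_aucs, k = k, repeats = repeats),
            class = "mda_cv")
}

#' @export
print.mda_cv <- function(x, ...) {
  cat(sprintf("<mda_cv> %d-fold CV, %d repeats: AUC = %.4f +/- %.4f\n",
              x$k, x$repeats, x$auc_mean, x$auc_sd))
  invisible(x)
}

#' ROC curve and AUC from hidden-positive ranks
#'
#' Each hidden positive carries its mid-rank among its own candidate
#' (negative) set. The AUC is the Mann-Whitney statistic: the probability
#' that a positive outranks a negative, ties counted 1/2, averaged over
#' positives: `mean((N + 1 - rank) / N)`. The ROC curve is swept over all
#' integer rank thresholds.
#'
#' @param positive_ranks numeric vector of ranks (mid-ranks allowed), each
#'   in `[1, candidate size + 1]`.
#' @param candidate_counts integer vector of candidate-set sizes, recycled
#'   if of length 1.
#' @return list with `auc` and `roc` (data frame of `fpr`, `tpr`).
#' @export
roc_auc <- function(positive_ranks, candidate_counts) {
  if (length(positive_ranks) == 0) stopf("no ranks supplied")
  n <- rep_len(candidate_counts, length(positive_ranks))
  if (any(positive_ranks < 1 | positive_ranks > n + 1))
    stopf("rank outside [1, candidate size + 1]")
  auc <- mean((n + 1 - positive_ranks) / n)
  thresholds <- 0:(max(n) + 1)
  tpr <- vapply(thresholds, function(t) mean(positive_ranks <= t), numeric(1))
  fpr <- vapply(thresholds, function(t)
    mean((pmin(t, n + 1) - (positive_ranks <= t)) / n), numeric(1))
  list(auc = auc, roc = data.frame(fpr = pmax(fpr, 0), tpr = tpr))
}

#' Rank cumulative distribution (recall at k)
#'
#' Fraction of hidden positives recovered within the top `k` predictions,
#' for each `k` on the grid.
#'
#' @param ranks numeric vector of hidden-positive ranks, >= 1.
#' @param k_grid integer vector of cutoffs.
#' @return data frame with columns `k` and `recall`.
#' @export
rank_cdf <- function(ranks, k_grid) {
  if (any(ranks < 1)) stopf("ranks must be >= 1")
  data.frame(k = k_grid,
             recall = vapply(k_grid, function(k) mean(ranks <= k),
                             numeric(1)))
}

#' Robustness to random removal of known associations
#'
#' Repeats the case-study ranking after flipping a random fraction of the
#' known associations to 0 (fresh draw per repeat), and reports how much of
#' the unperturbed top-k list survives. The candidate set is held fixed at
#' the unperturbed one (miRNAs unassociated with the disease in the
#' original matrix) so that lists are comparable across repeats. The
#' expected overlap of two random k-lists, `k^2 / #candidates`, is reported
#' as the chance baseline.
#'
#' @inheritParams global_loocv
#' @param disease disease identifier to rank candidates for.
#' @param fraction fraction of known associations removed, in (0, 1).
#' @param repeats number of random removals.
#' @param top_k length of the candidate list compared.
#' @param seed master seed for the removals (defaults to `config$seed`).
#' @return list with `baseline_top`, `repeat_tops`, `overlaps` (counts per
#'   repeat), `overlap_mean` and `random_expected_overlap`.
#' @export
perturbation_experiment <- function(dataset, disease,
                                    config = ekrr_config(), model = "ekrr",
                                    fraction = 0.2, repeats = 10,
                                    top_k = 10, seed = config$seed,
                                    forest = NULL, fs = NULL) {
  if (fraction <= 0 || fraction >= 1) stopf("fraction must lie in (0, 1)")
  A <- dataset$A
  d <- match(disease, colnames(A))
  if (is.na(d)) stopf("unknown disease id '%s'", disease)
  model_fn <- resolve_model(model)
  sem <- if (!is.null(forest)) {
    ss1 <- semantic_similarity(forest, 1, config$delta)
    ss2 <- semantic_similarity(forest, 2, log_base = config$log_base)
    (ss1 + ss2) / 2
  }
  cand <- which(A[, d] == 0)
  top_k <- min(top_k, length(cand))
  top_list <- function(S) {
    sc <- S[cand, d]
    names(cand)[order(-sc, cand)][seq_len(top_k)]
  }
  sims0 <- fold_similarities(A, sem, fs, config)
  baseline_top <- top_list(model_fn(A, sims0$SM, sims0$SD, config))
  pos <- which(A == 1)
  n_remove <- floor(fraction * length(pos))
  rep_seeds <- derive_seeds(seed, repeats)
  repeat_tops <- vector("list", repeats)
  for (rp in seq_len(repeats)) {
    Am <- A
    if (n_remove > 0) {
      drop_idx <- with_seed(rep_seeds[rp], sample(pos, n_remove))
      Am[drop_idx] <- 0
    }
    sims <- fold_similarities(Am, sem, fs, config)
    repeat_tops[[rp]] <- top_list(model_fn(Am, sims$SM, sims$SD, config))
  }
  overlaps <- vapply(repeat_tops,
                     function(tp) length(intersect(tp, baseline_top)),
                     numeric(1))
  list(baseline_top = baseline_top, repeat_tops = repeat_tops,
       overlaps = overlaps, overlap_mean = mean(overlaps),
       random_expected_overlap = top_k^2 / length(cand))
}

#' Sensitivity of LOOCV AUC to the Gaussian kernel bandwidth
#'
#' Sweeps the kernel bandwidth sigma of
#' `exp(-||x - y||^2 / (2 sigma^2))` over a grid, running global and local
#' LOOCV at each point via `bandwidth_override = 2 * sigma^2`. A sigma with
#' `2 sigma^2` equal to the reduced feature count reproduces the default
#' bandwidth rule exactly.
#'
#' @inheritParams global_loocv
#' @param sigma_grid positive numeric vector of bandwidths.
#' @return data frame with columns `sigma`, `global_auc`, `local_auc`.
#' @export
bandwidth_sensitivity <- function(dataset, sigma_grid,
                                  config = ekrr_config(), model = "ekrr",
                                  forest = NULL, fs = NULL,
                                  static_similarity = FALSE) {
  if (any(sigma_grid <= 0)) stopf("sigma must be > 0")
  rows <- lapply(sigma_grid, function(sg) {
    cfg <- config
    cfg$bandwidth_override <- 2 * sg^2
    data.frame(sigma = sg,
               global_auc = global_loocv(dataset, cfg, model, forest, fs,
                                         static_similarity)$auc,
               local_auc = local_loocv(dataset, cfg, model, forest, fs,
                                       static_similarity)$auc)
  })
  do.call(rbind, rows)
}

#' Case-study ranking of candidate miRNAs for one disease
#'
#' Ranks miRNAs for the given disease by predicted score. With
#' `new_disease = TRUE`, every known association of the disease is masked
#' before training, so the disease is treated as having no association
#' evidence (its scores then come entirely from similarity-based
#' propagation) and all miRNAs are candidates; otherwise candidates are the
#' miRNAs unassociated with the disease.
#'
#' @inheritParams global_loocv
#' @param disease disease identifier.
#' @param new_disease mask the disease's associations before training.
#' @param top_k number of candidates returned (clamped to the candidate
#'   count).
#' @return data frame with columns `mirna`, `score` and `known` (the
#'   original association label, informative in `new_disease` mode).
#' @export
case_study_rank <- function(dataset, disease, config = ekrr_config(),
                            model = "ekrr", new_disease = FALSE,
                            top_k = 50, forest = NULL, fs = NULL) {
  A <- dataset$A
  d <- match(disease, colnames(A))
  if (is.na(d)) stopf("unknown disease id '%s'", disease)
  model_fn <- resolve_model(model)
  sem <- if (!is.null(forest)) {
    ss1 <- semantic_similarity(forest, 1, config$delta)
    ss2 <- semantic_similarity(forest, 2, log_base = config$log_base)
    (ss1 + ss2) / 2
  }
  Am <- A
  if (new_disease) Am[, d] <- 0
  sims <- fold_similarities(Am, sem, fs, config)
  S <- model_fn(Am, sims$SM, sims$SD, config)
  cand <- which(Am[, d] == 0)
  sc <- S[cand, d]
  ord <- order(-sc, cand)
  keep <- ord[seq_len(min(top_k, length(cand)))]
  data.frame(mirna = rownames(A)[cand[keep]],
             score = sc[keep],
             known = A[cand[keep], d] == 1,
             stringsAsFactors = FALSE)
}
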