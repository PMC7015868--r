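# cheap deterministic "models" for harness tests
oracle_model <- function(truth) {
  function(A, SM, SD, config) truth  # scores = the full true matrix
}
constant_model <- function(A, SM, SD, config) {
  matrix(1, nrow(A), ncol(A), dimnames = dimnames(A))
}

test_that("roc_auc equals brute-force concordance counting", {
  # frozen example: pos scores {0.9, 0.4} vs neg {0.6, 0.1} -> 3/4
  pos <- c(0.9, 0.4); neg <- c(0.6, 0.1)
  ranks <- vapply(pos, function(s) 1 + sum(neg > s) + 0.5 * sum(neg == s),
                  numeric(1))
  expect_equal(roc_auc(ranks, length(neg))$auc, 3 / 4)

  for (seed in 1:20) {
    scores <- with_seed_local(seed, round(stats::runif(60), 2))  # many ties
    lab <- with_seed_local(seed + 99, stats::rbinom(60, 1, 0.3))
    if (!any(lab == 1) || !any(lab == 0)) next
    pos <- scores[lab == 1]; neg <- scores[lab == 0]
    brute <- mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
    ranks <- vapply(pos, function(s) 1 + sum(neg > s) + 0.5 * sum(neg == s),
                    numeric(1))
    expect_equal(roc_auc(ranks, length(neg))$auc, brute, tolerance = 1e-12)
  }
})

test_that("roc_auc boundary conventions: perfect, tied, and invalid input", {
  # a positive of rank 1 beats its whole candidate set
  expect_equal(roc_auc(c(1, 1), c(2, 2))$auc, 1)
  # rank 2 among 2 negatives concedes one discordant pair
  expect_equal(roc_auc(c(1, 2), c(2, 2))$auc, 0.75)
  # all scores tied: every rank is the mid-rank -> 0.5
  n <- 10
  expect_equal(roc_auc(rep(1 + n / 2, 4), n)$auc, 0.5)
  expect_error(roc_auc(numeric(0), 5), "no ranks")
  expect_error(roc_auc(8, 5), "outside")
  roc <- roc_auc(c(1, 3, 5), 6)$roc
  expect_true(all(diff(roc$tpr) >= 0))
  expect_true(all(diff(roc$fpr) >= -1e-12))
  expect_equal(roc$tpr[nrow(roc)], 1)
  expect_equal(roc$fpr[nrow(roc)], 1)
})

test_that("rank_cdf counts recovered positives per cutoff", {
  expect_equal(rank_cdf(c(1, 5, 10), 5)$recall, 2 / 3)
  expect_equal(rank_cdf(c(1, 5, 10), c(0, 10, 50))$recall, c(0, 1, 1))
  grid <- rank_cdf(c(2, 4, 9), 1:10)
  expect_true(all(diff(grid$recall) >= 0))
  expect_error(rank_cdf(c(0, 2), 5), ">= 1")
})

test_that("LOOCV ranks an oracle model at AUC 1 and a constant model at 0.5", {
  fx <- small_fixture()
  truth <- fx$dataset$A + with_seed_local(1, matrix(stats::runif(
    length(fx$dataset$A), 0, 0.1), nrow(fx$dataset$A)))
  dimnames(truth) <- dimnames(fx$dataset$A)
  ev <- global_loocv(fx$dataset, fast_config(), oracle_model(truth))
  expect_equal(ev$auc, 1)
  ev <- local_loocv(fx$dataset, fast_config(), oracle_model(truth))
  expect_equal(ev$auc, 1)
  ev <- global_loocv(fx$dataset, fast_config(), constant_model)
  expect_equal(ev$auc, 0.5)
})

test_that("the LOOCV harness only ever shows the model the masked matrix", {
  fx <- small_fixture()
  A <- fx$dataset$A
  pos <- which(A == 1, arr.ind = TRUE)
  seen <- new.env(); seen$hidden_was_masked <- TRUE; seen$calls <- 0
  spy <- function(Am, SM, SD, config) {
    seen$calls <- seen$calls + 1
    # exactly one known association must be hidden in every call
    if (sum(A - Am) != 1) seen$hidden_was_masked <- FALSE
    matrix(stats::runif(length(Am)), nrow(Am), dimnames = dimnames(Am))
  }
  global_loocv(fx$dataset, fast_config(), spy)
  expect_equal(seen$calls, nrow(pos))
  expect_true(seen$hidden_was_masked)
})

test_that("similarities are rebuilt from the masked matrix unless frozen", {
  fx <- small_fixture()
  sims_full <- build_similarities(fx$dataset$A, fs = fx$fs)
  seen <- new.env(); seen$gm_changed <- TRUE; seen$gm_static <- TRUE
  spy_dynamic <- function(Am, SM, SD, config) {
    # the GIP part of SD depends on A; masking must change it
    if (identical(SD, sims_full$SD)) seen$gm_changed <- FALSE
    matrix(0, nrow(Am), ncol(Am), dimnames = dimnames(Am))
  }
  spy_static <- function(Am, SM, SD, config) {
    if (!identical(SD, sims_full$SD)) seen$gm_static <- FALSE
    matrix(0, nrow(Am), ncol(Am), dimnames = dimnames(Am))
  }
  global_loocv(fx$dataset, fast_config(), spy_dynamic, fs = fx$fs)
  expect_true(seen$gm_changed)
  global_loocv(fx$dataset, fast_config(), spy_static, fs = fx$fs,
               static_similarity = TRUE)
  expect_true(seen$gm_static)
})

test_that("local LOOCV on a single-disease dataset restricts global ranks to that column", {
  A <- matrix(c(1, 0, 1, 0, 0, 0), 6, 1,
              dimnames = list(sprintf("m%d", 1:6), "d1"))
  # single disease: gip on disease side is 1x1; use a function model to
  # avoid degenerate kernel learning and test the harness arithmetic
  truth <- matrix(c(0.9, 0.2, 0.8, 0.4, 0.3, 0.1), 6, 1,
                  dimnames = dimnames(A))
  ds <- association_dataset(rownames(A), "d1", A)
  g <- global_loocv(ds, fast_config(), oracle_model(truth))
  l <- local_loocv(ds, fast_config(), oracle_model(truth))
  expect_equal(g$ranks, l$ranks)
  expect_equal(g$cand_sizes, l$cand_sizes)
})

test_that("random scores give AUC near 1/2 on a 30x20 dataset", {
  spec <- synthetic_spec(m = 30, n = 20, density = 100 / 600, seed = 8)
  fx <- generate_fixture(spec)
  rng_model <- function(Am, SM, SD, config)
    matrix(stats::runif(length(Am)), nrow(Am), dimnames = dimnames(Am))
  ev <- with_seed_local(31, global_loocv(fx$dataset, fast_config(), rng_model))
  # binomial 3-sigma band around 0.5 for ~100 hidden positives
  expect_gt(ev$auc, 0.4)
  expect_lt(ev$auc, 0.6)
})

test_that("k-fold CV partitions evenly, seeds reproducibly, and errors when infeasible", {
  fx <- small_fixture()
  cv1 <- kfold_cv(fx$dataset, fast_config(), constant_model, k = 5,
                  repeats = 2, seed = 7)
  cv2 <- kfold_cv(fx$dataset, fast_config(), constant_model, k = 5,
                  repeats = 2, seed = 7)
  expect_identical(cv1$repeat_aucs, cv2$repeat_aucs)
  expect_equal(cv1$auc_mean, 0.5)  # constant scores, mid-rank ties

  # fold sizes differ by at most one
  P <- sum(fx$dataset$A)
  folds <- krrmda:::with_seed(1, sample(rep_len(1:5, P)))
  expect_lte(diff(range(table(folds))), 1)

  tiny <- association_dataset("m1", c("d1", "d2"),
                              matrix(c(1, 1), 1, 2))
  expect_error(kfold_cv(tiny, fast_config(), constant_model, k = 5),
               "fewer associations")
  expect_error(kfold_cv(fx$dataset, fast_config(), constant_model, k = 1),
               "k must be")
})

test_that("k-fold CV with the real model recovers signal on the planted fixture", {
  fx <- small_fixture()
  cv <- kfold_cv(fx$dataset, fast_config(), "ekrr", k = 5, repeats = 2,
                 seed = 11, forest = fx$forest, fs = fx$fs)
  expect_gt(cv$auc_mean, 0.6)
  expect_length(cv$repeat_aucs, 2)
  expect_true(is.finite(cv$auc_sd))
})

test_that("bandwidth sweep reproduces the default run at 2*sigma^2 = k and sweeps the grid", {
  fx <- small_fixture()
  cfg <- fast_config(use_tsvd = FALSE, use_subsampling = FALSE)
  # without subsampling, features = full similarity rows: k = m and n; a
  # single sigma cannot match both sides, so check equivalence on one side
  # via the model path instead: explicit override equal to the default
  # denominator must give identical kernels
  sims <- build_similarities(fx$dataset$A, fx$forest, fx$fs)
  S_default <- base_predict(fx$dataset$A, sims$SM, sims$SD, cfg)$S
  m <- nrow(fx$dataset$A)
  cfg_ovr <- cfg; cfg_ovr$bandwidth_override <- m
  S_ovr <- base_predict(fx$dataset$A, sims$SM, sims$SD, cfg_ovr)$S
  # miRNA-space scores agree exactly (m = default denominator there)
  expect_equal(base_predict(fx$dataset$A, sims$SM, sims$SD, cfg_ovr)$S_M,
               base_predict(fx$dataset$A, sims$SM, sims$SD, cfg)$S_M)

  tab <- bandwidth_sensitivity(fx$dataset, c(1, 3), fast_config(M = 1),
                               model = "ekrr", forest = fx$forest, fs = fx$fs)
  expect_equal(tab$sigma, c(1, 3))
  expect_true(all(tab$global_auc >= 0 & tab$global_auc <= 1))
  expect_true(all(tab$local_auc >= 0 & tab$local_auc <= 1))
  expect_error(bandwidth_sensitivity(fx$dataset, c(-1), fast_config()),
               "sigma")
})

test_that("case-study ranking handles known and new diseases", {
  fx <- small_fixture()
  d <- fx$dataset$disease_ids[1]
  top <- case_study_rank(fx$dataset, d, fast_config(), "ekrr", top_k = 5,
                         forest = fx$forest, fs = fx$fs)
  expect_lte(nrow(top), 5)
  expect_false(any(top$known))  # known pairs are not candidates here
  expect_true(all(diff(top$score) <= 0))

  # new-disease mode: all miRNAs are candidates, hidden knowns flagged
  topn <- case_study_rank(fx$dataset, d, fast_config(), "ekrr",
                          new_disease = TRUE, top_k = nrow(fx$dataset$A),
                          forest = fx$forest, fs = fx$fs)
  expect_equal(nrow(topn), nrow(fx$dataset$A))
  expect_equal(sum(topn$known), sum(fx$dataset$A[, d]))
  expect_error(case_study_rank(fx$dataset, "nope", fast_config()),
               "unknown disease")
})

test_that("hidden positives of a masked disease rank above the median candidate", {
  fx <- generate_fixture(synthetic_spec(m = 30, n = 15, density = 0.15,
                                        seed = 21))
  A <- fx$dataset$A
  # pick the best-covered disease so the hidden signal is real
  d <- colnames(A)[which.max(colSums(A))]
  topn <- case_study_rank(fx$dataset, d, ekrr_config(M = 10, seed = 2),
                          "ekrr", new_disease = TRUE, top_k = nrow(A),
                          forest = fx$forest, fs = fx$fs)
  med <- stats::median(seq_len(nrow(topn)))
  mean_rank_hidden <- mean(which(topn$known))
  expect_lt(mean_rank_hidden, med)
})

test_that("20%-removal robustness keeps top lists above the chance baseline", {
  fx <- small_fixture()
  d <- fx$dataset$disease_ids[which.max(colSums(fx$dataset$A))]
  out <- perturbation_experiment(fx$dataset, d, ekrr_config(M = 5, seed = 3),
                                 "ekrr", fraction = 0.2, repeats = 3,
                                 top_k = 5, forest = fx$forest, fs = fx$fs)
  expect_length(out$overlaps, 3)
  expect_gt(out$overlap_mean, out$random_expected_overlap)
  # same seed, same removals
  out2 <- perturbation_experiment(fx$dataset, d, ekrr_config(M = 5, seed = 3),
                                  "ekrr", fraction = 0.2, repeats = 3,
                                  top_k = 5, forest = fx$forest, fs = fx$fs)
  expect_identical(out$repeat_tops, out2$repeat_tops)
  # a fraction too small to remove anything reproduces the baseline list
  out0 <- perturbation_experiment(fx$dataset, d, fast_config(),
                                  "ekrr", fraction = 1e-4, repeats = 1,
                                  top_k = 5, forest = fx$forest, fs = fx$fs)
  expect_identical(out0$repeat_tops[[1]], out0$baseline_top)
})
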