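# krrmda

Prediction of candidate miRNA–disease associations by an ensemble of
kernel ridge regression (KRR) classifiers over randomly subsampled,
SVD-reduced similarity features.

## The problem and the model

Experimentally supported miRNA–disease associations form a sparse
bipartite network: a binary matrix *A* ∈ {0,1}^(m×n) over *m* miRNAs and
*n* diseases. The task is to rank the unobserved pairs so that true but
unrecorded associations concentrate at the top — a shortlist for
experimental validation.

Features for both sides come from an integrated similarity stack:

* **Disease semantic similarity** over MeSH-style DAGs, two models — a
  per-generation decay Δ along ancestor paths, and a specificity weight
  −log(count(t)/n) — combined as their mean;
* **miRNA functional similarity** (an external matrix, e.g. MISIM);
* **Gaussian interaction profile (GIP) kernels**
  K(i,j) = exp(−β‖IV_i − IV_j‖²), β = β′ / mean‖IV‖², filling pairs with
  no semantic/functional similarity.

Each of *M* base learners samples a fraction *r* of the similarity
features per side, compresses them with a truncated SVD (top
⌊0.2·sampled⌋ singular values, features U·S), builds Gaussian kernels
exp(−‖x−y‖²/k) with k the reduced feature count, and scores both spaces in
closed form:

    S_M = KM (KM + λI)⁻¹ A        S_D = KD (KD + λI)⁻¹ Aᵀ
    S   = ½ S_M + ½ S_Dᵀ

Entities without training associations are scored by similarity-weighted
averaging over known entities. Ensemble scores are the mean over the *M*
learners. A Kronecker-product-kernel variant (one KRR on KM ⊗ KD, solved
via the per-side eigendecompositions) is included for comparison, as are
polynomial kernels, global/local leave-one-out and repeated 5-fold
cross-validation, recall@k curves, bandwidth-sensitivity sweeps,
case-study ranking and a 20%-removal robustness protocol.

A synthetic generator produces self-contained fixtures (DAG forest,
planted low-rank association matrix, coherent functional similarity) so
the whole stack is testable without any external database.

## Worked example

```r
library(krrmda)

fx <- generate_fixture(synthetic_spec(m = 50, n = 40, latent_rank = 3,
                                      density = 0.07, seed = 1))
fx$dataset
#> <assoc_dataset> 50 miRNAs x 40 diseases, 159 known associations

sims <- build_similarities(fx$dataset$A, fx$forest, fx$fs)
pred <- ekrr_predict(fx$dataset$A, sims$SM, sims$SD,
                     ekrr_config(M = 100, seed = 7))
head(rank_pairs(pred, fx$dataset$A), 5)
#>   mirna disease score
#> 1  m023    d036 0.519
#> 2  m033    d011 0.461
#> 3  m038    d040 0.418
#> 4  m038    d001 0.412
#> 5  m024    d020 0.412

ev <- global_loocv(fx$dataset, ekrr_config(M = 10, seed = 7), "ekrr",
                   forest = fx$forest, fs = fx$fs)
ev
#> <mda_eval> global LOOCV: 159 hidden positives, AUC = 0.8934
rank_cdf(ev$ranks, c(10, 50, 100))
#>     k recall
#> 1  10  0.233
#> 2  50  0.503
#> 3 100  0.635
```

The ranked pairs are the model's candidate shortlist: `m023–d036` is the
unobserved pair the ensemble considers most likely to be a genuine
association. The LOOCV AUC of 0.89 says that a hidden true association
outranks a random unknown pair 89% of the time on this fixture; the
recall curve says half of the hidden positives surface within the top 50
of ~1,850 candidate pairs.

A thin CLI over the same functions ships in `inst/scripts/krrmda`
(subcommands `synth`, `similarity`, `predict`, `rank`, `loocv`).

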