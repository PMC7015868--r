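---
title: "Methods: ensemble kernel ridge regression for miRNA-disease association prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble kernel ridge regression for miRNA-disease association prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(krrmda)
```

## The problem

Experimentally validated miRNA-disease associations form a sparse bipartite
network: an $m \times n$ binary matrix $A$ over $m$ miRNAs and $n$
diseases, with $A_{ij} = 1$ when the association is supported by evidence.
Curated collections of this kind cover a few hundred entities per side and
on the order of ten known associations per disease, so most of the matrix
is unobserved rather than negative. The prediction task is to rank the
unobserved pairs so that true-but-unrecorded associations concentrate at
the top. The package implements a random-subspace ensemble of kernel ridge
regression (KRR) classifiers for this task, together with the similarity
construction it feeds on and the cross-validation protocols used to assess
it.

## Similarity construction

**Disease semantic similarity.** Diseases are organized in a MeSH-style
hierarchy; each disease $d$ is described by the DAG of its ancestors
$T(d)$. Two contribution models weight the terms of $T(d)$:

* *Model 1* assigns $C_d(d) = 1$ and, for an ancestor $t$,
  $C_d(t) = \Delta \cdot \max\{C_d(t') : t' \text{ child of } t \text{ in } T(d)\}$,
  so the weight decays by the factor $\Delta \in (0, 1)$ per generation
  along the most direct ancestry line. The hierarchy may be a
  polyhierarchy (multiple parents); the recursion is evaluated in reverse
  topological order and the max runs over all children inside $T(d)$,
  which is the only reading under which the recursion is well defined.
* *Model 2* weights a term by its specificity across the disease set:
  $C(t) = -\log(\mathrm{count}(t) / n)$, where $\mathrm{count}(t)$ is the
  number of disease DAGs containing $t$. The log base is a free choice
  (the defining formula only says "log"); the package uses the natural
  log by default and exposes `log_base`. Counts are taken over the
  diseases in the dataset at hand, since no larger vocabulary is
  available to the tool.

Either model yields the similarity
$$SS(d_i, d_j) = \frac{\sum_{t \in T(d_i) \cap T(d_j)} \big(C_i(t) + C_j(t)\big)}{DV_i + DV_j}, \qquad DV_i = \sum_{t \in T(d_i)} C_i(t),$$
which is symmetric, lies in $[0, 1]$ and has unit diagonal whenever
$DV > 0$. Under model 2 a disease whose every term occurs in all DAGs has
$DV = 0$; such pairs are defined to have similarity 0 (with a warning)
rather than 0/0.

**GIP kernel similarity.** The Gaussian interaction profile kernel treats
each entity's row (or column) of $A$ as a binary profile $IV$ and sets
$K(i, j) = \exp(-\beta \|IV_i - IV_j\|^2)$ with
$\beta = \beta' / \overline{\|IV\|^2}$. The base bandwidth $\beta'$
defaults to 1 on both sides, the customary choice for this construction.
An all-zero $A$ leaves the bandwidth undefined and is an error.

**Integration.** Disease similarity uses the mean $(SS1 + SS2)/2$ where a
pair has semantic similarity and the GIP value elsewhere; miRNA similarity
uses the (externally supplied) functional similarity $FS$ where available
and GIP elsewhere. What "has similarity" means is genuinely ambiguous for
pairwise data, so both readings are implemented: `sim_mask = "pairwise"`
(default) takes pairs whose primary similarity is positive, literally
following the pairwise phrasing of the combination rule; `"entity"` takes
pairs where both entities carry similarity information at all. Neither is
declared the intended one; the default is the literal reading.

## The predictor

Each base learner works on the integrated similarity rows as feature
vectors and runs four stages per side:

1. **Random subspace.** Sample $\lfloor r \cdot m \rfloor$ of the $m$
   miRNA features and $\lfloor r \cdot n \rfloor$ of the disease features,
   uniformly without replacement ($r = 0.2$ by default). The two sides
   draw independently; whether the draws should be coupled is not
   determined by the method's description, so independent draws are the
   default and `link_subsets` couples them.
2. **Truncated SVD.** Keep the top
   $k = \lfloor \text{trunc\_fraction} \cdot \text{(sampled)} \rfloor$
   singular values of the sampled feature matrix $F = U S V^\top$ and use
   $U S$ as reduced features. All sampled/reduced counts are clamped to at
   least 1 so degenerate inputs reduce gracefully instead of crashing.
   Singular-vector signs are fixed (largest-magnitude entry of each left
   vector made positive) so results do not depend on the LAPACK backend.
3. **Kernel.** Gaussian kernel
   $\exp(-\|x_i - x_j\|^2 / k)$ on the reduced features, i.e. the
   denominator $2\sigma^2$ equals the reduced feature count $k$;
   `bandwidth_override` substitutes an explicit $2\sigma^2$ for
   sensitivity sweeps. Polynomial alternatives $1 + x^\top y$ and
   $(1 + x^\top y)^2$ are available for comparison.
4. **KRR + propagation.** Closed-form scores $K (K + \lambda I)^{-1} A$
   in the miRNA space and $K (K + \lambda I)^{-1} A^\top$ in the disease
   space, with $\lambda = 1$ by default. Solves go through a linear
   solve, never an explicit inverse, and must meet the residual contract
   $\|(K + \lambda I) X - Y\|_F \le 10^{-8} \|Y\|_F$. An entity with no
   training association cannot be scored by KRR; its score column is
   replaced by the similarity-weighted average of the known entities'
   columns. Which entities are "new" is detected per call from the
   training matrix, so cross-validation folds trigger the propagation
   rule automatically.

The base score is the average of the two spaces,
$S = \tfrac12 S_M + \tfrac12 S_D^\top$, and the ensemble score is the
entrywise mean over $M$ base learners ($M = 100$ by default; the source
method does not state its ensemble size, so this default is flagged
prominently). Per-learner seeds are derived deterministically from the
master seed, which makes the ensemble mean exactly reproducible and
replayable learner by learner.

**Kronecker variant.** Instead of two per-space KRRs, one KRR on the
pairwise kernel $K((m_i, d_j), (m_k, d_l)) = KM(i, k) \, KD(j, l)$ solves
$\mathrm{vec}(S^\top) = K (K + \lambda I)^{-1} \mathrm{vec}(A^\top)$. The
$nm \times nm$ system is never formed: with eigendecompositions
$KM = V_m \Lambda_m V_m^\top$ and $KD = V_d \Lambda_d V_d^\top$,
$$\mathrm{vec}(Z) = (\Lambda_m \otimes \Lambda_d)(\Lambda_m \otimes \Lambda_d + \lambda I)^{-1} \mathrm{vec}(V_d^\top A^\top V_m), \qquad S = V_m Z^\top V_d^\top.$$
The eigendecomposition path is checked against the naive dense Kronecker
solve in the test suite. The description of this variant writes its ridge
parameter once as $\sigma$; it is treated as the same $\lambda$. The
variant runs under the same subsample/TSVD/ensemble framework as the main
model.

## Evaluation protocols

* **Global LOOCV**: each known association is hidden in turn and ranked
  against all pairs without association evidence in the original matrix.
* **Local LOOCV**: the hidden association is ranked only against the
  miRNAs unassociated with its disease.
* **Repeated 5-fold CV**: known associations are partitioned into five
  folds (sizes within 1); each fold is hidden together; one pooled AUC per
  repeat, summarized as mean ± sd.

In every protocol the GIP and integrated similarities are **rebuilt from
the masked matrix** inside each fold. The GIP kernel is a function of $A$;
computing it once from the full matrix would encode the held-out label in
the features. Whether the original study recomputed it is not stated; the
non-leaky variant is the defensible default, and `static_similarity =
TRUE` reproduces the leaky shortcut for comparison.

AUC is the Mann-Whitney statistic computed from per-sample ranks: a hidden
positive with mid-rank $r$ among $N$ candidates contributes
$(N + 1 - r)/N$, ties counting one half. Top-$k$ lists break score ties by
(miRNA index, disease index), so all rankings are deterministic. The rank
CDF (recall at $k$) and a bandwidth-sensitivity sweep
(`bandwidth_override` $= 2\sigma^2$) follow directly. At the documented
operating point (495 miRNAs, 383 diseases, $r = 0.2$, truncation 0.2) the
pipeline dimensions are $99 \to 19$ miRNA features and $76 \to 15$ disease
features, giving default bandwidths $\sigma \approx 3.1$ and $2.7$.

Case studies rank candidate miRNAs for one disease; in *new disease* mode
every known association of that disease is masked before training, its
scores then come entirely from the propagation rule, and **all** miRNAs
are candidates — so previously known (now hidden) associations can be
recovered and counted, which is how such case studies are validated. The
robustness experiment removes a random 20% of all known associations
(10 repeats by default), re-ranks, and reports how much of the unperturbed
top-$k$ list survives, against the chance baseline $k^2/\text{candidates}$.
The candidate pool is held fixed at the unperturbed one so lists are
comparable across repeats.

## The synthetic generator

Downloading the curated association database, MeSH and the functional
similarity matrix is out of scope, so the package generates fixtures with
the statistical structure the method assumes:

* a layered random DAG forest in which diseases share ancestors by
  construction (`dag_depth = 1` degenerates to isolated roots);
* nonnegative latent factors $P$ ($m \times$ rank) and $Q$
  ($n \times$ rank), with each disease's factor built from its DAG
  ancestors' latent vectors plus noise — so semantically similar diseases
  associate with similar miRNAs, the assumption the predictor exploits;
* $A_{ij} \sim \text{Bernoulli}(\mathrm{plogis}(a + 2 z_{ij}))$ with
  $z$ the standardized $\langle P_i, Q_j \rangle$ and the intercept $a$
  solved numerically for the target density (default 0.07 at
  $50 \times 40$, a few positives per disease, emulating the sparsity of
  the real collection); the slope 2 fixes a clearly recoverable but not
  deterministic planted signal;
* functional similarity = cosine similarity of the miRNA factors;
* optional label-flip noise (default 0: curated associations are treated
  as ground truth; noise is the explicit degradation dial);
* full coverage: an empty row or column receives its highest-probability
  planted pair. Pair-list datasets have no zero-degree entities — an
  entity exists because it appears in a pair — and coverage is also what
  lets generator output round-trip through the pair-list reader.

What the fixture does **not** emulate: the heavy-tailed degree
distribution of real collections, sparse/missing functional-similarity
coverage (the synthetic $FS$ is dense and positive, so with the pairwise
mask the miRNA side rarely falls back to GIP), MeSH-scale vocabularies,
and biased evidence collection. Passing tests on the fixture therefore
demonstrate correct mechanics and recoverable planted structure, not
performance on real data.

## Problem sizes and numerical choices

Tests and the acceptance script run the full LOOCV stack on the default
$50 \times 40$ rank-3 fixture (about 170 positives, so one LOOCV sweep is
~170 retrains of the whole pipeline including similarity rebuilds), with
$M = 100$ learners for headline numbers and $M \le 10$ in unit tests;
these sizes keep a complete run in minutes on one CPU while leaving the
ensemble averaging visibly converged. Paper-scale runs
($495 \times 383$, thousands of retrains) use the identical code path and
are a cluster-scale undertaking, documented but not executed in tests.

One scale effect deserves note: at $50 \times 40$ with $r =
\text{trunc\_fraction} = 0.2$ the truncation stage operates at its clamp
floor ($10 \to 2$ miRNA features, $8 \to 1$ disease features), which
discards nearly all feature variance per learner. In this regime the
dimensionality-reduction step can cost a little accuracy relative to a
single KRR on raw features, whereas the random-subspace ensembling itself
remains beneficial; at the documented operating point ($99 \to 19$,
$76 \to 15$) the truncation has room to denoise instead. The acceptance
script reports both the ensemble and the raw-feature single-KRR baseline
so this can be inspected directly.

Other numerical choices: linear solves are required to meet the residual
contract rather than prescribing a factorization; Gaussian kernels are
symmetrized after construction to remove floating-point asymmetry;
eigendecompositions used in the Kronecker path must reconstruct their
kernel to $10^{-6}$ relative Frobenius error; a zero similarity-mass
entity in the propagation rule receives score 0 with a warning; all
randomness flows from one master seed through derived sub-seeds, so any
single base learner can be replayed in isolation.

## Known limitations

* Ranks from LOOCV folds are pooled into one AUC; diseases with many
  associations weigh more in the global figure.
* The per-disease DAG-count table for model 2 is computed from the input
  disease set, so adding diseases changes model-2 similarities.
* The ensemble size default ($M = 100$) is a package choice, not a value
  fixed by the method's description.
* `ekkrr_predict` does not apply the new-entity propagation rule (the
  two-space formulation defines it; the Kronecker formulation does not);
  entities with empty profiles receive near-zero scores from the kernel
  itself.
* Dense linear algebra throughout: fine to a few thousand entities per
  side, no sparse path.
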