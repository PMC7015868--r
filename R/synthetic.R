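#' Specification of a synthetic benchmark fixture
#'
#' Parameters of the generator that emulates the inputs the predictor
#' expects: a MeSH-style disease DAG forest, a planted low-rank association
#' matrix and a miRNA functional similarity derived from the same latent
#' factors.
#'
#' @param m number of miRNAs.
#' @param n number of diseases.
#' @param latent_rank number of latent factors generating associations.
#' @param density expected fraction of positive associations, in (0, 1).
#' @param dag_depth depth of the disease hierarchy (1 = all diseases are
#'   roots, no shared ancestry).
#' @param branching mean branching factor of the hierarchy.
#' @param noise label-flip probability in `[0, 0.5)`; 0 keeps the planted
#'   associations exact.
#' @param seed integer seed; the whole fixture is a deterministic function
#'   of the spec.
#' @return a validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(m = 50, n = 40, latent_rank = 3, density = 0.07,
                           dag_depth = 3, branching = 2, noise = 0,
                           seed = 1L) {
  if (density <= 0 || density >= 1) stopf("density must lie in (0, 1)")
  if (latent_rank < 1) stopf("latent_rank must be >= 1")
  if (noise < 0 || noise >= 0.5) stopf("noise must lie in [0, 0.5)")
  if (dag_depth < 1) stopf("dag_depth must be >= 1")
  structure(list(m = as.integer(m), n = as.integer(n),
                 latent_rank = as.integer(latent_rank), density = density,
                 dag_depth = as.integer(dag_depth), branching = branching,
                 noise = noise, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a random disease DAG forest
#'
#' Builds a layered hierarchy of internal terms (roots at the top, each
#' deeper term attached to one or occasionally two parents) and attaches
#' each disease to the deepest internal layer, so that nearby diseases
#' share ancestors by construction. With `dag_depth = 1` all diseases are
#' isolated roots.
#'
#' @param spec a [synthetic_spec()].
#' @return a [dag_forest()] over diseases `d001 ... d<n>`.
#' @export
generate_dag_forest <- function(spec) {
  ids <- sprintf("d%03d", seq_len(spec$n))
  if (spec$dag_depth == 1) return(dag_forest(ids, matrix(character(0), 0, 2)))
  with_seed(derive_seeds(spec$seed, 2)[1], {
    depth <- spec$dag_depth
    n_roots <- max(2L, ceiling(spec$n / spec$branching^(depth - 1)))
    layers <- vector("list", depth - 1)
    edges <- NULL
    for (l in seq_len(depth - 1)) {
      size <- min(spec$n, ceiling(n_roots * spec$branching^(l - 1)))
      layers[[l]] <- sprintf("T%d_%02d", l, seq_len(size))
      if (l > 1) {
        parents <- sample(layers[[l - 1]], size, replace = TRUE)
        edges <- rbind(edges, cbind(layers[[l]], parents))
        extra <- which(stats::runif(size) < 0.2)
        if (length(extra))
          edges <- rbind(edges, cbind(layers[[l]][extra],
                                      sample(layers[[l - 1]], length(extra),
                                             replace = TRUE)))
      }
    }
    leaf_layer <- layers[[depth - 1]]
    parents <- sample(leaf_layer, spec$n, replace = TRUE)
    edges <- rbind(edges, cbind(ids, parents))
    extra <- which(stats::runif(spec$n) < 0.2)
    if (length(extra))
      edges <- rbind(edges, cbind(ids[extra],
                                  sample(leaf_layer, length(extra),
                                         replace = TRUE)))
    dag_forest(ids, unique(edges))
  })
}

#' Generate a planted low-rank association dataset
#'
#' Draws nonnegative latent factors `P` (miRNAs x rank) and `Q` (diseases x
#' rank) and sets `A[i, j] = 1` with probability
#' `plogis(a + z(<P_i, Q_j>))`, where the intercept `a` is solved
#' numerically so the expected density matches the target; labels are then
#' flipped with probability `noise`. When a forest is supplied, each DAG
#' node carries its own latent vector and a disease's factor is the mean
#' over its ancestor closure plus independent noise, so diseases sharing
#' ancestors associate with similar miRNAs - the assumption the predictor
#' relies on. The functional similarity is the cosine similarity of the
#' miRNA factors, hence functionally similar miRNAs relate to similar
#' diseases by construction.
#'
#' Every miRNA and every disease is guaranteed at least one association:
#' an empty row or column receives its highest-probability planted pair.
#' Datasets read from association pair lists have this property by
#' construction (an entity exists only because it appears in a pair), and
#' it is what makes the generator's output round-trip through
#' [write_associations()] / [read_associations()] unchanged.
#'
#' A degenerate draw (all-zero or all-one matrix) is resampled with a
#' warning, at most 10 attempts.
#'
#' @param spec a [synthetic_spec()].
#' @param forest optional [dag_forest()] whose diseases the factors follow.
#' @return list with `dataset` (an [association_dataset()]) and `fs`
#'   (labeled functional similarity matrix).
#' @export
generate_dataset <- function(spec, forest = NULL) {
  mirna_ids <- sprintf("m%03d", seq_len(spec$m))
  disease_ids <- if (is.null(forest)) sprintf("d%03d", seq_len(spec$n))
                 else forest$disease_ids
  with_seed(derive_seeds(spec$seed, 2)[2], {
    for (attempt in 1:10) {
      P <- matrix(abs(stats::rnorm(spec$m * spec$latent_rank)), spec$m)
      Q <- if (is.null(forest)) {
        matrix(abs(stats::rnorm(spec$n * spec$latent_rank)), spec$n)
      } else {
        node_latent <- matrix(abs(stats::rnorm(length(forest$nodes) *
                                                 spec$latent_rank)),
                              length(forest$nodes),
                              dimnames = list(forest$nodes, NULL))
        t(vapply(disease_ids, function(d) {
          anc <- dag_ancestors(forest, d)
          colMeans(node_latent[anc, , drop = FALSE]) +
            0.5 * abs(stats::rnorm(spec$latent_rank))
        }, numeric(spec$latent_rank)))
      }
      eta <- tcrossprod(P, Q)
      z <- (eta - mean(eta)) / stats::sd(eta)
      intercept <- stats::uniroot(
        function(a) mean(stats::plogis(a + 2 * z)) - spec$density,
        lower = -50, upper = 50)$root
      prob <- stats::plogis(intercept + 2 * z)
      A <- matrix(stats::rbinom(length(prob), 1, prob), spec$m)
      if (spec$noise > 0) {
        flip <- matrix(stats::rbinom(length(A), 1, spec$noise), spec$m)
        A <- abs(A - flip)
      }
      # pair-list datasets have no zero-degree entity; plant the most
      # probable association for any empty row/column
      for (i in which(rowSums(A) == 0)) A[i, which.max(prob[i, ])] <- 1
      for (j in which(colSums(A) == 0)) A[which.max(prob[, j]), j] <- 1
      if (sum(A) > 0 && sum(A) < length(A)) break
      if (attempt == 10) stopf("could not generate a non-degenerate matrix")
      warning("degenerate association draw; resampling")
    }
    pn <- P / sqrt(rowSums(P^2))
    fs <- tcrossprod(pn)
    fs[fs < 0] <- 0
    fs[fs > 1] <- 1
    diag(fs) <- 1
    dimnames(fs) <- list(mirna_ids, mirna_ids)
    dimnames(A) <- list(mirna_ids, disease_ids)
    list(dataset = association_dataset(mirna_ids, disease_ids, A), fs = fs)
  })
}

#' Generate a complete synthetic fixture
#'
#' Forest, association dataset and functional similarity in one call, all
#' deterministic functions of the spec.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `dataset`, `fs` and `forest`.
#' @export
generate_fixture <- function(spec = synthetic_spec()) {
  forest <- generate_dag_forest(spec)
  out <- generate_dataset(spec, forest)
  out$forest <- forest
  out
}
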