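#' Construct an association dataset
#'
#' Bundles the ordered miRNA and disease identifier lists with the binary
#' adjacency matrix `A` (rows = miRNAs, columns = diseases, `A[i, j] = 1`
#' iff the association is known).
#'
#' @param mirna_ids character vector of unique miRNA identifiers.
#' @param disease_ids character vector of unique disease identifiers.
#' @param A binary matrix with `length(mirna_ids)` rows and
#'   `length(disease_ids)` columns.
#' @return an object of class `assoc_dataset` with elements `mirna_ids`,
#'   `disease_ids` and `A` (with dimnames set from the id lists).
#' @export
association_dataset <- function(mirna_ids, disease_ids, A) {
  mirna_ids <- as.character(mirna_ids)
  disease_ids <- as.character(disease_ids)
  if (anyDuplicated(mirna_ids)) stopf("duplicate miRNA ids")
  if (anyDuplicated(disease_ids)) stopf("duplicate disease ids")
  A <- as.matrix(A)
  if (nrow(A) != length(mirna_ids) || ncol(A) != length(disease_ids))
    stopf("adjacency matrix is %dx%d but there are %d miRNAs and %d diseases",
          nrow(A), ncol(A), length(mirna_ids), length(disease_ids))
  if (!all(A %in% c(0, 1))) stopf("adjacency matrix must be binary")
  storage.mode(A) <- "double"
  dimnames(A) <- list(mirna_ids, disease_ids)
  structure(list(mirna_ids = mirna_ids, disease_ids = disease_ids, A = A),
            class = "assoc_dataset")
}

#' @export
print.assoc_dataset <- function(x, ...) {
  cat(sprintf("<assoc_dataset> %d miRNAs x %d diseases, %d known associations\n",
              length(x$mirna_ids), length(x$disease_ids), sum(x$A)))
  invisible(x)
}

#' Read known associations from a two-column TSV pair list
#'
#' Each line holds at least two tab-separated fields: a miRNA id and a
#' disease id. Duplicate pairs collapse to a single entry. Entities are
#' ordered by first appearance, making the resulting matrix layout
#' deterministic without any sorting assumption.
#'
#' @param path path to the TSV file (no header, UTF-8).
#' @return an [association_dataset()].
#' @export
read_associations <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stopf("no associations in '%s'", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, function(p) length(p) < 2 ||
                        !nzchar(p[1]) || !nzchar(p[2]), logical(1)))
  if (length(bad))
    stopf("malformed association line %d in '%s'", bad[1], path)
  mir <- vapply(parts, `[`, character(1), 1)
  dis <- vapply(parts, `[`, character(1), 2)
  mirna_ids <- unique(mir)
  disease_ids <- unique(dis)
  A <- matrix(0, length(mirna_ids), length(disease_ids),
              dimnames = list(mirna_ids, disease_ids))
  A[cbind(match(mir, mirna_ids), match(dis, disease_ids))] <- 1
  association_dataset(mirna_ids, disease_ids, A)
}

#' Write an association dataset as a TSV pair list
#'
#' Pairs are emitted row-major (miRNA order, then disease order), one known
#' association per line, so that [read_associations()] reproduces the same
#' entity ordering.
#'
#' @param dataset an [association_dataset()].
#' @param path output path.
#' @export
write_associations <- function(dataset, path) {
  idx <- which(t(dataset$A) == 1, arr.ind = TRUE)
  # t() so pairs come out in miRNA-major order
  lines <- paste(dataset$mirna_ids[idx[, 2]], dataset$disease_ids[idx[, 1]],
                 sep = "\t")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a labeled dense matrix from TSV
#'
#' Expected layout: first row = column ids (optionally preceded by an empty
#' cell), first column = row ids, numeric body. This is the on-disk form of
#' every similarity, kernel and score matrix the package handles.
#'
#' @param path path to the TSV file.
#' @return a numeric matrix with row and column names.
#' @export
read_labeled_matrix <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stopf("labeled matrix file '%s' has no body", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  header <- parts[[1]]
  body <- parts[-1]
  widths <- lengths(body)
  if (length(unique(widths)) != 1)
    stopf("ragged rows in '%s': line %d has %d fields, line 2 has %d",
          path, which(widths != widths[1])[1] + 1,
          widths[widths != widths[1]][1], widths[1])
  ncol_body <- widths[1] - 1L
  if (length(header) == ncol_body + 1L) header <- header[-1]
  if (length(header) != ncol_body)
    stopf("column count mismatch in '%s': %d column ids, %d value columns",
          path, length(header), ncol_body)
  row_ids <- vapply(body, `[`, character(1), 1)
  vals <- suppressWarnings(
    vapply(body, function(p) as.numeric(p[-1]), numeric(ncol_body)))
  vals <- if (ncol_body == 1) matrix(vals, nrow = length(body))
          else t(vals)
  if (anyNA(vals)) {
    at <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stopf("non-numeric cell in '%s' at row %d ('%s'), column %d ('%s')",
          path, at[1], row_ids[at[1]], at[2], header[at[2]])
  }
  dimnames(vals) <- list(row_ids, header)
  vals
}

#' Write a labeled matrix as TSV
#'
#' Values are written as decimal text with 15 significant digits so that a
#' write/read round trip is stable to well below 1e-12.
#'
#' @param mat numeric matrix with row and column names.
#' @param path output path.
#' @export
write_labeled_matrix <- function(mat, path) {
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stopf("matrix must carry row and column names")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("", colnames(mat)), collapse = "\t"), con)
  body <- apply(mat, 1, function(r)
    paste(sprintf("%.15g", r), collapse = "\t"))
  writeLines(paste(rownames(mat), body, sep = "\t"), con)
  invisible(path)
}

#' Construct a disease DAG forest
#'
#' Holds the child-to-parent edge set of the disease hierarchy (MeSH-style)
#' together with the list of diseases of interest. Nodes with no parent are
#' roots. Multiple parents per node are allowed (polyhierarchy); the graph
#' must be acyclic.
#'
#' @param disease_ids character vector of disease identifiers; each is a
#'   node of the forest (possibly isolated).
#' @param edges two-column character matrix or data frame of
#'   (child, parent) edges; may have zero rows.
#' @return an object of class `dag_forest` with elements `disease_ids`,
#'   `edges` (character matrix with columns child/parent) and `nodes`.
#' @export
dag_forest <- function(disease_ids, edges) {
  disease_ids <- as.character(disease_ids)
  if (anyDuplicated(disease_ids)) stopf("duplicate disease ids")
  edges <- as.matrix(edges)
  if (length(edges) == 0) {
    edges <- matrix(character(0), 0, 2)
  } else if (ncol(edges) != 2) {
    stopf("edges must have two columns (child, parent)")
  }
  storage.mode(edges) <- "character"
  colnames(edges) <- c("child", "parent")
  edges <- unique(edges)
  nodes <- unique(c(disease_ids, as.vector(edges)))
  cyc <- find_cycle(edges, nodes)
  if (!is.null(cyc))
    stopf("disease hierarchy contains a cycle: %s", paste(cyc, collapse = " -> "))
  structure(list(disease_ids = disease_ids, edges = edges, nodes = nodes),
            class = "dag_forest")
}

#' @export
print.dag_forest <- function(x, ...) {
  cat(sprintf("<dag_forest> %d diseases, %d nodes, %d edges\n",
              length(x$disease_ids), length(x$nodes), nrow(x$edges)))
  invisible(x)
}

# Kahn's algorithm on child->parent edges; returns NULL if acyclic,
# otherwise one cycle as a node sequence.
find_cycle <- function(edges, nodes) {
  if (nrow(edges) == 0) return(NULL)
  adj <- split(edges[, "parent"], edges[, "child"])
  indeg <- table(factor(edges[, "parent"], levels = nodes))
  indeg <- stats::setNames(as.integer(indeg), nodes)
  queue <- nodes[indeg == 0]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]; seen <- seen + 1L
    for (p in adj[[v]] %||% character(0)) {
      indeg[p] <- indeg[p] - 1L
      if (indeg[p] == 0L) queue <- c(queue, p)
    }
  }
  if (seen == length(nodes)) return(NULL)
  # walk forward from any node left in the cyclic core until a repeat
  core <- names(indeg)[indeg > 0]
  v <- core[1]; path <- v
  repeat {
    nxt <- intersect(adj[[v]] %||% character(0), core)[1]
    if (nxt %in% path)
      return(c(path[which(path == nxt):length(path)], nxt))
    path <- c(path, nxt); v <- nxt
  }
}

#' Ancestor closure of a disease in a DAG forest
#'
#' Returns the node set `T(d)`: the disease itself plus every node reachable
#' by following child-to-parent edges.
#'
#' @param forest a [dag_forest()].
#' @param disease a node identifier present in the forest.
#' @return character vector of node ids, starting with `disease`.
#' @export
dag_ancestors <- function(forest, disease) {
  if (!disease %in% forest$nodes)
    stopf("unknown node '%s'", disease)
  adj <- split(forest$edges[, "parent"], forest$edges[, "child"])
  closure <- character(0)
  frontier <- disease
  while (length(frontier)) {
    closure <- c(closure, frontier)
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    frontier <- setdiff(nxt, closure)
  }
  closure
}

#' Read a DAG forest from TSV
#'
#' Format: tab-separated (child, parent) edge lines, followed by a
#' `#DISEASES` marker line and one disease id per line. The graph is
#' validated to be acyclic on read.
#'
#' @param path path to the forest file.
#' @return a [dag_forest()].
#' @export
read_dag_forest <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  marker <- which(lines == "#DISEASES")
  if (length(marker) != 1)
    stopf("forest file '%s' must contain exactly one #DISEASES block", path)
  edge_lines <- lines[seq_len(marker - 1)]
  disease_ids <- trimws(lines[seq(marker + 1, length.out = length(lines) - marker)])
  if (length(disease_ids) == 0) stopf("empty #DISEASES block in '%s'", path)
  if (length(edge_lines)) {
    parts <- strsplit(edge_lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 2)
    if (length(bad)) stopf("malformed edge line %d in '%s'", bad[1], path)
    edges <- cbind(vapply(parts, `[`, character(1), 1),
                   vapply(parts, `[`, character(1), 2))
  } else {
    edges <- matrix(character(0), 0, 2)
  }
  dag_forest(disease_ids, edges)
}

#' Write a DAG forest as TSV
#'
#' @param forest a [dag_forest()].
#' @param path output path.
#' @export
write_dag_forest <- function(forest, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (nrow(forest$edges))
    writeLines(paste(forest$edges[, "child"], forest$edges[, "parent"],
                     sep = "\t"), con)
  writeLines(c("#DISEASES", forest$disease_ids), con)
  invisible(path)
}

#' Read run configuration from a flat key-value file
#'
#' Lines of the form `key = value` (or `key<TAB>value`); keys match the
#' arguments of [ekrr_config()]. Unknown keys raise an error. Blank lines
#' and lines starting with `#` are ignored.
#'
#' @param path path to the config file.
#' @param ... overrides applied on top of the file values (e.g. from CLI
#'   flags).
#' @return an [ekrr_config()].
#' @export
read_config <- function(path, ...) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)[ \t=:]+(.*)$", lines))
  bad <- which(lengths(kv) != 3)
  if (length(bad)) stopf("malformed config line: '%s'", lines[bad[1]])
  vals <- stats::setNames(lapply(kv, `[`, 3), vapply(kv, `[`, character(1), 2))
  known <- names(formals(ekrr_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stopf("unknown config key '%s'", unknown[1])
  coerce <- function(key, v) {
    switch(key,
           kernel = , sim_mask = as.character(v),
           use_subsampling = , use_tsvd = , link_subsets = as.logical(v),
           M = , seed = as.integer(v),
           as.numeric(v))
  }
  vals <- Map(coerce, names(vals), vals)
  vals[names(list(...))] <- list(...)
  do.call(ekrr_config, vals)
}
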