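#' Binary incidence matrices over model features
#'
#' Model scope is compared by binary vectors: a 1 whenever a feature (an
#' ORF, or a ChEBI metabolite identifier) is present in a model. Rows are
#' models, columns the sorted union of features across models.
#'
#' For metabolites, features are ChEBI identifiers; a metabolite annotated
#' with several ChEBI ids (database redundancy) contributes only its FIRST
#' id, and metabolites without any ChEBI annotation are excluded — this
#' comparison is by necessity less comprehensive than genomic coverage. A
#' model contributing no annotated metabolites yields an all-zero row and
#' a warning.
#'
#' @param models list of `metabolic_model` objects (at least 2 for
#'   [gene_incidence()]).
#' @return an `incidence_matrix`: binary matrix with model ids as rownames
#'   and feature ids as colnames.
#' @export
gene_incidence <- function(models) {
  stopifnot(length(models) >= 2L)
  feats <- sort(unique(unlist(lapply(models, `[[`, "genes"))))
  build_incidence(models, feats, function(m) m$genes)
}

#' @rdname gene_incidence
#' @export
metabolite_incidence <- function(models) {
  first_chebi <- function(m) {
    ids <- vapply(m$metabolites$chebi, function(ch) {
      if (length(ch)) ch[[1]] else NA_character_
    }, character(1))
    unique(ids[!is.na(ids)])
  }
  per_model <- lapply(models, first_chebi)
  empty <- vapply(per_model, length, integer(1)) == 0L
  if (any(empty)) {
    warning("model(s) with no ChEBI annotation: ",
            paste(vapply(models[empty], `[[`, character(1), "model_id"),
                  collapse = ", "))
  }
  feats <- sort(unique(unlist(per_model)))
  build_incidence(models, feats, first_chebi)
}

build_incidence <- function(models, feats, getter) {
  ids <- vapply(models, `[[`, character(1), "model_id")
  mat <- matrix(0L, length(models), length(feats),
                dimnames = list(ids, feats))
  for (i in seq_along(models)) {
    mat[i, feats %in% getter(models[[i]])] <- 1L
  }
  class(mat) <- c("incidence_matrix", class(mat))
  mat
}

#' Row-aligned comparative feature table
#'
#' The long/tabular form of an incidence matrix: one row per feature,
#' one 0/1 column per model — suitable for export as a comparative table.
#' @param m an `incidence_matrix`.
#' @return a tibble with column `feature` followed by one column per model.
#' @export
incidence_table <- function(m) {
  out <- tibble::as_tibble(t(unclass(m)))
  dplyr::bind_cols(tibble::tibble(feature = colnames(m)), out)
}

#' Pairwise distances between model incidence rows
#'
#' @param m an `incidence_matrix` (rows = models).
#' @param metric `"euclidean"` (default), `"hamming"` (number of differing
#'   features) or `"jaccard"` (1 - intersection/union over present
#'   features).
#' @return a symmetric `dist`-compatible matrix with zero diagonal.
#' @export
pairwise_distance <- function(m, metric = c("euclidean", "hamming", "jaccard")) {
  metric <- match.arg(metric)
  x <- unclass(m)
  d <- switch(metric,
    euclidean = as.matrix(stats::dist(x, method = "euclidean")),
    hamming = as.matrix(stats::dist(x, method = "manhattan")),
    jaccard = as.matrix(stats::dist(x, method = "binary"))
  )
  diag(d) <- 0
  d
}

#' Hierarchical clustering of models
#'
#' Average linkage by default (single and complete available); returns the
#' `hclust` merge tree, whose heights are non-decreasing, so cutting at a
#' given k yields a model partition via [stats::cutree()].
#'
#' @param d symmetric distance matrix (e.g. from [pairwise_distance()]).
#' @param linkage `"average"` (default), `"single"` or `"complete"`.
#' @return an object of class `hclust`.
#' @export
hierarchical_cluster <- function(d, linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  stats::hclust(stats::as.dist(d), method = linkage)
}

#' Export a dendrogram as a Newick string
#' @param hc an `hclust` tree.
#' @param path optional file to write to.
#' @return the Newick string, invisibly when writing to a file.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Classical multidimensional scaling of model distances
#'
#' Double-centered Gram eigen-decomposition (Torgerson scaling) of a
#' distance matrix, giving one coordinate row per model ordered by
#' eigenvalue. When fewer than `k` positive eigenvalues exist the returned
#' dimensionality is reduced with a warning; negative eigenvalues (non-
#' Euclidean input) are truncated, also with a warning.
#'
#' @param d symmetric distance matrix.
#' @param k target number of dimensions (>= 1).
#' @return tibble with `model_id` and coordinate columns `dim1..dimk`;
#'   attribute `"eigenvalues"` carries the full eigenvalue spectrum.
#' @export
classical_mds <- function(d, k = 2) {
  stopifnot(k >= 1)
  n <- nrow(d)
  # cmdscale warns about non-positive eigenvalues on its own; this function
  # re-reports both degeneracies with more specific messages below
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(d), k = min(k, n - 1), eig = TRUE))
  eig <- fit$eig
  if (any(eig < -1e-8 * max(abs(eig)))) {
    warning("distance matrix is not Euclidean-embeddable; ",
            "negative eigenvalues truncated")
  }
  pts <- fit$points
  if (ncol(pts) < k) {
    warning("only ", ncol(pts), " positive-eigenvalue dimensions available; ",
            "returning ", ncol(pts), " instead of ", k)
  }
  out <- tibble::tibble(model_id = rownames(d))
  for (j in seq_len(ncol(pts))) out[[paste0("dim", j)]] <- pts[, j]
  attr(out, "eigenvalues") <- eig
  out
}
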