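#' Construct a genome-scale metabolic model object
#'
#' The central data structure of the package: a stoichiometric network with
#' flux bounds, boolean gene-protein-reaction (GPR) rules and a biomass
#' objective. All screens, variability analyses and growth scans operate on
#' this object. Boundary metabolites (flagged explicitly or via the
#' COBRA-style `"_b"` id suffix) are excluded from the steady-state
#' constraint \eqn{S v = 0}.
#'
#' Exchange status is always recomputed, never trusted from input: a
#' reaction is an exchange if it touches exactly one non-boundary
#' metabolite, or if its id starts with `"EX_"` or `"R_EX_"`.
#'
#' @param model_id character scalar naming the model.
#' @param metabolites tibble with columns `id`, `name`, `compartment`,
#'   `chebi` (list-column of character vectors, possibly empty) and
#'   `boundary` (logical). Missing optional columns are filled.
#' @param reactions tibble with columns `id`, `name`, `lb`, `ub`, `stoich`
#'   (list-column of named numeric vectors; negative = consumed) and
#'   `gpr` (character GPR strings, `NA` for none).
#' @param objective id of the objective (biomass) reaction.
#' @param genes optional character vector of gene (ORF) identifiers; when
#'   `NULL`, the union of genes appearing in GPRs is used. Gene ids are
#'   opaque, case-sensitive strings; no nomenclature translation happens.
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(model_id, metabolites, reactions, objective,
                            genes = NULL) {
  metabolites <- tibble::as_tibble(metabolites)
  reactions <- tibble::as_tibble(reactions)
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"compartment" %in% names(metabolites)) metabolites$compartment <- "c"
  if (!"chebi" %in% names(metabolites)) metabolites$chebi <- list(character())
  if (!"boundary" %in% names(metabolites)) metabolites$boundary <- FALSE
  metabolites$boundary <- metabolites$boundary | grepl("_b$", metabolites$id)
  metabolites$chebi <- lapply(metabolites$chebi, as.character)
  if (!"name" %in% names(reactions)) reactions$name <- reactions$id
  if (!"gpr" %in% names(reactions)) reactions$gpr <- NA_character_

  if (anyDuplicated(metabolites$id)) {
    stop("duplicate metabolite ids: ",
         paste(unique(metabolites$id[duplicated(metabolites$id)]), collapse = ", "))
  }
  if (anyDuplicated(reactions$id)) {
    stop("duplicate reaction ids: ",
         paste(unique(reactions$id[duplicated(reactions$id)]), collapse = ", "))
  }
  all_refs <- unique(unlist(lapply(reactions$stoich, names)))
  dangling <- setdiff(all_refs, metabolites$id)
  if (length(dangling)) {
    stop("reactions reference unknown metabolites: ",
         paste(dangling, collapse = ", "))
  }
  if (any(reactions$lb > reactions$ub)) {
    bad <- reactions$id[reactions$lb > reactions$ub]
    stop("lower bound exceeds upper bound for: ", paste(bad, collapse = ", "))
  }
  if (!objective %in% reactions$id) {
    stop("objective reaction '", objective, "' not found in model")
  }

  gpr_trees <- lapply(reactions$gpr, function(g) {
    if (is.na(g) || !nzchar(trimws(g))) NULL else parse_gpr(g)
  })
  gpr_genes <- unique(unlist(lapply(gpr_trees, gpr_genes)))
  genes <- sort(unique(c(as.character(genes %||% character()), gpr_genes)))
  reactions$gpr <- vapply(gpr_trees, function(t) {
    if (is.null(t)) NA_character_ else format(t)
  }, character(1))

  boundary_ids <- metabolites$id[metabolites$boundary]
  # the objective (biomass) drain is never an exchange, even in toy models
  # where it happens to touch a single precursor
  reactions$exchange <- purrr::map2_lgl(reactions$stoich, reactions$id, function(s, id) {
    if (id == objective) return(FALSE)
    n_internal <- sum(!names(s) %in% boundary_ids)
    n_internal == 1L || grepl("^(R_)?EX_", id)
  })

  structure(list(
    model_id = model_id,
    genes = genes,
    metabolites = metabolites[, c("id", "name", "compartment", "chebi", "boundary")],
    reactions = reactions[, c("id", "name", "lb", "ub", "stoich", "gpr", "exchange")],
    objective = objective
  ), class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$model_id, "\n", sep = "")
  cat("  genes:       ", length(x$genes), "\n")
  cat("  metabolites: ", nrow(x$metabolites),
      " (", sum(x$metabolites$boundary), " boundary)\n", sep = "")
  cat("  reactions:   ", nrow(x$reactions),
      " (", sum(x$reactions$exchange), " exchange)\n", sep = "")
  cat("  objective:   ", x$objective, "\n", sep = "")
  invisible(x)
}

#' Stoichiometric matrix of a model
#'
#' @param model a `metabolic_model`.
#' @param drop_boundary drop rows for boundary metabolites (default), i.e.
#'   the rows actually used in the steady-state constraint.
#' @return numeric matrix, rows = metabolites, columns = reactions.
#' @export
stoich_matrix <- function(model, drop_boundary = TRUE) {
  mets <- model$metabolites
  if (drop_boundary) mets <- mets[!mets$boundary, , drop = FALSE]
  S <- matrix(0, nrow(mets), nrow(model$reactions),
              dimnames = list(mets$id, model$reactions$id))
  for (j in seq_len(nrow(model$reactions))) {
    s <- model$reactions$stoich[[j]]
    keep <- names(s) %in% mets$id
    if (any(keep)) S[names(s)[keep], j] <- s[keep]
  }
  S
}

#' Test two models for field-exact equality
#' @param a,b `metabolic_model` objects.
#' @return logical scalar.
#' @export
model_equal <- function(a, b) {
  norm <- function(m) {
    m$reactions$stoich <- lapply(m$reactions$stoich, function(s) s[order(names(s))])
    m$metabolites <- m$metabolites[order(m$metabolites$id), ]
    m$reactions <- m$reactions[order(m$reactions$id), ]
    m$metabolites$chebi <- lapply(m$metabolites$chebi, as.character)
    m
  }
  isTRUE(all.equal(norm(a), norm(b), check.attributes = FALSE))
}

#' Replace the bounds of one reaction
#' @param model a `metabolic_model`.
#' @param reaction_id reaction to modify.
#' @param lb,ub new bounds; `NULL` leaves a bound unchanged.
#' @return modified copy of the model.
#' @export
set_bounds <- function(model, reaction_id, lb = NULL, ub = NULL) {
  i <- match(reaction_id, model$reactions$id)
  if (is.na(i)) stop("unknown reaction: ", reaction_id)
  if (!is.null(lb)) model$reactions$lb[i] <- lb
  if (!is.null(ub)) model$reactions$ub[i] <- ub
  model
}

#' Summary statistics of a metabolic model
#'
#' Computes the per-model descriptive statistics used when tabulating a
#' collection of models: gene counts (with the number of genes flagged as
#' "dubious" ORFs against a supplied list), metabolite and dead-end counts,
#' reaction and gene-associated-reaction counts, and blocked-reaction counts
#' under the model's own biomass and optionally under a common biomass
#' definition. Blocked counts are evaluated with all exchange reactions
#' opened (see [blocked_reactions()]).
#'
#' @param model a `metabolic_model`.
#' @param dubious_orfs character vector of ORFs annotated as dubious
#'   (default empty).
#' @param common_biomass optional [biomass_definition()]; when it cannot be
#'   applied to the model (missing precursors) the corresponding blocked
#'   count is reported as `NA`, not zero.
#' @return one-row tibble of counts.
#' @export
summarize_model <- function(model, dubious_orfs = character(),
                            common_biomass = NULL) {
  internal <- model$metabolites[!model$metabolites$boundary, ]
  dead <- dead_end_metabolites(model)
  has_gpr <- !is.na(model$reactions$gpr)
  blocked_default <- length(blocked_reactions(model))
  blocked_common <- NA_integer_
  if (!is.null(common_biomass)) {
    m2 <- tryCatch(set_biomass(model, common_biomass), error = function(e) NULL)
    if (!is.null(m2)) blocked_common <- length(blocked_reactions(m2))
  }
  tibble::tibble(
    model_id = model$model_id,
    n_genes = length(model$genes),
    n_dubious_genes = length(intersect(model$genes, dubious_orfs)),
    n_metabolites = nrow(internal),
    n_dead_ends = nrow(dead),
    n_reactions = nrow(model$reactions),
    n_gene_associated_reactions = sum(has_gpr),
    n_blocked_default_biomass = blocked_default,
    n_blocked_common_biomass = blocked_common
  )
}

#' Read a one-ORF-per-line gene list
#' @param path file path; blank lines and `#` comments are skipped.
#' @return character vector.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read a two-column TSV of unordered gene pairs
#' @param path file path (columns gene_a, gene_b; header optional).
#' @return tibble with columns `gene_a`, `gene_b`, each pair sorted so that
#'   `gene_a < gene_b`.
#' @export
read_pair_list <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (identical(tolower(raw[1, 1]), "gene_a")) raw <- raw[-1, , drop = FALSE]
  normalize_pairs(tibble::tibble(gene_a = as.character(raw[[1]]),
                                 gene_b = as.character(raw[[2]])))
}

normalize_pairs <- function(pairs) {
  a <- pmin(pairs$gene_a, pairs$gene_b)
  b <- pmax(pairs$gene_a, pairs$gene_b)
  dplyr::distinct(tibble::tibble(gene_a = a, gene_b = b))
}
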