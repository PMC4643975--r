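#' Screen configuration
#'
#' Decision thresholds used by the deletion screens: a gene is predicted
#' essential when the mutant's maximum biomass flux falls below
#' `essentiality_threshold` (default 1e-6 flux units; infeasible mutants
#' count as zero flux), and a double mutant is predicted synthetic lethal
#' when its flux is at most `sl_wildtype_fraction` (default 0.10) of the
#' wild-type biomass flux. The 10% rule defines non-lethal as strictly
#' greater than the fraction, so the boundary is assigned to lethal.
#'
#' @param essentiality_threshold positive flux threshold.
#' @param sl_wildtype_fraction fraction in (0, 1).
#' @return a `screen_config`.
#' @export
screen_config <- function(essentiality_threshold = 1e-6,
                          sl_wildtype_fraction = 0.10) {
  stopifnot(essentiality_threshold > 0,
            sl_wildtype_fraction > 0, sl_wildtype_fraction < 1)
  structure(list(essentiality_threshold = essentiality_threshold,
                 sl_wildtype_fraction = sl_wildtype_fraction),
            class = "screen_config")
}

#' Single-gene deletion screen
#'
#' Runs one FBA per gene with that gene deleted (reactions whose GPR
#' evaluates FALSE closed) and calls each gene essential when the mutant's
#' maximum biomass flux is below the threshold. Optionally applies a medium
#' and/or substitutes the biomass objective first, so the same model can be
#' screened across a grid of standardized conditions.
#'
#' @param model a `metabolic_model`.
#' @param medium optional [medium_definition()] applied before screening.
#' @param biomass optional [biomass_definition()] substituted before
#'   screening.
#' @param gene_universe genes to evaluate; defaults to the model's genes.
#'   Ids outside the model are recorded with `in_model = FALSE` and an `NA`
#'   flux (their scoring is a reference-list policy decision, see
#'   [build_confusion_single()]). For Kuepfer-style evaluation pass the
#'   intersection universe explicitly.
#' @param config a [screen_config()].
#' @return a `single_screen_result`: list with `genes` (tibble: `gene`,
#'   `in_model`, `max_biomass_flux`, `essential`), `wild_type_flux` and
#'   context labels. Errors if the wild type does not grow in the medium,
#'   since an essentiality screen on a non-growing model is meaningless.
#' @export
single_deletion_screen <- function(model, medium = NULL, biomass = NULL,
                                   gene_universe = NULL,
                                   config = screen_config()) {
  if (!is.null(medium)) model <- apply_medium(model, medium)
  if (!is.null(biomass)) model <- set_biomass(model, biomass)
  gene_universe <- gene_universe %||% model$genes
  wt <- solve_fba(model)
  wt_flux <- fba_growth(wt)
  if (is.na(wt_flux) || wt_flux < config$essentiality_threshold) {
    stop("model '", model$model_id, "' does not grow in medium '",
         if (is.null(medium)) "Default" else medium$name,
         "' (wild-type status: ", wt$status, ")")
  }
  in_model <- gene_universe %in% model$genes
  flux <- rep(NA_real_, length(gene_universe))
  for (i in which(in_model)) {
    mut <- apply_deletions(model, gene_universe[i], warn_unknown = FALSE)
    flux[i] <- fba_growth(solve_fba(mut))
    if (is.na(flux[i])) flux[i] <- Inf  # unbounded mutant: certainly grows
  }
  structure(list(
    model_id = model$model_id,
    medium = if (is.null(medium)) "Default" else medium$name,
    biomass = if (is.null(biomass)) "Default" else biomass$name,
    wild_type_flux = wt_flux,
    config = config,
    genes = tibble::tibble(
      gene = gene_universe,
      in_model = in_model,
      max_biomass_flux = flux,
      essential = !is.na(flux) & flux < config$essentiality_threshold
    )
  ), class = "single_screen_result")
}

#' @export
print.single_screen_result <- function(x, ...) {
  cat("<single_screen_result> ", x$model_id, " [medium: ", x$medium,
      ", biomass: ", x$biomass, "]\n", sep = "")
  cat("  wild-type flux: ", signif(x$wild_type_flux, 6), "\n", sep = "")
  cat("  genes evaluated: ", sum(x$genes$in_model), " (",
      sum(x$genes$essential), " predicted essential)\n", sep = "")
  invisible(x)
}

#' Genes predicted essential by a screen
#' @param screen a `single_screen_result`.
#' @return character vector of gene ids.
#' @export
essential_genes <- function(screen) {
  screen$genes$gene[screen$genes$essential]
}

#' Double-gene deletion screen
#'
#' Evaluates the maximum biomass flux of every unordered pair of model
#' genes (enumerated lexicographically with `gene_a < gene_b`), using the
#' model's default medium and biomass — the convention for synthetic
#' lethality screens. An optional skip logic reuses fluxes that are
#' provably equal to an already-computed value: when neither gene disables
#' any reaction the wild-type flux applies, and when the pair disables
#' exactly the reactions one single mutant disables, that single-mutant
#' flux applies. Skipping is provably neutral and is checked against the
#' exhaustive path in the test-suite.
#'
#' @param model a `metabolic_model`.
#' @param config a [screen_config()].
#' @param genes optional subset of genes to restrict the pair grid to.
#' @param skip use the provably-neutral skip logic (default TRUE).
#' @param checkpoint optional path to a TSV file; completed pair records
#'   are streamed there and a rerun resumes after the last completed pair.
#' @return a `double_screen_result`: list with `pairs` (tibble: `gene_a`,
#'   `gene_b`, `pair_flux`), the embedded `singles` screen used for the
#'   gate, and `wild_type_flux`.
#' @export
double_deletion_screen <- function(model, config = screen_config(),
                                   genes = NULL, skip = TRUE,
                                   checkpoint = NULL) {
  genes <- sort(genes %||% model$genes)
  stopifnot(all(genes %in% model$genes))
  singles <- single_deletion_screen(model, gene_universe = genes, config = config)
  single_flux <- stats::setNames(singles$genes$max_biomass_flux, singles$genes$gene)
  dis_single <- lapply(genes, function(g) disabled_reactions(model, g))
  names(dis_single) <- genes

  done <- tibble::tibble(gene_a = character(), gene_b = character(),
                         pair_flux = numeric())
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    done <- tibble::as_tibble(utils::read.table(checkpoint, header = TRUE,
                                                sep = "\t", stringsAsFactors = FALSE))
  }
  con <- NULL
  if (!is.null(checkpoint)) {
    new_file <- !file.exists(checkpoint)
    con <- file(checkpoint, open = "a")
    on.exit(close(con), add = TRUE)
    if (new_file) writeLines("gene_a\tgene_b\tpair_flux", con)
  }

  n <- length(genes)
  rows <- vector("list", n * (n - 1) / 2)
  k <- 0L
  for (i in seq_len(max(n - 1, 0))) {
    for (j in seq((i + 1), n)) {
      k <- k + 1L
      a <- genes[i]; b <- genes[j]
      if (nrow(done) && any(done$gene_a == a & done$gene_b == b)) {
        rows[[k]] <- done[done$gene_a == a & done$gene_b == b, ][1, ]
        next
      }
      flux <- NA_real_
      if (skip) {
        # the joint disabled set decides whether an LP is avoidable: it may
        # exceed the union of the single sets (isozyme pairs), so it is
        # always recomputed, never inferred from the singles
        dab <- disabled_reactions(model, c(a, b))
        if (length(dab) == 0L) flux <- singles$wild_type_flux
        else if (setequal(dab, dis_single[[a]])) flux <- single_flux[[a]]
        else if (setequal(dab, dis_single[[b]])) flux <- single_flux[[b]]
      }
      if (is.na(flux)) {
        mut <- apply_deletions(model, c(a, b), warn_unknown = FALSE)
        flux <- fba_growth(solve_fba(mut))
        if (is.na(flux)) flux <- Inf
      }
      rows[[k]] <- tibble::tibble(gene_a = a, gene_b = b, pair_flux = flux)
      if (!is.null(con)) {
        writeLines(sprintf("%s\t%s\t%.12g", a, b, flux), con)
        flush(con)
      }
    }
  }
  structure(list(
    model_id = model$model_id,
    wild_type_flux = singles$wild_type_flux,
    config = config,
    singles = singles,
    pairs = dplyr::bind_rows(rows)
  ), class = "double_screen_result")
}

#' @export
print.double_screen_result <- function(x, ...) {
  lethal <- x$pairs$pair_flux <= x$config$sl_wildtype_fraction * x$wild_type_flux
  cat("<double_screen_result> ", x$model_id, ": ", nrow(x$pairs),
      " pairs (", sum(lethal), " below the lethality fraction)\n", sep = "")
  invisible(x)
}

#' Classify double-deletion predictions against a synthetic-lethal reference
#'
#' Scores predicted synthetic lethality over the pairs where neither gene
#' is individually predicted essential (the strict definition): a pair is
#' predicted lethal when its flux is at most `sl_wildtype_fraction` of the
#' wild-type flux. Reference pairs where that gate fails (one of the genes
#' is predicted individually essential) are counted as `other_errors` — the
#' error was already accounted for in the single-gene screen — and are
#' excluded from the MCC. Reference pairs with a gene absent from the model
#' are out of scope and counted separately. Enumerated non-reference pairs
#' failing the gate are dropped from the evaluated universe (reported as
#' `n_gate_excluded`).
#'
#' @param singles the `single_screen_result` for the same model/config.
#' @param doubles the `double_screen_result` for the same model/config.
#' @param reference_pairs tibble with columns `gene_a`, `gene_b` (unordered
#'   pairs; normalized internally) or path understood by
#'   [read_pair_list()].
#' @param config a [screen_config()]; defaults to the config embedded in
#'   `doubles`.
#' @return a `confusion_matrix` tibble row (see [confusion_matrix()]) with
#'   `other_errors`, `out_of_scope` and `n_gate_excluded` filled in.
#' @export
classify_synthetic_lethality <- function(singles, doubles, reference_pairs,
                                         config = NULL) {
  config <- config %||% doubles$config
  if (is.character(reference_pairs)) reference_pairs <- read_pair_list(reference_pairs)
  reference_pairs <- normalize_pairs(reference_pairs)
  ess <- essential_genes(singles)
  model_genes <- singles$genes$gene[singles$genes$in_model]

  ref_key <- paste(reference_pairs$gene_a, reference_pairs$gene_b)
  in_scope_ref <- reference_pairs$gene_a %in% model_genes &
    reference_pairs$gene_b %in% model_genes
  out_of_scope <- sum(!in_scope_ref)

  pairs <- doubles$pairs
  key <- paste(pairs$gene_a, pairs$gene_b)
  in_ref <- key %in% ref_key[in_scope_ref]
  gate_ok <- !(pairs$gene_a %in% ess) & !(pairs$gene_b %in% ess)
  cutoff <- config$sl_wildtype_fraction * doubles$wild_type_flux
  pred_lethal <- pairs$pair_flux <= cutoff

  tp <- sum(gate_ok & in_ref & pred_lethal)
  fn <- sum(gate_ok & in_ref & !pred_lethal)
  fp <- sum(gate_ok & !in_ref & pred_lethal)
  tn <- sum(gate_ok & !in_ref & !pred_lethal)
  other <- sum(!gate_ok & in_ref)
  gate_excluded <- sum(!gate_ok & !in_ref)

  cm <- confusion_matrix(tp, tn, fp, fn,
                         model_id = doubles$model_id,
                         medium = singles$medium, biomass = singles$biomass,
                         reference = "synthetic_lethal_pairs")
  cm$other_errors <- other
  cm$out_of_scope <- out_of_scope
  cm$n_gate_excluded <- gate_excluded
  cm
}
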