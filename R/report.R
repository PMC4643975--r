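#' Run a full comparison grid
#'
#' Drives the standardized comparison: for every model x medium x biomass
#' cell, runs a single-gene deletion screen, scores it against each
#' reference list, and collects confusion matrices, per-gene prediction
#' classes and per-model pooled MCCs. Model summaries and (for two or more
#' models) the gene/metabolite scope comparison are produced alongside.
#' A failing cell (e.g. a model that cannot grow in a medium) is recorded
#' with its error message and the grid continues.
#'
#' @param models named list of `metabolic_model` objects (or file paths to
#'   flat/SBML models, loaded by extension).
#' @param media named list of [medium_definition()]s; a `NULL` element
#'   means the model's default medium. Default: default medium only.
#' @param biomasses named list of [biomass_definition()]s; `NULL` element =
#'   model default. Default: default biomass only.
#' @param references named list of reference essential-gene lists
#'   (character vectors or file paths); each is scored for every cell.
#' @param universe_policy passed to [build_confusion_single()]; either one
#'   policy or a named vector keyed by reference name.
#' @param reference_universes optional named list of screened-gene
#'   universes (for `"intersect"` policies).
#' @param config a [screen_config()].
#' @param dubious_orfs ORFs counted as dubious in model summaries.
#' @param common_biomass optional biomass used for the summary table's
#'   common-biomass blocked count.
#' @param out_dir optional directory; when given, heatmap-ready TSVs, the
#'   per-gene prediction lists and a JSON run manifest are written there,
#'   each with a provenance header echoing the configuration.
#' @param seed integer recorded in the manifest (the grid itself is
#'   deterministic).
#' @return list of tibbles: `cells` (one row per grid cell x reference,
#'   with `status` and `mcc`), `confusions`, `gene_predictions`,
#'   `model_mcc` (pooled per model), `summaries`, and `scope` (list with
#'   incidence/distance/cluster/MDS objects, or `NULL`).
#' @export
run_comparison <- function(models,
                           media = list(Default = NULL),
                           biomasses = list(Default = NULL),
                           references = list(),
                           universe_policy = "model_genes",
                           reference_universes = list(),
                           config = screen_config(),
                           dubious_orfs = character(),
                           common_biomass = NULL,
                           out_dir = NULL,
                           seed = 1L) {
  models <- lapply(models, function(m) {
    if (is.character(m)) {
      if (grepl("\\.(xml|sbml)$", m, ignore.case = TRUE)) read_sbml(m)
      else read_flat_model(m)
    } else m
  })
  if (is.null(names(models)) || any(!nzchar(names(models)))) {
    names(models) <- vapply(models, `[[`, character(1), "model_id")
  }
  references <- lapply(references, function(r) {
    if (is.character(r) && length(r) == 1L && file.exists(r)) read_gene_list(r) else r
  })

  grid <- tidyr::expand_grid(model = names(models), medium = names(media),
                             biomass = names(biomasses))
  cells <- list(); confusions <- list(); preds <- list()
  for (i in seq_len(nrow(grid))) {
    mn <- grid$model[i]; men <- grid$medium[i]; bn <- grid$biomass[i]
    res <- tryCatch({
      scr <- single_deletion_screen(models[[mn]], medium = media[[men]],
                                    biomass = biomasses[[bn]], config = config)
      list(screen = scr, error = NULL)
    }, error = function(e) list(screen = NULL, error = conditionMessage(e)))
    if (is.null(res$screen)) {
      cells[[length(cells) + 1L]] <- tibble::tibble(
        model = mn, medium = men, biomass = bn, reference = NA_character_,
        status = "failed", error = res$error, mcc = NA_real_)
      next
    }
    scr <- res$screen
    for (rn in names(references)) {
      pol <- if (length(universe_policy) > 1L) universe_policy[[rn]] else universe_policy
      cm <- tryCatch(
        build_confusion_single(scr, references[[rn]],
                               universe_policy = pol,
                               reference_universe = reference_universes[[rn]],
                               reference_name = rn),
        error = function(e) e)
      if (inherits(cm, "error")) {
        cells[[length(cells) + 1L]] <- tibble::tibble(
          model = mn, medium = men, biomass = bn, reference = rn,
          status = "failed", error = conditionMessage(cm), mcc = NA_real_)
        next
      }
      confusions[[length(confusions) + 1L]] <- cm
      cells[[length(cells) + 1L]] <- tibble::tibble(
        model = mn, medium = men, biomass = bn, reference = rn,
        status = "ok", error = NA_character_, mcc = suppressMessages(mcc(cm)))
      ann <- scr$genes[scr$genes$in_model, ]
      in_ref <- ann$gene %in% references[[rn]]
      preds[[length(preds) + 1L]] <- tibble::tibble(
        model = mn, medium = men, biomass = bn, reference = rn,
        gene = ann$gene,
        predicted = ifelse(ann$essential, "essential", "viable"),
        annotated = ifelse(in_ref, "essential", "viable"),
        class = dplyr::case_when(
          !ann$essential & !in_ref ~ "TP",
          ann$essential & in_ref ~ "TN",
          !ann$essential & in_ref ~ "FP",
          TRUE ~ "FN"))
    }
    if (length(references) == 0L) {
      cells[[length(cells) + 1L]] <- tibble::tibble(
        model = mn, medium = men, biomass = bn, reference = NA_character_,
        status = "ok", error = NA_character_, mcc = NA_real_)
    }
  }
  cells <- dplyr::bind_rows(cells)
  confusions <- if (length(confusions)) dplyr::bind_rows(confusions) else NULL
  gene_predictions <- if (length(preds)) dplyr::bind_rows(preds) else NULL
  model_mcc <- NULL
  if (!is.null(confusions)) {
    model_mcc <- confusions |>
      dplyr::group_by(.data$model_id) |>
      dplyr::group_modify(~ tibble::tibble(
        pooled_mcc = suppressMessages(overall_mcc(.x)),
        conditions = nrow(.x))) |>
      dplyr::ungroup()
  }
  summaries <- dplyr::bind_rows(lapply(models, summarize_model,
                                       dubious_orfs = dubious_orfs,
                                       common_biomass = common_biomass))
  scope <- NULL
  if (length(models) >= 2L) {
    gi <- gene_incidence(models)
    gd <- pairwise_distance(gi)
    scope <- list(
      gene_incidence = gi,
      gene_distance = gd,
      gene_cluster = hierarchical_cluster(gd),
      gene_mds = suppressWarnings(classical_mds(gd, k = min(2, length(models) - 1)))
    )
    mi <- tryCatch(suppressWarnings(metabolite_incidence(models)),
                   error = function(e) NULL)
    if (!is.null(mi) && ncol(mi) > 0L) {
      md <- pairwise_distance(mi)
      scope$metabolite_incidence <- mi
      scope$metabolite_distance <- md
      scope$metabolite_cluster <- hierarchical_cluster(md)
    }
  }
  out <- list(cells = cells, confusions = confusions,
              gene_predictions = gene_predictions, model_mcc = model_mcc,
              summaries = summaries, scope = scope)
  if (!is.null(out_dir)) {
    write_report_bundle(out, out_dir, models = models, media = media,
                        biomasses = biomasses, references = references,
                        config = config, seed = seed)
  }
  if (any(cells$status == "failed")) {
    attr(out, "n_failed") <- sum(cells$status == "failed")
  }
  out
}

provenance_header <- function(manifest) {
  c(paste0("# config_hash: ", rlang::hash(manifest)),
    paste0("# ", names(manifest), ": ", vapply(manifest, function(x)
      paste(as.character(x), collapse = ", "), character(1))))
}

write_tsv_with_header <- function(df, path, header) {
  con <- file(path, open = "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_report_bundle <- function(out, out_dir, models, media, biomasses,
                                references, config, seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    models = names(models),
    media = names(media),
    biomasses = names(biomasses),
    references = names(references),
    essentiality_threshold = config$essentiality_threshold,
    sl_wildtype_fraction = config$sl_wildtype_fraction,
    seed = seed
  )
  hdr <- provenance_header(manifest)
  write_tsv_with_header(out$cells, file.path(out_dir, "mcc_grid.tsv"), hdr)
  write_tsv_with_header(out$summaries, file.path(out_dir, "model_summaries.tsv"), hdr)
  if (!is.null(out$confusions)) {
    write_tsv_with_header(tidy(out$confusions),
                          file.path(out_dir, "confusion_matrices.tsv"), hdr)
  }
  if (!is.null(out$gene_predictions)) {
    write_tsv_with_header(out$gene_predictions,
                          file.path(out_dir, "gene_predictions.tsv"), hdr)
  }
  if (!is.null(out$model_mcc)) {
    write_tsv_with_header(out$model_mcc,
                          file.path(out_dir, "model_pooled_mcc.tsv"), hdr)
  }
  if (!is.null(out$scope)) {
    write_tsv_with_header(incidence_table(out$scope$gene_incidence),
                          file.path(out_dir, "gene_incidence.tsv"), hdr)
    writeLines(dendrogram_newick(out$scope$gene_cluster),
               file.path(out_dir, "gene_cluster.nwk"))
    write_tsv_with_header(out$scope$gene_mds,
                          file.path(out_dir, "gene_mds.tsv"), hdr)
  }
  manifest$config_hash <- rlang::hash(manifest)
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
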