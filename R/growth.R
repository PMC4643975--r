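#' Growth observations
#'
#' One row per chemostat condition: the measured uptake fluxes used as
#' exchange constraints (non-negative numbers; applied as negative lower
#' bounds) and the observed growth rate. Stored as a tidy tibble with a
#' `condition` column, one column per exchange key, and `growth_rate`.
#'
#' @param path TSV file: column `condition`, one numeric column per
#'   exchange key, column `growth_rate`.
#' @return tibble of observations.
#' @export
read_growth_observations <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  out <- tibble::as_tibble(tab)
  stopifnot("condition" %in% names(out), "growth_rate" %in% names(out))
  num <- setdiff(names(out), "condition")
  if (any(unlist(out[num]) < 0, na.rm = TRUE)) {
    stop("uptake values and growth rates must be non-negative")
  }
  out
}

#' FBA biomass maxima under measured uptake constraints
#'
#' For each observation, sets the listed exchange reactions' lower bounds
#' to minus the measured uptake (leaving all other bounds as configured by
#' the medium in force) and records the FBA optimum. Constraining one
#' exchange at a time probes whether that nutrient is the sole limiting
#' factor; constraining several jointly exposes stoichiometric interplay
#' (e.g. the glucose:oxygen ratio). Unbounded optima are flagged, not
#' clamped.
#'
#' @param model a `metabolic_model`, already standardized (medium/biomass)
#'   as desired.
#' @param observations tibble from [read_growth_observations()] (or built
#'   in code): `condition`, uptake columns, `growth_rate`.
#' @param which character vector of exchange keys (column names in
#'   `observations`) to constrain; the others are ignored.
#' @return tibble: `condition`, `predicted_flux`, `status`, `growth_rate`.
#' @export
constrained_growth_scan <- function(model, observations, which) {
  stopifnot(all(which %in% names(observations)))
  rids <- vapply(which, resolve_exchange, character(1), model = model)
  rows <- purrr::map(seq_len(nrow(observations)), function(i) {
    m <- model
    for (j in seq_along(which)) {
      m <- set_bounds(m, rids[[j]], lb = -as.numeric(observations[[which[j]]][i]))
    }
    res <- solve_fba(m)
    tibble::tibble(
      condition = observations$condition[i],
      predicted_flux = if (identical(res$status, "optimal")) res$objective_value else NA_real_,
      status = res$status,
      growth_rate = observations$growth_rate[i]
    )
  })
  dplyr::bind_rows(rows)
}

#' Pearson correlation between predicted and observed growth
#'
#' Standard product-moment correlation; zero variance on either side is an
#' error (a silent 0 would misrepresent a flat prediction profile).
#' Spearman rank correlation is available behind the `method` flag.
#'
#' @param predicted,observed equal-length numeric vectors (length >= 3).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return correlation in \[-1, 1\].
#' @export
growth_correlation <- function(predicted, observed,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(predicted) == length(observed), length(predicted) >= 3)
  if (anyNA(predicted) || anyNA(observed)) {
    stop("missing (e.g. unbounded) predictions; resolve before correlating")
  }
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0) {
    stop("zero variance in ", if (stats::sd(predicted) == 0) "predicted" else "observed",
         " values; correlation undefined")
  }
  stats::cor(predicted, observed, method = method)
}

#' Rank internal reactions by one-norm-minimized flux
#'
#' Runs l1-minimized FBA and ranks internal (non-exchange) reactions by
#' absolute flux, descending (ties broken by reaction id). Unrealistically
#' large internal fluxes surviving one-norm minimization are the signature
#' of erroneous high-flux shortcuts (e.g. an unsupported transport
#' reaction) in models that overpredict biomass flux.
#'
#' @param model a `metabolic_model` (feasible).
#' @return tibble: `reaction_id`, `flux`, `abs_flux`, sorted.
#' @export
diagnose_high_flux_reactions <- function(model) {
  res <- solve_fba_l1min(model)
  if (!identical(res$status, "optimal")) {
    stop("l1-min FBA not optimal: ", res$status)
  }
  internal <- !model$reactions$exchange & model$reactions$id != model$objective
  out <- tibble::tibble(
    reaction_id = model$reactions$id[internal],
    flux = unname(res$fluxes[model$reactions$id[internal]])
  )
  out$abs_flux <- abs(out$flux)
  dplyr::arrange(out, dplyr::desc(.data$abs_flux), .data$reaction_id)
}

#' Re-run a growth scan with one reaction removed
#'
#' Soft removal (bounds set to 0,0 — provably equivalent to deleting the
#' column for FBA purposes) of a suspect reaction, followed by the same
#' constrained growth scan, returning predictions and correlations before
#' and after. This is the workflow for confirming that a diagnosed
#' high-flux reaction is responsible for overprediction.
#'
#' @param model a standardized `metabolic_model`.
#' @param reaction_id reaction to remove; unknown ids raise an error
#'   listing near-matches.
#' @param observations,which as in [constrained_growth_scan()].
#' @return list with `before`/`after` scan tibbles and
#'   `correlation_before`/`correlation_after`.
#' @export
remove_reaction_and_rescan <- function(model, reaction_id, observations, which) {
  if (!reaction_id %in% model$reactions$id) {
    near <- utils::head(model$reactions$id[
      order(utils::adist(reaction_id, model$reactions$id))], 3)
    stop("unknown reaction '", reaction_id, "'; nearest ids: ",
         paste(near, collapse = ", "))
  }
  before <- constrained_growth_scan(model, observations, which)
  after <- constrained_growth_scan(set_bounds(model, reaction_id, lb = 0, ub = 0),
                                   observations, which)
  list(
    before = before,
    after = after,
    correlation_before = growth_correlation(before$predicted_flux, before$growth_rate),
    correlation_after = growth_correlation(after$predicted_flux, after$growth_rate)
  )
}

#' Per-model ids of the mitochondrial aspartate transport reaction
#'
#' Published yeast models encode the same suspect mitochondrial aspartate
#' transport step under different reaction ids. This lookup maps model
#' names to the id to pass to [remove_reaction_and_rescan()].
#'
#' @param model_id model name (e.g. `"Yeast 4"`, `"iMM904"`).
#' @return reaction id string, or `NA` for models without the reaction
#'   (e.g. models lacking a mitochondrial compartment).
#' @export
aspartate_transport_id <- function(model_id) {
  lookup <- c(
    "Yeast 4" = "r_1163", "Yeast 5" = "r_1117", "Yeast 6" = "r_1117",
    "Yeast 7" = "r_1117", "iAZ900" = "ASSPt2M", "iND750" = "ASPt2M",
    "iIN800" = "AGC1_2", "iTO977" = "AGC1_2",
    "iMM904" = "ASPt2m", "iMM904bs" = "ASPt2m",
    "iFF708" = NA_character_, "Biomodels.db" = NA_character_
  )
  if (!model_id %in% names(lookup)) return(NA_character_)
  unname(lookup[[model_id]])
}
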