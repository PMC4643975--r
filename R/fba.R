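#' Flux balance analysis
#'
#' Maximizes flux through the model's objective (biomass) reaction subject
#' to steady-state mass balance over non-boundary metabolites
#' (\eqn{S v = 0}) and the flux bounds. The objective flux proxies growth
#' rate; flux units are model-relative (mmol/gDW/h by convention) and no
#' unit conversion is attempted.
#'
#' @param model a `metabolic_model`.
#' @param objective optional reaction id to optimize instead of the model's
#'   stored objective.
#' @param maximize maximize (default) or minimize the objective flux.
#' @return an `fba_result`: list with `status` (`"optimal"`, `"infeasible"`
#'   or `"unbounded"`), `objective_value`, and `fluxes` (named numeric
#'   vector; `NULL` unless optimal). Unbounded problems are reported as
#'   such, never clamped — downstream growth scans treat unboundedness as a
#'   model pathology worth flagging.
#' @export
solve_fba <- function(model, objective = NULL, maximize = TRUE) {
  objective <- objective %||% model$objective
  j <- match(objective, model$reactions$id)
  if (is.na(j)) stop("objective reaction '", objective, "' not in model")
  S <- stoich_matrix(model)
  n <- nrow(model$reactions)
  obj <- numeric(n)
  obj[j] <- 1
  res <- solve_lp(obj, S, rep(0, nrow(S)),
                  model$reactions$lb, model$reactions$ub, maximize = maximize)
  fba_result(res, model$reactions$id)
}

fba_result <- function(res, reaction_ids) {
  fluxes <- NULL
  if (identical(res$status, "optimal")) {
    fluxes <- stats::setNames(res$solution, reaction_ids)
  }
  structure(list(status = res$status,
                 objective_value = if (identical(res$status, "optimal")) res$objective else NA_real_,
                 fluxes = fluxes),
            class = "fba_result")
}

#' @export
print.fba_result <- function(x, ...) {
  cat("<fba_result> status:", x$status,
      if (!is.na(x$objective_value)) paste0(" objective: ", signif(x$objective_value, 6)),
      "\n")
  invisible(x)
}

#' Growth value of an FBA result for screening purposes
#'
#' Infeasible mutants are scored as zero growth (essential); this matches a
#' binary growth/no-growth reading of the LP outcome.
#' @param res an `fba_result`.
#' @return numeric flux (0 when infeasible), `NA` when unbounded.
#' @export
fba_growth <- function(res) {
  switch(res$status,
         optimal = res$objective_value,
         infeasible = 0,
         unbounded = NA_real_)
}

#' One-norm-minimized flux balance analysis
#'
#' First maximizes biomass flux, then — with biomass fixed at its optimum —
#' finds the flux distribution of minimal total flux \eqn{\sum_j |v_j|} via
#' the standard split into positive and negative flux components. The
#' returned `objective_value` is the (unchanged) biomass flux; the returned
#' fluxes have minimal one-norm among alternate optima. Thermodynamically
#' infeasible cycles that carry no objective benefit are driven to zero,
#' which is what makes this the loop diagnostic used by
#' [diagnose_high_flux_reactions()].
#'
#' @inheritParams solve_fba
#' @param fix_tol numeric slack used when fixing the biomass flux to the
#'   phase-one optimum.
#' @return an `fba_result` with the l1-minimal flux vector.
#' @export
solve_fba_l1min <- function(model, objective = NULL, fix_tol = 1e-8) {
  objective <- objective %||% model$objective
  first <- solve_fba(model, objective = objective)
  if (!identical(first$status, "optimal")) return(first)
  opt <- first$objective_value

  S <- stoich_matrix(model)
  n <- nrow(model$reactions)
  lb <- model$reactions$lb
  ub <- model$reactions$ub
  j <- match(objective, model$reactions$id)
  lb[j] <- opt - fix_tol
  ub[j] <- opt + fix_tol
  # v = p - q, p,q >= 0: S p - S q = 0, minimize sum(p) + sum(q)
  A <- cbind(S, -S)
  plb <- pmax(lb, 0); pub <- pmax(ub, 0)
  qlb <- pmax(-ub, 0); qub <- pmax(-lb, 0)
  res <- solve_lp(rep(1, 2 * n), A, rep(0, nrow(S)),
                  c(plb, qlb), c(pub, qub), maximize = FALSE)
  if (!identical(res$status, "optimal")) {
    return(fba_result(res, model$reactions$id))
  }
  v <- res$solution[seq_len(n)] - res$solution[n + seq_len(n)]
  structure(list(status = "optimal", objective_value = opt,
                 fluxes = stats::setNames(v, model$reactions$id),
                 l1_norm = sum(abs(v))),
            class = "fba_result")
}

#' Flux variability analysis
#'
#' For each requested reaction, minimizes and maximizes its flux subject to
#' the model's steady-state and bound constraints. No objective-fraction
#' constraint is imposed by default: blockage is assessed as a structural
#' property with the biomass reaction present but not fixed. An optional
#' `objective_fraction` forces biomass \eqn{\ge} that fraction of its
#' optimum first.
#'
#' @param model a `metabolic_model`.
#' @param reaction_ids reactions to analyse (default: all).
#' @param objective_fraction optional value in (0, 1]; default `NULL`
#'   (none).
#' @return tibble with columns `reaction_id`, `v_min`, `v_max`.
#' @export
flux_variability <- function(model, reaction_ids = NULL,
                             objective_fraction = NULL) {
  reaction_ids <- reaction_ids %||% model$reactions$id
  stopifnot(all(reaction_ids %in% model$reactions$id))
  if (!is.null(objective_fraction)) {
    wt <- solve_fba(model)
    if (!identical(wt$status, "optimal")) stop("infeasible, check medium")
    j <- match(model$objective, model$reactions$id)
    model$reactions$lb[j] <- objective_fraction * wt$objective_value
  }
  S <- stoich_matrix(model)
  lb <- model$reactions$lb
  ub <- model$reactions$ub
  n <- nrow(model$reactions)
  feas <- solve_lp(numeric(n), S, rep(0, nrow(S)), lb, ub)
  if (!identical(feas$status, "optimal")) stop("infeasible, check medium")
  rows <- purrr::map(reaction_ids, function(rid) {
    j <- match(rid, model$reactions$id)
    obj <- numeric(n); obj[j] <- 1
    lo <- solve_lp(obj, S, rep(0, nrow(S)), lb, ub, maximize = FALSE)
    hi <- solve_lp(obj, S, rep(0, nrow(S)), lb, ub, maximize = TRUE)
    tibble::tibble(
      reaction_id = rid,
      v_min = if (identical(lo$status, "optimal")) lo$objective else -Inf,
      v_max = if (identical(hi$status, "optimal")) hi$objective else Inf
    )
  })
  dplyr::bind_rows(rows)
}

#' Blocked reactions under fully open exchanges
#'
#' A reaction is blocked when it cannot carry any flux given the network
#' structure. Blockage is evaluated with every exchange reaction allowed to
#' carry flux (lower bounds opened to -1000, upper to +1000) so that medium
#' choice does not masquerade as structural blockage; the biomass
#' definition in force still matters, which is why summaries report the
#' count under both the default and a common biomass.
#'
#' @param model a `metabolic_model`.
#' @param eps_block absolute flux below which a range counts as zero
#'   (default 1e-6, the same scale as the essentiality threshold).
#' @return character vector of blocked reaction ids.
#' @export
blocked_reactions <- function(model, eps_block = 1e-6) {
  ex <- model$reactions$exchange
  model$reactions$lb[ex] <- -1000
  model$reactions$ub[ex] <- 1000
  fva <- flux_variability(model)
  fva$reaction_id[abs(fva$v_min) < eps_block & abs(fva$v_max) < eps_block]
}

#' Dead-end metabolites
#'
#' A (non-boundary) metabolite is a dead end when (a) it participates in
#' exactly one reaction, or (b) taking reaction reversibility into account
#' it can only ever be produced, or only ever be consumed, across all
#' reactions it joins. This is a purely structural property — exchange and
#' biomass changes do not affect it. Both clauses are reported per
#' metabolite rather than collapsed, since they capture subtly different
#' failure modes of a reconstruction.
#'
#' @param model a `metabolic_model`.
#' @return tibble with columns `metabolite_id`, `single_reaction` (clause
#'   a), `orphan_direction` (clause b: `"never_produced"`,
#'   `"never_consumed"` or `NA`).
#' @export
dead_end_metabolites <- function(model) {
  mets <- model$metabolites$id[!model$metabolites$boundary]
  lb <- model$reactions$lb
  ub <- model$reactions$ub
  rows <- purrr::map(mets, function(mid) {
    coefs <- vapply(model$reactions$stoich, function(s) {
      if (mid %in% names(s)) s[[mid]] else 0
    }, numeric(1))
    touch <- which(coefs != 0)
    if (length(touch) == 0L) return(NULL)
    can_produce <- any((coefs[touch] > 0 & ub[touch] > 0) |
                       (coefs[touch] < 0 & lb[touch] < 0))
    can_consume <- any((coefs[touch] < 0 & ub[touch] > 0) |
                       (coefs[touch] > 0 & lb[touch] < 0))
    single <- length(touch) == 1L
    direction <- if (!can_produce && can_consume) "never_produced"
                 else if (can_produce && !can_consume) "never_consumed"
                 else if (!can_produce && !can_consume) "inert"
                 else NA_character_
    if (!single && is.na(direction)) return(NULL)
    tibble::tibble(metabolite_id = mid, single_reaction = single,
                   orphan_direction = direction)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(metabolite_id = character(),
                          single_reaction = logical(),
                          orphan_direction = character())
  }
  out
}
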