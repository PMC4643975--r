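#' Medium definitions
#'
#' A medium is the set of exchange-reaction uptake bounds applied before a
#' simulation. Uptake is encoded as a negative lower bound on the exchange
#' reaction; "unconstrained exchange" means a lower bound of -1000 (the
#' COBRA magnitude convention). Standardized media are what make screens
#' comparable across models: applying a medium first closes every exchange
#' uptake, then opens exactly the listed components (plus any per-model
#' supplements a model needs to grow at all, e.g. an extra iron exchange).
#'
#' Components are addressed by a key, resolved against a model in this
#' order: exchanged metabolite id, metabolite ChEBI id, exchange reaction
#' id. Because published models use incompatible exchange ids, media are
#' serializable to editable YAML (with optional per-model key maps) rather
#' than being hard-coded.
#'
#' @param name medium name (e.g. `"Min-Glu"`).
#' @param uptake_bounds tibble/data.frame with columns `key`, `lb`, `ub`
#'   (one row per opened component; `lb` is negative for uptake).
#' @param supplements optional named list: model_id -> character vector of
#'   extra keys opened at -1000 for that model only.
#' @return a `medium_definition`.
#' @export
medium_definition <- function(name, uptake_bounds, supplements = list()) {
  uptake_bounds <- tibble::as_tibble(uptake_bounds)
  stopifnot(all(c("key", "lb", "ub") %in% names(uptake_bounds)))
  structure(list(name = name, uptake_bounds = uptake_bounds,
                 supplements = supplements),
            class = "medium_definition")
}

#' Construct a minimal glucose-limited medium
#'
#' Unconstrained exchange of ammonium, oxygen, phosphate and sulphate plus
#' a constrained glucose uptake. The glucose bound is a parameter (default
#' 10) and is echoed in every report header; keys must match the target
#' model's exchanged metabolite ids (or ChEBI ids).
#'
#' @param glucose_key,ammonium_key,oxygen_key,phosphate_key,sulphate_key
#'   component keys.
#' @param glucose_uptake maximum glucose uptake (positive number; applied
#'   as lower bound `-glucose_uptake`).
#' @param supplements per-model supplement list, see [medium_definition()].
#' @return a `medium_definition` named `"Min-Glu"`.
#' @export
minimal_glucose_medium <- function(glucose_key = "glc_e",
                                   ammonium_key = "nh4_e",
                                   oxygen_key = "o2_e",
                                   phosphate_key = "pi_e",
                                   sulphate_key = "so4_e",
                                   glucose_uptake = 10,
                                   supplements = list()) {
  medium_definition(
    "Min-Glu",
    tibble::tibble(
      key = c(glucose_key, ammonium_key, oxygen_key, phosphate_key, sulphate_key),
      lb = c(-glucose_uptake, -1000, -1000, -1000, -1000),
      ub = rep(1000, 5)
    ),
    supplements = supplements
  )
}

resolve_exchange <- function(model, key) {
  ex <- model$reactions[model$reactions$exchange, ]
  if (key %in% ex$id) return(key)
  boundary <- model$metabolites$id[model$metabolites$boundary]
  exchanged <- vapply(ex$stoich, function(s) {
    internal <- setdiff(names(s), boundary)
    if (length(internal) == 1L) internal else NA_character_
  }, character(1))
  hit <- which(exchanged == key)
  if (length(hit) == 1L) return(ex$id[hit])
  if (length(hit) > 1L) {
    stop("medium key '", key, "' matches multiple exchanges: ",
         paste(ex$id[hit], collapse = ", "))
  }
  # ChEBI resolution
  chebi_hit <- which(vapply(exchanged, function(mid) {
    !is.na(mid) && key %in% model$metabolites$chebi[[match(mid, model$metabolites$id)]]
  }, logical(1)))
  if (length(chebi_hit) == 1L) return(ex$id[chebi_hit])
  stop("cannot resolve medium component '", key, "' in model '",
       model$model_id, "'; exchanged metabolites are: ",
       paste(stats::na.omit(exchanged), collapse = ", "))
}

#' Apply a medium definition to a model
#'
#' Closes all exchange uptake (every exchange lower bound to 0), then opens
#' the medium's components to their stated bounds and the model's
#' supplements to -1000. Secretion (upper bounds) is left open unless the
#' medium overrides it. Unresolvable components are a hard error listing
#' the model's exchanged metabolites — never a silent skip. The operation
#' is idempotent.
#'
#' @param model a `metabolic_model`.
#' @param medium a `medium_definition`.
#' @return a modified copy of the model.
#' @export
apply_medium <- function(model, medium) {
  stopifnot(inherits(medium, "medium_definition"))
  ex <- model$reactions$exchange
  model$reactions$lb[ex] <- pmax(model$reactions$lb[ex], 0)
  for (i in seq_len(nrow(medium$uptake_bounds))) {
    comp <- medium$uptake_bounds[i, ]
    rid <- resolve_exchange(model, comp$key)
    model <- set_bounds(model, rid, lb = comp$lb, ub = comp$ub)
  }
  extra <- medium$supplements[[model$model_id]]
  for (key in extra %||% character()) {
    rid <- resolve_exchange(model, key)
    model <- set_bounds(model, rid, lb = -1000)
  }
  model
}

#' Biomass definitions
#'
#' A biomass definition is a drain stoichiometry over precursor
#' metabolites, used to substitute a common objective across models so
#' that screens compare reconstructions rather than each author's tuned
#' objective. Keys are resolved by metabolite id first, then ChEBI id.
#'
#' @param name definition name (e.g. `"iFF"`).
#' @param stoichiometry named numeric vector, metabolite key -> coefficient
#'   (negative = consumed). At least one component must be consumed.
#' @return a `biomass_definition`.
#' @export
biomass_definition <- function(name, stoichiometry) {
  stopifnot(is.numeric(stoichiometry), length(names(stoichiometry)) == length(stoichiometry))
  if (!any(stoichiometry < 0)) stop("biomass definition consumes nothing")
  structure(list(name = name, stoichiometry = stoichiometry),
            class = "biomass_definition")
}

resolve_metabolite <- function(model, key) {
  if (key %in% model$metabolites$id) return(key)
  hit <- which(vapply(model$metabolites$chebi, function(ch) key %in% ch, logical(1)))
  if (length(hit) >= 1L) return(model$metabolites$id[hit[1]])
  NA_character_
}

#' Substitute a model's biomass objective
#'
#' Replaces the objective with a new reaction carrying the given
#' stoichiometry. If any component cannot be resolved in the model, the
#' whole operation fails and reports the full missing list — mirroring the
#' practice of excluding models that cannot satisfy a common biomass
#' rather than silently dropping precursors.
#'
#' @param model a `metabolic_model`.
#' @param biomass a `biomass_definition`.
#' @return a modified copy with objective reaction
#'   `biomass_<name>` (bounds 0..1000); the previous objective reaction is
#'   kept in the table but closed (bounds 0, 0), so the substituted
#'   objective fully replaces it in every downstream analysis.
#' @export
set_biomass <- function(model, biomass) {
  stopifnot(inherits(biomass, "biomass_definition"))
  keys <- names(biomass$stoichiometry)
  resolved <- vapply(keys, resolve_metabolite, character(1), model = model)
  if (any(is.na(resolved))) {
    stop("model '", model$model_id, "' cannot satisfy biomass '",
         biomass$name, "'; missing components: ",
         paste(keys[is.na(resolved)], collapse = ", "))
  }
  stoich <- stats::setNames(as.numeric(biomass$stoichiometry), resolved)
  stoich <- vapply(split(stoich, names(stoich)), sum, numeric(1))
  new_id <- paste0("biomass_", gsub("[^A-Za-z0-9_]", "_", biomass$name))
  old <- match(model$objective, model$reactions$id)
  model$reactions$lb[old] <- 0
  model$reactions$ub[old] <- 0
  model$reactions <- model$reactions[model$reactions$id != new_id, ]
  model$reactions <- dplyr::bind_rows(
    model$reactions,
    tibble::tibble(id = new_id, name = paste("biomass:", biomass$name),
                   lb = 0, ub = 1000, stoich = list(stoich),
                   gpr = NA_character_, exchange = FALSE)
  )
  model$objective <- new_id
  model
}

#' Read/write medium and biomass definitions as YAML
#'
#' @param path YAML file path.
#' @return the parsed definition object.
#' @export
read_medium <- function(path) {
  y <- yaml::read_yaml(path)
  medium_definition(
    y$name,
    tibble::tibble(key = vapply(y$components, `[[`, character(1), "key"),
                   lb = vapply(y$components, function(c) as.numeric(c$lb), numeric(1)),
                   ub = vapply(y$components, function(c) as.numeric(c$ub %||% 1000), numeric(1))),
    supplements = y$supplements %||% list()
  )
}

#' @rdname read_medium
#' @param medium a `medium_definition`.
#' @export
write_medium <- function(medium, path) {
  comps <- lapply(seq_len(nrow(medium$uptake_bounds)), function(i) {
    r <- medium$uptake_bounds[i, ]
    list(key = r$key, lb = r$lb, ub = r$ub)
  })
  yaml::write_yaml(list(name = medium$name, components = comps,
                        supplements = medium$supplements), path)
  invisible(path)
}

#' @rdname read_medium
#' @export
read_biomass <- function(path) {
  y <- yaml::read_yaml(path)
  biomass_definition(y$name, unlist(y$stoichiometry))
}

#' @rdname read_medium
#' @param biomass a `biomass_definition`.
#' @export
write_biomass <- function(biomass, path) {
  yaml::write_yaml(list(name = biomass$name,
                        stoichiometry = as.list(biomass$stoichiometry)), path)
  invisible(path)
}
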