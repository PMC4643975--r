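#' Specification for a synthetic toy metabolic model
#'
#' The generator builds linear pathways feeding a biomass reaction, then
#' decorates pathway steps with the GPR motifs whose phenotypes are known
#' by construction: a plain single-gene step is essential; an `or` isozyme
#' pair is individually dispensable but synthetic lethal; an `and` complex
#' makes both subunit genes essential; a gene whose step has a spontaneous
#' (GPR-less) parallel route is dispensable and not synthetic lethal with
#' anything. Dead-end metabolites and blocked reactions are planted on
#' side branches disconnected from biomass, so they never affect growth.
#' The planted truth is derived constructively during generation — never by
#' the LP machinery under test — which is what makes it an independent
#' oracle for the screens.
#'
#' @param n_linear_pathways number of substrate-to-biomass pathways.
#' @param pathway_length reactions per pathway.
#' @param n_isozyme_pairs `or`-rule steps (each plants one synthetic-lethal
#'   pair).
#' @param n_complexes `and`-rule steps (each plants two essential genes).
#' @param n_parallel_routes steps duplicated by a GPR-less alternative
#'   reaction (each makes one gene dispensable).
#' @param n_dead_ends planted dead-end side reactions (each adds one
#'   dead-end metabolite and one blocked reaction).
#' @param n_blocked planted blocked two-reaction stubs (each adds two
#'   blocked reactions and one dead-end metabolite at the stub tip).
#' @param n_compartments compartment labels cycled over pathway
#'   metabolites.
#' @param seed integer seed; generation is a pure function of the spec.
#' @return a `toy_model_spec`.
#' @export
toy_model_spec <- function(n_linear_pathways = 3, pathway_length = 5,
                           n_isozyme_pairs = 2, n_complexes = 2,
                           n_parallel_routes = 1, n_dead_ends = 1,
                           n_blocked = 1, n_compartments = 1, seed = 1L) {
  spec <- list(n_linear_pathways = n_linear_pathways,
               pathway_length = pathway_length,
               n_isozyme_pairs = n_isozyme_pairs,
               n_complexes = n_complexes,
               n_parallel_routes = n_parallel_routes,
               n_dead_ends = n_dead_ends,
               n_blocked = n_blocked,
               n_compartments = n_compartments,
               seed = as.integer(seed))
  counts <- unlist(spec[setdiff(names(spec), "seed")])
  if (any(counts < 0)) stop("all toy-model spec counts must be >= 0")
  if (n_linear_pathways < 1 || pathway_length < 1) {
    stop("need at least one pathway with at least one reaction")
  }
  n_steps <- n_linear_pathways * pathway_length
  n_feat <- n_isozyme_pairs + n_complexes + n_parallel_routes
  if (n_feat > n_steps) {
    stop("requested ", n_feat, " decorated steps but only ", n_steps,
         " pathway steps exist")
  }
  structure(spec, class = "toy_model_spec")
}

local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Generate a toy metabolic model with planted ground truth
#'
#' @param spec a [toy_model_spec()].
#' @return list with `model` (a `metabolic_model`) and `truth` (a
#'   `toy_model_truth`: `essential_genes`, `synthetic_lethal_pairs` tibble,
#'   `dead_end_metabolites`, `blocked_reactions`). Deterministic per seed:
#'   the same spec always yields byte-identical [write_model()] output.
#' @export
generate_toy_model <- function(spec) {
  stopifnot(inherits(spec, "toy_model_spec"))
  restore <- local_seed(spec$seed)
  on.exit(restore())

  P <- spec$n_linear_pathways
  L <- spec$pathway_length
  comp <- paste0("c", seq_len(max(spec$n_compartments, 1)))

  n_steps <- P * L
  step_ids <- seq_len(n_steps)
  decorated <- sample(step_ids,
                      spec$n_isozyme_pairs + spec$n_complexes + spec$n_parallel_routes)
  iso_steps <- decorated[seq_len(spec$n_isozyme_pairs)]
  cpx_steps <- decorated[spec$n_isozyme_pairs + seq_len(spec$n_complexes)]
  par_steps <- decorated[spec$n_isozyme_pairs + spec$n_complexes +
                         seq_len(spec$n_parallel_routes)]

  n_genes_needed <- n_steps + spec$n_isozyme_pairs + spec$n_complexes
  gene_pool <- sprintf("YSN%03d%s", sample(seq_len(n_genes_needed)),
                       rep_len(c("W", "C"), n_genes_needed))
  gi <- 0L
  next_gene <- function() {
    gi <<- gi + 1L
    gene_pool[gi]
  }

  mets <- list(); rxns <- list()
  essential <- character()
  sl_pairs <- list()
  add_met <- function(id, compartment = comp[1], boundary = FALSE) {
    mets[[length(mets) + 1L]] <<- tibble::tibble(
      id = id, name = id, compartment = compartment,
      chebi = list(character()), boundary = boundary)
  }
  add_rxn <- function(id, stoich, lb, ub, gpr = NA_character_) {
    rxns[[length(rxns) + 1L]] <<- tibble::tibble(
      id = id, name = id, lb = lb, ub = ub,
      stoich = list(stoich), gpr = gpr)
  }

  step_no <- 0L
  terminals <- character()
  for (p in seq_len(P)) {
    for (j in 0:L) {
      add_met(sprintf("m_p%d_%d", p, j),
              compartment = comp[((j) %% length(comp)) + 1L])
    }
    add_rxn(sprintf("EX_sub%d", p),
            stats::setNames(-1, sprintf("m_p%d_0", p)), lb = -10, ub = 1000)
    for (j in seq_len(L)) {
      step_no <- step_no + 1L
      rid <- sprintf("R_p%d_s%d", p, j)
      st <- stats::setNames(c(-1, 1),
                            c(sprintf("m_p%d_%d", p, j - 1),
                              sprintf("m_p%d_%d", p, j)))
      if (step_no %in% iso_steps) {
        ga <- next_gene(); gb <- next_gene()
        add_rxn(rid, st, 0, 1000, gpr = sprintf("(%s or %s)", ga, gb))
        sl_pairs[[length(sl_pairs) + 1L]] <- sort(c(ga, gb))
      } else if (step_no %in% cpx_steps) {
        ga <- next_gene(); gb <- next_gene()
        add_rxn(rid, st, 0, 1000, gpr = sprintf("(%s and %s)", ga, gb))
        essential <- c(essential, ga, gb)
      } else if (step_no %in% par_steps) {
        g <- next_gene()
        add_rxn(rid, st, 0, 1000, gpr = g)
        add_rxn(paste0(rid, "_alt"), st, 0, 1000)  # spontaneous bypass
      } else {
        g <- next_gene()
        add_rxn(rid, st, 0, 1000, gpr = g)
        essential <- c(essential, g)
      }
    }
    terminals <- c(terminals, sprintf("m_p%d_%d", p, L))
  }
  add_rxn("biomass", stats::setNames(rep(-1, length(terminals)), terminals),
          lb = 0, ub = 1000)

  dead_end_mets <- character()
  blocked_rxns <- character()
  anchor <- "m_p1_1"  # producible pathway metabolite hosting the side branches
  for (k in seq_len(spec$n_dead_ends)) {
    mid <- sprintf("m_de%d", k)
    add_met(mid)
    add_rxn(sprintf("R_de%d", k), stats::setNames(c(-1, 1), c(anchor, mid)),
            0, 1000)
    dead_end_mets <- c(dead_end_mets, mid)
    blocked_rxns <- c(blocked_rxns, sprintf("R_de%d", k))
  }
  for (k in seq_len(spec$n_blocked)) {
    mid1 <- sprintf("m_blk%d_mid", k)
    tip <- sprintf("m_blk%d_tip", k)
    add_met(mid1); add_met(tip)
    add_rxn(sprintf("R_blk%d_a", k),
            stats::setNames(c(-1, 1), c(anchor, mid1)), 0, 1000)
    add_rxn(sprintf("R_blk%d_b", k),
            stats::setNames(c(-1, 1), c(mid1, tip)), 0, 1000)
    dead_end_mets <- c(dead_end_mets, tip)
    blocked_rxns <- c(blocked_rxns, sprintf("R_blk%d_a", k),
                      sprintf("R_blk%d_b", k))
  }

  model <- metabolic_model(
    sprintf("toy_seed%d", spec$seed),
    dplyr::bind_rows(mets), dplyr::bind_rows(rxns), "biomass"
  )
  truth <- structure(list(
    essential_genes = sort(essential),
    synthetic_lethal_pairs = if (length(sl_pairs)) {
      normalize_pairs(tibble::tibble(
        gene_a = vapply(sl_pairs, `[`, character(1), 1),
        gene_b = vapply(sl_pairs, `[`, character(1), 2)))
    } else tibble::tibble(gene_a = character(), gene_b = character()),
    dead_end_metabolites = sort(dead_end_mets),
    blocked_reactions = sort(blocked_rxns)
  ), class = "toy_model_truth")
  list(model = model, truth = truth)
}

#' Noisy reference lists from planted truth
#'
#' Emulates imperfect literature-derived reference lists: each gene's
#' essentiality label, and each gene pair's synthetic-lethality label, is
#' flipped independently with probability `flip_rate`. At rate 0 the lists
#' equal the truth; as the rate approaches 0.5 the expected MCC of a
#' perfect predictor scored against the noisy list approaches 0 (the
#' expectation is computable in closed form from the two binomial flip
#' counts).
#'
#' @param truth a `toy_model_truth`.
#' @param genes the gene universe the lists cover (typically the model's
#'   genes).
#' @param flip_rate label flip probability in \[0, 0.5).
#' @param seed integer seed.
#' @param include_pairs also emit the noisy pair list (default TRUE; the
#'   pair universe is quadratic in the gene count, so studies that only
#'   need the essential list can skip it).
#' @return list with `essential` (character vector) and `pairs` (tibble
#'   `gene_a`/`gene_b`, `NULL` when skipped).
#' @export
generate_reference_lists <- function(truth, genes, flip_rate = 0, seed = 1L,
                                     include_pairs = TRUE) {
  stopifnot(flip_rate >= 0, flip_rate < 0.5)
  restore <- local_seed(seed)
  on.exit(restore())
  genes <- sort(genes)
  is_ess <- genes %in% truth$essential_genes
  flip <- stats::runif(length(genes)) < flip_rate
  essential <- genes[xor(is_ess, flip)]

  if (!include_pairs) {
    return(list(essential = essential, pairs = NULL))
  }
  if (length(genes) >= 2) {
    cmb <- utils::combn(genes, 2)
    pair_tab <- tibble::tibble(gene_a = cmb[1, ], gene_b = cmb[2, ])
    truth_key <- paste(truth$synthetic_lethal_pairs$gene_a,
                       truth$synthetic_lethal_pairs$gene_b)
    is_sl <- paste(pair_tab$gene_a, pair_tab$gene_b) %in% truth_key
    flip_p <- stats::runif(nrow(pair_tab)) < flip_rate
    pairs <- pair_tab[xor(is_sl, flip_p), ]
  } else {
    pairs <- tibble::tibble(gene_a = character(), gene_b = character())
  }
  list(essential = essential, pairs = pairs)
}

#' Simulated chemostat growth observations
#'
#' Runs FBA at each grid point and perturbs the optimum with multiplicative
#' gaussian noise (mean 1, sd `noise_sd`), truncated at zero — a simple
#' emulation of measured growth-rate tables with uptake constraints. The
#' uptake columns of `constraint_grid` become the observation's constrained
#' exchange fluxes.
#'
#' @param model a `metabolic_model`.
#' @param constraint_grid tibble: `condition` plus one non-negative uptake
#'   column per exchange key.
#' @param noise_sd standard deviation of the multiplicative noise.
#' @param seed integer seed.
#' @return observation tibble (`condition`, uptake columns, `growth_rate`).
#' @export
generate_growth_observations <- function(model, constraint_grid,
                                         noise_sd = 0, seed = 1L) {
  restore <- local_seed(seed)
  on.exit(restore())
  keys <- setdiff(names(constraint_grid), "condition")
  grid <- constraint_grid
  grid$growth_rate <- 0
  scan <- constrained_growth_scan(model, grid, keys)
  if (any(scan$status != "optimal")) {
    stop("model not feasible/bounded over the constraint grid")
  }
  noise <- pmax(stats::rnorm(nrow(grid), mean = 1, sd = noise_sd), 0)
  grid$growth_rate <- scan$predicted_flux * noise
  grid
}
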