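# Small models built in code, reused across test files.

rxn_row <- function(id, stoich, lb, ub, gpr = NA_character_) {
  tibble::tibble(id = id, name = id, lb = lb, ub = ub,
                 stoich = list(stoich), gpr = gpr)
}

met_tbl <- function(ids, boundary = rep(FALSE, length(ids)),
                    chebi = NULL) {
  tibble::tibble(id = ids, name = ids, compartment = "c",
                 chebi = chebi %||% rep(list(character()), length(ids)),
                 boundary = boundary)
}

# EX_A (uptake 10) -> A, A -> B capped at 5, B -> biomass
chain_model <- function() {
  metabolic_model(
    "chain",
    met_tbl(c("A", "B")),
    dplyr::bind_rows(
      rxn_row("EX_A", c(A = -1), -10, 1000),
      rxn_row("R1", c(A = -1, B = 1), 0, 5, gpr = "G1"),
      rxn_row("biomass", c(B = -1), 0, 1000)
    ),
    "biomass"
  )
}

# Branched 8-reaction toy with a capped favourable route and a costly
# bypass; optimum is a genuine multi-constraint vertex, good oracle fodder.
branched_model <- function() {
  metabolic_model(
    "branched",
    met_tbl(c("A", "B", "C", "D")),
    dplyr::bind_rows(
      rxn_row("EX_A", c(A = -1), -10, 1000),
      rxn_row("EX_C", c(C = -1), 0, 1000),          # secretion only
      rxn_row("R1", c(A = -1, B = 1), 0, 6, gpr = "G1"),
      rxn_row("R2", c(A = -1, C = 1), 0, 1000, gpr = "(G2 and G3)"),
      rxn_row("R3", c(C = -2, B = 1), 0, 1000, gpr = "G4"),
      rxn_row("R4", c(B = -1, D = 1), 0, 1000, gpr = "(G5 or G6)"),
      rxn_row("R5", c(B = -1, D = 2), 0, 3, gpr = "G7"),
      rxn_row("biomass", c(D = -1), 0, 1000)
    ),
    "biomass"
  )
}

# Chain plus a free reversible internal 2-reaction loop B <-> C.
loop_model <- function(force_loop = FALSE) {
  lo <- if (force_loop) 20 else -1000
  metabolic_model(
    "loopy",
    met_tbl(c("A", "B", "C")),
    dplyr::bind_rows(
      rxn_row("EX_A", c(A = -1), -10, 1000),
      rxn_row("R1", c(A = -1, B = 1), 0, 1000),
      rxn_row("L1", c(B = -1, C = 1), lo, 1000),
      rxn_row("L2", c(C = -1, B = 1), -1000, 1000),
      rxn_row("biomass", c(B = -1), 0, 1000)
    ),
    "biomass"
  )
}

# Respiration-style model: biomass needs 1 glc + 2 o2, so at fixed oxygen
# the optimum plateaus once glucose stops being the binding constraint.
respiration_model <- function() {
  metabolic_model(
    "resp",
    met_tbl(c("glc", "o2", "prec")),
    dplyr::bind_rows(
      rxn_row("EX_glc", c(glc = -1), -10, 1000),
      rxn_row("EX_o2", c(o2 = -1), -20, 1000),
      rxn_row("RESP", c(glc = -1, o2 = -2, prec = 1), 0, 1000),
      rxn_row("biomass", c(prec = -1), 0, 1000)
    ),
    "biomass"
  )
}

random_toy_model <- function(seed) {
  set.seed(seed)
  generate_toy_model(toy_model_spec(
    n_linear_pathways = sample(2:3, 1),
    pathway_length = sample(3:5, 1),
    n_isozyme_pairs = sample(0:2, 1),
    n_complexes = sample(0:2, 1),
    n_parallel_routes = sample(0:1, 1),
    n_dead_ends = sample(0:2, 1),
    n_blocked = sample(0:1, 1),
    seed = seed
  ))
}

toy5_path <- function() system.file("extdata", "toy5.xml", package = "fbascreen")
toy_flat_path <- function() system.file("extdata", "toy_flat.tsv", package = "fbascreen")
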