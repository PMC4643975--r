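test_that("FBA finds the bottleneck-limited optimum on a linear chain", {
  m <- chain_model()
  res <- solve_fba(m)
  expect_equal(res$status, "optimal")
  expect_equal(res$objective_value, 5)
  # mass balance holds at the solution
  expect_lt(max(abs(stoich_matrix(m) %*% res$fluxes)), 1e-8)
})

test_that("with all exchange uptake closed the optimum is zero", {
  m <- chain_model()
  m$reactions$lb[m$reactions$exchange] <- 0
  expect_equal(solve_fba(m)$objective_value, 0)
})

test_that("branched toy optimum equals the vertex-enumeration oracle", {
  m <- branched_model()
  res <- solve_fba(m)
  want <- oracle_fba(m)
  expect_equal(res$objective_value, want$opt, tolerance = 1e-7)
  expect_equal(res$objective_value, 11)  # hand-derived: 6 via R1 + 2 via R2/R3, R5 capped
})

test_that("FBA optimum is invariant to row scaling and to row/column order", {
  m <- branched_model()
  base <- solve_fba(m)$objective_value
  scaled <- m
  scaled$reactions$stoich <- lapply(scaled$reactions$stoich, function(s) {
    s[names(s) == "B"] <- 3 * s[names(s) == "B"]  # scale metabolite-B row
    s
  })
  expect_equal(solve_fba(scaled)$objective_value, base, tolerance = 1e-8)
  perm <- m
  set.seed(2)
  perm$metabolites <- perm$metabolites[sample(nrow(perm$metabolites)), ]
  ord <- sample(nrow(perm$reactions))
  perm$reactions <- perm$reactions[ord, ]
  expect_equal(solve_fba(perm)$objective_value, base, tolerance = 1e-8)
})

test_that("relaxing any single bound never decreases the optimum", {
  set.seed(17)
  for (s in 1:5) {
    tm <- random_toy_model(s)
    base <- solve_fba(tm$model)$objective_value
    for (j in sample(nrow(tm$model$reactions), 4)) {
      relaxed <- tm$model
      relaxed$reactions$lb[j] <- relaxed$reactions$lb[j] - 5
      relaxed$reactions$ub[j] <- relaxed$reactions$ub[j] + 5
      expect_gte(solve_fba(relaxed)$objective_value, base - 1e-8)
    }
  }
})

test_that("l1-min FBA preserves the optimum and reproduces unique solutions", {
  m <- chain_model()
  plain <- solve_fba(m)
  l1 <- solve_fba_l1min(m)
  expect_equal(l1$objective_value, plain$objective_value, tolerance = 1e-8)
  expect_equal(l1$fluxes, plain$fluxes, tolerance = 1e-7)
})

test_that("l1-min zeroes a free internal loop", {
  m <- loop_model()
  l1 <- solve_fba_l1min(m)
  expect_equal(l1$objective_value, 10, tolerance = 1e-7)
  expect_equal(unname(l1$fluxes[c("L1", "L2")]), c(0, 0), tolerance = 1e-7)
})

test_that("l1-min norm is minimal among random alternate optima", {
  m <- branched_model()
  l1 <- solve_fba_l1min(m)
  opt <- solve_fba(m)$objective_value
  S <- stoich_matrix(m)
  lb <- m$reactions$lb; ub <- m$reactions$ub
  j <- match("biomass", m$reactions$id)
  lb[j] <- opt - 1e-9; ub[j] <- opt + 1e-9
  set.seed(5)
  for (i in 1:50) {
    alt <- solve_lp(stats::runif(length(lb), -1, 1), S, rep(0, nrow(S)), lb, ub)
    expect_equal(alt$status, "optimal")
    expect_lte(l1$l1_norm, sum(abs(alt$solution)) + 1e-6)
  }
})

test_that("flux variability matches the per-reaction oracle, including signs", {
  m <- branched_model()
  fva <- flux_variability(m)
  for (i in seq_len(nrow(fva))) {
    want <- oracle_fva_range(m, fva$reaction_id[i])
    expect_equal(c(fva$v_min[i], fva$v_max[i]), want, tolerance = 1e-7,
                 info = fva$reaction_id[i])
  }
  expect_true(all(fva$v_min <= fva$v_max + 1e-9))
  # exchange feeding the network spans negative (uptake) values
  expect_lt(fva$v_min[fva$reaction_id == "EX_A"], 0)
})

test_that("a reaction downstream of an absent producer is stuck at (0, 0)", {
  m <- metabolic_model(
    "stub", met_tbl(c("A", "B", "C")),
    dplyr::bind_rows(
      rxn_row("EX_A", c(A = -1), -10, 1000),
      rxn_row("R1", c(A = -1, B = 1), 0, 1000),
      rxn_row("R2", c(C = -1, B = 1), 0, 1000),  # C has no producer
      rxn_row("biomass", c(B = -1), 0, 1000)
    ), "biomass")
  fva <- flux_variability(m, "R2")
  expect_equal(c(fva$v_min, fva$v_max), c(0, 0))
})

test_that("infeasible constraint sets raise the medium diagnostic", {
  m <- chain_model()
  m$reactions$lb[m$reactions$id == "biomass"] <- 100  # demands more than uptake allows
  expect_error(flux_variability(m), "infeasible, check medium")
})

test_that("blocked reactions are exactly the planted ones and shrink under relaxation", {
  tm <- generate_toy_model(toy_model_spec(n_dead_ends = 0, n_blocked = 1, seed = 13))
  expect_setequal(blocked_reactions(tm$model), tm$truth$blocked_reactions)
  expect_length(tm$truth$blocked_reactions, 2)

  # opening a previously closed exchange can only shrink the blocked set
  m <- tm$model
  closed <- m
  closed$reactions$lb[closed$reactions$id == "EX_sub2"] <- 0
  closed$reactions$ub[closed$reactions$id == "EX_sub2"] <- 0
  b_closed <- blocked_reactions(closed)
  b_open <- blocked_reactions(m)
  expect_true(all(b_open %in% b_closed))
})

test_that("blocked-set differences across biomass variants touch only coupled reactions", {
  tm <- generate_toy_model(toy_model_spec(n_linear_pathways = 2, pathway_length = 3,
                                          n_isozyme_pairs = 0, n_complexes = 0,
                                          n_parallel_routes = 0, n_dead_ends = 0,
                                          n_blocked = 0, seed = 2))
  m <- tm$model
  # biomass A: both terminals; biomass B: only pathway 1's terminal
  bA <- blocked_reactions(m)
  mB <- set_biomass(m, biomass_definition("p1only", stats::setNames(-1, "m_p1_3")))
  bB <- blocked_reactions(mB)
  diff <- union(setdiff(bA, bB), setdiff(bB, bA))
  # only pathway-2 reactions (decoupled from the p1-only biomass) and the two
  # objective reactions themselves may change status
  expect_true(all(grepl("_p2_|sub2|biomass", diff)))
})

test_that("dead-end detection matches the sign-pattern oracle and reports clauses", {
  for (s in c(1, 8)) {
    tm <- random_toy_model(s)
    de <- dead_end_metabolites(tm$model)
    expect_setequal(de$metabolite_id, oracle_dead_ends(tm$model))
    expect_setequal(de$metabolite_id, tm$truth$dead_end_metabolites)
  }
  # a metabolite in a single reversible reaction is a dead end by clause (a)
  m <- metabolic_model(
    "one", met_tbl(c("A", "B")),
    dplyr::bind_rows(rxn_row("EX_A", c(A = -1), -10, 10),
                     rxn_row("R1", c(A = -1, B = 1), -10, 10),
                     rxn_row("biomass", c(A = -1), 0, 10)),
    "biomass")
  de <- dead_end_metabolites(m)
  expect_true("B" %in% de$metabolite_id)
  row <- de[de$metabolite_id == "B", ]
  expect_true(row$single_reaction)
  # B in one reversible reaction can be both made and unmade, so clause (b)
  # does not fire for it
  expect_true(is.na(row$orphan_direction))
  # produced-by-one-irreversible, consumed-by-none: clause (b)
  m2 <- metabolic_model(
    "two", met_tbl(c("A", "B", "C")),
    dplyr::bind_rows(rxn_row("EX_A", c(A = -1), -10, 10),
                     rxn_row("R1", c(A = -1, B = 1), 0, 10),
                     rxn_row("R2", c(A = -1, B = 1, C = 1), 0, 10),
                     rxn_row("biomass", c(B = -1), 0, 10)),
    "biomass")
  de2 <- dead_end_metabolites(m2)
  expect_equal(de2$orphan_direction[de2$metabolite_id == "C"], "never_consumed")
})
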