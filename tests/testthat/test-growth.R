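test_that("predictions scale linearly while one nutrient is the binding constraint", {
  m <- respiration_model()
  obs <- tibble::tibble(condition = c("lo", "hi"), glc = c(2, 4),
                        growth_rate = c(NA_real_, NA_real_))
  scan <- constrained_growth_scan(m, obs, "glc")
  expect_equal(scan$predicted_flux[2], 2 * scan$predicted_flux[1], tolerance = 1e-9)
  expect_equal(scan$predicted_flux[1], 2)  # 1 glc -> 1 biomass, O2 ample
})

test_that("beyond the oxygen-limited ceiling extra glucose leaves the optimum flat", {
  m <- respiration_model()
  m <- set_bounds(m, "EX_o2", lb = -10)       # fixed O2 supply
  obs <- tibble::tibble(condition = paste0("g", 1:4), glc = c(2, 4, 6, 12),
                        growth_rate = NA_real_)
  scan <- constrained_growth_scan(m, obs, "glc")
  # biomass needs 2 O2 per glc: ceiling at 5
  expect_equal(scan$predicted_flux, c(2, 4, 5, 5), tolerance = 1e-9)
})

test_that("a scan equals per-point independent FBA", {
  m <- respiration_model()
  obs <- tibble::tibble(condition = paste0("c", 1:5),
                        glc = c(1, 2, 3, 4, 5), o2 = c(10, 8, 6, 4, 2),
                        growth_rate = NA_real_)
  scan <- constrained_growth_scan(m, obs, c("glc", "o2"))
  for (i in 1:5) {
    mi <- set_bounds(m, "EX_glc", lb = -obs$glc[i])
    mi <- set_bounds(mi, "EX_o2", lb = -obs$o2[i])
    expect_equal(scan$predicted_flux[i], solve_fba(mi)$objective_value,
                 tolerance = 1e-9)
  }
})

test_that("joint constraints reveal the limiting-nutrient switch", {
  m <- respiration_model()
  obs <- tibble::tibble(condition = paste0("c", 1:4),
                        glc = c(1, 2, 4, 8), o2 = rep(6, 4),
                        growth_rate = NA_real_)
  scan <- constrained_growth_scan(m, obs, c("glc", "o2"))
  expect_equal(scan$predicted_flux, c(1, 2, 3, 3), tolerance = 1e-9)
})

test_that("correlation handles the canonical cases and rejects degenerate input", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(growth_correlation(2 * x, x), 1.0)
  expect_equal(growth_correlation(-x, x), -1.0)
  # fixed five-point pair, hand-evaluated product-moment formula
  y <- c(2, 1, 4, 3, 6)
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(growth_correlation(x, y), num / den, tolerance = 1e-12)
  expect_equal(growth_correlation(x, y, method = "spearman"),
               stats::cor(x, y, method = "spearman"))
  expect_error(growth_correlation(rep(1, 5), x), "zero variance")
  expect_error(growth_correlation(c(1, 2), c(1, 2)))
  expect_error(growth_correlation(c(1, 2, NA), c(1, 2, 3)), "missing")
})

test_that("a forced loop tops the l1-min diagnostic ranking", {
  m <- loop_model(force_loop = TRUE)
  rank <- diagnose_high_flux_reactions(m)
  expect_equal(rank$reaction_id[1:2], c("L1", "L2"))
  expect_gte(rank$abs_flux[1], 20)
  # without the forcing bound the loop carries nothing and the chain ordering
  # follows pathway stoichiometry (unique solution)
  free <- diagnose_high_flux_reactions(loop_model())
  expect_equal(free$abs_flux[free$reaction_id == "L1"], 0, tolerance = 1e-8)
  expect_equal(free$abs_flux[free$reaction_id == "R1"], 10, tolerance = 1e-8)
  # ties broken by reaction id
  expect_equal(free$reaction_id[free$abs_flux < 1e-8], sort(c("L1", "L2")))
})

test_that("exchange-only models yield an empty diagnostic", {
  m <- metabolic_model("exo", met_tbl("A"),
                       dplyr::bind_rows(rxn_row("EX_A", c(A = -1), -10, 1000),
                                        rxn_row("EX_A2", c(A = 1), -10, 1000)),
                       "EX_A2")
  expect_equal(nrow(diagnose_high_flux_reactions(m)), 0)
})

test_that("removing a zero-flux reaction changes nothing; removing a shortcut lowers it", {
  # model with a planted shortcut that inflates the optimum
  m <- metabolic_model(
    "shortcut", met_tbl(c("A", "B")),
    dplyr::bind_rows(
      rxn_row("EX_A", c(A = -1), -10, 1000),
      rxn_row("R1", c(A = -1, B = 1), 0, 1000),
      rxn_row("CHEAT", c(B = 2), 0, 5),            # makes B from nothing
      rxn_row("biomass", c(B = -1), 0, 1000)
    ), "biomass")
  obs <- tibble::tibble(condition = c("a", "b", "c"), A = c(1, 2, 3),
                        growth_rate = c(1, 2, 3))
  res <- remove_reaction_and_rescan(m, "CHEAT", obs, "A")
  expect_true(all(res$after$predicted_flux < res$before$predicted_flux))
  expect_equal(res$after$predicted_flux, c(1, 2, 3), tolerance = 1e-9)
  expect_gte(res$correlation_after, 0.999)

  # a reaction idle at every scan point: identical predictions
  m2 <- loop_model()
  obs2 <- tibble::tibble(condition = c("a", "b", "c"), A = c(1, 2, 3),
                         growth_rate = c(1, 2, 3))
  res2 <- remove_reaction_and_rescan(m2, "L1", obs2, "A")
  expect_equal(res2$after$predicted_flux, res2$before$predicted_flux,
               tolerance = 1e-9)
  expect_error(remove_reaction_and_rescan(m2, "L1X", obs2, "A"), "nearest ids")
})

test_that("soft and hard reaction removal give identical optima", {
  tm <- generate_toy_model(toy_model_spec(seed = 21))
  m <- tm$model
  target <- "R_p1_s2"
  soft <- set_bounds(m, target, lb = 0, ub = 0)
  hard <- m
  hard$reactions <- hard$reactions[hard$reactions$id != target, ]
  expect_equal(fba_growth(solve_fba(soft)), fba_growth(solve_fba(hard)),
               tolerance = 1e-9)
})

test_that("the aspartate-transport id resolver knows the per-model ids", {
  expect_equal(aspartate_transport_id("Yeast 4"), "r_1163")
  expect_equal(aspartate_transport_id("Yeast 6"), "r_1117")
  expect_equal(aspartate_transport_id("Yeast 7"), "r_1117")
  expect_equal(aspartate_transport_id("iAZ900"), "ASSPt2M")
  expect_equal(aspartate_transport_id("iND750"), "ASPt2M")
  expect_equal(aspartate_transport_id("iIN800"), "AGC1_2")
  expect_equal(aspartate_transport_id("iMM904"), "ASPt2m")
  expect_true(is.na(aspartate_transport_id("iFF708")))
  expect_true(is.na(aspartate_transport_id("never heard of it")))
})

test_that("observation tables read from TSV and reject negative uptakes", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("condition\tglc\to2\tgrowth_rate",
               "c1\t1\t10\t0.1", "c2\t2\t8\t0.2"), p)
  obs <- read_growth_observations(p)
  expect_equal(nrow(obs), 2)
  expect_equal(obs$glc, c(1, 2))
  writeLines(c("condition\tglc\tgrowth_rate", "c1\t-1\t0.1"), p)
  expect_error(read_growth_observations(p), "non-negative")
})
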