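test_that("applying a medium closes everything, then opens exactly the listed uptakes", {
  tm <- generate_toy_model(toy_model_spec(n_linear_pathways = 3, seed = 6))
  med <- medium_definition("two-substrate",
                           tibble::tibble(key = c("m_p1_0", "m_p2_0"),
                                          lb = c(-10, -5), ub = c(1000, 1000)))
  m2 <- apply_medium(tm$model, med)
  ex <- m2$reactions[m2$reactions$exchange, ]
  expect_setequal(ex$id[ex$lb < 0], c("EX_sub1", "EX_sub2"))
  expect_equal(ex$lb[ex$id == "EX_sub2"], -5)
  # idempotent
  expect_true(model_equal(m2, apply_medium(m2, med)))
})

test_that("unresolvable medium components are a hard error listing candidates", {
  m <- chain_model()
  med <- medium_definition("bad", tibble::tibble(key = "unobtainium",
                                                 lb = -1, ub = 1000))
  expect_error(apply_medium(m, med), "cannot resolve.*unobtainium")
  expect_error(apply_medium(m, med), "exchanged metabolites")
})

test_that("medium keys resolve by metabolite id, reaction id and ChEBI id", {
  mb <- read_flat_model(toy_flat_path())
  for (key in c("glc_c", "EX_glc", "CHEBI:17234")) {
    med <- medium_definition("one", tibble::tibble(key = key, lb = -3, ub = 1000))
    m2 <- apply_medium(mb, med)
    expect_equal(m2$reactions$lb[m2$reactions$id == "EX_glc"], -3, info = key)
  }
})

test_that("per-model supplements open additional exchanges for that model only", {
  tm <- generate_toy_model(toy_model_spec(n_linear_pathways = 2, seed = 4))
  med <- medium_definition("p1-only",
                           tibble::tibble(key = "m_p1_0", lb = -10, ub = 1000),
                           supplements = stats::setNames(list("m_p2_0"),
                                                         tm$model$model_id))
  m2 <- apply_medium(tm$model, med)
  expect_equal(m2$reactions$lb[m2$reactions$id == "EX_sub2"], -1000)
  other <- tm$model; other$model_id <- "someone_else"
  # without its supplement the second substrate stays closed and the model starves
  m3 <- apply_medium(other, med)
  expect_equal(m3$reactions$lb[m3$reactions$id == "EX_sub2"], 0)
  expect_lt(fba_growth(solve_fba(m3)), 1e-6)
  expect_gte(fba_growth(solve_fba(m2)), 1e-6)
})

test_that("biomass substitution fails listing every missing component", {
  m <- chain_model()
  bad <- biomass_definition("wish", c(B = -1, unicorn = -2, pixie = -1))
  err <- tryCatch(set_biomass(m, bad), error = conditionMessage)
  expect_match(err, "unicorn")
  expect_match(err, "pixie")
  expect_error(biomass_definition("nothing", c(B = 1)), "consumes nothing")
})

test_that("identity biomass substitution leaves screen results unchanged", {
  tm <- generate_toy_model(toy_model_spec(n_isozyme_pairs = 1, n_complexes = 1,
                                          seed = 12))
  m <- tm$model
  own <- m$reactions$stoich[[match("biomass", m$reactions$id)]]
  sub <- set_biomass(m, biomass_definition("own_copy", own))
  s1 <- single_deletion_screen(m)
  s2 <- single_deletion_screen(sub)
  expect_equal(s1$genes$essential, s2$genes$essential)
  expect_equal(s1$wild_type_flux, s2$wild_type_flux, tolerance = 1e-8)
})

test_that("changing one biomass precursor moves exactly that pathway's genes", {
  # pathway 2 genes are essential only when biomass demands pathway 2's terminal
  tm <- generate_toy_model(toy_model_spec(n_linear_pathways = 2, pathway_length = 3,
                                          n_isozyme_pairs = 0, n_complexes = 0,
                                          n_parallel_routes = 0, n_dead_ends = 0,
                                          n_blocked = 0, seed = 19))
  m <- tm$model
  both <- set_biomass(m, biomass_definition("both", c(m_p1_3 = -1, m_p2_3 = -1)))
  p1 <- set_biomass(m, biomass_definition("p1", c(m_p1_3 = -1)))
  e_both <- essential_genes(single_deletion_screen(both))
  e_p1 <- essential_genes(single_deletion_screen(p1))
  moved <- setdiff(e_both, e_p1)
  p2_reactions <- m$reactions[grepl("_p2_", m$reactions$id), ]
  p2_genes <- unique(unlist(lapply(p2_reactions$gpr[!is.na(p2_reactions$gpr)],
                                   function(g) gpr_genes(parse_gpr(g)))))
  expect_setequal(moved, p2_genes)
  expect_length(setdiff(e_p1, e_both), 0)
})

test_that("medium application and biomass substitution commute", {
  tm <- generate_toy_model(toy_model_spec(n_linear_pathways = 2, seed = 8))
  med <- medium_definition("m", tibble::tibble(key = c("m_p1_0", "m_p2_0"),
                                               lb = c(-4, -7), ub = c(1000, 1000)))
  bio <- biomass_definition("b", c(m_p1_5 = -1))
  a <- set_biomass(apply_medium(tm$model, med), bio)
  b <- apply_medium(set_biomass(tm$model, bio), med)
  expect_true(model_equal(a, b))
})

test_that("tightening a medium never increases the optimum", {
  tm <- generate_toy_model(toy_model_spec(n_linear_pathways = 3, seed = 15))
  full <- medium_definition("full", tibble::tibble(
    key = c("m_p1_0", "m_p2_0", "m_p3_0"), lb = rep(-10, 3), ub = rep(1000, 3)))
  tight <- medium_definition("tight", tibble::tibble(
    key = c("m_p1_0", "m_p2_0"), lb = rep(-10, 2), ub = rep(1000, 2)))
  f_full <- fba_growth(solve_fba(apply_medium(tm$model, full)))
  f_tight <- fba_growth(solve_fba(apply_medium(tm$model, tight)))
  expect_lte(f_tight, f_full + 1e-9)
})

test_that("medium and biomass YAML definitions round-trip", {
  med <- minimal_glucose_medium(supplements = list(toyX = c("fe2_e")))
  p <- withr::local_tempfile(fileext = ".yaml")
  write_medium(med, p)
  back <- read_medium(p)
  expect_equal(back$name, med$name)
  expect_equal(back$uptake_bounds, med$uptake_bounds)
  expect_equal(back$supplements$toyX, "fe2_e")

  bio <- biomass_definition("common", c(prec_c = -1, atp_c = -30.5))
  pb <- withr::local_tempfile(fileext = ".yaml")
  write_biomass(bio, pb)
  expect_equal(read_biomass(pb)$stoichiometry, bio$stoichiometry)

  shipped <- read_medium(system.file("extdata", "media", "min-glu.yaml",
                                     package = "fbascreen"))
  expect_equal(shipped$name, "Min-Glu")
  mb <- apply_medium(read_flat_model(toy_flat_path()), shipped)
  expect_equal(fba_growth(solve_fba(mb)), 10)
})
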