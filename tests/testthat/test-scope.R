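scope_models <- function() {
  mk <- function(id, genes, chebi_ids) {
    mets <- tibble::tibble(
      id = paste0("m", seq_along(chebi_ids)), name = paste0("m", seq_along(chebi_ids)),
      compartment = "c", chebi = chebi_ids, boundary = FALSE)
    rxns <- dplyr::bind_rows(
      rxn_row("EX_m1", stats::setNames(-1, "m1"), -10, 1000),
      rxn_row("R1", stats::setNames(c(-1, 1), c("m1", mets$id[nrow(mets)])), 0, 1000,
              gpr = paste0("(", paste(genes, collapse = " and "), ")")),
      rxn_row("biomass", stats::setNames(-1, mets$id[nrow(mets)]), 0, 1000))
    metabolic_model(id, mets, rxns, "biomass")
  }
  list(
    mk("mA", c("G1", "G2", "G3"), list("CHEBI:1", c("CHEBI:2", "CHEBI:9"), "CHEBI:3")),
    mk("mB", c("G1", "G2", "G3"), list("CHEBI:1", "CHEBI:2", "CHEBI:3")),
    mk("mC", c("G7", "G8"), list("CHEBI:7", "CHEBI:8"))
  )
}

test_that("gene incidence reflects overlap structure", {
  ms <- scope_models()
  gi <- gene_incidence(ms)
  expect_equal(dim(gi), c(3, 5))
  expect_equal(unname(rowSums(unclass(gi))), c(3, 3, 2))
  # identical gene sets give identical rows at distance zero
  d <- pairwise_distance(gi)
  expect_equal(d["mA", "mB"], 0)
  # disjoint models: block pattern, all features differ
  expect_equal(d["mA", "mC"]^2, 5, tolerance = 1e-12)
})

test_that("metabolite incidence uses only the first ChEBI id of each metabolite", {
  ms <- scope_models()
  mi <- metabolite_incidence(ms)
  expect_false("CHEBI:9" %in% colnames(mi))   # second id of a redundant annotation
  expect_true("CHEBI:2" %in% colnames(mi))
  expect_equal(sum(unclass(mi)["mA", ] * unclass(mi)["mB", ]), 3)
})

test_that("models without ChEBI annotation warn and produce an all-zero row", {
  ms <- scope_models()
  bare <- generate_toy_model(toy_model_spec(seed = 2))$model   # no ChEBI ids
  expect_warning(mi <- metabolite_incidence(c(ms[1:2], list(bare))),
                 "no ChEBI annotation")
  expect_equal(sum(unclass(mi)[bare$model_id, ]), 0)
})

test_that("pairwise distances equal an explicit double loop for every metric", {
  set.seed(77)
  m <- matrix(sample(0:1, 6 * 12, replace = TRUE), 6, 12,
              dimnames = list(paste0("mod", 1:6), paste0("f", 1:12)))
  class(m) <- c("incidence_matrix", class(m))
  for (metric in c("euclidean", "hamming", "jaccard")) {
    d <- pairwise_distance(m, metric)
    expect_true(isSymmetric(unname(d)))
    expect_equal(unname(diag(d)), rep(0, 6))
    for (i in 1:6) for (j in 1:6) {
      a <- unclass(m)[i, ]; b <- unclass(m)[j, ]
      want <- switch(metric,
        euclidean = sqrt(sum((a - b)^2)),
        hamming = sum(a != b),
        jaccard = if (sum(a | b) == 0) 0 else 1 - sum(a & b) / sum(a | b))
      expect_equal(d[i, j], want, tolerance = 1e-12)
    }
  }
})

test_that("hierarchical clustering merges the close pair first and recovers planted blocks", {
  d <- matrix(c(0, 1, 9, 1, 0, 9.5, 9, 9.5, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  hc <- hierarchical_cluster(d)
  expect_equal(sort(stats::cutree(hc, 2)[c("x", "y")]), c(x = 1, y = 1))
  expect_true(all(diff(hc$height) >= -1e-12))

  # two planted blocks with inter-block distance >> intra
  set.seed(3)
  block <- rbind(matrix(sample(0:1, 4 * 6, TRUE, prob = c(0.1, 0.9)), 4, 6),
                 matrix(0L, 4, 6))
  other <- rbind(matrix(0L, 4, 6),
                 matrix(sample(0:1, 4 * 6, TRUE, prob = c(0.1, 0.9)), 4, 6))
  inc <- cbind(block, other)
  rownames(inc) <- paste0("m", 1:8)
  colnames(inc) <- paste0("f", 1:12)
  class(inc) <- c("incidence_matrix", class(inc))
  cl <- stats::cutree(hierarchical_cluster(pairwise_distance(inc)), 2)
  expect_equal(length(unique(cl[1:4])), 1)
  expect_equal(length(unique(cl[5:8])), 1)
  expect_false(cl[1] == cl[5])
})

test_that("clustering is invariant to row permutation up to relabeling", {
  set.seed(9)
  inc <- matrix(sample(0:1, 5 * 8, TRUE), 5, 8,
                dimnames = list(paste0("m", 1:5), paste0("f", 1:8)))
  class(inc) <- c("incidence_matrix", class(inc))
  cl1 <- stats::cutree(hierarchical_cluster(pairwise_distance(inc)), 2)
  perm <- sample(5)
  inc2 <- inc[perm, ]
  class(inc2) <- c("incidence_matrix", class(inc2))
  cl2 <- stats::cutree(hierarchical_cluster(pairwise_distance(inc2)), 2)
  expect_equal(unname(table(paste(cl1[rownames(inc2)], cl2))) > 0,
               unname(table(cl1)) > 0)
  # same partition: co-membership matrices agree
  co1 <- outer(cl1[rownames(inc2)], cl1[rownames(inc2)], "==")
  co2 <- outer(cl2, cl2, "==")
  expect_equal(co1, co2)
})

test_that("ultrametric distances are reproduced exactly by the dendrogram", {
  d <- matrix(c(0, 2, 8, 8,
                2, 0, 8, 8,
                8, 8, 0, 4,
                8, 8, 4, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  hc <- hierarchical_cluster(d)
  expect_equal(sort(hc$height), c(2, 4, 8))
  expect_equal(as.matrix(stats::cophenetic(hc))[letters[1:4], letters[1:4]], d)
})

test_that("dendrograms export as Newick readable by ape", {
  ms <- scope_models()
  hc <- hierarchical_cluster(pairwise_distance(gene_incidence(ms)))
  txt <- dendrogram_newick(hc)
  phy <- ape::read.tree(text = txt)
  expect_setequal(phy$tip.label, c("mA", "mB", "mC"))
})

test_that("classical MDS recovers planted configurations", {
  # collinear points embed in one dimension: second eigenvalue ~ 0
  pts1 <- cbind(c(0, 3, 7))
  d1 <- as.matrix(stats::dist(pts1))
  rownames(d1) <- colnames(d1) <- paste0("p", 1:3)
  out1 <- classical_mds(d1, k = 2)
  ev <- attr(out1, "eigenvalues")
  expect_lt(abs(ev[2]), 1e-8 * ev[1])

  # random planar configuration: procrustes alignment residual < 1e-8
  set.seed(12)
  pts <- matrix(stats::rnorm(12), 6, 2)
  d <- as.matrix(stats::dist(pts))
  rownames(d) <- colnames(d) <- paste0("p", 1:6)
  out <- classical_mds(d, k = 2)
  proc <- vegan::procrustes(pts, as.matrix(out[, c("dim1", "dim2")]),
                            symmetric = FALSE)
  expect_lt(proc$ss, 1e-8)

  # duplicated model at distance zero gets identical coordinates
  d3 <- rbind(cbind(d, dup = d[, 1]), dup = c(d[1, ], 0))
  rownames(d3)[7] <- "dup"
  out3 <- classical_mds(d3, k = 2)
  expect_equal(unlist(out3[7, c("dim1", "dim2")]),
               unlist(out3[1, c("dim1", "dim2")]), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("MDS reproduces Euclidean-embeddable distances and warns otherwise", {
  set.seed(5)
  pts <- matrix(stats::rnorm(10), 5, 2)
  d <- as.matrix(stats::dist(pts))
  rownames(d) <- colnames(d) <- paste0("p", 1:5)
  out <- classical_mds(d, k = 2)
  rec <- as.matrix(stats::dist(as.matrix(out[, c("dim1", "dim2")])))
  expect_equal(unname(rec), unname(d), tolerance = 1e-8)
  # a non-Euclidean (4-point star violating embeddability in any dim) warns
  dn <- matrix(1, 4, 4) - diag(4)
  dn[1, 2] <- dn[2, 1] <- 2.2   # violates triangle-ish embedding
  rownames(dn) <- colnames(dn) <- paste0("q", 1:4)
  w <- capture_warnings(classical_mds(dn, k = 3))
  expect_length(w, 2)
  expect_match(w, "negative eigenvalues|dimensions", all = TRUE)
})

test_that("incidence_table is the row-aligned transpose of the matrix", {
  ms <- scope_models()
  gi <- gene_incidence(ms)
  tab <- incidence_table(gi)
  expect_equal(names(tab), c("feature", "mA", "mB", "mC"))
  expect_equal(tab$mA, unname(unclass(gi)["mA", ]))
})
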