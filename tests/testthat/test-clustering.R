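ultra3 <- function() {
  # ultrametric 3-leaf matrix: d(A,B) = 0.2, d(A,C) = d(B,C) = 0.5
  m <- matrix(c(0, 0.2, 0.5,
                0.2, 0, 0.5,
                0.5, 0.5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  stats::as.dist(m)
}

test_that("linkage trees agglomerate as hand-worked", {
  d2 <- stats::as.dist(matrix(c(0, 0.3, 0.3, 0), 2, 2,
                              dimnames = list(c("A", "B"), c("A", "B"))))
  tr <- hierarchical_tree(d2, "average")
  expect_equal(tr$height, 0.3)

  tr3 <- hierarchical_tree(ultra3(), "average")
  expect_equal(sort(tr3$height), c(0.2, 0.5))

  expect_error(hierarchical_tree(d2, "upgma_typo"), "unknown linkage")
  # both naming conventions are accepted for all eight methods
  for (m in c("ward_d", "ward.D2", "single", "complete", "average",
              "mcquitty", "median", "centroid"))
    expect_s3_class(hierarchical_tree(ultra3(), m), "hclust")
})

test_that("UPGMA merge heights are monotone non-decreasing", {
  gm <- random_gm(15, 100, seed = 2)
  tr <- hierarchical_tree(gd_matrix(gm), "average")
  expect_true(all(diff(tr$height) >= -1e-12))
})

test_that("CCC is 1 for ultrametric input and matches brute force", {
  expect_equal(cophenetic_correlation(ultra3(),
                                      hierarchical_tree(ultra3(), "average")),
               1.0, tolerance = 1e-12)

  # 4-leaf case against an independent LCA-height computation
  gm <- random_gm(4, 80, seed = 13)
  gdd <- gd_matrix(gm)
  tr <- hierarchical_tree(gdd, "average")
  # brute-force cophenetic: height of the first merge joining each pair
  n <- 4
  coph <- matrix(NA_real_, n, n)
  merged <- list()
  for (s in seq_len(nrow(tr$merge))) {
    a <- tr$merge[s, 1]; b <- tr$merge[s, 2]
    sa <- if (a < 0) -a else merged[[a]]
    sb <- if (b < 0) -b else merged[[b]]
    for (i in sa) for (j in sb) coph[i, j] <- coph[j, i] <- tr$height[s]
    merged[[s]] <- c(sa, sb)
  }
  expect_equal(as.vector(stats::as.dist(coph)),
               as.vector(stats::cophenetic(tr)), tolerance = 1e-12)

  const <- stats::as.dist(matrix(0.5, 3, 3) - diag(3) * 0.5)
  tr0 <- hierarchical_tree(const, "average")
  expect_warning(ccc <- cophenetic_correlation(const, tr0), "zero variance")
  expect_true(is.na(ccc))
})

test_that("cophenetic distances from monotone methods are ultrametric", {
  gm <- random_gm(10, 80, seed = 4)
  gdd <- gd_matrix(gm)
  for (m in c("average", "complete", "single")) {
    cp <- as.matrix(stats::cophenetic(hierarchical_tree(gdd, m)))
    n <- nrow(cp)
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n)
      expect_lte(cp[i, j], max(cp[i, k], cp[j, k]) + 1e-12)
  }
})

test_that("method selection is seeded, honors single-entry lists, and favors UPGMA on clock-like data", {
  sim <- simulate_collection(sim_config(
    n_subpops = 3, fst = 0.3, n_genotypes_per_subpop = 6, n_snps = 400,
    seed = 15))
  one <- select_linkage_method(sim$gm, methods = "complete", n_boot = 5,
                               seed = 1)
  expect_equal(one$winner, "complete")

  sel1 <- select_linkage_method(sim$gm, n_boot = 20, seed = 9)
  sel2 <- select_linkage_method(sim$gm, n_boot = 20, seed = 9)
  expect_identical(sel1$table, sel2$table)

  # clock-like divergence: UPGMA should top the CCC ranking
  expect_equal(sel1$winner, "average")

  expect_error(select_linkage_method(sim$gm, methods = character(), n_boot = 2,
                                     seed = 1), "empty methods")
  expect_error(select_linkage_method(sim$gm, n_boot = 0, seed = 1), "n_boot")
})

test_that("bootstrap support is high for planted splits and exact clones", {
  sim <- simulate_collection(sim_config(
    n_subpops = 2, fst = 0.4, n_genotypes_per_subpop = 5,
    clone_copies = c(G001 = 1L), intra_library_miscall = 0,
    inter_library_miscall = 0, missing_rate = 0.02, n_snps = 500, seed = 33))
  st <- bootstrap_support(sim$gm, n_boot = 50, seed = 3)
  phy <- st$phylo
  # the two-leaf clade of the exact clone pair
  pair <- which(phy$tip.label %in% c("G001", "G001_c1"))
  mrca <- ape::getMRCA(phy, pair)
  node_idx <- mrca - length(phy$tip.label)
  expect_gte(st$support[node_idx], 99)
  # the deepest split separates the two planted sub-populations with
  # near-total support: find the node whose clade is exactly subpop 1
  sp1 <- names(sim$truth$genotype_subpop)[sim$truth$genotype_subpop == 1]
  tips1 <- which(phy$tip.label %in% c(sp1, paste0(sp1, "_c1")))
  mrca1 <- ape::getMRCA(phy, tips1)
  clade_tips <- ape::extract.clade(phy, mrca1)$tip.label
  expect_setequal(clade_tips, phy$tip.label[tips1])
  expect_gte(st$support[mrca1 - length(phy$tip.label)], 95)

  expect_error(bootstrap_support(sim$gm, n_boot = 0, seed = 1), "n_boot")
})

test_that("newick export preserves topology and support labels", {
  gm <- random_gm(6, 150, seed = 8)
  st <- bootstrap_support(gm, n_boot = 10, seed = 2)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(st, f)
  phy <- ape::read.tree(f)
  expect_setequal(phy$tip.label, gm$accessions$accession_id)
  expect_length(phy$node.label, phy$Nnode)
})
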