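make_gdd <- function(gd, ids) {
  dimnames(gd) <- list(ids, ids)
  structure(list(gd = gd, n_snps = (gd * 0) + 100L, accession_ids = ids,
                 coding = "collapsed"), class = "gd_dist")
}

test_that("groups are connected components of the at-threshold graph", {
  ids <- c("A", "B", "C", "D")
  gd <- matrix(1, 4, 4); diag(gd) <- 0
  gd[1, 2] <- gd[2, 1] <- 0.001
  gd[2, 3] <- gd[3, 2] <- 0.002
  gd[1, 3] <- gd[3, 1] <- 0.010  # above threshold, chained anyway
  gdd <- make_gdd(gd, ids)
  p <- redundancy_groups(gdd, 0.0046)
  expect_equal(p$groups, list(c("A", "B", "C")))
  expect_equal(p$singletons, "D")
  expect_equal(p$max_intra_gd, 0.010)

  # no pair below threshold -> all singletons
  p0 <- redundancy_groups(gdd, 1e-6)
  expect_length(p0$groups, 0L)
  expect_equal(p0$singletons, ids)

  # exact clones group at any positive threshold
  gd2 <- matrix(0.5, 3, 3); diag(gd2) <- 0
  gd2[1, 2] <- gd2[2, 1] <- 0
  pc <- redundancy_groups(make_gdd(gd2, c("X", "Y", "Z")), 1e-9)
  expect_equal(pc$groups, list(c("X", "Y")))

  expect_error(redundancy_groups(gdd, NA), "finite")
})

test_that("undefined GD pairs are conservatively distinct", {
  gd <- matrix(NA_real_, 2, 2); diag(gd) <- 0
  p <- redundancy_groups(make_gdd(gd, c("A", "B")), 0.05)
  expect_equal(p$singletons, c("A", "B"))
})

test_that("the partition is invariant to accession order", {
  gm <- random_gm(15, 200, seed = 5)
  # plant two clone pairs
  gm$dosage[2, ] <- gm$dosage[1, ]
  gm$dosage[10, ] <- gm$dosage[9, ]
  gdd <- gd_matrix(gm)
  p1 <- redundancy_groups(gdd, 0.01)
  perm <- sample(15)
  gm2 <- subset_gm(gm, accessions = perm)
  p2 <- redundancy_groups(gd_matrix(gm2), 0.01)
  expect_identical(p1$groups, p2$groups)
  expect_identical(p1$singletons, p2$singletons)
})

test_that("representatives maximize read abundance with lexical ties", {
  part <- structure(list(groups = list(c("A", "B"), c("C", "D"), c("E", "F")),
                         singletons = "G",
                         representatives = rep(NA_character_, 3),
                         max_intra_gd = rep(0, 3), threshold_used = 0.01),
                    class = "redundancy_partition")
  meta <- data.frame(
    accession_id = c("A", "B", "C", "D", "E", "F", "G"),
    total_pe_reads = c(10e6, 12e6, 8e6, 8e6, NA, NA, 1),
    stringsAsFactors = FALSE)
  expect_warning(out <- choose_representatives(part, meta), "missing read")
  expect_equal(out$representatives, c("B", "C", "E"))
  expect_equal(curation_shortlist(out), c("B", "C", "E", "G"))
})

test_that("collection summaries reproduce their defining identities", {
  s <- collection_summary(103, 60)
  expect_equal(s$redundancy_pct, 41.7)
  s2 <- collection_summary(28, 13)
  expect_equal(s2$redundancy_pct, 53.6)
  expect_equal(s2$overestimation_pct, 115.4)
  expect_equal(round(s2$overestimation_pct), 115)
  s3 <- collection_summary(54, 26)
  expect_equal(round(s3$overestimation_pct), 108)
  s4 <- collection_summary(20, 20)
  expect_equal(s4$redundancy_pct, 0)
  expect_equal(s4$overestimation_pct, 0)
  # identities hold exactly before rounding
  s5 <- collection_summary(101, 60, digits = 10)
  expect_equal(s5$redundancy_pct, 100 * (101 - 60) / 101, tolerance = 1e-9)
  expect_equal(s5$overestimation_pct, 100 * (101 / 60 - 1), tolerance = 1e-9)
  expect_error(collection_summary(10, 0), "n_unique")
  expect_error(collection_summary(10, 11), "exceed")
})

test_that("passport conflicts are flagged by category", {
  part <- structure(list(groups = list(c("A1", "A2")), singletons = c("B", "C"),
                         representatives = "A1", max_intra_gd = 0,
                         threshold_used = 0.01),
                    class = "redundancy_partition")
  meta <- data.frame(
    accession_id = c("A1", "A2", "B", "C"),
    display_name = c("Jumbo", "Chico", "Krupnoplodnaya", "Krupnoplodnaya"),
    observed_gender = c("female", "male", "female", "male"),
    species_label = c("sp1", "sp2", "sp1", "sp1"),
    stringsAsFactors = FALSE)
  fl <- flag_conflicts(part, meta)
  expect_setequal(fl$type, c("usurper", "synonym", "gender_mismatch",
                             "species_mismatch"))
  expect_equal(fl$name[fl$type == "usurper"], "Krupnoplodnaya")
  expect_true(grepl("Jumbo", fl$name[fl$type == "synonym"]))

  clean <- flag_conflicts(part, within(meta, {
    display_name <- c("X", "X", "B", "C")  # one name per genotype unit
    observed_gender <- "female"
    species_label <- "sp1"
  }))
  expect_equal(nrow(clean), 0L)
})

test_that("clone partitions are recovered on calibrated synthetic collections", {
  hits <- vapply(1:3, function(seed) {
    cc <- stats::setNames(c(2L, 1L, 1L, 2L), sprintf("G%03d", c(1, 3, 5, 8)))
    sim <- simulate_collection(sim_config(
      n_subpops = 2, fst = 0.15, n_genotypes_per_subpop = 6,
      clone_copies = cc, ploidy_map = 2L, n_snps = 2000, seed = 70 + seed))
    gdd <- gd_matrix(sim$gm)
    sets <- replicate_gd_sets(gdd, sim$gm$accessions)
    thr <- estimate_threshold(sets$technical)
    part <- redundancy_groups(gdd, thr$gd99)
    # planted partition from the truth clone map
    truth <- split(names(sim$truth$clone_map), sim$truth$clone_map)
    planted <- unname(lapply(truth[vapply(truth, length, 1L) > 1], sort))
    planted <- planted[order(vapply(planted, `[`, "", 1L))]
    got <- lapply(part$groups, sort)
    members_ok <- mean(vapply(names(sim$truth$clone_map), function(acc) {
      g_true <- Filter(function(g) acc %in% g, planted)
      g_got <- Filter(function(g) acc %in% g, got)
      identical(g_true, g_got) ||
        (length(g_true) == 0 && length(g_got) == 0)
    }, TRUE))
    members_ok
  }, 0)
  expect_gte(mean(hits), 0.99)
})
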