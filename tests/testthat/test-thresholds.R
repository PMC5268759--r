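test_that("replicate pairs are classified by library and lane", {
  meta <- data.frame(
    accession_id = c("r1a", "r1b", "r2a", "r2b", "r2c", "solo"),
    replicate_group = c("g1", "g1", "g2", "g2", "g2", NA),
    library_id = c("1", "1", "1", "2", "1", "1"),
    lane_id = c("1", "1", "1", "2", "1", "1"),
    stringsAsFactors = FALSE)
  n <- nrow(meta)
  gd <- matrix(0.01, n, n, dimnames = list(meta$accession_id,
                                           meta$accession_id))
  diag(gd) <- 0
  gdd <- structure(list(gd = gd, n_snps = gd * 0 + 100L,
                        accession_ids = meta$accession_id,
                        coding = "collapsed"), class = "gd_dist")
  sets <- replicate_gd_sets(gdd, meta)
  # g1 pair same lib/lane -> biological; g2 gives 3 pairwise GDs,
  # two of them split across libraries -> technical
  expect_length(sets$biological$gd_values, 2L)
  expect_length(sets$technical$gd_values, 2L)
  expect_setequal(sets$technical$pair_labels, c("r2a~r2b", "r2b~r2c"))

  meta$replicate_group[6] <- "lonely"
  expect_warning(replicate_gd_sets(gdd, meta), "< 2 members")
})

test_that("threshold estimation follows the normal-percentile route", {
  est <- estimate_threshold(c(0.002, 0.003, 0.004))
  expect_equal(est$mean_gd, 0.003)
  expect_equal(est$sd_gd, 0.001)
  expect_equal(est$method, "normal_percentile")
  expect_equal(est$gd99, 0.003 + stats::qnorm(0.99) * 0.001, tolerance = 1e-12)
  expect_equal(est$gd99, 0.0053263, tolerance = 1e-4)
  expect_gte(est$gd99, est$mean_gd)

  expect_warning(d <- estimate_threshold(rep(0.001, 5)), "degenerate")
  expect_equal(d$gd99, 0.001)
  expect_error(estimate_threshold(c(0.1, 0.2)), "at least 3")
})

test_that("monte-carlo normal draws recover the analytic 99th percentile", {
  set.seed(99)
  g <- abs(rnorm(500, 0.003, 0.0007))
  est <- estimate_threshold(g)
  expect_equal(est$gd99, 0.003 + stats::qnorm(0.99) * 0.0007,
               tolerance = 0.1 * 0.004629)
})

test_that("threshold coverage: ~1% of true-clone pairs exceed gd99", {
  set.seed(7)
  mu <- 0.003; sigma <- 0.0006
  fit <- estimate_threshold(rnorm(200, mu, sigma))
  draws <- rnorm(10000, mu, sigma)
  exceed <- mean(draws > fit$gd99)
  expect_lt(abs(exceed - 0.01), 0.01)
})

test_that("gd99 is monotone in the mean and SD of the input set", {
  set.seed(1)
  z <- rnorm(50)
  base <- estimate_threshold(0.003 + 0.0005 * z)
  shift <- estimate_threshold(0.004 + 0.0005 * z)
  spread <- estimate_threshold(0.003 + 0.0010 * z)
  expect_gt(shift$gd99, base$gd99)
  expect_gt(spread$gd99, base$gd99)
})

test_that("read sub-sampling at fraction 1 reproduces the original calls", {
  sim <- simulate_collection(sim_config(
    n_subpops = 1, n_genotypes_per_subpop = 3, n_snps = 400, seed = 3))
  gm <- sim$gm
  sub <- subsample_depths(gm, 1, fraction = 1, n_subsamples = 4L, seed = 5)
  for (s in 1:4) {
    d <- call_genotypes(gm$ref_depth[1, ], gm$alt_depth[1, ], gm$ploidy[1])
    expect_identical(unname(sub$profiles[s, ]), unname(d))
  }
  set1 <- subsample_gd_set(gm, 1, fraction = 1, n_subsamples = 4L, seed = 5)
  expect_true(all(set1$gd_values == 0))
  expect_length(set1$gd_values, 6L)
})

test_that("binomial thinning halves depth and preserves the ratio", {
  gm <- genotype_matrix(matrix(1L, 1, 500), 2L,
                        ref_depth = matrix(20L, 1, 500),
                        alt_depth = matrix(20L, 1, 500))
  sub <- subsample_depths(gm, 1, fraction = 0.5, n_subsamples = 2L, seed = 11,
                          min_call_depth = 1L, min_minor_reads = 0L)
  # a (20, 20) site thins to ~(10, 10): still a balanced het call
  expect_gt(mean(sub$profiles == 1L, na.rm = TRUE), 0.95)

  zero <- genotype_matrix(matrix(NA_integer_, 1, 5), 2L)
  expect_error(subsample_depths(zero, 1, seed = 1), "no allele depth")
})

test_that("sub-sampling GD sets yield 45 pairs for 10 profiles", {
  sim <- simulate_collection(sim_config(
    n_subpops = 1, n_genotypes_per_subpop = 2, n_snps = 600, seed = 19))
  s <- subsample_gd_set(sim$gm, 1, seed = 23)
  expect_length(s$gd_values, 45L)
  expect_equal(s$category, "subsampling")
})

test_that("extrapolation divides the read-sampling threshold by the ratio", {
  expect_equal(extrapolate_threshold(0.0045, 0.30)$gd99, 0.0150)
  expect_equal(extrapolate_threshold(0.21, 1)$gd99, 0.21)
  expect_error(extrapolate_threshold(0.0045, 0), "ratio")
  ext <- extrapolate_threshold(0.0045, 0.30)
  expect_equal(ext$method, "extrapolated")
  expect_true(is.na(ext$shapiro_W) && is.na(ext$shapiro_p))
})

test_that("the cross-species threshold ratio is the mean of the quotients", {
  expect_equal(estimate_ratio(list(c(0.0017, 0.0046), c(0.0029, 0.0112))),
               mean(c(0.0017 / 0.0046, 0.0029 / 0.0112)))
  expect_equal(estimate_ratio(list(c(0.0017, 0.0046), c(0.0029, 0.0112)),
                              digits = 2), 0.31)
  expect_equal(estimate_ratio(list(c(0.5, 1.0))), 0.5)
  expect_equal(estimate_ratio(list(c(0.2, 0.2))), 1.0)
  expect_error(estimate_ratio(list(c(0.1, 0))), "zero")
})

test_that("technical gd99 exceeds biological gd99 on calibrated collections", {
  cc <- stats::setNames(rep(2L, 6), sprintf("G%03d", 1:6))
  sim <- simulate_collection(sim_config(
    n_subpops = 2, n_genotypes_per_subpop = 6, clone_copies = cc,
    ploidy_map = 2L, n_snps = 3000, seed = 61))
  gdd <- gd_matrix(sim$gm)
  sets <- replicate_gd_sets(gdd, sim$gm$accessions)
  bio <- estimate_threshold(sets$biological)
  tech <- estimate_threshold(sets$technical)
  expect_gt(tech$gd99, bio$gd99)
})
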