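test_that("VCF ingestion maps GT/AD to dosage, ploidy and depths", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2"), collapse = "\t"),
    paste(c("c1", "101", "snp1", "A", "C", ".", "PASS", ".", "GT:AD",
            "0/1:10,10", "0/0:20,0"), collapse = "\t"),
    paste(c("c2", "55", "snp2", "G", "T", ".", "PASS", ".", "GT:AD",
            "1/1:0,30", "./.:0,0"), collapse = "\t"))
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  gm <- read_vcf(f)
  expect_equal(unname(gm$dosage["S1", ]), c(1L, 2L))
  expect_equal(unname(gm$dosage["S2", ]), c(0L, NA))
  expect_equal(gm$ploidy, c(2L, 2L))
  expect_equal(unname(gm$ref_depth["S1", ]), c(10L, 0L))
  expect_equal(unname(gm$alt_depth["S1", ]), c(10L, 30L))
  expect_equal(gm$snps$position, c(101L, 55L))

  # tetraploid GT: 0/0/0/1 with AD 30,10 -> dosage 1 of ploidy 4
  vcf4 <- c(vcf[1:4],
            paste(c("c1", "7", "s", "A", "G", ".", "PASS", ".", "GT:AD",
                    "0/0/0/1:30,10", "1/1/1/1:0,44"), collapse = "\t"))
  f4 <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf4, f4)
  gm4 <- read_vcf(f4)
  expect_equal(unname(gm4$dosage[, 1]), c(1L, 4L))
  expect_equal(gm4$ploidy, c(4L, 4L))
  expect_equal(gm4$alt_depth["S1", 1] /
                 (gm4$ref_depth["S1", 1] + gm4$alt_depth["S1", 1]), 0.25)
})

test_that("multi-allelic records error in strict mode, reduce otherwise", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="AD">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2"), collapse = "\t"),
    paste(c("c1", "1", "m", "A", "C,G", ".", "PASS", ".", "GT:AD",
            "0/1:10,12,0", "0/2:14,0,3"), collapse = "\t"))
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  expect_error(read_vcf(f, strict = TRUE), "multi-allelic")
  expect_warning(gm <- read_vcf(f), "major alternate")
  # allele C has the larger summed depth; S2 carries the dropped G allele
  expect_equal(unname(gm$dosage[, 1]), c(1L, NA))
})

test_that("genotype table round-trips dosage, depths and missingness", {
  sim <- simulate_collection(sim_config(
    n_subpops = 1, n_genotypes_per_subpop = 4, ploidy_map = c(2L, 4L),
    n_snps = 30, seed = 9))
  gm <- sim$gm
  f <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_table(gm, f)
  gm2 <- read_genotype_table(f)
  expect_identical(gm2$dosage, gm$dosage)
  expect_identical(gm2$ref_depth, gm$ref_depth)
  expect_identical(gm2$alt_depth, gm$alt_depth)
  expect_identical(gm2$ploidy, gm$ploidy)

  # VCF round trip preserves the same content
  fv <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm, fv)
  gm3 <- read_vcf(fv)
  expect_identical(unname(gm3$dosage), unname(gm$dosage))
  expect_identical(unname(gm3$ref_depth), unname(gm$ref_depth))
  expect_identical(gm3$ploidy, gm$ploidy)
})

test_that("simplex-only filtering and malformed tables behave as specified", {
  dosage <- matrix(c(0L, 1L, 2L, 1L, 0L, 2L, 1L, 1L, 0L, 2L), 2, 5)
  dimnames(dosage) <- list(c("A", "B"), paste0("s", 1:5))
  snps <- data.frame(snp_id = paste0("s", 1:5),
                     snps_in_centroid = c(1L, 2L, 1L, 3L, 1L))
  gm <- genotype_matrix(dosage, 2L, snps = snps)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_table(gm, f)
  expect_equal(n_snps(read_genotype_table(f, simplex_only = TRUE)), 3L)
  expect_equal(n_snps(read_genotype_table(f, simplex_only = FALSE)), 5L)

  # duplicate accession column
  lines <- readLines(f)
  lines[2] <- sub("\tB$", "\tA", lines[2])
  writeLines(lines, f)
  expect_error(read_genotype_table(f), "duplicate accession")
})

test_that("collection summary percentages are exact and sum to 100", {
  # 4 cells: het, hom, hom, missing
  gm <- make_depth_gm(rbind(a = c(1L, 0L), b = c(2L, NA)), ploidy = 2L,
                      depth = 44L)
  s <- summarize_collection(gm)
  expect_equal(s$pct_het, 25)
  expect_equal(s$pct_hom, 50)
  expect_equal(s$pct_missing, 25)
  expect_equal(s$pct_het + s$pct_hom + s$pct_missing, 100, tolerance = 1e-9)
  expect_equal(s$mean_depth, 44)
  expect_equal(s$pct_depth_gt, 100)

  all_na <- genotype_matrix(matrix(NA_integer_, 2, 2), 2L)
  expect_error(summarize_collection(all_na), "missing")
})

test_that("summary percentages sum to 100 on simulated collections", {
  for (seed in 1:3) {
    gm <- simulate_collection(sim_config(
      n_subpops = 2, n_genotypes_per_subpop = 5, n_snps = 200,
      seed = seed))$gm
    s <- summarize_collection(gm)
    expect_equal(s$pct_het + s$pct_hom + s$pct_missing, 100,
                 tolerance = 1e-9)
  }
})

test_that("locus filters remove monomorphic, sparse and shallow SNPs", {
  dosage <- rbind(a = c(0L, 1L, NA, 1L),
                  b = c(0L, 2L, NA, 0L),
                  c = c(0L, 1L, 0L, NA),
                  d = c(0L, 0L, NA, 1L))
  gm <- make_depth_gm(dosage, 2L, depth = 30L)
  out <- suppressMessages(filter_loci(gm, min_maf = 0.01, max_missing = 0.4))
  # SNP1 monomorphic, SNP3 missing in 75% of accessions
  expect_equal(gm$snps$snp_id[c(2, 4)], out$snps$snp_id)

  # zero thresholds are an identity
  out0 <- suppressMessages(filter_loci(gm))
  expect_identical(out0$dosage, gm$dosage)

  expect_error(suppressMessages(filter_loci(gm, min_mean_depth = 1000)),
               "binding filter: depth")
})
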