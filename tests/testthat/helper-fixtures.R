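# Small in-code fixtures shared across test files.

# Diploid 5-SNP two-accession pair from the worked GD example:
# x = (AA, AB, BB, AA, --), y = (AA, BB, BB, AB, AA)
make_gd_example_gm <- function() {
  dosage <- rbind(
    x = c(0L, 1L, 2L, 0L, NA),
    y = c(0L, 2L, 2L, 1L, 0L))
  genotype_matrix(dosage, ploidy = 2L)
}

# dense depths so every call is depth-supported
make_depth_gm <- function(dosage, ploidy, depth = 40L) {
  alt <- round(depth * dosage / ploidy)
  ref <- depth - alt
  alt[is.na(alt)] <- 0; ref[is.na(ref)] <- 0
  genotype_matrix(dosage, ploidy, ref_depth = ref, alt_depth = alt)
}

# random diploid dosage matrix with missingness, for property tests
random_gm <- function(n_acc, n_snp, ploidy = 2L, miss = 0.1, seed = 1) {
  set.seed(seed)
  p <- runif(n_snp, 0.1, 0.9)
  dosage <- vapply(seq_len(n_snp), function(j)
    rbinom(n_acc, ploidy, p[j]), integer(n_acc))
  dosage[matrix(runif(n_acc * n_snp) < miss, n_acc, n_snp)] <- NA_integer_
  rownames(dosage) <- sprintf("A%02d", seq_len(n_acc))
  genotype_matrix(dosage, ploidy)
}

# independent per-SNP-loop implementation of the modified Gower formula,
# scoring states by the published rules (not by coordinate distance)
gd_bruteforce <- function(gm, a, b, coding = "collapsed") {
  score_collapsed <- function(da, pa, db, pb) {
    st <- function(d, p) if (d == 0) "rr" else if (d == p) "aa" else "het"
    sa <- st(da, pa); sb <- st(db, pb)
    if (sa == sb) 1
    else if (sa == "het" || sb == "het") 0.5
    else 0
  }
  s_sum <- 0; w_sum <- 0
  for (j in seq_len(n_snps(gm))) {
    da <- gm$dosage[a, j]; db <- gm$dosage[b, j]
    if (is.na(da) || is.na(db)) next
    w_sum <- w_sum + 1
    s_sum <- s_sum + if (coding == "collapsed")
      score_collapsed(da, gm$ploidy[a], db, gm$ploidy[b])
    else 1 - abs(da / gm$ploidy[a] - db / gm$ploidy[b])
  }
  if (w_sum == 0) return(list(gd = NA_real_, n = 0L))
  list(gd = 1 - s_sum / w_sum, n = w_sum)
}

# independent brute-force AMOVA oracle: sums of squared allele mismatches
# over all pairs of allele copies, per stratum, from first principles
amova_oracle <- function(dosage, ploidy, group) {
  n_acc <- nrow(dosage)
  ss_pairs <- function(allele_mat) {
    # allele_mat: rows = copies, one column per locus (NA copies skipped)
    tot <- 0
    for (j in seq_len(ncol(allele_mat))) {
      x <- allele_mat[, j]
      x <- x[!is.na(x)]
      n <- length(x)
      if (n < 2) next
      dd <- outer(x, x, function(a, b) (a - b)^2)
      tot <- tot + sum(dd[upper.tri(dd)]) / n
    }
    tot
  }
  stack <- function(rows) {
    mats <- lapply(rows, function(i) {
      m <- vapply(seq_len(ncol(dosage)), function(j) {
        d <- dosage[i, j]
        if (is.na(d)) rep(NA_real_, ploidy[i])
        else c(rep(1, d), rep(0, ploidy[i] - d))
      }, numeric(ploidy[i]))
      m  # copies x loci
    })
    do.call(rbind, mats)
  }
  ss_total <- ss_pairs(stack(seq_len(n_acc)))
  ss_within_geno <- sum(vapply(seq_len(n_acc), function(i) ss_pairs(stack(i)),
                               0))
  ss_within_grp <- sum(vapply(unique(group), function(g)
    ss_pairs(stack(which(group == g))), 0))
  c(among_groups = ss_total - ss_within_grp,
    among_genotypes = ss_within_grp - ss_within_geno,
    within_genotypes = ss_within_geno)
}
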