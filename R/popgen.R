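#' PCA of a genotype matrix
#'
#' Ordination on the accessions-by-SNPs dosage-fraction matrix. Missing cells
#' are imputed to the per-SNP mean (the only place the package imputes),
#' columns are centered, and optionally unit-scaled; constant SNPs contribute
#' nothing and are left unscaled when `scale = TRUE`.
#'
#' @param gm a `genotype_matrix`
#' @param scale logical; divide columns by their SD (default `FALSE`)
#' @param max_axes number of axes to return (default all)
#' @return object of class `pca_result`: list with `scores` (accessions x
#'   axes), `pct_variance` (per returned axis, relative to total variance,
#'   non-increasing), `sdev`
#' @export
pca_genotypes <- function(gm, scale = FALSE, max_axes = NULL) {
  if (n_accessions(gm) < 2L || n_snps(gm) < 2L)
    stop("need at least 2 accessions and 2 SNPs")
  f <- dosage_fraction(gm)
  all_missing <- colSums(!is.na(f)) == 0L
  if (any(all_missing))
    stop(sum(all_missing), " SNP(s) missing in every accession")
  mu <- colMeans(f, na.rm = TRUE)
  idx <- which(is.na(f), arr.ind = TRUE)
  if (nrow(idx)) f[idx] <- mu[idx[, 2]]
  if (scale) {
    s <- apply(f, 2L, stats::sd)
    s[s == 0] <- 1
    f <- sweep(f, 2L, s, `/`)
  }
  p <- stats::prcomp(f, center = TRUE, scale. = FALSE)
  total_var <- sum(p$sdev^2)
  k <- if (is.null(max_axes)) length(p$sdev) else min(max_axes, length(p$sdev))
  structure(list(
    scores = p$x[, seq_len(k), drop = FALSE],
    pct_variance = 100 * p$sdev[seq_len(k)]^2 / total_var,
    sdev = p$sdev), class = "pca_result")
}

#' Select the number of genetic clusters by K-means and BIC
#'
#' Runs seeded K-means (multiple restarts) on the leading principal
#' components explaining at least `retained_variance` of the total variance,
#' over each K in `k_range`, scoring each solution with
#' `BIC(K) = n ln(WSS_K / n) + K ln(n)`. The chosen K is the smallest K
#' attaining the minimum BIC (the elbow rule: the lowest K followed by an
#' increase in BIC); with no structure, BIC is non-decreasing and the
#' smallest evaluated K is chosen.
#'
#' @param pca a `pca_result` from [pca_genotypes()]
#' @param k_range integer Ks to evaluate (default `2:10`)
#' @param retained_variance fraction of variance the retained PCs must reach
#'   (default 0.9)
#' @param seed integer seed
#' @param nstart K-means restarts per K (default 20)
#' @return object of class `k_selection`: list with `bic` (named numeric over
#'   K), `chosen_k`, `assignments` (cluster per accession at `chosen_k`),
#'   `k_range`
#' @export
select_k_bic <- function(pca, k_range = 2:10, retained_variance = 0.9, seed,
                         nstart = 20L) {
  if (missing(seed)) stop("a seed is required")
  if (length(k_range) == 0L) stop("empty k_range")
  n <- nrow(pca$scores)
  if (any(k_range < 1L | k_range > n - 1L))
    stop("k_range must lie within 1..n-1")
  cum <- cumsum(pca$pct_variance) / 100
  n_pc <- max(1L, which(cum >= retained_variance)[1])
  if (is.na(n_pc)) n_pc <- length(pca$pct_variance)
  x <- pca$scores[, seq_len(n_pc), drop = FALSE]
  set.seed(seed)
  bic <- numeric(length(k_range))
  fits <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    fit <- stats::kmeans(x, centers = k, nstart = nstart, iter.max = 100L)
    wss <- fit$tot.withinss
    bic[i] <- n * log(wss / n) + k * log(n)
    fits[[i]] <- fit
  }
  names(bic) <- k_range
  best <- which.min(bic)  # first index attaining the minimum
  structure(list(bic = bic, chosen_k = k_range[best],
                 assignments = stats::setNames(fits[[best]]$cluster,
                                               rownames(pca$scores)),
                 k_range = k_range), class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat(sprintf("k_selection: chosen K = %d (BIC %s)\n", x$chosen_k,
              paste(sprintf("%s:%.1f", names(x$bic), x$bic), collapse = " ")))
  invisible(x)
}

# Allele-level nested sums of squares for one locus set.
# dosage: accessions x loci (NA = missing); ploidy per accession;
# group: integer group index per accession.
# Returns per-stratum SS summed over loci.
.amova_ss <- function(dosage, ploidy, group) {
  typed <- !is.na(dosage)
  a <- dosage; a[!typed] <- 0
  p_mat <- ploidy * typed             # copies contributed per cell
  n_tot <- colSums(p_mat)             # copies per locus
  a_tot <- colSums(a)
  ss_tot <- ifelse(n_tot > 0, a_tot * (n_tot - a_tot) / n_tot, 0)
  ss_wi <- colSums(ifelse(p_mat > 0, a * (p_mat - a) / pmax(p_mat, 1L), 0))
  ss_wg <- 0
  for (g in unique(group)) {
    rows <- group == g
    n_g <- colSums(p_mat[rows, , drop = FALSE])
    a_g <- colSums(a[rows, , drop = FALSE])
    ss_wg <- ss_wg + ifelse(n_g > 0, a_g * (n_g - a_g) / pmax(n_g, 1L), 0)
  }
  c(total = sum(ss_tot), within_groups = sum(ss_wg), within_geno = sum(ss_wi))
}

#' Allele-level analysis of molecular variance (AMOVA)
#'
#' Hierarchical partitioning of allele-frequency variance into three strata:
#' among groups, among genotypes within groups, and within genotypes. Each
#' accession contributes `ploidy` allele copies per typed locus (dosage =
#' alternate copies); sums of squares derive from squared allele mismatch
#' distances, and variance components from the standard expected-mean-square
#' coefficients of the nested design. Significance per stratum comes from
#' permutation: genotypes are permuted among groups for the among-group and
#' among-genotype strata, and allele copies among genotypes within groups for
#' the within-genotype stratum. `F_ST` is the among-group component over the
#' total.
#'
#' @param gm a `genotype_matrix`
#' @param grouping group label per accession: a named vector (names =
#'   accession ids) or a vector in accession order; >= 2 groups required
#' @param n_perm permutations for p-values (default 10000; 0 skips testing)
#' @param seed integer seed for the permutations
#' @return object of class `amova_table`: list with `table` (data.frame rows
#'   `among_groups`, `among_genotypes`, `within_genotypes`: `df`, `SS`, `MS`,
#'   `p_value`, `Var`, `Var_pct`), `F_ST`, `truncated` (flag: negative
#'   component(s) truncated to zero and `Var_pct` renormalized)
#' @export
amova <- function(gm, grouping, n_perm = 10000L, seed = 1L) {
  ids <- gm$accessions$accession_id
  grp <- if (!is.null(names(grouping))) grouping[ids] else grouping
  if (length(grp) != length(ids) || anyNA(grp))
    stop("every accession must be assigned a group")
  grp <- as.integer(factor(grp))
  G <- length(unique(grp))
  if (G < 2L) stop("need at least 2 groups")
  if (any(tabulate(grp) < 2L))
    warning("group(s) with a single genotype; df collapse")
  I <- length(ids)
  ploidy <- gm$ploidy

  ss <- .amova_ss(gm$dosage, ploidy, grp)
  ss_ag <- unname(ss["total"] - ss["within_groups"])
  ss_ai <- unname(ss["within_groups"] - ss["within_geno"])
  ss_wi <- unname(ss["within_geno"])

  df_ag <- G - 1L
  df_ai <- I - G
  df_wi <- sum(ploidy - 1L)
  ms_ag <- ss_ag / df_ag
  ms_ai <- if (df_ai > 0) ss_ai / df_ai else NA_real_
  ms_wi <- ss_wi / df_wi

  # expected-mean-square copy-count coefficients (design counts, full data)
  n_i <- ploidy
  n_g <- tapply(n_i, grp, sum)
  N <- sum(n_i)
  s_within <- tapply(n_i^2, grp, sum) / n_g
  n_c <- (N - sum(s_within)) / df_ai
  n_cp <- (sum(s_within) - sum(n_i^2) / N) / df_ag
  n_cpp <- (N - sum(n_g^2) / N) / df_ag

  var_wi <- ms_wi
  var_ai <- if (df_ai > 0) (ms_ai - var_wi) / n_c else 0
  var_ag <- (ms_ag - var_wi - n_cp * var_ai) / n_cpp
  comps <- c(var_ag, var_ai, var_wi)
  truncated <- any(comps < 0)
  comps[comps < 0] <- 0
  var_pct <- 100 * comps / sum(comps)
  fst <- comps[1] / sum(comps)

  p_vals <- rep(NA_real_, 3L)
  if (n_perm > 0L) {
    set.seed(seed)
    stat_ag <- numeric(n_perm); stat_ai <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      pg <- sample(grp)
      pss <- .amova_ss(gm$dosage, ploidy, pg)
      p_ss_ag <- pss["total"] - pss["within_groups"]
      p_ss_ai <- pss["within_groups"] - pss["within_geno"]
      p_ms_ag <- p_ss_ag / df_ag
      p_ms_ai <- if (df_ai > 0) p_ss_ai / df_ai else NA_real_
      p_var_ai <- if (df_ai > 0) (p_ms_ai - ms_wi) / n_c else 0
      stat_ag[b] <- (p_ms_ag - ms_wi - n_cp * p_var_ai) / n_cpp
      stat_ai[b] <- p_var_ai
    }
    p_vals[1] <- (1 + sum(stat_ag >= var_ag - 1e-12)) / (n_perm + 1)
    # within-genotype stratum: permute allele copies among genotypes
    stat_wi <- .permute_within(gm$dosage, ploidy, grp, n_perm)
    p_vals[3] <- (1 + sum(stat_wi >= ss_wi / df_wi - 1e-12)) / (n_perm + 1)
    # among-genotypes stratum: group-label permutation of its component
    obs_ai <- if (df_ai > 0) (ms_ai - ms_wi) / n_c else 0
    p_vals[2] <- (1 + sum(stat_ai >= obs_ai - 1e-12)) / (n_perm + 1)
  }

  tab <- data.frame(
    stratum = c("among_groups", "among_genotypes", "within_genotypes"),
    df = c(df_ag, df_ai, df_wi),
    SS = c(ss_ag, ss_ai, ss_wi),
    MS = c(ms_ag, ms_ai, ms_wi),
    p_value = p_vals,
    Var = comps,
    Var_pct = var_pct,
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, F_ST = fst, truncated = truncated,
                 n_perm = n_perm), class = "amova_table")
}

# permutation distribution of the within-genotype mean square under
# re-dealing of allele copies among genotypes within each group
.permute_within <- function(dosage, ploidy, grp, n_perm) {
  typed <- !is.na(dosage)
  a <- dosage; a[!typed] <- 0
  L <- ncol(dosage)
  df_wi <- sum(ploidy - 1L)
  out <- numeric(n_perm)
  groups <- unique(grp)
  for (b in seq_len(n_perm)) {
    ss_wi <- 0
    for (g in groups) {
      rows <- which(grp == g)
      p_mat <- ploidy[rows] * typed[rows, , drop = FALSE]
      alt_rem <- colSums(a[rows, , drop = FALSE])
      tot_rem <- colSums(p_mat)
      for (i in rows) {
        k <- ploidy[i] * typed[i, ]
        ref_rem <- tot_rem - alt_rem
        ai <- suppressWarnings(
          stats::rhyper(L, m = alt_rem, n = ref_rem, k = k))
        ai[k == 0L] <- 0L
        ss_wi <- ss_wi + sum(ifelse(k > 0, ai * (k - ai) / pmax(k, 1L), 0))
        alt_rem <- alt_rem - ai
        tot_rem <- tot_rem - k
      }
    }
    out[b] <- ss_wi / df_wi
  }
  out
}

#' @export
print.amova_table <- function(x, ...) {
  cat(sprintf("AMOVA (%d permutations): F_ST = %.4f%s\n", x$n_perm, x$F_ST,
              if (x$truncated) " [negative component truncated]" else ""))
  print(x$table, digits = 4)
  invisible(x)
}

#' Per-population diversity statistics
#'
#' For each locus with allele copies `n_c` (sum of ploidy over typed
#' accessions) and alternate frequency `p` from dosage sums: the effective
#' number of alleles `N_E = 1 / (p^2 + q^2)`, unbiased expected
#' heterozygosity `uH_E = n_c / (n_c - 1) (1 - p^2 - q^2)`, observed
#' heterozygosity `H_O` (fraction of heterozygous accessions), minor allele
#' frequency. Summaries are means over retained loci; `F_IS = 1 - H_O / H_E`
#' over polymorphic loci (negative under excess heterozygosity, as expected
#' in dioecious outcrossers).
#'
#' @param gm a `genotype_matrix`
#' @param population accession ids or indices to summarize (default all)
#' @return one-row data.frame: `n_accessions`, `n_loci`, `pct_maf_gt_0.1`,
#'   `N_E`, `H_O`, `uH_E`, `mean_gd`, `F_IS`
#' @export
diversity_stats <- function(gm, population = NULL) {
  if (!is.null(population)) gm <- subset_gm(gm, accessions = population)
  if (n_accessions(gm) == 0L) stop("empty population")
  d <- gm$dosage
  typed <- !is.na(d)
  a <- d; a[!typed] <- 0L
  p_mat <- gm$ploidy * typed
  n_c <- colSums(p_mat)
  keep <- n_c > 1L
  if (!any(keep)) stop("no locus with more than one allele copy")
  p <- colSums(a)[keep] / n_c[keep]
  q <- 1 - p
  n_ck <- n_c[keep]
  ne <- 1 / (p^2 + q^2)
  uhe <- n_ck / (n_ck - 1) * (1 - p^2 - q^2)
  het <- is_het(gm)
  ho <- colSums(het & typed, na.rm = TRUE)[keep] / colSums(typed)[keep]
  maf <- pmin(p, q)

  poly <- maf > 0
  fis <- if (any(poly)) 1 - mean(ho[poly]) / mean(uhe[poly]) else NA_real_
  gdd <- if (n_accessions(gm) >= 2L) {
    g <- suppressWarnings(gd_matrix(gm, "collapsed"))$gd
    mean(g[upper.tri(g)], na.rm = TRUE)
  } else NA_real_

  data.frame(n_accessions = n_accessions(gm), n_loci = sum(keep),
             pct_maf_gt_0.1 = 100 * mean(maf > 0.1),
             N_E = mean(ne), H_O = mean(ho), uH_E = mean(uhe),
             mean_gd = gdd, F_IS = fis)
}
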