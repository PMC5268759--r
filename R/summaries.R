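#' Summarize a genotype collection
#'
#' Computes the descriptive summary reported per species in GBS germplasm
#' surveys: numbers of accessions and SNPs, mean read depth `D` over
#' non-missing calls, the percentage of SNPs whose mean depth reaches
#' `depth_cut`, and the percentages of heterozygous, homozygous and missing
#' calls over all accession-by-SNP cells.
#'
#' @param gm a `genotype_matrix`
#' @param depth_cut integer; SNP-level mean-depth threshold for the
#'   `pct_depth_gt` column (default 20)
#' @return a one-row data.frame with columns `n_accessions`, `n_snps`,
#'   `mean_depth`, `pct_depth_gt`, `pct_het`, `pct_hom`, `pct_missing`.
#'   `pct_het + pct_hom + pct_missing` is exactly 100.
#' @export
summarize_collection <- function(gm, depth_cut = 20L) {
  if (n_accessions(gm) == 0L || n_snps(gm) == 0L) stop("empty genotype matrix")
  d <- gm$dosage
  n_cells <- length(d)
  het <- is_het(gm)
  n_het <- sum(het, na.rm = TRUE)
  n_miss <- sum(is.na(d))
  n_hom <- n_cells - n_het - n_miss

  tot <- gm$ref_depth + gm$alt_depth
  typed <- !is.na(d)
  if (!any(typed)) stop("all calls missing; mean depth undefined")
  mean_depth <- mean(tot[typed])
  snp_depth <- vapply(seq_len(ncol(d)), function(j) {
    tj <- typed[, j]
    if (!any(tj)) NA_real_ else mean(tot[tj, j])
  }, 0)
  pct_gt <- 100 * mean(snp_depth >= depth_cut, na.rm = TRUE)

  data.frame(
    n_accessions = n_accessions(gm), n_snps = n_snps(gm),
    mean_depth = mean_depth, pct_depth_gt = pct_gt,
    pct_het = 100 * n_het / n_cells,
    pct_hom = 100 * n_hom / n_cells,
    pct_missing = 100 * n_miss / n_cells)
}

#' Filter SNPs by frequency, missingness and depth
#'
#' Pre-analysis marker hygiene: keeps SNPs whose minor allele frequency
#' (computed from dosage sums over ploidy-weighted allele copies), call rate
#' and mean depth pass the given thresholds. Accession order is unchanged.
#'
#' @param gm a `genotype_matrix`
#' @param min_maf minimum minor allele frequency in `[0, 0.5]`
#' @param max_missing maximum fraction of missing calls per SNP in `[0, 1]`
#' @param min_mean_depth minimum mean total depth over typed calls
#' @return the filtered `genotype_matrix`; the per-filter removal counts are
#'   attached as attribute `"filter_report"` and reported via `message()`
#' @export
filter_loci <- function(gm, min_maf = 0, max_missing = 1, min_mean_depth = 0) {
  stopifnot(min_maf >= 0, min_maf <= 0.5, max_missing >= 0, max_missing <= 1)
  d <- gm$dosage
  typed <- !is.na(d)
  p_mat <- gm$ploidy * typed  # allele copies contributed per cell

  alt_copies <- colSums(d * typed, na.rm = TRUE)
  tot_copies <- colSums(p_mat)
  p <- ifelse(tot_copies > 0, alt_copies / tot_copies, NA_real_)
  maf <- pmin(p, 1 - p)
  miss_frac <- colMeans(!typed)
  tot <- gm$ref_depth + gm$alt_depth
  mean_dep <- vapply(seq_len(ncol(d)), function(j) {
    tj <- typed[, j]
    if (!any(tj)) 0 else mean(tot[tj, j])
  }, 0)

  fail_maf <- if (min_maf > 0) is.na(maf) | maf < min_maf else rep(FALSE, length(maf))
  fail_miss <- miss_frac > max_missing
  fail_dep <- mean_dep < min_mean_depth
  keep <- !(fail_maf | fail_miss | fail_dep)
  report <- c(maf = sum(fail_maf), missing = sum(fail_miss),
              depth = sum(fail_dep), kept = sum(keep))
  if (!any(keep)) {
    binding <- names(which.max(report[1:3]))
    stop("all SNPs removed; binding filter: ", binding)
  }
  message(sprintf("filter_loci: kept %d/%d SNPs (maf fails %d, missing fails %d, depth fails %d)",
                  sum(keep), length(keep), report["maf"], report["missing"],
                  report["depth"]))
  out <- subset_gm(gm, snps = which(keep))
  attr(out, "filter_report") <- report
  out
}
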