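#' Pairwise modified Gower dissimilarity between two accessions
#'
#' The modified Gower dissimilarity (GD) quantifies identity-by-state across
#' all bi-allelic SNPs typed in both accessions:
#' \deqn{GD(x, y) = 1 - \frac{\sum_i s_i w_i}{\sum_i w_i}}
#' where \eqn{w_i = 1} iff both accessions carry a genotype call at SNP i
#' (pairwise deletion of missing data), and the per-SNP similarity score
#' \eqn{s_i} depends on the coding:
#'
#' * `"collapsed"` — three IBS states per SNP regardless of ploidy
#'   (homozygous reference, heterozygous, homozygous alternate):
#'   \eqn{s = 1} for identical states, \eqn{s = 0.5} for heterozygote vs
#'   either homozygote, \eqn{s = 0} for opposite homozygotes. Valid across
#'   accessions of different ploidy.
#' * `"dosage"` — genotype states are dosage fractions
#'   \eqn{f \in \{0, 1/p, \dots, 1\}} and \eqn{s = 1 - |f_x - f_y|}. On
#'   diploids this reproduces the collapsed scores exactly; on tetraploids it
#'   splits the heterozygous IBS class into the 3:1, 1:1 and 1:3 dosage
#'   states (0.25/0.5/0.75), scoring cross-class heterozygotes by linear
#'   dosage distance. Refuses mixed-ploidy pairs.
#' * `"diploidized"` — collapsed coding restricted to a subset of
#'   effectively diploidized SNPs (see [select_diploidized_snps()]).
#'
#' @param gm a `genotype_matrix`
#' @param a,b accession ids or indices
#' @param coding one of `"collapsed"` (default), `"dosage"`, `"diploidized"`
#' @param diploidized_snp_ids SNP ids to restrict to when
#'   `coding = "diploidized"`
#' @return list with `gd` (fraction in `[0, 1]`, `NA` if the pair shares no
#'   typed SNP) and `n_used` (number of co-genotyped SNPs, \eqn{\sum w_i})
#' @export
gd_pair <- function(gm, a, b, coding = c("collapsed", "dosage", "diploidized"),
                    diploidized_snp_ids = NULL) {
  coding <- match.arg(coding)
  x <- .gd_coordinates(gm, coding, diploidized_snp_ids)
  ai <- .acc_index(gm, a); bi <- .acc_index(gm, b)
  if (coding == "dosage" && gm$ploidy[ai] != gm$ploidy[bi])
    stop("dosage coding is undefined across ploidies; use collapsed coding")
  xa <- x[ai, ]; xb <- x[bi, ]
  w <- !is.na(xa) & !is.na(xb)
  n_used <- sum(w)
  gd <- if (n_used == 0L) NA_real_ else sum(abs(xa[w] - xb[w])) / n_used
  list(gd = gd, n_used = n_used)
}

.acc_index <- function(gm, a) {
  i <- if (is.character(a)) match(a, gm$accessions$accession_id) else as.integer(a)
  if (is.na(i) || i < 1L || i > n_accessions(gm)) stop("unknown accession: ", a)
  i
}

# Genotype coordinates under a GD coding: GD reduces to the mean absolute
# coordinate difference over co-genotyped SNPs, since s = 1 - |x_a - x_b|
# reproduces the 1 / 0.5 / 0 collapsed scores when x is the collapsed state.
.gd_coordinates <- function(gm, coding, diploidized_snp_ids = NULL) {
  if (coding == "dosage") return(dosage_fraction(gm))
  x <- collapsed_state(gm)
  if (coding == "diploidized") {
    if (is.null(diploidized_snp_ids) || length(diploidized_snp_ids) == 0L)
      stop("diploidized coding requires a non-empty SNP subset")
    keep <- match(diploidized_snp_ids, gm$snps$snp_id)
    if (anyNA(keep)) stop("unknown diploidized SNP id(s)")
    x <- x[, keep, drop = FALSE]
  }
  x
}

#' Full pairwise Gower dissimilarity matrix
#'
#' Applies [gd_pair()] to all unordered accession pairs, returning a
#' `gd_dist` object holding the symmetric GD matrix and, mirroring the
#' two-triangle summary matrices of germplasm surveys, the per-pair counts of
#' co-genotyped SNPs. Pairs sharing no typed SNP are recorded as `NA` and
#' reported, never silently zeroed.
#'
#' @inheritParams gd_pair
#' @return a `gd_dist` object: list with `gd` (symmetric numeric matrix,
#'   zero diagonal), `n_snps` (symmetric integer matrix of \eqn{\sum w_i}),
#'   `accession_ids`, `coding`
#' @export
gd_matrix <- function(gm, coding = c("collapsed", "dosage", "diploidized"),
                      diploidized_snp_ids = NULL) {
  coding <- match.arg(coding)
  if (n_accessions(gm) < 2L) stop("need at least 2 accessions")
  if (coding == "dosage" && length(unique(gm$ploidy)) > 1L)
    stop("dosage coding is undefined across ploidies; use collapsed coding")
  x <- .gd_coordinates(gm, coding, diploidized_snp_ids)
  n <- nrow(x)
  ids <- gm$accessions$accession_id
  gd <- matrix(0, n, n, dimnames = list(ids, ids))
  cnt <- matrix(0L, n, n, dimnames = list(ids, ids))
  typed <- !is.na(x)
  x0 <- x; x0[!typed] <- 0
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      w <- typed[a, ] & typed[b, ]
      nw <- sum(w)
      cnt[a, b] <- cnt[b, a] <- nw
      gd[a, b] <- gd[b, a] <-
        if (nw == 0L) NA_real_ else sum(abs(x0[a, w] - x0[b, w])) / nw
    }
  }
  cnt[cbind(seq_len(n), seq_len(n))] <- rowSums(typed)
  n_undef <- sum(is.na(gd[upper.tri(gd)]))
  if (n_undef > 0L)
    warning(n_undef, " accession pair(s) share no typed SNP; GD undefined")
  structure(list(gd = gd, n_snps = cnt, accession_ids = ids, coding = coding),
            class = "gd_dist")
}

#' @export
print.gd_dist <- function(x, ...) {
  v <- x$gd[upper.tri(x$gd)]
  cat(sprintf("gd_dist: %d accessions (%s coding); GD range %.4g..%.4g, mean %.4g\n",
              length(x$accession_ids), x$coding,
              min(v, na.rm = TRUE), max(v, na.rm = TRUE), mean(v, na.rm = TRUE)))
  invisible(x)
}

#' Convert a gd_dist to a stats::dist object
#' @param gdd a `gd_dist`
#' @return a `dist` object of the GD values
#' @export
as_dist <- function(gdd) stats::as.dist(gdd$gd)

#' Select effectively diploidized SNPs in a polyploid collection
#'
#' In a polyploid, markers segregating within (rather than between)
#' homoeologous sub-genomes behave as diploid loci: their heterozygotes show
#' a consistent minor allele-depth ratio near `1/ploidy` (~0.25 in a
#' tetraploid) across accessions. This identifies such SNPs by requiring at
#' least `min_het_accessions` heterozygous accessions whose mean het depth
#' ratio lies within `tol` of `target_ratio` or `1 - target_ratio`, with
#' ratio SD at most `tol`.
#'
#' @param gm a `genotype_matrix` of polyploid (e.g. 4x) accessions
#' @param target_ratio expected minor depth ratio (default 0.25 for 4x)
#' @param tol tolerance on the mean ratio and maximum SD (default 0.05)
#' @param min_het_accessions minimum heterozygous accessions per SNP
#'   (default 3)
#' @param min_site_depth minimum total depth for a het site to contribute its
#'   ratio (default 10)
#' @return character vector of SNP ids (possibly empty)
#' @export
select_diploidized_snps <- function(gm, target_ratio = 0.25, tol = 0.05,
                                    min_het_accessions = 3L,
                                    min_site_depth = 10L) {
  het <- is_het(gm)
  het[is.na(het)] <- FALSE
  tot <- gm$ref_depth + gm$alt_depth
  ratio <- ifelse(tot > 0, gm$alt_depth / tot, NA_real_)
  use <- het & tot >= min_site_depth & !is.na(ratio)
  keep <- vapply(seq_len(n_snps(gm)), function(j) {
    r <- ratio[use[, j], j]
    if (length(r) < min_het_accessions) return(FALSE)
    m <- mean(r)
    s <- if (length(r) > 1L) stats::sd(r) else 0
    near <- abs(m - target_ratio) <= tol || abs(m - (1 - target_ratio)) <= tol
    near && s <= tol
  }, TRUE)
  gm$snps$snp_id[keep]
}

#' Write / read a two-triangle GD summary matrix
#'
#' CSV layout used in germplasm survey supplements: pairwise GD values below
#' the diagonal, co-genotyped SNP counts above the diagonal, per-accession
#' typed-SNP counts on the diagonal.
#'
#' @param gdd a `gd_dist`
#' @param path output CSV path
#' @return `path` (writer) or a `gd_dist` (reader), invisibly
#' @export
write_gd_triangles <- function(gdd, path) {
  n <- length(gdd$accession_ids)
  m <- matrix("", n, n)
  m[lower.tri(m)] <- format(gdd$gd[lower.tri(gdd$gd)], digits = 15, trim = TRUE)
  m[upper.tri(m)] <- gdd$n_snps[upper.tri(gdd$n_snps)]
  diag(m) <- diag(gdd$n_snps)
  out <- cbind(accession_id = gdd$accession_ids, as.data.frame(m))
  names(out)[-1] <- gdd$accession_ids
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gd_triangles
#' @param coding coding label to attach on read (not stored in the CSV)
#' @export
read_gd_triangles <- function(path, coding = "collapsed") {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- tab$accession_id
  m <- as.matrix(tab[, -1, drop = FALSE])
  n <- length(ids)
  gd <- matrix(0, n, n, dimnames = list(ids, ids))
  cnt <- matrix(0L, n, n, dimnames = list(ids, ids))
  gd[lower.tri(gd)] <- suppressWarnings(as.numeric(m[lower.tri(m)]))
  gd[upper.tri(gd)] <- t(gd)[upper.tri(gd)]
  cnt[upper.tri(cnt)] <- suppressWarnings(as.integer(m[upper.tri(m)]))
  cnt[lower.tri(cnt)] <- t(cnt)[lower.tri(cnt)]
  diag(cnt) <- suppressWarnings(as.integer(diag(m)))
  structure(list(gd = gd, n_snps = cnt, accession_ids = ids, coding = coding),
            class = "gd_dist")
}

#' Long-format (tidy) export of a GD matrix
#' @param gdd a `gd_dist`
#' @return data.frame with columns `a`, `b`, `gd`, `n_snps` (unordered pairs)
#' @export
gd_long <- function(gdd) {
  n <- length(gdd$accession_ids)
  idx <- which(upper.tri(gdd$gd), arr.ind = TRUE)
  data.frame(a = gdd$accession_ids[idx[, 1]], b = gdd$accession_ids[idx[, 2]],
             gd = gdd$gd[idx], n_snps = gdd$n_snps[idx],
             stringsAsFactors = FALSE)
}
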