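#' Construct a genotype matrix with allele depths
#'
#' The central data container of the package: an accessions-by-SNPs grid of
#' dosage calls (counts of the alternate allele, `0..ploidy`, `NA` when no
#' genotype was assigned) together with per-cell reference/alternate read
#' depths, per-accession passport metadata, and per-SNP marker metadata.
#'
#' @param dosage integer matrix, accessions in rows, SNPs in columns. `NA`
#'   encodes a missing call. Row/column names, if present, seed the
#'   accession/SNP identifiers.
#' @param ploidy integer vector (length 1 or `nrow(dosage)`) of per-accession
#'   ploidies; must be even and >= 2. Dosages are validated against it.
#' @param ref_depth,alt_depth non-negative integer matrices of per-cell read
#'   depths supporting the reference and alternate allele; default all zero
#'   (depth information absent).
#' @param accessions optional data.frame of passport metadata, one row per
#'   accession. Recognized columns: `accession_id`, `display_name`,
#'   `species_label`, `library_id`, `lane_id`, `total_pe_reads`,
#'   `reported_gender`, `observed_gender`, `ploidy`, `replicate_group`.
#'   Missing columns are filled with defaults.
#' @param snps optional data.frame of marker metadata, one row per SNP.
#'   Recognized columns: `snp_id`, `centroid_id`, `position`, `ref_allele`,
#'   `alt_allele`, `snps_in_centroid`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage`, `ref_depth`, `alt_depth`, `ploidy`, `accessions`, `snps`.
#' @export
genotype_matrix <- function(dosage, ploidy, ref_depth = NULL, alt_depth = NULL,
                            accessions = NULL, snps = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  n_acc <- nrow(dosage)
  n_snp <- ncol(dosage)
  if (length(ploidy) == 1L) ploidy <- rep(ploidy, n_acc)
  ploidy <- as.integer(ploidy)
  if (length(ploidy) != n_acc)
    stop("'ploidy' must have length 1 or nrow(dosage)")
  if (any(ploidy < 2L | ploidy %% 2L != 0L))
    stop("ploidy must be even and >= 2")
  bad <- sweep(dosage, 1L, ploidy, function(d, p) !is.na(d) & (d < 0L | d > p))
  if (any(bad)) stop("dosage outside 0..ploidy for ", sum(bad), " cell(s)")

  zero <- matrix(0L, n_acc, n_snp)
  if (is.null(ref_depth)) ref_depth <- zero else ref_depth <- as.matrix(ref_depth)
  if (is.null(alt_depth)) alt_depth <- zero else alt_depth <- as.matrix(alt_depth)
  storage.mode(ref_depth) <- "integer"
  storage.mode(alt_depth) <- "integer"
  ref_depth[is.na(ref_depth)] <- 0L
  alt_depth[is.na(alt_depth)] <- 0L
  if (!identical(dim(ref_depth), dim(dosage)) ||
      !identical(dim(alt_depth), dim(dosage)))
    stop("depth matrices must match dosage dimensions")
  if (any(ref_depth < 0L) || any(alt_depth < 0L))
    stop("allele depths must be non-negative")

  acc_ids <- rownames(dosage)
  if (is.null(acc_ids)) acc_ids <- sprintf("ACC%03d", seq_len(n_acc))
  snp_ids <- colnames(dosage)
  if (is.null(snp_ids)) snp_ids <- sprintf("SNP%05d", seq_len(n_snp))

  accessions <- .complete_accession_meta(accessions, acc_ids, ploidy)
  if (anyDuplicated(accessions$accession_id))
    stop("accession_id values must be unique")
  snps <- .complete_snp_meta(snps, snp_ids)

  dimnames(dosage) <- dimnames(ref_depth) <- dimnames(alt_depth) <-
    list(accessions$accession_id, snps$snp_id)

  structure(
    list(dosage = dosage, ref_depth = ref_depth, alt_depth = alt_depth,
         ploidy = ploidy, accessions = accessions, snps = snps),
    class = "genotype_matrix")
}

.complete_accession_meta <- function(meta, acc_ids, ploidy) {
  n <- length(acc_ids)
  defaults <- data.frame(
    accession_id = acc_ids,
    display_name = acc_ids,
    species_label = "unknown",
    library_id = "1",
    lane_id = "1",
    total_pe_reads = NA_real_,
    reported_gender = "unknown",
    observed_gender = "unknown",
    ploidy = ploidy,
    replicate_group = NA_character_,
    stringsAsFactors = FALSE)
  if (is.null(meta)) return(defaults)
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (!"accession_id" %in% names(meta))
    stop("passport table must carry an 'accession_id' column")
  idx <- match(acc_ids, meta$accession_id)
  for (col in setdiff(names(defaults), "accession_id")) {
    if (col %in% names(meta)) {
      vals <- meta[[col]][idx]
      keep <- !is.na(idx) & !is.na(vals)
      defaults[[col]][keep] <- vals[keep]
    }
  }
  defaults$ploidy <- ploidy  # the authoritative per-accession ploidy
  defaults
}

.complete_snp_meta <- function(meta, snp_ids) {
  n <- length(snp_ids)
  defaults <- data.frame(
    snp_id = snp_ids,
    centroid_id = snp_ids,
    position = NA_integer_,
    ref_allele = "A",
    alt_allele = "C",
    snps_in_centroid = 1L,
    stringsAsFactors = FALSE)
  if (is.null(meta)) return(defaults)
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (!"snp_id" %in% names(meta)) meta$snp_id <- snp_ids
  idx <- match(snp_ids, meta$snp_id)
  for (col in setdiff(names(defaults), "snp_id")) {
    if (col %in% names(meta)) {
      vals <- meta[[col]][idx]
      keep <- !is.na(idx) & !is.na(vals)
      defaults[[col]][keep] <- vals[keep]
    }
  }
  defaults
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d accessions x %d SNPs\n",
              n_accessions(x), n_snps(x)))
  tb <- table(x$ploidy)
  cat(sprintf("  ploidies: %s\n",
              paste(sprintf("%sx:%d", names(tb), as.integer(tb)), collapse = " ")))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Number of accessions / SNPs in a genotype matrix
#' @param gm a `genotype_matrix`
#' @return integer scalar
#' @export
n_accessions <- function(gm) nrow(gm$dosage)

#' @rdname n_accessions
#' @export
n_snps <- function(gm) ncol(gm$dosage)

#' Dosage fractions of a genotype matrix
#'
#' Returns the matrix of dosage fractions `f = dosage / ploidy`, the universal
#' genotype coordinate that makes diploid, tetraploid and hexaploid calls
#' comparable (0 = homozygous reference, 1 = homozygous alternate).
#'
#' @param gm a `genotype_matrix`
#' @return numeric matrix with `NA` where calls are missing
#' @export
dosage_fraction <- function(gm) {
  gm$dosage / gm$ploidy
}

#' Collapsed identity-by-state genotype coordinates
#'
#' Maps every call to one of three states irrespective of ploidy:
#' 0 (homozygous reference), 0.5 (heterozygous, `0 < dosage < ploidy`),
#' 1 (homozygous alternate).
#'
#' @param gm a `genotype_matrix`
#' @return numeric matrix in \{0, 0.5, 1\} with `NA` for missing calls
#' @export
collapsed_state <- function(gm) {
  f <- dosage_fraction(gm)
  s <- f
  s[f > 0 & f < 1] <- 0.5
  s
}

#' Heterozygosity indicator matrix
#' @param gm a `genotype_matrix`
#' @return logical matrix; `TRUE` where `0 < dosage < ploidy`, `NA` if missing
#' @keywords internal
is_het <- function(gm) {
  d <- gm$dosage
  d > 0L & d < gm$ploidy
}

#' Subset a genotype matrix
#'
#' @param gm a `genotype_matrix`
#' @param accessions accession ids or indices to keep (default all)
#' @param snps SNP ids or indices to keep (default all)
#' @return a `genotype_matrix` restricted to the requested rows/columns
#' @export
subset_gm <- function(gm, accessions = NULL, snps = NULL) {
  ai <- if (is.null(accessions)) seq_len(n_accessions(gm)) else {
    if (is.character(accessions)) match(accessions, gm$accessions$accession_id)
    else accessions
  }
  if (anyNA(ai)) stop("unknown accession id(s)")
  si <- if (is.null(snps)) seq_len(n_snps(gm)) else {
    if (is.character(snps)) match(snps, gm$snps$snp_id) else snps
  }
  if (anyNA(si)) stop("unknown SNP id(s)")
  genotype_matrix(gm$dosage[ai, si, drop = FALSE], gm$ploidy[ai],
                  gm$ref_depth[ai, si, drop = FALSE],
                  gm$alt_depth[ai, si, drop = FALSE],
                  accessions = gm$accessions[ai, , drop = FALSE],
                  snps = gm$snps[si, , drop = FALSE])
}
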