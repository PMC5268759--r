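#' Read a genotype matrix from a VCF file
#'
#' Ingests a VCF 4.x file carrying per-sample `GT` (and, for the ploidy and
#' threshold stages, `AD`) fields. Dosage is the count of non-reference
#' alleles in `GT` at any ploidy (e.g. `0/0/0/1` gives dosage 1 of ploidy 4);
#' a missing `GT` (`./.` or `.`) gives a missing call. Allele depths come
#' from `AD` (`ref,alt`).
#'
#' @param path path to a (plain-text or gzipped) VCF file
#' @param passport optional passport data.frame (see [read_passport()]) or
#'   path to a passport CSV; matched to VCF samples by `accession_id`
#' @param strict logical; if `TRUE`, multi-allelic records and VCF samples
#'   absent from the passport are errors. If `FALSE` (default), multi-allelic
#'   records are reduced to their major alternate allele with a warning
#'   (genotypes carrying a minor alternate allele become missing), and
#'   unmatched samples only warn.
#' @return a [genotype_matrix()]
#' @export
read_vcf <- function(path, passport = NULL, strict = FALSE) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  keep_allele <- rep(1L, length(alt))
  if (any(multi)) {
    if (strict) stop(sum(multi), " multi-allelic record(s) in strict mode")
    warning(sum(multi),
            " multi-allelic record(s) reduced to their major alternate allele")
  }

  gt <- vcfR::extract.gt(v, element = "GT")
  ad <- tryCatch(vcfR::extract.gt(v, element = "AD"), error = function(e) NULL)
  samples <- colnames(gt)
  n_snp <- nrow(gt)
  n_acc <- length(samples)

  ad_counts <- function(ad_str, allele) {
    # per-record vector of sample AD strings -> ref/alt integer counts
    out_ref <- integer(length(ad_str)); out_alt <- integer(length(ad_str))
    ok <- !is.na(ad_str) & ad_str != "."
    if (any(ok)) {
      parts <- strsplit(ad_str[ok], ",", fixed = TRUE)
      out_ref[ok] <- vapply(parts, function(p) suppressWarnings(as.integer(p[1])), 1L)
      out_alt[ok] <- vapply(parts, function(p) {
        a <- suppressWarnings(as.integer(p[allele + 1L]))
        if (is.na(a)) 0L else a
      }, 1L)
      out_ref[is.na(out_ref)] <- 0L
    }
    list(ref = out_ref, alt = out_alt)
  }

  dosage <- matrix(NA_integer_, n_acc, n_snp)
  refd <- matrix(0L, n_acc, n_snp)
  altd <- matrix(0L, n_acc, n_snp)
  ploidy_obs <- matrix(NA_integer_, n_acc, n_snp)

  if (any(multi) && !is.null(ad)) {
    # choose major alternate by total depth across samples
    for (j in which(multi)) {
      tot <- rep(0, length(strsplit(alt[j], ",")[[1]]))
      ok <- !is.na(ad[j, ]) & ad[j, ] != "."
      for (p in strsplit(ad[j, ok], ",", fixed = TRUE)) {
        a <- suppressWarnings(as.integer(p[-1]))
        a[is.na(a)] <- 0L
        tot[seq_along(a)] <- tot[seq_along(a)] + a
      }
      keep_allele[j] <- which.max(tot)
    }
  }

  for (j in seq_len(n_snp)) {
    g <- gt[j, ]
    al <- strsplit(ifelse(is.na(g), ".", g), "[/|]")
    k <- as.character(keep_allele[j])
    for (i in seq_len(n_acc)) {
      a <- al[[i]]
      if (length(a) == 0L || any(a == ".") || all(a == "")) next
      other_alt <- a != "0" & a != k
      if (any(other_alt)) next  # carries a dropped alternate allele
      dosage[i, j] <- sum(a == k)
      ploidy_obs[i, j] <- length(a)
    }
    if (!is.null(ad)) {
      d <- ad_counts(ad[j, ], keep_allele[j])
      refd[, j] <- d$ref
      altd[, j] <- d$alt
    }
  }

  ploidy <- apply(ploidy_obs, 1L, function(p) {
    p <- p[!is.na(p)]
    if (length(p) == 0L) 2L else as.integer(stats::median(p))
  })

  meta <- NULL
  if (!is.null(passport)) {
    meta <- if (is.character(passport)) read_passport(passport) else passport
    missing_samp <- setdiff(samples, meta$accession_id)
    if (length(missing_samp)) {
      msg <- paste0("VCF sample(s) absent from passport: ",
                    paste(missing_samp, collapse = ", "))
      if (strict) stop(msg) else warning(msg)
    }
    pp <- meta$ploidy[match(samples, meta$accession_id)]
    ploidy <- ifelse(!is.na(pp), as.integer(pp), ploidy)
  }

  rownames(dosage) <- samples
  alt_out <- vapply(seq_along(alt), function(j)
    strsplit(alt[j], ",", fixed = TRUE)[[1]][keep_allele[j]], "")
  snps <- data.frame(
    snp_id = if (all(is.na(fix[, "ID"])) )
      paste0(fix[, "CHROM"], "_", fix[, "POS"]) else fix[, "ID"],
    centroid_id = fix[, "CHROM"],
    position = suppressWarnings(as.integer(fix[, "POS"])),
    ref_allele = fix[, "REF"],
    alt_allele = alt_out,
    snps_in_centroid = 1L,
    stringsAsFactors = FALSE)
  colnames(dosage) <- snps$snp_id
  genotype_matrix(dosage, ploidy, refd, altd, accessions = meta, snps = snps)
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits a VCF 4.2 file with `GT` and `AD` per-sample fields, using each
#' accession's ploidy to lay out the genotype string (alternate alleles
#' listed last, e.g. dosage 1 of ploidy 4 becomes `0/0/0/1`).
#'
#' @param gm a `genotype_matrix`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_vcf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=germdecon",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$accessions$accession_id), collapse = "\t")), con)
  n_acc <- n_accessions(gm)
  for (j in seq_len(n_snps(gm))) {
    cells <- character(n_acc)
    for (i in seq_len(n_acc)) {
      d <- gm$dosage[i, j]
      p <- gm$ploidy[i]
      gt <- if (is.na(d)) paste(rep(".", p), collapse = "/")
            else paste(c(rep("0", p - d), rep("1", d)), collapse = "/")
      cells[i] <- paste0(gt, ":", gm$ref_depth[i, j], ",", gm$alt_depth[i, j])
    }
    s <- gm$snps[j, ]
    pos <- if (is.na(s$position)) j else s$position
    writeLines(paste(c(s$centroid_id, pos, s$snp_id, s$ref_allele,
                       s$alt_allele, ".", "PASS", ".", "GT:AD", cells),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a genotype matrix from a tabular master file
#'
#' Reads the package's documented TSV/CSV genotype-table dialect: one row per
#' SNP with marker-metadata columns `snp_id`, `centroid_id`, `position`,
#' `ref_allele`, `alt_allele`, `snps_in_centroid`, followed by one column per
#' accession whose cells are `dosage|ref,alt` (dosage `.` when the call is
#' missing). A header row `#ploidy` maps each accession column to its ploidy.
#'
#' @param path path to the table
#' @param simplex_only logical; drop SNPs whose centroid carries more than one
#'   polymorphism (`snps_in_centroid > 1`), retaining only high-confidence
#'   simplex markers
#' @param passport optional passport data.frame or CSV path
#' @param sep field separator, `"\t"` (default) or `","`
#' @return a [genotype_matrix()]
#' @export
read_genotype_table <- function(path, simplex_only = FALSE, passport = NULL,
                                sep = "\t") {
  if (!file.exists(path)) stop("cannot read genotype table: ", path)
  lines <- readLines(path)
  ploidy_line <- grep("^#ploidy", lines, value = TRUE)
  tab <- utils::read.table(text = lines[!startsWith(lines, "#")], sep = sep,
                           header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character")
  meta_cols <- c("snp_id", "centroid_id", "position", "ref_allele",
                 "alt_allele", "snps_in_centroid")
  if (!all(meta_cols %in% names(tab)))
    stop("malformed genotype table: missing column(s) ",
         paste(setdiff(meta_cols, names(tab)), collapse = ", "))
  acc_cols <- names(tab)[!names(tab) %in% meta_cols]
  if (length(acc_cols) == 0L) stop("genotype table has no accession columns")
  if (anyDuplicated(acc_cols))
    stop("duplicate accession column name(s): ",
         paste(unique(acc_cols[duplicated(acc_cols)]), collapse = ", "))

  snps <- data.frame(snp_id = tab$snp_id, centroid_id = tab$centroid_id,
                     position = suppressWarnings(as.integer(tab$position)),
                     ref_allele = tab$ref_allele, alt_allele = tab$alt_allele,
                     snps_in_centroid = as.integer(tab$snps_in_centroid),
                     stringsAsFactors = FALSE)
  if (simplex_only) {
    keep <- snps$snps_in_centroid == 1L
    tab <- tab[keep, , drop = FALSE]
    snps <- snps[keep, , drop = FALSE]
  }
  n_snp <- nrow(tab)
  n_acc <- length(acc_cols)

  ploidy <- rep(2L, n_acc)
  if (length(ploidy_line)) {
    pv <- strsplit(sub("^#ploidy[\t ,]*", "", ploidy_line[1]),
                   if (sep == "\t") "\t" else sep)[[1]]
    if (length(pv) == n_acc) ploidy <- as.integer(pv)
  }

  dosage <- matrix(NA_integer_, n_acc, n_snp)
  refd <- matrix(0L, n_acc, n_snp)
  altd <- matrix(0L, n_acc, n_snp)
  for (i in seq_len(n_acc)) {
    cells <- tab[[acc_cols[i]]]
    parts <- strsplit(cells, "|", fixed = TRUE)
    bad <- lengths(parts) != 2L
    if (any(bad)) stop("malformed cell(s) in column ", acc_cols[i])
    d <- vapply(parts, `[`, "", 1L)
    dp <- strsplit(vapply(parts, `[`, "", 2L), ",", fixed = TRUE)
    dosage[i, ] <- suppressWarnings(as.integer(ifelse(d == ".", NA, d)))
    refd[i, ] <- as.integer(vapply(dp, `[`, "", 1L))
    altd[i, ] <- as.integer(vapply(dp, `[`, "", 2L))
  }
  rownames(dosage) <- acc_cols
  colnames(dosage) <- snps$snp_id
  meta <- if (is.character(passport)) read_passport(passport) else passport
  genotype_matrix(dosage, ploidy, refd, altd, accessions = meta, snps = snps)
}

#' Write a genotype matrix in the tabular dialect of [read_genotype_table()]
#'
#' @param gm a `genotype_matrix`
#' @param path output file path
#' @param sep field separator (default tab)
#' @return `path`, invisibly
#' @export
write_genotype_table <- function(gm, path, sep = "\t") {
  d <- gm$dosage
  cells <- matrix(paste0(ifelse(is.na(d), ".", d), "|",
                         gm$ref_depth, ",", gm$alt_depth),
                  nrow = nrow(d))
  header <- paste(c("snp_id", "centroid_id", "position", "ref_allele",
                    "alt_allele", "snps_in_centroid",
                    gm$accessions$accession_id), collapse = sep)
  ploidy_line <- paste0("#ploidy", sep, paste(gm$ploidy, collapse = sep))
  s <- gm$snps
  rows <- vapply(seq_len(n_snps(gm)), function(j) {
    paste(c(s$snp_id[j], s$centroid_id[j],
            ifelse(is.na(s$position[j]), "", s$position[j]),
            s$ref_allele[j], s$alt_allele[j], s$snps_in_centroid[j],
            cells[, j]), collapse = sep)
  }, "")
  writeLines(c(ploidy_line, header, rows), path)
  invisible(path)
}

#' Read an accession passport table
#'
#' A CSV with one row per accession. Required column: `accession_id`.
#' Recognized optional columns: `display_name`, `species_label`, `library_id`,
#' `lane_id`, `total_pe_reads`, `reported_gender`, `observed_gender`,
#' `ploidy`, `replicate_group`.
#'
#' @param path path to the CSV
#' @return a data.frame
#' @export
read_passport <- function(path) {
  pp <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"accession_id" %in% names(pp))
    stop("passport table must carry an 'accession_id' column")
  pp
}
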