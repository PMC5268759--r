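#' Allele-depth ratios at heterozygous sites
#'
#' For one accession, returns `alt / (ref + alt)` at every heterozygous,
#' non-missing SNP with total depth at least `min_site_depth`. The shape of
#' this distribution reveals ploidy: diploid heterozygotes cluster at 0.5,
#' tetraploids show three modes near 0.25/0.5/0.75, hexaploids five modes
#' near 0.17/0.33/0.5/0.67/0.83.
#'
#' @param gm a `genotype_matrix`
#' @param accession accession id or index
#' @param min_site_depth minimum total depth for a site to contribute
#'   (default 20; ratio precision scales with depth)
#' @return numeric vector of ratios in (0, 1); may be empty
#' @export
het_depth_ratios <- function(gm, accession, min_site_depth = 20L) {
  i <- .acc_index(gm, accession)
  d <- gm$dosage[i, ]
  het <- !is.na(d) & d > 0L & d < gm$ploidy[i]
  tot <- gm$ref_depth[i, ] + gm$alt_depth[i, ]
  use <- het & tot >= min_site_depth
  as.numeric(gm$alt_depth[i, use] / tot[use])
}

#' Detect modes of an allele-depth-ratio distribution
#'
#' Fits a Gaussian kernel density on the ratio distribution and returns local
#' maxima whose density reaches `min_prominence` times the global maximum,
#' restricted to `[0.05, 0.95]` (residual sequencing error piles mass near
#' 0 and 1). Maxima closer together than `merge_radius` — narrower than the
#' smallest spacing of any ploidy template (1/6) — are merged into their
#' density-weighted mean position, so that sampling wiggle on top of one true
#' mode is not reported as several.
#'
#' @param ratios numeric vector of het depth ratios
#' @param bandwidth KDE bandwidth; `NULL` (default) uses the Sheather-Jones
#'   plug-in (`bw.SJ`; falls back to Silverman's `bw.nrd0` if it fails),
#'   which tracks multimodal mixtures better than Silverman's rule
#' @param min_prominence minimum peak density as a fraction of the global
#'   maximum density (default 0.1)
#' @param min_het_loci minimum number of ratios required (default 100); fewer
#'   raises a condition of class `germdecon_insufficient_data`
#' @param merge_radius maxima closer than this are pooled (default 0.1)
#' @return object of class `ratio_peaks`: list with `positions` (sorted
#'   increasing), `density` (the `stats::density` fit) and `n` (ratios used)
#' @export
detect_ratio_peaks <- function(ratios, bandwidth = NULL, min_prominence = 0.1,
                               min_het_loci = 100L, merge_radius = 0.1) {
  ratios <- ratios[!is.na(ratios)]
  if (length(ratios) < min_het_loci) {
    cond <- structure(
      class = c("germdecon_insufficient_data", "error", "condition"),
      list(message = sprintf("only %d het ratios (< %d)", length(ratios),
                             min_het_loci), call = sys.call()))
    stop(cond)
  }
  bw <- if (is.null(bandwidth)) {
    # floor the plug-in bandwidth: depth ratios live on a coarse lattice of
    # read counts, which can drive bw.SJ towards zero and shatter one mode
    max(0.02,
        tryCatch(stats::bw.SJ(ratios), error = function(e) stats::bw.nrd0(ratios)))
  } else bandwidth
  dens <- stats::density(ratios, bw = bw, from = 0, to = 1, n = 512)
  y <- dens$y
  x <- dens$x
  k <- 2:(length(y) - 1L)
  is_max <- y[k] > y[k - 1L] & y[k] >= y[k + 1L]
  pos <- x[k][is_max]
  height <- y[k][is_max]
  keep <- pos >= 0.05 & pos <= 0.95 & height >= min_prominence * max(y)
  pos <- pos[keep]; height <- height[keep]
  # pool maxima closer than merge_radius (density-weighted mean position)
  while (length(pos) > 1L) {
    ord <- order(pos)
    pos <- pos[ord]; height <- height[ord]
    gaps <- diff(pos)
    if (min(gaps) >= merge_radius) break
    i <- which.min(gaps)
    w <- height[i:(i + 1L)]
    pos[i] <- sum(pos[i:(i + 1L)] * w) / sum(w)
    height[i] <- max(w)
    pos <- pos[-(i + 1L)]; height <- height[-(i + 1L)]
  }
  structure(list(positions = sort(pos), density = dens,
                 n = length(ratios)), class = "ratio_peaks")
}

#' @export
print.ratio_peaks <- function(x, ...) {
  cat(sprintf("ratio_peaks: %d peak(s) at %s (n = %d het ratios)\n",
              length(x$positions),
              paste(sprintf("%.3f", x$positions), collapse = ", "), x$n))
  invisible(x)
}

# canonical heterozygous depth-ratio templates per ploidy
.ploidy_templates <- list(
  `2` = 0.5,
  `4` = c(0.25, 0.5, 0.75),
  `6` = c(1, 2, 3, 4, 5) / 6)

#' Infer ploidy from detected depth-ratio peaks
#'
#' Matches the detected peak positions against the canonical templates
#' \{0.5\} (2x), \{0.25, 0.5, 0.75\} (4x) and \{1/6..5/6\} (6x) by
#' nearest-template assignment with a per-peak tolerance of ±`tol`. A
#' template is consistent when every template position is matched by exactly
#' one observed peak and no observed peak is left unmatched. Exactly one
#' consistent template yields that ploidy; otherwise the call is `unclear`.
#' When the KDE is available (a `ratio_peaks` input) and only the central
#' 0.5 peak was found, the 2x call is downgraded to `unclear` if the density
#' at the tetraploid shoulder positions (0.25/0.75) reaches half the central
#' peak density — a conservative guard against suppressed shoulders.
#'
#' @param peaks numeric vector of peak positions, or a `ratio_peaks` object
#' @param tol per-peak matching tolerance (default 0.06)
#' @param accession_id optional id recorded in the result
#' @return object of class `ploidy_call`: list with `accession_id`,
#'   `n_het_loci_used`, `peak_positions`, `inferred_ploidy` (2, 4, 6 or `NA`)
#'   and `status` (`"ok"`, `"unclear"` or `"insufficient_data"`)
#' @export
infer_ploidy <- function(peaks, tol = 0.06, accession_id = NA_character_) {
  dens <- NULL
  n_used <- NA_integer_
  if (inherits(peaks, "ratio_peaks")) {
    dens <- peaks$density
    n_used <- peaks$n
    peaks <- peaks$positions
  }
  consistent <- vapply(names(.ploidy_templates), function(p) {
    tmpl <- .ploidy_templates[[p]]
    if (length(peaks) != length(tmpl)) return(FALSE)
    all(abs(sort(peaks) - tmpl) <= tol)
  }, TRUE)
  ploidy <- NA_integer_
  status <- "unclear"
  if (sum(consistent) == 1L) {
    ploidy <- as.integer(names(.ploidy_templates)[consistent])
    status <- "ok"
    if (ploidy == 2L && !is.null(dens)) {
      at <- function(q) dens$y[which.min(abs(dens$x - q))]
      if (max(at(0.25), at(0.75)) >= 0.5 * at(0.5)) {
        ploidy <- NA_integer_
        status <- "unclear"
      }
    }
  }
  structure(list(accession_id = accession_id, n_het_loci_used = n_used,
                 peak_positions = peaks, inferred_ploidy = ploidy,
                 status = status), class = "ploidy_call")
}

#' @export
print.ploidy_call <- function(x, ...) {
  cat(sprintf("ploidy_call %s: %s (peaks: %s)\n",
              x$accession_id,
              if (x$status == "ok") paste0(x$inferred_ploidy, "x") else x$status,
              paste(sprintf("%.3f", x$peak_positions), collapse = ", ")))
  invisible(x)
}

#' Infer ploidy for every accession in a collection
#'
#' Runs [het_depth_ratios()], [detect_ratio_peaks()] and [infer_ploidy()] per
#' accession and tabulates the calls.
#'
#' @param gm a `genotype_matrix`
#' @param min_site_depth minimum depth per het site (default 20)
#' @param min_het_loci minimum het ratios per accession (default 100)
#' @param bandwidth,min_prominence,tol passed to the peak detector / matcher
#' @return data.frame with one row per accession: `accession_id`,
#'   `n_het_loci_used`, `n_peaks`, `peak_positions` (comma-separated),
#'   `inferred_ploidy`, `status`
#' @export
infer_ploidy_all <- function(gm, min_site_depth = 20L, min_het_loci = 100L,
                             bandwidth = NULL, min_prominence = 0.1,
                             tol = 0.06) {
  rows <- lapply(seq_len(n_accessions(gm)), function(i) {
    id <- gm$accessions$accession_id[i]
    r <- het_depth_ratios(gm, i, min_site_depth)
    pk <- tryCatch(
      detect_ratio_peaks(r, bandwidth, min_prominence, min_het_loci),
      germdecon_insufficient_data = function(e) NULL)
    if (is.null(pk)) {
      return(data.frame(accession_id = id, n_het_loci_used = length(r),
                        n_peaks = NA_integer_, peak_positions = "",
                        inferred_ploidy = NA_integer_,
                        status = "insufficient_data",
                        stringsAsFactors = FALSE))
    }
    call <- infer_ploidy(pk, tol, accession_id = id)
    data.frame(accession_id = id, n_het_loci_used = pk$n,
               n_peaks = length(pk$positions),
               peak_positions = paste(sprintf("%.3f", pk$positions),
                                      collapse = ","),
               inferred_ploidy = call$inferred_ploidy, status = call$status,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Annotate unresolved ploidy calls from redundancy partners
#'
#' Accessions whose depth-ratio distribution is unclear can inherit the
#' ploidy of a redundant partner (an accession of the same genotype). This
#' post-redundancy pass never overwrites an `ok` call: it only fills
#' `unclear`/`insufficient_data` rows whose redundancy group contains exactly
#' one distinct `ok` ploidy, setting status to `"inherited"`.
#'
#' @param calls data.frame from [infer_ploidy_all()]
#' @param partition a [redundancy_groups()] partition over the same accessions
#' @return the annotated calls data.frame
#' @export
annotate_ploidy_from_redundancy <- function(calls, partition) {
  for (grp in partition$groups) {
    rows <- match(grp, calls$accession_id)
    rows <- rows[!is.na(rows)]
    ok <- rows[calls$status[rows] == "ok"]
    pl <- unique(calls$inferred_ploidy[ok])
    if (length(pl) == 1L) {
      fill <- rows[calls$status[rows] %in% c("unclear", "insufficient_data")]
      calls$inferred_ploidy[fill] <- pl
      calls$status[fill] <- "inherited"
    }
  }
  calls
}

#' Plot the heterozygous depth-ratio distribution of an accession
#'
#' Histogram plus kernel density with detected peaks marked; the visual used
#' to judge ploidy.
#'
#' @param gm a `genotype_matrix`
#' @param accession accession id or index
#' @param min_site_depth,min_het_loci,bandwidth,min_prominence as in
#'   [infer_ploidy_all()]
#' @param ... passed to [graphics::hist()]
#' @return the `ratio_peaks` object, invisibly
#' @export
plot_depth_ratios <- function(gm, accession, min_site_depth = 20L,
                              min_het_loci = 100L, bandwidth = NULL,
                              min_prominence = 0.1, ...) {
  r <- het_depth_ratios(gm, accession, min_site_depth)
  graphics::hist(r, breaks = seq(0, 1, by = 0.02), freq = FALSE,
                 xlab = "alt-allele depth ratio",
                 main = paste0("Het depth ratios: ", accession), ...)
  pk <- tryCatch(
    detect_ratio_peaks(r, bandwidth, min_prominence, min_het_loci),
    germdecon_insufficient_data = function(e) NULL)
  if (!is.null(pk)) {
    graphics::lines(pk$density, col = "steelblue", lwd = 2)
    graphics::abline(v = pk$positions, col = "firebrick", lty = 2)
  }
  invisible(pk)
}
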