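#' Collect replicate GD sets from a dissimilarity matrix
#'
#' Accessions tagged with a shared `replicate_group` are replicate samples of
#' one genotype. Every replicate pair is classified by its library/lane
#' passport fields: same `library_id` and `lane_id` gives a *biological*
#' replicate pair (duplicate DNA isolations within one library and lane),
#' anything else a *technical* pair (duplicates split across library
#' preparations or lanes, which carry larger genotyping error). The pair GDs
#' are pulled from `gdd`.
#'
#' @param gdd a `gd_dist` from [gd_matrix()]
#' @param meta accession passport data.frame (e.g. `gm$accessions`) with
#'   `accession_id`, `replicate_group`, `library_id`, `lane_id`
#' @return list of `replicate_gd_set` objects (categories `"biological"`
#'   and/or `"technical"`), each a list with `category`, `gd_values`,
#'   `pair_labels`
#' @export
replicate_gd_sets <- function(gdd, meta) {
  grp <- meta$replicate_group
  tags <- unique(grp[!is.na(grp) & grp != ""])
  if (length(tags) == 0L) stop("no replicate_group tags present")
  bio <- list(gd = numeric(), labels = character())
  tech <- list(gd = numeric(), labels = character())
  for (tag in tags) {
    members <- meta$accession_id[!is.na(grp) & grp == tag]
    if (length(members) < 2L) {
      warning("replicate_group '", tag, "' has < 2 members; skipped")
      next
    }
    for (i in seq_len(length(members) - 1L)) {
      for (j in (i + 1L):length(members)) {
        a <- members[i]; b <- members[j]
        ia <- match(a, meta$accession_id); ib <- match(b, meta$accession_id)
        same <- meta$library_id[ia] == meta$library_id[ib] &&
          meta$lane_id[ia] == meta$lane_id[ib]
        gd <- gdd$gd[a, b]
        lab <- paste(a, b, sep = "~")
        if (same) {
          bio$gd <- c(bio$gd, gd); bio$labels <- c(bio$labels, lab)
        } else {
          tech$gd <- c(tech$gd, gd); tech$labels <- c(tech$labels, lab)
        }
      }
    }
  }
  out <- list()
  if (length(bio$gd))
    out$biological <- new_replicate_gd_set("biological", bio$gd, bio$labels)
  if (length(tech$gd))
    out$technical <- new_replicate_gd_set("technical", tech$gd, tech$labels)
  out
}

#' Construct a replicate GD set
#' @param category `"biological"`, `"technical"` or `"subsampling"`
#' @param gd_values non-negative pairwise GD values
#' @param pair_labels optional pair labels
#' @return a `replicate_gd_set`
#' @export
new_replicate_gd_set <- function(category = c("biological", "technical",
                                              "subsampling"),
                                 gd_values, pair_labels = NULL) {
  category <- match.arg(category)
  if (any(gd_values < 0, na.rm = TRUE)) stop("GD values must be non-negative")
  structure(list(category = category, gd_values = as.numeric(gd_values),
                 pair_labels = pair_labels %||% rep(NA_character_,
                                                    length(gd_values))),
            class = "replicate_gd_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' In-silico read sub-sampling of one accession
#'
#' Emulates re-sequencing at reduced coverage: for each of `n_subsamples`
#' sub-samples, every SNP's reference and alternate depths are independently
#' binomially thinned at rate `fraction` (the with-replacement read-sampling
#' approximation at the allele-count level), and genotypes are re-called with
#' [call_genotypes()]. The pairwise GDs among the derived profiles estimate
#' intra-library genotyping error without wet-lab replicates.
#'
#' @param gm a `genotype_matrix` with allele depths
#' @param accession accession id or index
#' @param fraction thinning rate in (0, 1] (default 0.5)
#' @param n_subsamples number of derived profiles (default 10, giving 45
#'   profile pairs)
#' @param seed integer seed
#' @param min_call_depth,min_minor_reads caller parameters (defaults 6 / 3)
#' @return list with `profiles` (an `n_subsamples` x SNP dosage matrix) and
#'   `ploidy`
#' @export
subsample_depths <- function(gm, accession, fraction = 0.5, n_subsamples = 10L,
                             seed, min_call_depth = 6L, min_minor_reads = 3L) {
  if (missing(seed)) stop("a seed is required")
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  i <- .acc_index(gm, accession)
  ref <- gm$ref_depth[i, ]; alt <- gm$alt_depth[i, ]
  if (all(ref + alt == 0L)) stop("accession has no allele depth data")
  p <- gm$ploidy[i]
  set.seed(seed)
  profiles <- t(vapply(seq_len(n_subsamples), function(s) {
    r2 <- stats::rbinom(length(ref), ref, fraction)
    a2 <- stats::rbinom(length(alt), alt, fraction)
    call_genotypes(r2, a2, p, min_call_depth, min_minor_reads)
  }, integer(length(ref))))
  rownames(profiles) <- sprintf("%s_sub%02d", gm$accessions$accession_id[i],
                                seq_len(n_subsamples))
  list(profiles = profiles, ploidy = p)
}

#' Replicate GD set from read sub-sampling
#'
#' Convenience wrapper: runs [subsample_depths()] and computes all pairwise
#' GDs among the derived profiles (collapsed coding).
#'
#' @inheritParams subsample_depths
#' @return a `replicate_gd_set` of category `"subsampling"`
#' @export
subsample_gd_set <- function(gm, accession, fraction = 0.5, n_subsamples = 10L,
                             seed, min_call_depth = 6L, min_minor_reads = 3L) {
  sub <- subsample_depths(gm, accession, fraction, n_subsamples, seed,
                          min_call_depth, min_minor_reads)
  sgm <- genotype_matrix(sub$profiles, sub$ploidy)
  gdd <- gd_matrix(sgm, coding = "collapsed")
  long <- gd_long(gdd)
  new_replicate_gd_set("subsampling", long$gd,
                       paste(long$a, long$b, sep = "~"))
}

#' Estimate the GD redundancy threshold from a replicate GD set
#'
#' The replicate GD distribution describes the dissimilarity expected between
#' samples of the *same* genotype. The redundancy cutoff GD_99% is the
#' one-sided 99th percentile of that distribution: normality is checked with
#' a Shapiro–Wilk test, and if not rejected (p >= 0.05) the normal percentile
#' `mean + z * sd` (z = 2.3263 at 99%) is used; otherwise the empirical
#' percentile.
#'
#' @param set a `replicate_gd_set`, or a bare numeric vector of GD values
#' @param confidence one-sided coverage of the threshold (default 0.99)
#' @return object of class `threshold_estimate`: list with `category`,
#'   `n`, `mean_gd`, `sd_gd`, `shapiro_W`, `shapiro_p`, `gd99`, `method`
#'   (`"normal_percentile"`, `"empirical_percentile"` or `"degenerate"`)
#' @export
estimate_threshold <- function(set, confidence = 0.99) {
  if (inherits(set, "replicate_gd_set")) {
    category <- set$category
    g <- set$gd_values
  } else {
    category <- "unspecified"
    g <- as.numeric(set)
  }
  g <- g[!is.na(g)]
  if (length(g) < 3L) stop("need at least 3 GD values")
  m <- mean(g)
  s <- stats::sd(g)
  if (s == 0) {
    warning("degenerate replicate GD distribution (zero SD); gd99 = mean")
    return(structure(list(category = category, n = length(g), mean_gd = m,
                          sd_gd = 0, shapiro_W = NA_real_, shapiro_p = NA_real_,
                          gd99 = m, method = "degenerate"),
                     class = "threshold_estimate"))
  }
  # shapiro.test caps n at 5000; use a deterministic subset beyond that
  sw_g <- if (length(g) > 5000L) g[round(seq(1L, length(g), length.out = 5000L))] else g
  sw <- stats::shapiro.test(sw_g)
  if (sw$p.value >= 0.05) {
    gd99 <- m + stats::qnorm(confidence) * s
    method <- "normal_percentile"
  } else {
    gd99 <- as.numeric(stats::quantile(g, confidence, type = 7))
    method <- "empirical_percentile"
  }
  structure(list(category = category, n = length(g), mean_gd = m, sd_gd = s,
                 shapiro_W = unname(sw$statistic), shapiro_p = sw$p.value,
                 gd99 = gd99, method = method),
            class = "threshold_estimate")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf("threshold_estimate (%s, n = %s): mean GD %.4f, GD99 %.4f [%s]\n",
              x$category, x$n %||% NA, x$mean_gd, x$gd99, x$method))
  invisible(x)
}

#' Extrapolate a redundancy threshold from a read-sampling threshold
#'
#' When no replicates exist for a species, its GD_99% cutoff can be
#' extrapolated from the in-silico read-sampling threshold using the observed
#' cross-species ratio of read-sampling to technical-replicate thresholds:
#' `gd99 = readsample_gd99 / ratio`.
#'
#' @param readsample_gd99 the read-sampling GD_99% of the target species
#' @param ratio read-sampling : technical threshold ratio in (0, 1]
#'   (see [estimate_ratio()]; 0.30 in `paper_compat` usage)
#' @return a `threshold_estimate` with `method = "extrapolated"` (Shapiro
#'   fields unset)
#' @export
extrapolate_threshold <- function(readsample_gd99, ratio) {
  if (ratio <= 0 || ratio > 1) stop("ratio must lie in (0, 1]")
  structure(list(category = "extrapolated", n = NA_integer_,
                 mean_gd = NA_real_, sd_gd = NA_real_,
                 shapiro_W = NA_real_, shapiro_p = NA_real_,
                 gd99 = readsample_gd99 / ratio, method = "extrapolated"),
            class = "threshold_estimate")
}

#' Cross-species read-sampling : technical threshold ratio
#'
#' Mean over species of `readsample_gd99 / technical_gd99`; the stable ratio
#' that lets read sub-sampling stand in for technical replication.
#'
#' @param per_species a list of length-2 numeric vectors, or a 2-column
#'   matrix/data.frame, each row `(readsample_gd99, technical_gd99)`
#' @param digits optional rounding of the result (e.g. 2 to mirror reported
#'   ratios); default no rounding
#' @return the mean ratio (fraction)
#' @export
estimate_ratio <- function(per_species, digits = NULL) {
  if (is.list(per_species) && !is.data.frame(per_species))
    per_species <- do.call(rbind, per_species)
  per_species <- as.matrix(per_species)
  if (ncol(per_species) != 2L) stop("expected pairs (readsample, technical)")
  if (any(per_species[, 2] == 0)) stop("technical threshold of zero")
  r <- mean(per_species[, 1] / per_species[, 2])
  if (!is.null(digits)) r <- round(r, digits)
  r
}
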