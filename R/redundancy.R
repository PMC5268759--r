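#' Partition accessions into redundancy groups under a GD cutoff
#'
#' Declares two accessions identical when their GD is at or below `gd99`, and
#' groups accessions by single-linkage transitive closure (connected
#' components of the at-or-below-threshold graph). Components of size >= 2
#' are redundancy groups; the rest are singletons. Pairs with undefined GD
#' (no shared typed SNPs) are conservatively treated as distinct. Because
#' chained near-threshold links can merge distinct genotypes, the maximum
#' within-group GD is reported per group as a diagnostic.
#'
#' @param gdd a `gd_dist` from [gd_matrix()]
#' @param gd99 the redundancy cutoff (finite, non-negative), typically from
#'   [estimate_threshold()]
#' @return object of class `redundancy_partition`: list with `groups` (list
#'   of accession-id vectors, size >= 2), `singletons` (accession ids),
#'   `representatives` (`NA` until [choose_representatives()]),
#'   `max_intra_gd` per group, `threshold_used`
#' @export
redundancy_groups <- function(gdd, gd99) {
  if (!is.finite(gd99)) stop("gd99 must be finite")
  ids <- gdd$accession_ids
  n <- length(ids)
  # union-find over at-or-below-threshold edges
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  adj <- !is.na(gdd$gd) & gdd$gd <= gd99
  for (a in seq_len(n - 1L)) {
    for (b in which(adj[a, ] & seq_len(n) > a)) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(n), find, 1L)
  comp <- split(seq_len(n), root)
  groups <- list()
  singles <- character()
  max_intra <- numeric()
  for (members in comp) {
    if (length(members) >= 2L) {
      groups[[length(groups) + 1L]] <- ids[members]
      sub <- gdd$gd[members, members]
      max_intra <- c(max_intra, max(sub[upper.tri(sub)], na.rm = TRUE))
    } else {
      singles <- c(singles, ids[members])
    }
  }
  # canonical order: groups by smallest member id, for order invariance
  if (length(groups)) {
    groups <- lapply(groups, sort)
    ord <- order(vapply(groups, `[`, "", 1L))
    groups <- groups[ord]
    max_intra <- max_intra[ord]
  }
  structure(list(groups = groups, singletons = sort(singles),
                 representatives = rep(NA_character_, length(groups)),
                 max_intra_gd = max_intra, threshold_used = gd99),
            class = "redundancy_partition")
}

#' @export
print.redundancy_partition <- function(x, ...) {
  n_red <- sum(lengths(x$groups))
  cat(sprintf(
    "redundancy_partition @ GD <= %.4g: %d group(s) covering %d accessions, %d singletons\n",
    x$threshold_used, length(x$groups), n_red, length(x$singletons)))
  invisible(x)
}

#' Choose a representative accession per redundancy group
#'
#' The representative is the most read-abundant member (maximum
#' `total_pe_reads`); ties, or absent read counts, fall back to the
#' lexicographically smallest accession id (with a warning when counts are
#' missing).
#'
#' @param partition a `redundancy_partition`
#' @param meta passport data.frame with `accession_id` and `total_pe_reads`
#' @return the partition with `representatives` filled
#' @export
choose_representatives <- function(partition, meta) {
  reps <- vapply(partition$groups, function(grp) {
    reads <- meta$total_pe_reads[match(grp, meta$accession_id)]
    if (all(is.na(reads))) {
      warning("missing read counts; lexicographic representative for group ",
              grp[1])
      return(sort(grp)[1])
    }
    reads[is.na(reads)] <- -Inf
    best <- grp[reads == max(reads)]
    sort(best)[1]
  }, "")
  partition$representatives <- reps
  partition
}

#' Collection-level redundancy summary
#'
#' From the number of accessions analyzed and the number of unique genotypes
#' they represent: `redundancy_pct = 100 (n_analyzed - n_unique) /
#' n_analyzed` (the share of accessions that are redundant copies) and
#' `overestimation_pct = 100 (n_analyzed / n_unique - 1)` (the apparent
#' inflation of collection size, i.e. the excess curation burden).
#'
#' @param n_analyzed number of accessions analyzed (>= 1)
#' @param n_unique number of unique genotypes (1 <= n_unique <= n_analyzed)
#' @param digits rounding for the report columns (default 1 decimal)
#' @return one-row data.frame: `n_analyzed`, `n_unique`, `redundancy_pct`,
#'   `overestimation_pct`
#' @export
collection_summary <- function(n_analyzed, n_unique, digits = 1L) {
  if (n_unique < 1L) stop("n_unique must be >= 1")
  if (n_unique > n_analyzed) stop("n_unique cannot exceed n_analyzed")
  data.frame(
    n_analyzed = n_analyzed, n_unique = n_unique,
    redundancy_pct = round(100 * (n_analyzed - n_unique) / n_analyzed, digits),
    overestimation_pct = round(100 * (n_analyzed / n_unique - 1), digits))
}

#' Flag passport conflicts in a redundancy partition
#'
#' Emits the curation checkpoints germplasm surveys report:
#' * `usurper` — one display name shared by accessions in different
#'   genotype units (distinct genotypes under the same identifier);
#' * `synonym` — several display names within one redundancy group (the same
#'   genotype maintained under different identifiers);
#' * `gender_mismatch` — disagreeing observed genders within a group;
#' * `species_mismatch` — disagreeing species labels within a group.
#'
#' @param partition a `redundancy_partition`
#' @param meta passport data.frame with `accession_id`, `display_name`,
#'   `observed_gender`, `species_label`
#' @return data.frame with columns `type`, `name`, `detail` (zero rows when
#'   no conflicts)
#' @export
flag_conflicts <- function(partition, meta) {
  units <- c(partition$groups, as.list(partition$singletons))
  unit_of <- integer(0)
  for (u in seq_along(units))
    unit_of[units[[u]]] <- u
  flags <- list()
  add <- function(type, name, detail)
    flags[[length(flags) + 1L]] <<- data.frame(type = type, name = name,
                                               detail = detail,
                                               stringsAsFactors = FALSE)
  # usurpers: same display_name across different units
  dn <- meta$display_name
  for (nm in unique(dn[duplicated(dn)])) {
    accs <- meta$accession_id[dn == nm]
    if (length(unique(unit_of[accs])) > 1L)
      add("usurper", nm, paste(accs, collapse = ", "))
  }
  for (g in seq_along(partition$groups)) {
    grp <- partition$groups[[g]]
    idx <- match(grp, meta$accession_id)
    nms <- unique(meta$display_name[idx])
    if (length(nms) > 1L)
      add("synonym", paste(nms, collapse = " / "), paste(grp, collapse = ", "))
    gend <- unique(setdiff(meta$observed_gender[idx], c("unknown", NA)))
    if (length(gend) > 1L)
      add("gender_mismatch", paste(gend, collapse = "/"),
          paste(grp, collapse = ", "))
    spp <- unique(setdiff(meta$species_label[idx], c("unknown", NA)))
    if (length(spp) > 1L)
      add("species_mismatch", paste(spp, collapse = "/"),
          paste(grp, collapse = ", "))
  }
  if (length(flags) == 0L)
    return(data.frame(type = character(), name = character(),
                      detail = character(), stringsAsFactors = FALSE))
  do.call(rbind, flags)
}

#' Curation shortlist: one accession per unique genotype
#'
#' @param partition a `redundancy_partition` with representatives chosen
#' @return character vector of accession ids (group representatives plus all
#'   singletons), sorted
#' @export
curation_shortlist <- function(partition) {
  reps <- partition$representatives
  if (anyNA(reps) && length(partition$groups))
    stop("run choose_representatives() first")
  sort(c(reps, partition$singletons))
}
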