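.linkage_methods <- c(ward_d = "ward.D", ward_d2 = "ward.D2",
                      single = "single", complete = "complete",
                      average = "average", mcquitty = "mcquitty",
                      median = "median", centroid = "centroid")

.resolve_linkage <- function(method) {
  if (method %in% .linkage_methods) return(method)
  if (method %in% names(.linkage_methods)) return(.linkage_methods[[method]])
  stop("unknown linkage method: ", method,
       " (expected one of ", paste(names(.linkage_methods), collapse = ", "),
       ")")
}

#' Agglomerative clustering of a GD matrix
#'
#' Builds a dendrogram from pairwise GDs under one of the eight classical
#' Lance–Williams linkage rules: `ward_d`, `ward_d2`, `single`, `complete`,
#' `average` (UPGMA), `mcquitty` (WPGMA), `median` (WPGMC), `centroid`
#' (UPGMC). R's `hclust` spellings (`ward.D`, `ward.D2`, ...) are accepted
#' too. Merge heights are monotone for the first six; median and centroid
#' may show inversions.
#'
#' @param gdd a `gd_dist`, or a `dist` object
#' @param method linkage method name
#' @return an `hclust` tree (merge sequence, heights, leaf order, method)
#' @export
hierarchical_tree <- function(gdd, method = "average") {
  method <- .resolve_linkage(method)
  d <- if (inherits(gdd, "gd_dist")) as_dist(gdd) else stats::as.dist(gdd)
  if (anyNA(d)) stop("undefined (NA) entries in the dissimilarity matrix")
  stats::hclust(d, method = method)
}

#' Cophenetic correlation coefficient of a tree
#'
#' Pearson correlation between the input pairwise dissimilarities and the
#' tree's cophenetic distances (the merge height of each pair's lowest
#' common ancestor); the standard measure of how faithfully a dendrogram
#' preserves the original distances.
#'
#' @param gdd the `gd_dist` (or `dist`) the tree was built from
#' @param tree an `hclust` tree over the same accessions
#' @return the CCC (fraction); `NA` with a warning if either distance vector
#'   has zero variance
#' @export
cophenetic_correlation <- function(gdd, tree) {
  d <- if (inherits(gdd, "gd_dist")) as_dist(gdd) else stats::as.dist(gdd)
  cp <- stats::cophenetic(tree)
  if (stats::sd(d) == 0 || stats::sd(cp) == 0) {
    warning("zero variance; CCC undefined")
    return(NA_real_)
  }
  stats::cor(as.vector(d), as.vector(cp))
}

#' Select a linkage method by bootstrapped cophenetic correlation
#'
#' Resamples SNP columns with replacement `n_boot` times; on each bootstrap
#' replicate the GD matrix is recomputed and every candidate method's tree is
#' scored by its CCC against that replicate's GDs. The winner has the highest
#' mean CCC.
#'
#' @param gm a `genotype_matrix`
#' @param coding GD coding passed to [gd_matrix()]
#' @param methods linkage methods to evaluate (default all eight)
#' @param n_boot number of bootstrap replicates (>= 1)
#' @param seed integer seed
#' @param diploidized_snp_ids for `coding = "diploidized"`
#' @return object of class `method_selection`: list with `table` (data.frame
#'   `method`, `mean_ccc`, `sd_ccc`), `winner`, `n_boot`
#' @export
select_linkage_method <- function(gm, coding = "collapsed",
                                  methods = names(.linkage_methods),
                                  n_boot = 100L, seed,
                                  diploidized_snp_ids = NULL) {
  if (missing(seed)) stop("a seed is required")
  if (n_boot < 1L) stop("n_boot must be >= 1")
  if (length(methods) == 0L) stop("empty methods list")
  if (n_accessions(gm) < 2L) stop("need at least 2 accessions")
  methods <- vapply(methods, .resolve_linkage, "")
  set.seed(seed)
  m <- n_snps(gm)
  ccc <- matrix(NA_real_, n_boot, length(methods),
                dimnames = list(NULL, names(methods)))
  for (b in seq_len(n_boot)) {
    cols <- sample.int(m, m, replace = TRUE)
    bgm <- subset_gm(gm, snps = cols)
    gdd <- suppressWarnings(gd_matrix(bgm, coding = coding,
                                      diploidized_snp_ids = diploidized_snp_ids))
    if (anyNA(gdd$gd)) next
    for (k in seq_along(methods)) {
      tr <- stats::hclust(as_dist(gdd), method = methods[[k]])
      ccc[b, k] <- suppressWarnings(cophenetic_correlation(gdd, tr))
    }
  }
  tab <- data.frame(method = names(methods),
                    mean_ccc = colMeans(ccc, na.rm = TRUE),
                    sd_ccc = apply(ccc, 2L, stats::sd, na.rm = TRUE),
                    stringsAsFactors = FALSE, row.names = NULL)
  winner <- tab$method[which.max(tab$mean_ccc)]
  structure(list(table = tab, winner = winner, n_boot = n_boot),
            class = "method_selection")
}

#' @export
print.method_selection <- function(x, ...) {
  cat(sprintf("method_selection (%d bootstraps): winner = %s\n",
              x$n_boot, x$winner))
  print(x$table, digits = 4)
  invisible(x)
}

#' Bootstrap clade support for a reference tree
#'
#' Builds the reference tree from the full SNP set, then resamples SNP
#' columns with replacement `n_boot` times, rebuilding the tree each time.
#' The support of an internal node is the percentage of bootstrap trees
#' containing the same leaf bipartition (plain bootstrap proportions on the
#' rooted topology).
#'
#' @inheritParams select_linkage_method
#' @param method linkage method for all trees (default `"average"`, UPGMA)
#' @param n_boot bootstrap replicates (default 1000)
#' @return object of class `supported_tree`: list with `tree` (`hclust`),
#'   `phylo` (`ape::phylo` with node labels = support %), `support`
#'   (per-internal-node percentage), `n_boot`
#' @export
bootstrap_support <- function(gm, coding = "collapsed", method = "average",
                              n_boot = 1000L, seed,
                              diploidized_snp_ids = NULL) {
  if (missing(seed)) stop("a seed is required")
  if (n_boot < 1L) stop("n_boot must be >= 1")
  method <- .resolve_linkage(method)
  gdd <- gd_matrix(gm, coding = coding,
                   diploidized_snp_ids = diploidized_snp_ids)
  ref <- stats::hclust(as_dist(gdd), method = method)
  ref_phy <- ape::as.phylo(ref)
  set.seed(seed)
  m <- n_snps(gm)
  boots <- vector("list", n_boot)
  kept <- 0L
  for (b in seq_len(n_boot)) {
    cols <- sample.int(m, m, replace = TRUE)
    bgm <- subset_gm(gm, snps = cols)
    bgd <- suppressWarnings(gd_matrix(bgm, coding = coding,
                                      diploidized_snp_ids = diploidized_snp_ids))
    if (anyNA(bgd$gd)) next
    kept <- kept + 1L
    boots[[kept]] <- ape::as.phylo(stats::hclust(as_dist(bgd), method = method))
  }
  boots <- boots[seq_len(kept)]
  counts <- ape::prop.clades(ref_phy, boots, rooted = TRUE)
  counts[is.na(counts)] <- 0L
  support <- 100 * counts / kept
  ref_phy$node.label <- formatC(support, format = "f", digits = 1)
  structure(list(tree = ref, phylo = ref_phy, support = support,
                 n_boot = kept), class = "supported_tree")
}

#' @export
print.supported_tree <- function(x, ...) {
  cat(sprintf("supported_tree: %d leaves, %d bootstraps; node support %.0f-%.0f%%\n",
              length(x$phylo$tip.label), x$n_boot,
              min(x$support), max(x$support)))
  invisible(x)
}

#' Export a supported tree as Newick
#'
#' Branch lengths carry the merge heights; internal node labels carry the
#' bootstrap support percentages.
#'
#' @param st a `supported_tree` (or an `hclust`)
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_newick <- function(st, path) {
  phy <- if (inherits(st, "supported_tree")) st$phylo
         else ape::as.phylo(st)
  ape::write.tree(phy, file = path)
  invisible(path)
}
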