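#' Default deconvolution pipeline configuration
#'
#' @param input list describing the genotype source: either `vcf = path`
#'   (plus optional `passport`) or `table = path` (plus optional
#'   `simplex_only`, `passport`), or `simulate = list(...)` of
#'   [sim_config()] arguments
#' @param coding GD coding for the dissimilarity stage
#' @param threshold list: `strategy` (`"technical"`, `"biological"`,
#'   `"subsampling"` or `"fixed"`), `confidence`, `subsample_fraction`,
#'   `n_subsamples`, `gd99` (for `"fixed"`), `ratio` (for extrapolation)
#' @param clustering list: `method`, `select_method` flag, `n_boot_ccc`,
#'   `n_boot_support`
#' @param k_range K values for cluster-number selection
#' @param amova_permutations permutations for the AMOVA stage
#' @param seed master seed; every stochastic stage derives its own seed
#' @param out_dir output directory (created if absent); `NULL` disables file
#'   output
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(input, coding = "collapsed",
                            threshold = list(), clustering = list(),
                            k_range = 2:10, amova_permutations = 999L,
                            seed, out_dir = NULL) {
  if (missing(seed)) stop("a seed is mandatory")
  thr <- utils::modifyList(
    list(strategy = "technical", confidence = 0.99, subsample_fraction = 0.5,
         n_subsamples = 10L, gd99 = NULL, ratio = NULL), threshold)
  cl <- utils::modifyList(
    list(method = "average", select_method = FALSE, n_boot_ccc = 100L,
         n_boot_support = 200L), clustering)
  structure(list(input = input, coding = coding, threshold = thr,
                 clustering = cl, k_range = k_range,
                 amova_permutations = as.integer(amova_permutations),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys mirror the [pipeline_config()] arguments
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("config validation: missing key 'seed'")
  if (is.null(y$input)) stop("config validation: missing key 'input'")
  pipeline_config(
    input = y$input, coding = y$coding %||% "collapsed",
    threshold = y$threshold %||% list(),
    clustering = y$clustering %||% list(),
    k_range = if (is.null(y$k_range)) 2:10 else
      seq(y$k_range[[1]], y$k_range[[length(y$k_range)]]),
    amova_permutations = y$amova_permutations %||% 999L,
    seed = y$seed, out_dir = y$out_dir)
}

.load_input <- function(input, seed) {
  if (!is.null(input$simulate)) {
    args <- input$simulate
    if (is.null(args$seed)) args$seed <- seed
    if (!is.null(args$clone_copies))
      args$clone_copies <- unlist(args$clone_copies)
    sim <- simulate_collection(do.call(sim_config, args))
    return(list(gm = sim$gm, truth = sim$truth))
  }
  if (!is.null(input$vcf)) {
    if (!file.exists(input$vcf))
      stop("config validation: input$vcf not found: ", input$vcf)
    return(list(gm = read_vcf(input$vcf, passport = input$passport),
                truth = NULL))
  }
  if (!is.null(input$table)) {
    if (!file.exists(input$table))
      stop("config validation: input$table not found: ", input$table)
    return(list(gm = read_genotype_table(input$table,
                                         simplex_only = isTRUE(input$simplex_only),
                                         passport = input$passport),
                truth = NULL))
  }
  stop("config validation: input must name 'vcf', 'table' or 'simulate'")
}

.stage_seed <- function(seed, k) (seed + 7919L * k) %% 2147483647L

#' Run the full germplasm deconvolution pipeline
#'
#' Orchestrates, for one collection: load -> per-accession ploidy inference
#' -> GD matrix -> redundancy threshold -> redundancy partition,
#' representatives and passport-conflict flags -> redundancy-culled set ->
#' (optional) linkage-method selection -> bootstrap-supported UPGMA tree ->
#' PCA -> K-means/BIC cluster-number selection -> AMOVA over the chosen
#' clusters -> diversity statistics. All stage outputs are returned and, when
#' `out_dir` is set, written as CSV/JSON/Newick; the run summary records the
#' derived seed of every stochastic stage.
#'
#' @param cfg a `pipeline_config` (or path to a YAML config)
#' @return a `deconvolution_report` list; see its `$summary` element for the
#'   headline numbers (accessions analyzed, unique genotypes, redundancy and
#'   over-estimation percentages, GD threshold, chosen K, F_ST)
#' @export
run_deconvolution <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  seed <- cfg$seed

  stage <- "load"
  res <- tryCatch({
    inp <- .load_input(cfg$input, seed)
    gm <- inp$gm

    stage <- "ploidy"
    ploidy_calls <- infer_ploidy_all(gm)

    stage <- "gd"
    gdd <- suppressWarnings(gd_matrix(gm, coding = cfg$coding))

    stage <- "thresholds"
    thr_cfg <- cfg$threshold
    thr <- switch(
      thr_cfg$strategy,
      fixed = {
        if (is.null(thr_cfg$gd99)) stop("fixed strategy needs threshold$gd99")
        structure(list(category = "fixed", n = NA, mean_gd = NA, sd_gd = NA,
                       shapiro_W = NA, shapiro_p = NA, gd99 = thr_cfg$gd99,
                       method = "fixed"), class = "threshold_estimate")
      },
      biological = ,
      technical = {
        sets <- replicate_gd_sets(gdd, gm$accessions)
        set <- sets[[thr_cfg$strategy]]
        if (is.null(set)) stop("no ", thr_cfg$strategy, " replicate pairs")
        estimate_threshold(set, thr_cfg$confidence)
      },
      subsampling = {
        accs <- gm$accessions$accession_id[
          order(-gm$accessions$total_pe_reads)][1:min(3L, n_accessions(gm))]
        gds <- unlist(lapply(seq_along(accs), function(k)
          subsample_gd_set(gm, accs[k], thr_cfg$subsample_fraction,
                           thr_cfg$n_subsamples,
                           seed = .stage_seed(seed, 10L + k))$gd_values))
        est <- estimate_threshold(
          new_replicate_gd_set("subsampling", gds), thr_cfg$confidence)
        if (!is.null(thr_cfg$ratio))
          est <- extrapolate_threshold(est$gd99, thr_cfg$ratio)
        est
      },
      stop("unknown threshold strategy: ", thr_cfg$strategy))

    stage <- "redundancy"
    part <- redundancy_groups(gdd, thr$gd99)
    part <- choose_representatives(part, gm$accessions)
    conflicts <- flag_conflicts(part, gm$accessions)
    ploidy_calls <- annotate_ploidy_from_redundancy(ploidy_calls, part)
    keep <- curation_shortlist(part)
    n_unique <- length(keep)
    summ <- collection_summary(n_accessions(gm), n_unique)

    stage <- "culling"
    gm_cull <- subset_gm(gm, accessions = keep)
    gdd_cull <- suppressWarnings(gd_matrix(gm_cull, coding = cfg$coding))

    stage <- "method_selection"
    msel <- NULL
    method <- cfg$clustering$method
    if (isTRUE(cfg$clustering$select_method)) {
      msel <- select_linkage_method(gm_cull, coding = cfg$coding,
                                    n_boot = cfg$clustering$n_boot_ccc,
                                    seed = .stage_seed(seed, 2L))
      method <- msel$winner
    }

    stage <- "tree"
    tree <- bootstrap_support(gm_cull, coding = cfg$coding, method = method,
                              n_boot = cfg$clustering$n_boot_support,
                              seed = .stage_seed(seed, 3L))

    stage <- "pca"
    pca <- pca_genotypes(gm_cull)

    stage <- "k_selection"
    k_range <- cfg$k_range[cfg$k_range < n_accessions(gm_cull)]
    ksel <- if (length(k_range))
      select_k_bic(pca, k_range, seed = .stage_seed(seed, 4L)) else NULL

    stage <- "amova"
    amv <- if (!is.null(ksel) && length(unique(ksel$assignments)) >= 2L)
      amova(gm_cull, ksel$assignments, n_perm = cfg$amova_permutations,
            seed = .stage_seed(seed, 5L)) else NULL

    stage <- "diversity"
    div <- diversity_stats(gm_cull)

    summary <- list(
      n_accessions = n_accessions(gm),
      n_snps = n_snps(gm),
      n_unique = n_unique,
      redundancy_pct = summ$redundancy_pct,
      overestimation_pct = summ$overestimation_pct,
      gd99 = thr$gd99,
      threshold_method = thr$method,
      linkage_method = method,
      chosen_k = if (is.null(ksel)) NA else ksel$chosen_k,
      f_st = if (is.null(amv)) NA else amv$F_ST,
      n_conflicts = nrow(conflicts),
      seed = seed,
      stage_seeds = list(thresholds = .stage_seed(seed, 11L),
                         method_selection = .stage_seed(seed, 2L),
                         tree = .stage_seed(seed, 3L),
                         k_selection = .stage_seed(seed, 4L),
                         amova = .stage_seed(seed, 5L)))

    report <- structure(list(
      gm = gm, truth = inp$truth, ploidy_calls = ploidy_calls, gd = gdd,
      threshold = thr, partition = part, conflicts = conflicts,
      collection = summ, gm_culled = gm_cull, method_selection = msel,
      tree = tree, pca = pca, k_selection = ksel, amova = amv,
      diversity = div, summary = summary), class = "deconvolution_report")

    if (!is.null(cfg$out_dir)) .write_report(report, cfg$out_dir)
    report
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  res
}

.write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(out_dir, ...)
  utils::write.csv(report$ploidy_calls, fp("ploidy_calls.csv"),
                   row.names = FALSE)
  write_gd_triangles(report$gd, fp("gd_triangles.csv"))
  utils::write.csv(gd_long(report$gd), fp("gd_long.csv"), row.names = FALSE)
  part <- report$partition
  groups_df <- if (length(part$groups)) do.call(rbind, lapply(
    seq_along(part$groups), function(g)
      data.frame(group = g, accession_id = part$groups[[g]],
                 representative = part$representatives[g],
                 max_intra_gd = part$max_intra_gd[g])))
    else data.frame(group = integer(), accession_id = character(),
                    representative = character(), max_intra_gd = numeric())
  utils::write.csv(groups_df, fp("redundancy_groups.csv"), row.names = FALSE)
  writeLines(curation_shortlist(part), fp("curation_shortlist.txt"))
  utils::write.csv(report$conflicts, fp("conflicts.csv"), row.names = FALSE)
  if (!is.null(report$method_selection))
    utils::write.csv(report$method_selection$table, fp("ccc_by_method.csv"),
                     row.names = FALSE)
  write_newick(report$tree, fp("tree.nwk"))
  utils::write.csv(
    data.frame(accession_id = rownames(report$pca$scores),
               report$pca$scores[, seq_len(min(10, ncol(report$pca$scores))),
                                 drop = FALSE]),
    fp("pca_scores.csv"), row.names = FALSE)
  if (!is.null(report$amova))
    utils::write.csv(report$amova$table, fp("amova.csv"), row.names = FALSE)
  utils::write.csv(report$diversity, fp("diversity.csv"), row.names = FALSE)
  jsonlite::write_json(report$summary, fp("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.deconvolution_report <- function(x, ...) {
  s <- x$summary
  cat("deconvolution_report\n")
  cat(sprintf("  %d accessions, %d SNPs -> %d unique genotypes (redundancy %.1f%%, over-estimation %.1f%%)\n",
              s$n_accessions, s$n_snps, s$n_unique, s$redundancy_pct,
              s$overestimation_pct))
  cat(sprintf("  GD99 = %.4g (%s); linkage = %s; chosen K = %s; F_ST = %s; %d passport conflict(s)\n",
              s$gd99, s$threshold_method, s$linkage_method,
              ifelse(is.na(s$chosen_k), "-", s$chosen_k),
              ifelse(is.na(s$f_st), "-", sprintf("%.3f", s$f_st)),
              s$n_conflicts))
  invisible(x)
}
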