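#' Configuration for a synthetic germplasm collection
#'
#' Bundles and validates the parameters of [simulate_collection()]. Defaults
#' describe a realistic GBS germplasm survey: over-dispersed coverage near
#' 40x, ~6.5% missing calls, and clonal replicate error calibrated so that
#' diploid technical (inter-library) replicate pairs show a mean GD roughly
#' 6-7 times that of biological (intra-library) pairs, the ordering observed
#' between replicate classes in empirical GBS collections. The channel rates
#' differ by more than that factor because depth-resampling noise in the
#' caller contributes a baseline GD (~0.0007 at 40x for diploids) common to
#' both replicate classes.
#'
#' @param n_subpops number of diverged sub-populations
#' @param fst divergence of sub-population allele frequencies from the
#'   ancestral pool, in (0, 1) (Balding–Nichols model)
#' @param n_genotypes_per_subpop founder genotypes drawn per sub-population
#' @param clone_copies named integer vector: extra clonal copies to plant per
#'   founder genotype id (`G001`, `G002`, ...); may be empty
#' @param ploidy_map ploidy per founder genotype: single value in \{2, 4, 6\}
#'   or a vector recycled over founders
#' @param n_snps number of bi-allelic SNPs
#' @param mean_depth mean total read depth per call
#' @param depth_dispersion negative-binomial size parameter; smaller = more
#'   over-dispersed coverage (GBS coverage is over-dispersed, so the default
#'   is far from Poisson)
#' @param seq_error_rate per-read allele miscall probability
#' @param intra_library_miscall per-call genotype perturbation probability for
#'   clone copies prepared in the founder's library (biological replicates)
#' @param inter_library_miscall as above for copies prepared in a different
#'   library (technical replicates)
#' @param missing_rate extra fraction of calls masked to missing, on top of
#'   depth-gate missingness
#' @param min_call_depth minimum total depth to emit a call
#' @param min_minor_reads minimum reads on each allele required for a
#'   heterozygous call
#' @param seed integer seed; mandatory, every draw is reproducible from it
#' @return a `sim_config` list
#' @export
sim_config <- function(n_subpops = 2L, fst = 0.2, n_genotypes_per_subpop = 10L,
                       clone_copies = integer(), ploidy_map = 2L,
                       n_snps = 1000L, mean_depth = 40, depth_dispersion = 25,
                       seq_error_rate = 0.001,
                       intra_library_miscall = 0.0004,
                       inter_library_miscall = 0.0112,
                       missing_rate = 0.065,
                       min_call_depth = 6L, min_minor_reads = 3L,
                       seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  if (fst <= 0 || fst >= 1) stop("fst must lie in (0, 1)")
  rates <- c(seq_error_rate, intra_library_miscall, inter_library_miscall,
             missing_rate)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (!all(ploidy_map %in% c(2L, 4L, 6L)))
    stop("ploidy_map values must be 2, 4 or 6")
  structure(list(
    n_subpops = as.integer(n_subpops), fst = fst,
    n_genotypes_per_subpop = as.integer(n_genotypes_per_subpop),
    clone_copies = clone_copies, ploidy_map = as.integer(ploidy_map),
    n_snps = as.integer(n_snps), mean_depth = mean_depth,
    depth_dispersion = depth_dispersion, seq_error_rate = seq_error_rate,
    intra_library_miscall = intra_library_miscall,
    inter_library_miscall = inter_library_miscall,
    missing_rate = missing_rate, min_call_depth = as.integer(min_call_depth),
    min_minor_reads = as.integer(min_minor_reads), seed = as.integer(seed)),
    class = "sim_config")
}

#' Call a genotype dosage from allele depths
#'
#' Depth-ratio genotype caller used by the simulator and by in-silico read
#' sub-sampling: calls are missing below `min_call_depth`; otherwise dosage is
#' `round(ploidy * alt / (ref + alt))` clipped to `0..ploidy`. A heterozygous
#' call additionally requires at least `min_minor_reads` reads on each allele,
#' else it is rounded to the nearer homozygote.
#'
#' @param ref_depth,alt_depth non-negative read counts (vectorized)
#' @param ploidy accession ploidy (>= 2)
#' @param min_call_depth minimum total depth to emit a call (default 6)
#' @param min_minor_reads minimum per-allele reads for a het call (default 3)
#' @return integer vector of dosages with `NA` where no call is made
#' @export
call_genotypes <- function(ref_depth, alt_depth, ploidy, min_call_depth = 6L,
                           min_minor_reads = 3L) {
  if (any(ploidy < 2)) stop("ploidy must be >= 2")
  tot <- ref_depth + alt_depth
  if (any(tot < 0)) stop("depths must be non-negative")
  pl <- rep_len(as.integer(ploidy), length(tot))
  ratio <- ifelse(tot > 0, alt_depth / tot, NA_real_)
  # nearest dosage, halves away from zero (round() would send an exact
  # quarter ratio to the homozygote on even ploidies)
  d <- as.integer(pmin(pmax(floor(pl * ratio + 0.5), 0), pl))
  het <- !is.na(d) & d > 0L & d < pl
  weak <- het & (ref_depth < min_minor_reads | alt_depth < min_minor_reads)
  # nearer homozygote by depth ratio
  d[weak] <- ifelse(ratio[weak] >= 0.5, pl[weak], 0L)
  d[tot < min_call_depth] <- NA_integer_
  d
}

#' Simulate a germplasm collection with planted structure and clones
#'
#' Generates a genotype matrix with known ground truth: ancestral allele
#' frequencies ~ Uniform(0.05, 0.95); sub-population frequencies via a
#' Balding–Nichols draw `Beta(p(1-F)/F, (1-p)(1-F)/F)` at divergence
#' `fst = F`; founder dosages ~ Binomial(ploidy, p_subpop). Clone copies
#' duplicate their founder's dosages and then pass through a replicate-error
#' channel: with the library-dependent miscall probability each call moves by
#' one dosage step (or drops to missing, 10% of events), emulating
#' library-preparation and lane effects. Copies alternate between the
#' founder's library (biological replicate) and the other library (technical
#' replicate). Every accession's calls are then re-derived from sampled read
#' depths: total depth ~ NegBin(mean = `mean_depth`, size =
#' `depth_dispersion`), alternate depth ~ Binomial(depth, f') with
#' `f' = f(1-e) + (1-f)e` for sequencing error `e`, genotypes via
#' [call_genotypes()], and `missing_rate` masking on top.
#'
#' @param cfg a [sim_config()]
#' @return list with elements `gm` (a [genotype_matrix()]) and `truth` (a
#'   `sim_truth` list: `ancestral_freq`, `subpop_freq` matrix,
#'   `genotype_subpop`, `clone_map` accession -> founder genotype,
#'   `founder_dosage` matrix, `ploidy`)
#' @export
simulate_collection <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n_founders <- cfg$n_subpops * cfg$n_genotypes_per_subpop
  founder_ids <- sprintf("G%03d", seq_len(n_founders))
  subpop <- rep(seq_len(cfg$n_subpops), each = cfg$n_genotypes_per_subpop)
  ploidy_f <- rep_len(cfg$ploidy_map, n_founders)

  if (length(cfg$clone_copies)) {
    unknown <- setdiff(names(cfg$clone_copies), founder_ids)
    if (length(unknown))
      stop("clone_copies references unknown founder(s): ",
           paste(unknown, collapse = ", "))
  }

  p_anc <- stats::runif(cfg$n_snps, 0.05, 0.95)
  Fst <- cfg$fst
  subpop_freq <- vapply(seq_len(cfg$n_subpops), function(k)
    stats::rbeta(cfg$n_snps, p_anc * (1 - Fst) / Fst,
                 (1 - p_anc) * (1 - Fst) / Fst), numeric(cfg$n_snps))

  founder_dosage <- t(vapply(seq_len(n_founders), function(i)
    stats::rbinom(cfg$n_snps, ploidy_f[i], subpop_freq[, subpop[i]]),
    integer(cfg$n_snps)))
  rownames(founder_dosage) <- founder_ids

  # lay out the collection: founders first, then clone copies
  acc_founder <- seq_len(n_founders)
  copy_no <- rep(0L, n_founders)
  if (length(cfg$clone_copies)) {
    for (g in names(cfg$clone_copies)) {
      k <- cfg$clone_copies[[g]]
      if (k > 0) {
        fi <- match(g, founder_ids)
        acc_founder <- c(acc_founder, rep(fi, k))
        copy_no <- c(copy_no, seq_len(k))
      }
    }
  }
  n_acc <- length(acc_founder)
  acc_ids <- ifelse(copy_no == 0L, founder_ids[acc_founder],
                    sprintf("%s_c%d", founder_ids[acc_founder], copy_no))
  founder_lib <- rep_len(c("1", "2"), n_founders)
  # copies alternate: odd copy = founder's library (biological),
  # even copy = the other library (technical)
  lib <- founder_lib[acc_founder]
  tech <- copy_no %% 2L == 0L & copy_no > 0L
  lib[tech] <- ifelse(lib[tech] == "1", "2", "1")
  ploidy <- ploidy_f[acc_founder]

  true_dosage <- founder_dosage[acc_founder, , drop = FALSE]
  # replicate-error channel on clone copies (post-call genotype perturbation)
  for (i in which(copy_no > 0L)) {
    p_err <- if (tech[i]) cfg$inter_library_miscall else cfg$intra_library_miscall
    hit <- which(stats::runif(cfg$n_snps) < p_err)
    if (length(hit)) {
      d <- true_dosage[i, hit]
      drop <- stats::runif(length(hit)) < 0.1
      step <- ifelse(d == 0L, 1L,
                     ifelse(d == ploidy[i], -1L,
                            sample(c(-1L, 1L), length(hit), replace = TRUE)))
      d <- d + step
      d[drop] <- NA_integer_
      true_dosage[i, hit] <- d
    }
  }

  f <- true_dosage / ploidy
  e <- cfg$seq_error_rate
  f_obs <- f * (1 - e) + (1 - f) * e
  tot <- matrix(stats::rnbinom(n_acc * cfg$n_snps, mu = cfg$mean_depth,
                               size = cfg$depth_dispersion),
                n_acc, cfg$n_snps)
  f_flat <- as.vector(f_obs)
  alt <- rep(NA_integer_, length(f_flat))
  okf <- !is.na(f_flat)
  alt[okf] <- stats::rbinom(sum(okf), as.vector(tot)[okf], f_flat[okf])
  alt <- matrix(alt, n_acc, cfg$n_snps)
  alt[is.na(alt)] <- 0L
  tot[is.na(f_obs)] <- 0L  # perturbation dropped the call entirely
  ref <- tot - alt

  dosage <- matrix(call_genotypes(as.vector(ref), as.vector(alt),
                                  rep(ploidy, times = cfg$n_snps),
                                  cfg$min_call_depth, cfg$min_minor_reads),
                   n_acc, cfg$n_snps)
  if (cfg$missing_rate > 0) {
    mask <- matrix(stats::runif(n_acc * cfg$n_snps) < cfg$missing_rate,
                   n_acc, cfg$n_snps)
    dosage[mask] <- NA_integer_
  }
  rownames(dosage) <- acc_ids

  meta <- data.frame(
    accession_id = acc_ids,
    display_name = acc_ids,
    species_label = "synthetic",
    library_id = lib,
    lane_id = lib,
    total_pe_reads = as.numeric(rowSums(ref + alt)),
    reported_gender = "unknown", observed_gender = "unknown",
    ploidy = ploidy,
    replicate_group = ifelse(acc_founder %in% acc_founder[duplicated(acc_founder)],
                             founder_ids[acc_founder], NA_character_),
    stringsAsFactors = FALSE)

  gm <- genotype_matrix(dosage, ploidy, ref, alt, accessions = meta)
  truth <- structure(list(
    ancestral_freq = p_anc, subpop_freq = subpop_freq,
    genotype_subpop = stats::setNames(subpop, founder_ids),
    clone_map = stats::setNames(founder_ids[acc_founder], acc_ids),
    founder_dosage = founder_dosage,
    ploidy = stats::setNames(ploidy, acc_ids)), class = "sim_truth")
  list(gm = gm, truth = truth)
}
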