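# germdecon

Deconvolution of clonal germplasm collections from genotyping-by-sequencing
(GBS) data.

Clonally propagated crop collections accumulate redundancy, misnomers and
mix-ups over decades of exchange between repositories, nurseries and private
growers: the same genotype maintained under several names, several genotypes
sharing one name, wrong gender or species records. `germdecon` resolves this
convolution from a SNP genotype matrix with per-call allele depths — no
reference genome, pedigree or phenotype data required — and quantifies what
remains: the unique genotypes worth curating, the population structure among
them, and their diversity.

## The method

**Dissimilarity.** Pairwise relatedness uses a modified Gower dissimilarity
over bi-allelic SNPs with pairwise deletion of missing data:

    GD(x, y) = 1 − ( Σᵢ sᵢ wᵢ ) / ( Σᵢ wᵢ )

where `wᵢ = 1` iff both accessions are genotyped at SNP *i*, and `sᵢ` scores
identity-by-state: 1 for identical states, 0.5 for heterozygote vs
homozygote, 0 for opposite homozygotes (*collapsed* coding, valid across
ploidies). A *dosage* coding generalizes this to polyploid dosage fractions
`f ∈ {0, 1/p, …, 1}` with `s = 1 − |f_x − f_y|`, which splits the tetraploid
heterozygote class into its 3:1 / 1:1 / 1:3 states; a *diploidized* coding
restricts to markers that segregate within one polyploid sub-genome.

**Ploidy.** Each accession's ploidy is read off the distribution of allele
depth ratios at its heterozygous SNPs: one mode at 0.5 for diploids, three
modes near 0.25/0.5/0.75 for tetraploids, five near 1/6…5/6 for hexaploids.
`germdecon` formalizes this as kernel-density peak detection plus template
matching.

**Redundancy threshold.** Replicated samples of one genotype never reach GD
= 0 in practice; sequencing and sampling error set the floor. The cutoff
GD₉₉% below which two accessions are declared the same genotype is the
one-sided 99th percentile of the replicate GD distribution — estimated from
biological replicates (same library and lane), technical replicates (split
across libraries; the larger, and recommended, error), or in-silico read
sub-sampling, with a cross-species ratio extrapolation when no replicates
exist. Accessions are grouped by single-linkage closure under the cutoff and
each group is represented by its most read-abundant member.

**Structure and diversity.** UPGMA cladograms (linkage method selected by
bootstrapped cophenetic correlation over the eight classical rules) with
SNP-resampling bootstrap support; PCA; K-means over 2…10 clusters with BIC
selection of K; allele-level AMOVA with permutation tests; per-population
N_E, H_O, unbiased H_E, MAF and F_IS.

A synthetic-collection simulator (Balding–Nichols sub-population divergence,
planted clones with intra- vs inter-library replicate error, mixed ploidy,
negative-binomial coverage and binomial allele depths) makes every stage
testable offline against known truth.

## Worked example

```r
library(germdecon)

cfg <- pipeline_config(
  input = list(simulate = list(
    n_subpops = 2, fst = 0.25, n_genotypes_per_subpop = 12,
    clone_copies = list(G001 = 2L, G005 = 1L, G014 = 2L, G020 = 1L),
    ploidy_map = 2L, n_snps = 1200)),
  clustering = list(n_boot_support = 200L),
  amova_permutations = 199L, seed = 101)
report <- run_deconvolution(cfg)
print(report)
#> deconvolution_report
#>   30 accessions, 1200 SNPs -> 24 unique genotypes (redundancy 20.0%, over-estimation 25.0%)
#>   GD99 = 0.01138 (normal_percentile); linkage = average; chosen K = 2; F_ST = 0.252; 4 passport conflict(s)

print(report$threshold)
#> threshold_estimate (technical, n = 4): mean GD 0.0058, GD99 0.0114 [normal_percentile]
print(report$partition)
#> redundancy_partition @ GD <= 0.01138: 4 group(s) covering 10 accessions, 20 singletons
```

Reading: 30 accessions were planted as 24 distinct genotypes plus 6 clonal
copies. The technical-replicate GD distribution put the identity cutoff at
GD₉₉% = 0.0114; single-linkage grouping under it recovered exactly the four
planted clone groups (10 accessions), i.e. 20% of the collection is
redundant and curing it as-is would cost 25% more than necessary. K-means/
BIC found the two planted sub-populations (chosen K = 2) and AMOVA
attributes 25% of allelic variance to the split (F_ST 0.252, p = 0.005).

The same stages are available piecewise — `read_vcf()` /
`read_genotype_table()`, `infer_ploidy_all()`, `gd_matrix()`,
`estimate_threshold()`, `redundancy_groups()`, `flag_conflicts()`,
`bootstrap_support()`, `select_k_bic()`, `amova()`, `diversity_stats()` —
and from the shell via `inst/cli/germdecon.R` (subcommands `simulate` and
`run`).

### Genotype table dialect

Besides VCF (GT + AD), `read_genotype_table()` accepts a TSV/CSV with one
row per SNP: metadata columns `snp_id`, `centroid_id`, `position`,
`ref_allele`, `alt_allele`, `snps_in_centroid`, then one column per
accession with cells `dosage|ref,alt` (`.` for a missing call) and a
`#ploidy` header line mapping accession columns to ploidies.
`simplex_only = TRUE` drops SNPs from multi-SNP centroids. The passport CSV
needs `accession_id` plus any of `display_name`, `species_label`,
`library_id`, `lane_id`, `total_pe_reads`, `reported_gender`,
`observed_gender`, `ploidy`, `replicate_group`.

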