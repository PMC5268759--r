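Package: germdecon
Title: Deconvolution of Clonal Germplasm Collections from GBS Genotype Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to resolve redundancy, misnomers and misclassifications in
    clonally propagated germplasm collections genotyped by reduced-representation
    sequencing (GBS). From a multi-accession SNP matrix with per-call allele
    depths the package infers accession ploidy from heterozygous allele-depth
    ratio distributions, computes ploidy-aware modified Gower dissimilarities
    with pairwise deletion of missing data, estimates empirical redundancy
    thresholds from biological/technical replicates or in-silico read
    sub-sampling, partitions accessions into redundancy groups with
    read-abundance representatives, and characterizes population structure and
    diversity (hierarchical clustering with bootstrap support, PCA, K-means
    cluster-number selection by BIC, allele-level AMOVA, heterozygosity and
    fixation statistics). A synthetic-collection simulator with planted
    sub-populations, clones, replicate-error structure and mixed ploidy makes
    the whole pipeline testable without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    vcfR,
    ape,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
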