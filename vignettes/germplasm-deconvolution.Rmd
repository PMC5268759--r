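---
title: "Deconvoluting a germplasm collection: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvoluting a germplasm collection: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germdecon)
```

This vignette is the package's account of its science: the models behind
each stage, the parameters that matter and their defaults, what the
synthetic-data generator does and does not emulate, and the choices made
where the design was genuinely open.

## The problem

A germplasm collection holds *accessions* — uniquely labelled plant samples
— but clonally propagated crops circulate as cuttings, so several accessions
may be the same *genotype* (clones under different names), and one name may
be attached to several genotypes. Deconvolution means recovering the
genotype-level structure of the collection from marker data: which
accessions are redundant, which names are synonyms or usurpers, how many
distinct genotypes there are, and how diversity is organized among them.
The input is a reduced-representation (GBS) SNP matrix with per-call read
depths for both alleles; no reference genome is assumed (markers may live on
de-novo "centroid" fragments), and ploidy may vary between accessions.

## Genotype model

A call is a *dosage*: the count of alternate-allele copies, `0..p` for an
accession of ploidy `p`, or missing. The *dosage fraction* `f = dosage / p`
is the universal coordinate that makes diploid, tetraploid and hexaploid
calls commensurable; a heterozygote is any `0 < dosage < p`. Missing cells
stay missing everywhere except PCA (below) — imputing them before
dissimilarity or AMOVA would fabricate identity.

## The modified Gower dissimilarity

For accessions $x, y$ over $m$ SNPs,

$$GD(x,y) = 1 - \frac{\sum_{i=1}^m s_i w_i}{\sum_{i=1}^m w_i},$$

with $w_i = 1$ iff both are genotyped at SNP $i$. Under the default
**collapsed** coding each call is one of three identity-by-state classes
(hom-ref, het, hom-alt) and $s_i$ is 1 / 0.5 / 0 for identical / one-allele
/ opposite-homozygote differences. Writing the classes as coordinates
$x \in \{0, 0.5, 1\}$, these scores are exactly $s = 1 - |x_a - x_b|$, so GD
is the mean absolute coordinate difference over co-genotyped SNPs — the form
the implementation computes and the brute-force oracle in the test-suite
verifies score-by-score.

The **dosage** coding replaces the three classes by dosage fractions and
keeps $s = 1 - |f_a - f_b|$. On diploids only $f \in \{0, 0.5, 1\}$ occurs,
so the two codings coincide exactly (a tested invariant). On tetraploids the
heterozygous class splits into 3:1, 1:1 and 1:3 states (0.25/0.5/0.75); the
linear rule assigns the cross-class heterozygote scores (e.g. 3:1 vs 1:3
scores 0.5) which the three-class formulation leaves unspecified — this is a
deliberate completion, chosen because it reproduces every specified score
and is the unique extension linear in dosage distance. The heterozygous
state is taken from the called dosage, not from the raw depth ratio: calls
already encode the depth evidence. Mixed-ploidy pairs refuse the dosage
coding (the state lattices differ) and must use collapsed coding — this is
how a hexaploid sport can still be compared with its tetraploid relatives.

The **diploidized** coding is collapsed coding restricted to markers that
behave as diploid loci inside a polyploid because they segregate within one
homoeologous sub-genome. `select_diploidized_snps()` finds them by their
signature: heterozygous accessions show a consistent minor depth ratio near
`1/p` (mean within `tol = 0.05` of 0.25 or 0.75 for tetraploids, SD ≤ tol,
over at least 3 heterozygous accessions).

Pairs sharing no typed SNP get an `NA` GD with a warning, never a silent 0:
a fabricated zero would manufacture redundancy. Downstream,
`redundancy_groups()` treats such pairs as distinct.

## Ploidy from allele-depth ratios

At a heterozygous SNP, the alternate-allele depth fraction concentrates near
`dosage/p`: diploids show one mode at 0.5, tetraploids three modes
(0.25/0.5/0.75), hexaploids five (1/6 … 5/6). The package formalizes the
usual visual inspection:

1. collect `alt/(ref+alt)` at heterozygous sites with total depth ≥
   `min_site_depth` (default 20; ratio precision scales as $1/\sqrt{d}$, so
   40+ is recommended when hexaploids are possible);
2. fit a Gaussian KDE. The bandwidth is the Sheather–Jones plug-in, floored
   at 0.02: Silverman's rule oversmooths five-mode mixtures into four, while
   unfloored plug-in bandwidths chase the read-count lattice (ratios are
   rationals with small denominators) and shatter single modes;
3. keep local maxima with density ≥ `min_prominence` (0.1) of the global
   maximum, inside [0.05, 0.95] — residual sequencing error piles mass at
   the edges; pool maxima closer than `merge_radius` (0.1, below the
   smallest template spacing 1/6) into their density-weighted mean;
4. match against the templates {0.5}, {0.25, 0.5, 0.75}, {1/6…5/6} with a
   per-peak tolerance of ±0.06; exactly one fully matched template gives the
   ploidy, anything else is `unclear`. When only the central 0.5 peak is
   found but the KDE shows density at 0.25/0.75 reaching half the central
   peak, the 2x call is downgraded to `unclear` rather than guessed — the
   conservative direction, since an unclear accession can later inherit
   ploidy from a redundant partner (`annotate_ploidy_from_redundancy()`,
   which never overwrites an `ok` call).

With ≥ 500 usable het loci at depth ≥ 40, planted ploidies are recovered for
well over 95% of simulated accessions; hexaploids are the hardest (five
modes at spacing 0.167 against binomial spread) and account for nearly all
`unclear` outcomes.

## The redundancy threshold

True clones do not reach GD = 0: allele-depth sampling, sequencing error and
library effects leave a dissimilarity floor. The identity cutoff is the
**one-sided 99th percentile of the replicate GD distribution**. The
estimator checks normality (Shapiro–Wilk); if not rejected at 0.05 it uses
$\mathrm{GD}_{99\%} = \bar g + 2.3263\, s_g$, otherwise the empirical
percentile. Two readings of a "99% confidence interval from the mean GD"
were possible; the percentile (prediction-interval) reading was chosen
because a confidence interval of the *mean* shrinks with the number of
replicate pairs and would eventually declare true replicates non-identical —
the wrong behaviour for a clone test. Coverage is verified by simulation:
about 1% of true-clone GDs exceed the fitted threshold.

Replicate GD sets come from three sources, in decreasing order of realism:

* **technical replicates** — one DNA sample split across library
  preparations and lanes; carries library and lane effects and is the
  recommended basis for declaring redundancy in multi-library datasets;
* **biological replicates** — duplicate isolations within one library and
  lane; several-fold smaller GDs;
* **read sub-sampling** — `subsample_depths()` binomially thins each
  allele's depth at rate 0.5 (ten sub-samples, 45 profile pairs) and
  re-calls genotypes. This approximates with-replacement read sampling at
  the allele-count level; it cannot reproduce upstream alignment and SNP
  re-calling, so it estimates intra-library error only.

For a species with neither replicate class, `extrapolate_threshold()`
divides its read-sampling threshold by the cross-species
read-sampling:technical ratio (`estimate_ratio()`). Recomputing that ratio
from the two species with both quantities gives 0.3142 (mean of 0.0017/
0.0046 and 0.0029/0.0112); the conventionally reported 0.30 remains
available as an explicit argument for compatibility, and the package default
is the recomputed value.

Grouping under the cutoff is **single-linkage transitive closure**
(connected components of the at-or-below-threshold graph): the reading
implied by cutting a cladogram at a height. Chained near-threshold links can
in principle merge distinct genotypes, so each group reports its maximum
intra-group GD as a diagnostic. Representatives are the most read-abundant
members (ties broken lexicographically), and `flag_conflicts()` emits the
four curation checkpoints: usurpers (one name, several genotypes), synonyms
(one genotype, several names), gender mismatches and species-label
mismatches within a group.

## Clustering, K selection, AMOVA, diversity

All eight classical Lance–Williams linkages are available through
`stats::hclust`; the two Ward variants differ in whether the input distances
are squared (`ward_d2`) or not (`ward_d`). Method selection bootstraps SNP
columns (the feature-resampling convention; the resampling unit was an open
choice and SNPs were chosen for consistency with how clade support is
computed) and ranks methods by mean cophenetic correlation; on clock-like
simulated divergence UPGMA wins, as expected for ultrametric-generating
processes. Clade support is the plain bootstrap proportion of SNP-resampled
trees containing each leaf bipartition of the reference tree (rooted
comparison via `ape::prop.clades`); multiscale/AU corrections are
deliberately out of scope.

PCA runs on dosage fractions with per-SNP mean imputation of missing cells
(the only imputation in the package), centering, optional unit scaling
(constant SNPs are left unscaled and contribute nothing). K-means is run on
the leading PCs holding ≥ 90% of variance for K in 2…10 with
$BIC(K) = n \ln(WSS_K/n) + K \ln n$; the chosen K is the smallest K
attaining the minimum BIC, which under no structure degenerates to the
smallest K evaluated. The exact K-means BIC used by different programs
varies; this definition is fixed and documented rather than claimed
program-compatible.

AMOVA is allele-level: each accession contributes `p` allele copies per
typed locus, sums of squares over squared allele mismatches decompose into
among-groups / among-genotypes-within-groups / within-genotypes, and
variance components follow the standard expected-mean-square coefficients of
the nested design. Degrees of freedom and copy-count coefficients use the
design counts (ploidy), while per-locus sums of squares use only typed
calls; on complete data the components match a brute-force
pairwise-distance oracle to 1e-9 (tested). Negative components are truncated
to zero with a flag and `Var%` renormalized. Significance: group labels of
genotypes are permuted for the among-groups and among-genotypes strata;
allele copies are re-dealt among genotypes within groups
(multivariate-hypergeometric, per locus) for the within-genotypes stratum.
$F_{ST}$ is the among-groups component over the total. Permutation
p-values are uniform on structureless data (tested by Kolmogorov–Smirnov
over simulated datasets).

Diversity per locus uses allele copies $n_c = \sum p_i$ over typed
accessions and alternate frequency $p$ from dosage sums — the natural
polyploid generalization, since the data do not identify which homoeologous
copies carry which allele. $N_E = 1/(p^2+q^2)$, unbiased
$H_E = \frac{n_c}{n_c-1}(1-p^2-q^2)$, $H_O$ = fraction of heterozygous
accessions, and $F_{IS} = 1 - \bar H_O / \bar H_E$ over polymorphic loci
(ratio of means, the numerically stable form). Dioecious obligate
outcrossers are expected near zero or slightly negative; note that
population mixtures inflate $F_{IS}$ (Wahlund effect), so it is best read
within the clusters the structure analysis finds. Numerical parity with
specific desktop programs' internal polyploid conventions is not claimed —
only with these stated definitions and the test-suite oracles.

## The synthetic-data generator

`simulate_collection()` is first-class, tested code, not a fixture. Its
generative model:

* ancestral allele frequencies ~ Uniform(0.05, 0.95); sub-population
  frequencies by a Balding–Nichols draw
  $\mathrm{Beta}\!\big(p\frac{1-F}{F}, (1-p)\frac{1-F}{F}\big)$ at
  divergence `fst`; a Hudson-type estimator recovers the planted `fst`
  within ±0.1 (tested);
* founder dosages ~ Binomial(p, p_subpop); clone copies duplicate founder
  dosages and pass through a **post-call replicate-error channel**: with the
  library-dependent probability each call moves one dosage step (10% of
  events drop to missing instead). Modelling replicate error at the
  genotype level rather than re-simulating library chemistry keeps it
  directly calibratable against observed replicate GD magnitudes;
* per-cell total depth ~ NegBin(mean 40, size 25) — over-dispersed relative
  to Poisson, as GBS coverage is; alternate depth ~ Binomial(depth, f')
  with sequencing error folded in as $f' = f(1-e) + (1-f)e$, `e = 0.001`;
* genotypes re-called by `call_genotypes()`: missing below total depth 6,
  dosage = nearest integer to `p · alt/(ref+alt)` (halves away from zero —
  banker's rounding would send an exact quarter ratio to the homozygote),
  heterozygotes require ≥ 3 reads on each allele else round to the nearer
  homozygote; then 6.5% of calls are masked missing, the average missing
  rate of GBS germplasm panels at these depths.

**Calibration of the error channel.** Published replicate studies report
resulting GDs, not error rates. For diploids under collapsed coding the
relation is mean replicate GD ≈ baseline + 0.5·0.9·p_channel, where the
baseline ≈ 0.0007 at 40x mean depth is the caller's own depth-resampling
noise (measured with the channel off). Solving for the reference diploid
values — biological 0.0009, technical 0.0058 — fixes
`intra_library_miscall = 0.0004` and `inter_library_miscall = 0.0112`.
These were set once, from this closed form, and give a realized
technical:biological mean-GD ratio of ≈ 5–7 across seeds, the 6–7× ordering
reported for real diploid collections. For tetraploids the caller baseline
is larger (dosage-1 heterozygotes collapse to homozygote at the ~1–2% level
when the depth draw is skewed), which compresses the realized ratio; the
ratio invariant is therefore checked on diploid collections, while
tetraploid collections are used for what they are needed for — threshold
adaptation, clone recovery and the diploidized-subset concordance, all of
which hold because thresholds are estimated from the same distribution that
generates the noise.

**What the generator does not emulate**: linkage disequilibrium and genetic
maps (SNPs are independent), read-level artifacts (chimeras, paralog
collapse, allele-specific amplification), batch effects beyond the two-rate
library channel, and null alleles. Passing tests therefore demonstrate
correctness of the algorithms under a realistic error budget, not robustness
to every pathology of real GBS data; on real collections the empirical
replicate thresholds are the safeguard, which is exactly why they are
estimated per dataset rather than fixed.

## Numerical and degenerate-input choices

* Zero-SD replicate sets return GD₉₉% = mean with a degeneracy warning.
* Shapiro–Wilk caps at n = 5000; larger sets are tested on a deterministic
  evenly spaced subset.
* Agglomeration ties follow `stats::hclust`'s deterministic ordering; all
  stochastic stages take explicit seeds, and the pipeline derives per-stage
  seeds from its master seed, so reruns are byte-identical.
* An accession pair with no shared typed SNPs is `NA` throughout and
  conservatively treated as distinct.
* All-missing SNP columns are an error in PCA (nothing to impute from);
  loci with ≤ 1 allele copy are skipped in diversity statistics.

## Problem sizes used in the test-suite

Simulated collections in the tests use 12–60 genotypes and 300–8000 SNPs,
chosen to keep each statistical check comfortably powered (e.g. 2000 het
ratios per ploidy call, 45 sub-sampling pairs, 20 seeds for the K-selection
recovery rate) while the full suite stays fast to run routinely. These sizes
are the package's own testing conditions; the algorithms themselves scale as
O(N²M) in accessions and SNPs for the dissimilarity stage and have been run
at collection scale (hundreds of accessions, thousands of SNPs) without
special handling.

## Known limitations

* Single-linkage closure can chain distinct genotypes through intermediates
  when the threshold approaches the within-cluster GD scale; watch the
  reported maximum intra-group GD.
* The read sub-sampling surrogate underestimates technical error by
  construction; extrapolation across species assumes the
  read-sampling:technical ratio is stable, which is an empirical claim to
  re-check per platform and pipeline.
* Ploidy templates cover 2x/4x/6x; odd or higher ploidies are out of scope
  and will come back `unclear`.
* AMOVA degrees of freedom use design counts, so heavy locus-specific
  missingness slightly misstates within-genotype df; the components still
  match the direct-definition oracle on complete data.
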