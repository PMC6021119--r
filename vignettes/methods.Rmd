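---
title: "Methods: combining ability, trait correlations and genetic distance in a half-diallel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combining ability, trait correlations and genetic distance in a half-diallel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diallelkit)
```

# Scope

`diallelkit` analyses half-diallel crossing designs: `p` inbred parents, all
`p(p-1)/2` single-cross hybrids, and the `p` selfs, without reciprocals, grown
in a randomized complete block design (RCBD) with `b` blocks. It implements

* the fixed-effects combining-ability partition of the genotype sum of squares
  into general (GCA) and specific (SCA) components, with effect estimates,
  variance components, heritabilities, mid-parent heterosis and SCA
  percentages (`griffing_analysis()` and friends);
* trait–trait correlations on genotype means with a Bonferroni-adjusted
  critical correlation (`trait_correlations()`);
* molecular characterisation of the parents from SNP dosages: identity-by-state
  (IBS) genetic distances, UPGMA clustering with locus-bootstrap supports
  (`ibs_distance()`, `upgma()`, `bootstrap_upgma()`);
* linking parental genetic distance to hybrid performance, heterosis and SCA
  (`assemble_hybrid_records()`, `gd_correlations()`);
* a synthetic-data generator with known truth for validation
  (`simulate_diallel()`, `simulate_snps()`).

# The diallel model

## Notation and ANOVA

Let `x_ij` be the genotype mean (over blocks) of the cross between parents
`i` and `j` (`i <= j`; `x_ii` is the self). The two-way RCBD ANOVA on plot
values partitions variation into Blocks (`b - 1` df), Genotypes
(`p(p+1)/2 - 1` df) and Error; `diallel_anova()` obtains it from
`stats::aov()` and then splits the genotype line into

* GCA with `p - 1` df,
* SCA with `p(p-1)/2` df,

using the fixed-effects (Method 2, Model 1) sums of squares on a mean basis,

$$
S_g = \frac{1}{p+2}\sum_i (x_{i.}+x_{ii})^2 - \frac{4}{p(p+2)}x_{..}^2,
\qquad
S_s = \sum_{i \le j} x_{ij}^2 - \frac{1}{p+2}\sum_i (x_{i.}+x_{ii})^2
      + \frac{2}{(p+1)(p+2)}x_{..}^2,
$$

where `x_i.` is the row total of the full symmetric table (the diagonal
counted once) and `x_..` the grand total. Both are multiplied by `b` to put
them on the plot basis of the RCBD ANOVA, so that `SS_GCA + SS_SCA` equals the
genotype sum of squares exactly (this identity is asserted to floating-point
accuracy in the test suite, and both sums of squares are cross-checked against
an independent equality-constrained least-squares oracle). F statistics for
GCA and SCA use the RCBD error mean square as denominator; under the null the
decomposition is orthogonal and the tests are exact F tests, which the test
suite verifies by Monte Carlo calibration of the type-I error rate.

## Effects

`estimate_effects()` returns the standard fixed-effect estimates

$$
\hat\mu = \frac{2x_{..}}{p(p+1)},\qquad
\hat g_i = \frac{x_{i.}+x_{ii} - 2x_{..}/p}{p+2},\qquad
\hat s_{ij} = x_{ij} - \frac{t_i+t_j}{p+2} + \frac{2x_{..}}{(p+1)(p+2)},
$$

with `t_i = x_i. + x_ii`. They satisfy `sum(g) = 0` and, for each `i`,
`sum_j s_ij + s_ii = 0`; both constraints are asserted in tests.

## Variance components, ratios and heritability

`variance_components()` uses the method-of-moments estimators

$$
\hat\sigma^2_{gca} = \frac{MS_{GCA}-MS_e}{p+2},\qquad
\hat\sigma^2_{sca} = MS_{SCA}-MS_e,
$$

computed from the plot-basis mean squares. This is the convention used by
common diallel analysis software, and the package reports the ratio
`ratio_component = sigma2_gca / sigma2_sca` alongside Baker's
predictability ratio `2*sigma2_gca / (2*sigma2_gca + sigma2_sca)`. Two scale
caveats follow from the convention and are worth stating plainly:

* Because the mean squares are on a plot basis, the two estimators carry the
  block multiplier `b` differently: under the package's own generator (below)
  their expectations are approximately `(b(p+2)s2g + b·s2s + s2e - MSe)/(p+2)`
  and `s2e + b·s2s - MSe`, i.e. each is inflated by roughly the factor `b`
  relative to the generator's per-plot variances. The *ratio* of the two is
  therefore comparable across studies with different `b`, while the components
  themselves are not; interpret them on their own scale.
* Narrow- and broad-sense heritabilities from `heritabilities()`,
  `h2 = 2g/(2g + s + e)` and `H2 = (2g + s)/(2g + s + e)`, inherit the same
  scale convention. They are ratios of estimated components, so they are not
  unbiased for the corresponding population ratios; the recovery simulations
  in the test suite quantify the bias under the default generator and assert
  that the ratio of components is recovered to within 15% and h2 to within
  0.05 of its target, tolerances fixed before the tests were run.

Negative method-of-moments components are reported as-is by
`variance_components()` with `negative_gca`/`negative_sca` flags (no silent
truncation); only `heritabilities()` clamps negatives to zero, and flags that
it did so, because a heritability outside [0, 1] is not interpretable.

## Heterosis and SCA percentage

`heterosis()` computes mid-parent heterosis `100 (F1 - MP) / MP` with
`MP = (x_ii + x_jj)/2`; a zero mid-parent is flagged `undefined` rather than
producing infinities. `sca_percent()` scales each `s_ij` by the mean of the
hybrid genotype means, expressed as a percentage.

# Trait correlations

`trait_correlations()` correlates traits across *genotype means* (the
`p(p+1)/2` entries of the diallel table), not across plots, so that the
sample unit matches the genetic entity of interest. With `m = k(k-1)/2` pairs
among `k` traits, the Bonferroni-adjusted critical correlation is

$$
r^* = \frac{t^*}{\sqrt{t^{*2} + n - 2}},\qquad
t^* = t_{1-\alpha/(2m),\,n-2},
$$

with `n` the number of genotypes. Zero-variance traits yield `NA`
correlations flagged `degenerate`. Note that because the per-test level is
`alpha/m`, letting `alpha` approach 1 does *not* drive `r*` to 0 when
`m > 1`; it converges to the critical value at per-test level `1/m`.

# Genetic distance and clustering

## Distances

SNP genotypes are handled as alternate-allele dosages in {0, 1, 2}. Per pair
of samples and site, the identity-by-state similarity is
`1 - |d_a - d_b|/2`; the genetic distance is one minus its mean over sites.
For dosage data this coincides with the normalized Hamming distance
(`hamming_distance()`), the mean fraction of differing allele copies, so the
two functions agree exactly and are tested against each other and a worked
hand example. Distances are only defined on complete data:
`filter_snp_sites()` first removes any site with a missing call
(complete-case), then any monomorphic site, reporting both counts; computing
a distance on unfiltered data with missing calls is an error rather than a
silent pairwise-deletion fallback, so every pair is compared on the same set
of sites.

## UPGMA and bootstrap

`upgma()` implements average-linkage agglomeration directly: the closest pair
of clusters is merged at a node of height half their average distance, and
distances to the merged cluster are size-weighted averages. Exact ties are
broken deterministically by the lexicographically smallest pair of cluster
representative labels, so results are reproducible across platforms. The
implementation is verified against a brute-force oracle that recomputes
cluster averages from the original distance matrix at each step, and its node
heights against `stats::hclust(method = "average")`.

`bootstrap_upgma()` resamples sites (columns) with replacement `B` times,
rebuilds the tree each time, and reports for each internal node of the
original tree the percentage of bootstrap trees containing the same leaf set
(clade supports via `ape::prop.clades(rooted = TRUE)`). Supports are
meaningful only as a measure of signal consistency across loci; they say
nothing about the adequacy of the ultrametric (equal-rates) assumption UPGMA
imposes.

## Distance–performance records

`assemble_hybrid_records()` joins the parental distance matrix to hybrid
trait means (optionally heterosis and SCA effects) into one record per
hybrid; `gd_correlations()` then reports Pearson correlations of GD with each
response per trait, with `cor.test()` p-values and optional `p.adjust()`
multiplicity correction. With `p` parents there are only `p(p-1)/2` hybrid
records and the records share parents, so these correlations are descriptive:
the independence assumption behind the p-values is only approximate.

# The synthetic generator

`simulate_diallel()` draws, in documented order from one seed: parental GCA
effects `g_i ~ N(0, sigma2_gca)`, SCA effects `s_ij ~ N(0, sigma2_sca)` in
canonical genotype order, block effects `~ N(0, sigma2_block)`, and plot
residuals `~ N(0, sigma2_error)`; a plot value is
`mu + g_i + g_j + s_ij + block + error`. The returned `truth` element makes
every draw available for recovery checks. Defaults (`p = 10`, `b = 3`,
`sigma2_gca = 4`, `sigma2_sca = 1`, `sigma2_block = 0.5`,
`sigma2_error = 1`) emulate a ten-parent, three-block field study with a
4:1 GCA:SCA variance ratio, i.e. predominantly additive gene action with a
non-trivial non-additive component. Realism limits: effects are Gaussian and
homoscedastic, selfs carry the same `s_ii` variance as crosses (no inbreeding
depression term), there is no genotype-by-block interaction, and traits are
drawn independently of each other.

`simulate_snps()` generates fully homozygous inbred-parent genotypes (dosages
0/2) in `n_clusters` groups: a cluster consensus mutates a fraction
`p_between` of sites between clusters and `p_within` within, with optional
missing calls at rate `missing_rate`. It is deliberately simple — no linkage,
no allele-frequency spectrum, no heterozygosity — sufficient to exercise
distance, clustering and bootstrap code against a known grouping, not to
mimic real genome structure. `write_snp_vcf()` writes a minimal VCF 4.2 text
file whose round-trip through `read_snp_vcf()` is tested.

# Numerical and design choices

* All user-facing functions take a data frame (or matrix) first and return
  tibbles; `tidy()`, `glance()` and `autoplot()` methods cover the fitted
  objects.
* Genotype pairs are canonicalized by parent order on ingestion, so
  `(B, A)` and `(A, B)` records refer to the same hybrid.
* Incomplete diallels are an error that names the missing cells; the
  combining-ability algebra above is only valid for the complete design.
* Monte Carlo checks in the test suite use moderate sizes chosen to keep the
  suite under about a minute (for example, 2000 null replicates at `p = 6,
  b = 3` for test calibration and 500 replicates at the default generator
  settings for recovery); the acceptance script re-runs smaller versions of
  the same checks from a user-supplied seed.

# Limitations

* Fixed-effects (Model 1) analysis only: parents are the population of
  interest, and no random-effects (BLUP) machinery is provided.
* Complete half-diallels with equal replication only; no missing-cell or
  unbalanced analysis.
* The variance-component and heritability estimators are method-of-moments on
  the software-conventional plot-basis scale discussed above; treat absolute
  component values as convention-dependent and prefer ratios for
  interpretation.
* Distances require complete data after filtering; there is no imputation.
* UPGMA assumes ultrametricity; for markedly unequal divergence rates a
  different clustering method would be more appropriate.
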