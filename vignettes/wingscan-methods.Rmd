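---
title: "Detecting morph-associated outlier loci against a panmictic background"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting morph-associated outlier loci against a panmictic background}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis this package implements

wingscan reproduces, as tested code, a genome-scan study design for a
discrete morphological polymorphism segregating inside a single
panmictic population — the motivating case being wing reduction in an
alpine stonefly, where fully winged (macropterous) and vestigial-winged
(micropterous) adults co-occur in one stream reach. The design has four
stages:

1. **Morphometrics**: classify morphs from the forewing:body length
   ratio and confirm with a linear model that the classification is not
   confounded with size, sex or sampling altitude.
2. **Filtering and summaries**: starting from genotype calls (GENEPOP
   export of a GBS pipeline), retain loci genotyped in at least half the
   individuals with minor allele frequency at least 0.05, one SNP per
   RAD tag; report call rate, MAF, observed and expected heterozygosity.
3. **Structure diagnostics**: genomic relatedness, a neighbor-joining
   relatedness tree, principal components, and a BIC-based cluster-number
   choice. The expected outcome for a sympatric morph pair is *no*
   structure — one cluster, no PC separating morphs.
4. **Outlier scans with replication**: a Bayesian logistic-FST scan run
   twice on balanced split-half designs, a PCA Mahalanobis scan, and a
   randomized-group null calibration; shared outliers across the
   balanced runs are the replicated candidates, judged against the
   expected chance overlap and the hypergeometric tail probability.

Because no genotype accessions are bundled, a synthetic-data generator
with known ground truth stands in for the study data; every stage is
exercised end-to-end on it.

## The synthetic-data generator

`simulate_genotypes()` draws, per locus, one ancestral alternate-allele
frequency uniform on [`maf_low`, `maf_high`] (defaults 0.05–0.95) and
samples each diploid genotype as two binomial gene copies. Neutral loci
use the *same* frequency for both morphs: the background is exactly
panmictic. A small planted set (`n_assoc`, default 3) instead uses
group-specific frequencies (defaults 0.05 vs 0.95), emulating genomic
islands of divergence between morphs. Missingness is
genotype-independent (MCAR) at rate `missing_rate` (default 0.2).
Defaults mirror the emulated study's scale: 34 + 62 individuals and
6,843 loci.

Deliberate modelling choices:

* **Uniform post-filter frequency spectrum.** The study data are
  *post*-MAF-filter, and no site-frequency model is stated for them; a
  uniform draw on the retained range assumes the least. One consequence
  worth knowing: expected heterozygosity of the simulated matrix
  averages ≈ 0.37, higher than is typical for a real GBS spectrum, which
  is skewed toward rare alleles. None of the scan machinery depends on
  this.
* **Optional residual drift.** `background_fst > 0` draws per-group
  frequencies from a Balding–Nichols beta around the ancestral value;
  the default is 0 because the emulated study found no neutral
  structure. The option exists to create latent-group scenarios for the
  PCA scan tests.
* **Genotypes are 0/1/2 alternate-allele counts; missing is `NA`**,
  never a numeric sentinel.
* **One simulated tag per locus** by default; `two_per_tag = TRUE`
  emits a second SNP per tag so the one-SNP-per-tag filter has work to
  do.

What the generator does **not** emulate: linkage disequilibrium between
loci, family/relatedness structure, depth-dependent genotyping error,
allele dropout, and a realistic site-frequency spectrum. Passing tests
therefore demonstrate correctness of the statistical machinery under
idealized sampling, not robustness to those real-data artefacts.

`simulate_morphometrics()` draws each individual's forewing:body ratio
from its class distribution (defaults: means 1.06 and 0.26, spreads 0.15
and 0.28, the values reported for the emulated population), multiplies
by a body length with a female size offset, and assigns one of the three
sampling altitudes (90/130/200 m). The source material labels the two
spreads "(SE)", which for class sizes near 60 would imply implausibly
large individual-level variation if back-multiplied; they are more
plausibly standard deviations. The generator takes them as per-individual
standard deviations by default but exposes `dispersion = "se"` for the
literal reading — neither interpretation is hard-coded into any test of
the scan machinery.

## Filtering and per-locus summaries

* Call-rate and MAF thresholds are boundary-inclusive (a locus at
  exactly 0.5 call rate or 0.05 MAF is retained).
* MAF is computed over all individuals jointly, once, before any
  split-half design — matching a pipeline whose filtering happens in a
  single export step.
* The one-SNP-per-tag rule keeps the lowest position per tag (ties
  broken lexicographically on the full id), a deterministic stand-in for
  an unstated selection rule.
* Expected heterozygosity uses the small-sample correction
  `2 p (1-p) n_c / (n_c - 1)` with `n_c` called gene copies, the
  convention of the Arlequin-style summaries it replaces.
* Read-depth filters are upstream of this package: the artifact starts
  from genotype calls.

## Structure diagnostics

**Relatedness.** The "adjusted" genomic relatedness matrix is
implemented as the VanRaden allele-frequency-standardized estimator
`G = Z Zᵀ / (2 Σ p (1-p))` with mean-imputed missing calls. The source
material cites but does not describe its GRM adjustment; this choice is
explicit, not an inference. The neighbor-joining tree is built (via
\pkg{ape}) on the squared-Euclidean distances `G_xx + G_yy − 2 G_xy`
the GRM induces; negative NJ branches are clamped to zero with the
deficit moved to the sister branch, preserving path lengths through the
parent.

**PCA.** Genotypes are standardized by `sqrt(2 p (1-p))` after
centering; missing calls impute to the locus mean. Eigenvalues are
squared singular values, so they sum to the total standardized variance.

**Cluster number.** `choose_k_bic()` scores k-means solutions with
`BIC(k) = n ln(WSS_k / n) + k ln(n)`, ties toward smaller k. One
empirical subtlety drove a design decision: run on only a handful of PC
dimensions, k-means can always cut an isotropic Gaussian cloud roughly
in half, and the resulting drop in `n ln(WSS)` exceeds the `ln(n)`
penalty — BIC then reports spurious clusters on perfectly panmictic
data. On the *full-rank* score space the per-split reduction is diluted
by the untouched dimensions and the criterion correctly returns k = 1
under panmixia while still detecting genuinely separated groups. The
pipeline therefore clusters on all PCs.

**Scree rule.** `scree_k()` automates the Cattell elbow: K is the
largest index whose eigenvalue drop exceeds `tau` (default 0.1) of the
range of the eigenvalues *supplied*. Feed it the leading eigenvalues one
would actually plot (the first 10, say): the full spectrum ends in a
near-zero rank-deficiency eigenvalue whose preceding drop would
dominate the range.

## The Bayesian logistic-FST outlier scan

For locus *i* and group *j*, the alternate-allele count among the
`n_ij` called gene copies is beta-binomial,

```
a_ij ~ BetaBin(n_ij, theta_ij p_i, theta_ij (1 - p_i)),
theta_ij = 1/FST_ij - 1,   logit(FST_ij) = delta_i alpha_i + beta_j,
```

the biallelic reduction of the Dirichlet-multinomial island model. The
locus effect `alpha_i` (selection signal) is present only when the
indicator `delta_i` is 1; `beta_j` absorbs group-level drift. Priors:
`p_i` uniform, `alpha_i ~ N(0,1)`, `beta_j ~ N(-1,1)` (the reference
implementation's published defaults — the emulated study states only
the prior odds), and `Pr(delta_i = 1) = 1/(1 + prior_odds)` with prior
odds 10 by default, i.e. a 1-in-11 prior inclusion probability.

Sampling is reversible-jump Metropolis–Hastings, implemented in C++:

* `p_i` moves by a symmetric random walk reflected into (0, 1);
* `alpha_i` (when present) and `beta_j` move by Gaussian random walks;
* the jump move toggles `delta_i`, proposing a fresh `alpha*` from a
  zero-centered Gaussian whose width is the locus's tuned `alpha`
  proposal width; the acceptance ratio carries the prior/proposal
  density ratio and the prior-odds factor, and dimensions match because
  the discarded `alpha` is regenerated from the proposal at the next
  birth (no Jacobian term).
* Pilot runs adapt each proposal width toward acceptance rates in
  [0.25, 0.45] (factor-1.5 steps, widths bounded away from 0 and ∞).
* `logit(FST)` is clamped to ±15 before exponentiation — beyond that
  the likelihood is flat to double precision and `exp` would overflow.
* Missing genotypes are simply absent from `a_ij`/`n_ij`; no imputation
  enters the likelihood.
* Loci with zero called copies in one group contribute a likelihood of
  1 for that cell; monomorphic loci are rejected up front (filter
  first).

The per-locus posterior inclusion probability `P_i` is the fraction of
retained samples with `delta_i = 1`. The q-value of locus *i* is the
expected false-discovery rate of the list thresholded at it:
`q_i = mean(1 - P_j)` over loci with `P_j ≥ P_i`. When every retained
sample includes the locus, `q = 0` is reported; at 400 retained samples
that should be read as "< 1/400", a display convention, not a claim of
certainty.

Two chain profiles are provided. The `"full"` profile is the emulated
study's published configuration (10,000 retained samples, thinning 10,
burn-in 10,000, 20 pilot runs of 10,000). The `"fast"` profile (400
retained, thinning 2, burn-in 300, 3 pilots of 100) exists because the
posterior here is low-dimensional per locus and mixes quickly; with 400
retained samples the Monte-Carlo standard error of a `P_i` near 0.5 is
about 0.025 (larger with autocorrelation), which is ample for q < 0.2
decisions on strongly divergent loci. Simulation tests and the analysis
drivers use the fast profile; tolerances in the tests (e.g. 0.15 for
posterior symmetry checks) reflect its Monte-Carlo error.

## The PCA Mahalanobis scan

Each standardized SNP is regressed on the first K PC score vectors
(K from the scree rule); the K z-statistics per SNP feed a robust
Mahalanobis distance using a minimum-covariance-determinant scatter with
support fraction 0.75, so that the outlier loci themselves do not
inflate the null covariance. Distances are rescaled by the genomic
inflation factor `lambda = median(D²)/median(chisq_K)` and referred to a
chi-square(K); q-values are Benjamini–Hochberg. On null simulations
`lambda` sits in [0.8, 1.2] and the p-values are near-uniform.

## Replication design and overlap statistics

With 34 macropterous vs 62 micropterous individuals, a single scan
would be unbalanced — a known source of spurious outliers. The design
instead runs the scan twice, each run using **all** 34 macropterous
individuals against one of two disjoint random halves (31 + 31) of the
micropterous sample, and treats loci flagged in *both* runs as the
replicated candidates. The null calibration repeats the scan on
randomized designs: disjoint uniform-random groups of 34, labels
ignored. Randomized designs use two disjoint groups (mirroring the
balanced geometry; the source material does not say whether its
randomized groups were complementary) and derive each run's seed from a
base seed plus the run index, so any single run is reproducible in
isolation.

Loci that fall below the call-rate or MAF threshold after subsetting a
design's individuals are dropped for that run; overlap statistics are
computed on the set retained in both runs.

Two closed-form quantities summarize chance agreement between runs
flagging `n1` and `n2` of `L` loci:

* expected shared count `n1 n2 / L` (0.0348 at the emulated study's
  printed counts 17, 14 and 6,843);
* the exact upper-tail hypergeometric probability of at least the
  observed shared count.

For the "same top locus in both runs" event, two probabilities are
reported and labelled distinctly: `(1/L)²`, the chance that a
*pre-specified* locus tops both independent uniform rankings (the form
the emulated study prints), and `1/L`, the chance that the two top loci
merely coincide. Which is "the" right null depends on whether the locus
was named in advance; the report prints both and asserts neither.

## Statistical behavior worth knowing

* **Calibration.** On fully neutral simulations the scan flags
  essentially nothing at q ≤ 0.2 (prior odds 10 are conservative at
  these sample sizes); the randomized-null summaries in the bundled
  analysis are correspondingly clean, cleaner than a real study's,
  where library and depth artefacts feed the null runs.
* **The PC–morph permutation check is a 5%-level test with real signal
  in it.** The planted morph loci are genuinely label-associated, and
  under a nearly flat eigenvalue spectrum even three strong loci can
  boost a label-correlated direction into the leading PCs — reliably so
  at a few thousand loci, occasionally at the full 6,843. The package's
  tests therefore assert non-separation *in the majority of seeds* at
  the study scale rather than at every seed; a single-seed assertion
  would fail ~1 time in 6 by construction, not by bug. At markedly
  reduced locus counts the property should not be expected to hold at
  all.
* **Problem sizes.** The test suite runs its simulation studies at 150
  to 2,000 loci with the fast chain profile and 20 seeds for the
  calibration and power properties, and at the full 6,843 loci for the
  structure checks, where the property is scale-dependent. These sizes
  are the package's choice of a representative, quickly reproducible
  design.

## Known limitations

* The Bayesian model is written for J groups but only the two-group
  case is exercised and tested; hierarchical island structures are out
  of scope.
* Biallelic diploid SNPs only; no multi-allelic sites, phasing, or
  haploid data.
* The admixture-model cluster analysis of the original design is
  replaced by the PCA + BIC clustering combination; ancestry proportions
  are not estimated.
* BLAST annotation of outliers is out of scope (the emulated study
  itself could not map its outliers).
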