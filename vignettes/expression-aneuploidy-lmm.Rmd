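---
title: "Mixed-model association testing between gene expression and tumor aneuploidy"
author: "aneulmm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-model association testing between gene expression and tumor aneuploidy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aneulmm)
```

## The problem

Bulk tumor expression profiles are mixtures: the fraction of cancer cells in
a sample (tumor purity) moves the measured expression of hundreds of genes at
once (immune and stromal programs rise as purity falls, tumor-intrinsic
programs fall), and co-regulated pathways move hundreds more together. A
naive per-gene regression of expression against a genome-wide copy-number
burden phenotype therefore reports large blocks of spurious associations:
any gene whose expression tracks purity "associates" with aneuploidy simply
because purity also correlates with the copy-number signal, and any gene in
a module containing a causal gene inherits that gene's association.

`aneulmm` implements the mixed-model correction for this problem together
with the scoring, enrichment and simulation machinery needed to use and
validate it end to end.

## The phenotype: integrated copy-number burden

From segmented relative copy-number data (SEG format), each sample's burden
score is

$$\mathrm{ICNA}(n) = \sum_{i \in \mathrm{segments}_n} L_{in} \cdot t(C_{in}),$$

with $L$ the segment length, $C$ the relative copy-number change (log2
ratio) and $t$ a configurable transform. The default transform is the
absolute value: for a burden score a deletion is as much alteration as a
gain, and under the signed convention gains and losses cancel. Both
conventions are implemented (`value_transform`), and both SEG coordinate
dialects are supported (one-based inclusive by default; a flag switches to
0-based half-open) because public SEG files use both and the convention is
rarely declared.

## The model

For gene $k$ with expression vector $x_k$ across $m$ samples:

$$y = \beta_0 1 + \beta_1 x_k + u + \varepsilon,\qquad
u \sim \mathcal{N}(0, \sigma_g^2 K),\quad
\varepsilon \sim \mathcal{N}(0, \sigma_e^2 I).$$

$K$ is the inter-sample covariance of the gene-standardized expression
matrix $Z$ ($m \times n$, every gene centered to mean 0 and scaled to
variance 1): $K = ZZ^\top / n$. It plays the role the genetic relationship
matrix plays in GWAS mixed models: samples that share genome-wide expression
structure — driven by purity, batch, or co-regulated programs — are
"related", and the random effect $u$ absorbs the part of the phenotype that
follows this relatedness. A gene whose expression rides on a shared program
contributes little beyond $u$ and loses significance; a gene whose
expression varies independently of the global structure keeps it.

Numerical conventions, chosen for clean testable invariants:

* standardization uses the population (denominator $m$) standard deviation,
  so $\mathrm{trace}(K) = m$ exactly;
* division by $n$ (the gene count) follows the covariance definition above
  verbatim;
* column centering makes $K\,1 = 0$ exactly, so $K$ is always singular;
  $V = \sigma_g^2 K + \sigma_e^2 I$ stays positive definite for
  $\sigma_e^2 > 0$.

## Fitting and testing

Variance components are fitted once, by full maximum likelihood, under the
intercept-only null model (no REML), maximizing

$$-\tfrac12\left[m \log 2\pi + \log|V| + (y-\beta_0 1)^\top V^{-1}
(y-\beta_0 1)\right]$$

with $\beta_0$ profiled out by GLS. One eigendecomposition $K = U S U^\top$
reduces the problem to a 1-D search over the variance ratio
$\delta = \sigma_e^2/\sigma_g^2$: 100 log-spaced grid points on
$[10^{-5}, 10^{5}]$ followed by golden-section refinement to $10^{-8}$
relative precision, with the boundary model $\sigma_g^2 = 0$ evaluated
separately and ties resolved toward the larger residual variance. The fitted
components are then reused for every gene (the EMMAX approximation; a
`refit_per_gene` flag refits the ratio per gene for sensitivity analysis).
Each per-gene test costs $O(m)$ after rotating the expression matrix into
the eigenbasis.

Two numerical decisions deserve emphasis:

**The likelihood is unbounded at the edge.** Because $K 1 = 0$ and the GLS
intercept absorbs exactly that direction, the profiled likelihood diverges
as $\sigma_e^2 \to 0$: $\log|V|$ contributes $\log \sigma_e^2 \to -\infty$
while the quadratic form stays bounded. This is a genuine pathology of full
ML with a singular relatedness matrix and a profiled mean (REML would remove
it, but the method is defined with ML). The estimator is therefore *defined*
on the closed ratio domain $[10^{-5}, 10^{5}]$; at small $m$ the fit can sit
at the high-heritability edge of that domain, which is reported via the
`boundary`/`delta` fields. The package's tests compare the spectral fit
against a brute-force dense-likelihood grid search over the same domain.

**Wald covariance.** Fixed effects are the GLS estimator
$\hat\beta = (X^\top V^{-1} X)^{-1} X^\top V^{-1} y$. Its covariance is
taken as $\hat\sigma^2 (X^\top V^{-1} X)^{-1}$ with the correlation
structure held at the null fit and the residual scale $\hat\sigma^2$
re-estimated per gene from the GLS residuals (denominator $m-2$) — the
standard mixed-model GWAS practice. This makes the test collapse *exactly*
onto the OLS $t$-test when $\sigma_g^2 = 0$, so the only Wald-vs-$t$
discrepancy left is the normal-vs-$t$ reference distribution
($6.4\times10^{-4}$ in p at $m = 500$). A published variant of the
asymptotic covariance divides by the sample count; that variant shrinks
every standard error by $\sqrt m$ and is available behind
`paper_variance = TRUE` for reproducibility, not recommended for inference.
Two-sided p-values are clamped below at $10^{-300}$ so downstream ranking
never sees zeros.

## Purity genes and the depleted-K control

Given per-sample consensus purity estimates (CPE, consumed as input),
`purity_associated_genes()` flags genes whose expression correlates with
purity at Bonferroni-corrected $p < 0.01$ (Pearson by default — consistent
with the package's linear machinery; Spearman by flag; the Bonferroni family
is the number of genes actually tested). The decisive control for "is the
LMM really absorbing purity, or just adding noise?" rebuilds $K$ with all
purity-associated genes excluded (`compute_kinship_excluding()`, which
re-standardizes the remaining genes): with purity stripped from the variance
component, the purity-driven associations reappear in the LMM output.
Re-standardization after exclusion was an open choice; it is selected here
so the depleted $K$ retains $\mathrm{trace}(K) = m$ and all other invariants.

## Pre-ranked enrichment

Association results are ranked by the signed statistic (or the equivalent
correlation coefficient for OLS results) and scored against gene set
collections with the weighted Kolmogorov–Smirnov running-sum statistic
(hit increments $\propto |r|^p$, default $p = 1$; uniform miss decrements).
Significance comes from gene-label permutations (default 10,000 per set;
tests use 1,000): the NES divides the observed ES by the mean same-sign
permuted $|ES|$, the p-value is the classic same-sign tail frequency (it can
be exactly 0 when the observed ES beats every permutation), and the FDR q
compares pooled normalized permutation scores against the observed NES
distribution, followed by a step-up monotonicity adjustment within each NES
sign.

Strongly enriched sets saturate at $q = 0$, which makes their relative
strengths incomparable. `extrapolate_q()` fits a LOESS curve (span 0.75,
degree 2, direct surface so extrapolation is defined) of $-\log_{10} q$ on
NES through the nonzero-q sets — separately per NES sign, because the two
tails need not be symmetric — and reports $10^{-\mathrm{fit(NES)}}$ for the
saturated sets, clamped to $(0, 1]$. Original q-values are never modified;
a sign with fewer than 5 nonzero-q sets is skipped with a warning. A
`mask_genes` option removes a given gene list (e.g. histone genes) from
every set before scoring, generalizing the ad hoc masking such analyses
need when one small gene family dominates several sets.

## The synthetic world

`simulate_dataset()` generates the structure the method assumes, with
exported ground truth:

* latent purity $p \sim \mathcal{N}(0,1)$ per sample; module factors
  $f_j \sim \mathcal{N}(0,1)$;
* confounded genes $x = \pm\lambda p + \epsilon$ (random loading signs:
  purity raises immune/stromal programs and lowers tumor-intrinsic ones, so
  purity genes appear at both extremes of a confounded ranking); module
  genes $x = \lambda f_j + \epsilon$; independent causal and null genes
  $x = \epsilon$;
* phenotype $y = \beta \sum_{\mathrm{causal}} x_g + \gamma p + e$, then
  standardized; the exported CPE is $\Phi(p)$, a monotone map into $[0,1]$.

Defaults (frozen after a pilot calibration, not revisited): $m = 800$
samples, $n = 2000$ genes, 400 confounder-loaded null genes, one 200-gene
module, 5 independent + 5 module-embedded causal genes, $\lambda = 1$,
$\gamma = 1$, $\beta = 0.35$, unit noise. At these values the purity factor
is the leading eigenvector of $K$, OLS rejects essentially every
confounder-loaded null gene at $\alpha = 0.05$ while the full-K LMM stays
near nominal, and independent causal genes are recovered in the top 1% of
LMM p-values with power above 0.9.

What the generator deliberately does **not** emulate: count-level noise
(negative binomial marginals, library size), gene-gene correlation beyond
one factor per module, multiple overlapping confounders, and a purity
variable bounded in $[0,1]$ at the expression level. The method operates on
log-scale standardized values, for which Gaussian factors are the right
level of abstraction — but a green simulation test establishes correctness
of the machinery under the assumed structure, not performance on any
particular cohort.

`simulate_seg()` closes the loop for end-to-end tests: it emits SEG-format
segments whose summed length-weighted absolute values equal $\exp(y)$ per
sample, so the ICNA scorer recovers a phenotype monotone in the simulated
one from file input alone.

## Design choices where the design was genuinely open

* **"Power" for module-embedded causal genes.** At the calibrated defaults a
  causal gene inside the module has four causal siblings amplifying its
  marginal correlation, so both OLS and the LMM saturate rejection at any
  conventional $\alpha$ — there is no rejection-rate contrast to measure.
  The package's evaluation therefore reports detection as ranking in the
  scan's top 1% of p-values, and the module-vs-independent comparison is
  made on the statistic magnitude (the noncentrality that determines
  power): the LMM's statistics for module-embedded causal genes run at
  roughly a third of their OLS values, the quantitative face of the known
  limitation that pathway-embedded drivers are penalized by this correction.
* **Cohort-size trend.** In this synthetic world the purity eigenvalue of
  $K$ stands far above the random-matrix bulk even at $m = 100$, so the LMM
  corrects essentially completely at every cohort size and the
  spurious-association level is flat in $m$ (slightly conservative at large
  $m$), with a small non-monotone wiggle traceable to the edge-pinned ML fit
  at small $m$. An under-corrected small-cohort regime would require purity
  loadings weak enough to sink the purity eigenvalue into the bulk, which
  would simultaneously stop purity from being $K$'s leading factor. The
  package reports the trend experiment (`subsample_experiment()`) as
  measured rather than forcing a monotone outcome.
* **Bonferroni family** = genes actually tested after zero-variance
  removal; **BH q-values** are attached to every scan as standard practice
  even though per-gene scan correction is not part of the core method.
* **Joins are by sample id, never by position**; every pipeline run writes
  a join report and a manifest (package version, seed, config hash) from
  which the run is reproducible.

## Worked example

```{r example, eval = FALSE}
ds <- simulate_dataset(simulation_config(seed = 1))
K  <- compute_kinship(standardize_expression(ds$expr))

slr <- association_scan(ds$expr, ds$y, method = "slr")
lmm <- association_scan(ds$expr, ds$y, method = "lmm", K = K)

conf <- ds$truth$gene[ds$truth$class == "confounded"]
mean(slr$p_value[slr$gene %in% conf] < 0.05)   # ~1.00: all spurious
mean(lmm$p_value[lmm$gene %in% conf] < 0.05)   # ~0.04: controlled

evaluate_scan(lmm, ds$truth)$power_top          # causal gene recovery
```

## Known limitations

* Full ML (as specified) with a singular $K$ has the boundary pathology
  described above; heritability estimates at $m \lesssim 200$ frequently
  pin to the domain edge. Inference on $\beta_1$ is robust to this (the
  per-gene residual rescaling absorbs the scale), but the reported
  `heritability` field should not be over-interpreted at small $m$.
* The EMMAX approximation fits variance components once under the null;
  for genes with very large effects the per-gene refit flag gives the
  exact-ML answer at substantially higher cost.
* Pre-ranked enrichment uses gene-label permutations only; phenotype
  permutation, leading-edge analysis and plotting parity with the standard
  desktop tool are out of scope.
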