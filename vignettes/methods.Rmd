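---
title: "Methods: multi-trait meta-analysis for pleiotropy detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-trait meta-analysis for pleiotropy detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical procedure it
implements, the assumptions behind it, the knobs that matter, and the
design decisions taken where the method leaves room.

## The model

### Phenotype sets

Starting from a complete animal-by-trait panel, the discovery cohort's
traits are centred and scaled to z-scores. Three phenotype sets are
analysed in parallel:

* **RT**: the standardized raw traits themselves (correlated);
* **PC**: principal-component scores $u_n = T' g_n$, where $T$ are the
  eigenvectors of the correlation matrix of the standardized traits. PC
  scores are uncorrelated with variances equal to the eigenvalues, which
  sum to $k$ for a correlation matrix;
* **CT**: Cholesky-transformed traits $c_n = L^{-1} g_n$ with
  $L L' = \mathrm{COV}$. CTs are uncorrelated with unit variance, and the
  $j$-th CT is interpretable as the $j$-th trait corrected for the
  preceding $j-1$ traits; the first CT equals the first standardized
  trait.

All transform constants — means, SDs, $T$, $L$ — are estimated on the
discovery cohort only and applied verbatim to validation data
(`apply_transforms()` is a pure linear map). When a validation cohort
lacks some traits, `subset_refit()` refits the transforms on the shared
subset and the downstream stages rerun with the reduced $k$.

Assumptions: the panel is complete (no missing cells), the trait
covariance is positive definite (collinear traits are rejected with the
offending pair named), and the trait order used for the Cholesky factor
is meaningful to the analyst. CTs are order-dependent by construction;
the default is the input column order, and a biologically motivated
ordering can improve interpretability.

### Single-trait mixed-model scans

Each trait of each set is scanned with
$y = \mu + \text{breed} + b\,x + a + e$, $a \sim N(0, \sigma^2_g G)$,
where $G$ is the VanRaden method-1 genomic relationship matrix
($Z Z' / \sum_j 2 p_j (1-p_j)$ over all post-QC SNPs). SNP QC removes
markers with minor allele frequency below 0.01 or a pooled-sample
Hardy-Weinberg goodness-of-fit p-value below 0.001 (MAF first, so the
removal reasons are disjoint). HWE is tested pooled across breeds by
default; a within-breed mode exists because strongly differentiated
breeds can fail pooled HWE through the Wahlund effect alone, and the
chosen mode is recorded in the `QcReport`.

Variance components are estimated once per trait by REML on the
GRM-eigenrotated data (the restricted likelihood is profiled over the
heritability in one dimension; one eigendecomposition is shared by all
75 scans) and then held fixed for every SNP — the EMMAX approximation.
Per SNP the generalized-least-squares effect, standard error, signed
t-value and two-sided Wald-normal p-value are reported. The
approximation's standard caveat applies: for SNPs of very large effect
the fixed variance components are slightly misspecified, which is
immaterial for ranking and selection here.

### Multi-trait meta-analysis

Per SNP, the $k$ signed t-values are combined into
$\chi^2 = t' V^{-1} t$ with $k$ degrees of freedom, where $V$ is the
correlation matrix of t-values estimated over all scanned SNPs. $V$
captures both phenotypic correlation between traits and the shared-sample
correlation of estimation errors. Because strong polygenic signal can
inflate $V$, `estimate_v()` optionally restricts estimation to SNPs with
$|t| \le 2$ on every trait; the default uses all SNPs. Whether SNPs
should be LD-pruned before estimating $V$ is left open upstream; both
modes are available by subsetting the input.

The quadratic form is computed by linear solves, never an explicit
inverse; if the smallest eigenvalue of $V$ falls below $10^{-6}$, $V$ is
shrunk toward the identity exactly far enough to reach the floor and the
shrinkage weight is recorded.

False discovery rates use Storey's estimator: $\hat\pi_0(\lambda)$ on the
grid $0.05, 0.10, \dots, 0.95$, smoothed by a cubic spline (df = 3) and
evaluated at $\lambda = 0.95$; q-values follow the usual step-up
construction. Below 100 p-values the $\pi_0$ estimate is too unstable, so
the function warns and uses $\pi_0 = 1$ (the Benjamini-Hochberg limit).

As an additional pleiotropy check, `odd_even_split()` repeats the
meta-analysis separately on odd- and even-numbered PCs: a genuinely
pleiotropic locus spreads signal over many orthogonal components and
should stay significant in both halves.

### Lead selection, conditional and joint analysis

A SNP is a lead candidate when its meta-analysis p-value is below
$10^{-5}$ in **all three** sets (config flag for any-set mode). Within a
chromosome, candidates are taken greedily, most significant first (ranked
by the worst p-value across sets; ties go to the smaller coordinate),
each pick excluding a 1-Mb window. The current leads are then fitted as
fixed covariates in every single-trait scan, the meta-analysis is rerun
on the conditional t-values, and still-significant SNPs are added (again
one per 1-Mb interval) until a fixed point. New leads in a conditional
round are windowed against each other but not against existing leads:
recovering a second QTL inside an already-claimed window is precisely
what conditioning is for, and the old leads cannot re-enter because their
conditional signal is zero by construction. A newly proposed lead whose
dosage has $r^2 > 0.99$ with an earlier lead is dropped with a warning.

Finally all leads are fitted jointly per trait (GLS under the same fixed
variance components, breed covariates included) and a lead is pruned when
its joint p-value is $\ge 0.05$ for every trait in every set. With 75
trait-set combinations this unadjusted rule is deliberately weak — a
truly null lead survives it most of the time by chance — so
`joint_model_prune(p_adjust = "bonferroni")` (or any `p.adjust` method)
is available when a sharp filter is wanted; the default stays unadjusted
to match the conventional joint-P rule.

### Overlap tests

Trait-pair sharing of single-trait-significant SNPs ($p_s < 0.05$),
per-chromosome enrichment of a focal trait's shared SNPs, and
cross-cohort overlap of meta-analysis-significant SNP sets are all tested
with one-sided (enrichment) Fisher exact tests over the universe of
scanned SNPs. Exported matrices follow the rounded-log2 shared-count
convention, with zero shared mapped to a `-Inf` sentinel.

### Index validation

For each lead SNP, the phenotype set with the smallest discovery
meta-analysis p-value is chosen (the method's "most significant effect"
selector — the construction lists all three forms without naming the
selector, so the package makes this choice explicit). The index weights
are $C^{-1} b$, where $b$ is the SNP's discovery beta vector and $C$ the
covariance of betas over all scanned SNPs of that set (betas, not
t-values). Each validation animal's index value $w'y$ is regressed on the
lead dosage with breed covariates. The discovery-side index effect
$b' C^{-1} b$ is positive whenever $b \ne 0$, so a positive validation
slope on the same allele coding means direction agreement. The validation
regression is plain fixed-effects least squares by default — validation
animals have individual records, the response is a single derived index,
and no GRM is fitted; a mixed-model variant is available via the
`use_grm` argument. Validation is read-once: no validation quantity feeds
back into discovery selection.

### Effect clustering

Lead-by-trait matrices of signed t-values are masked to entries whose
effect direction is concordant between discovery and validation, then
correlated pairwise over mutually unmasked traits (pairs with fewer than
3 shared entries are undefined and imputed as distance 1 with a warning).
Hierarchical clustering uses distance $1 - r$ with average linkage (the
method names no linkage; average is the conventional choice for
correlation distances and is configurable). Heatmap display additionally
masks $|t| < 1$. Whether non-validated entries should enter the
correlations at all is ambiguous in the source description; masking is
the default, unmasked is available (`use_mask = FALSE`).

## The synthetic-data generator

The generator emulates the study design this method was built for:

* **Genotypes**: biallelic SNPs on 5 synthetic chromosomes of 100 Mb
  (a 29-autosome genome compressed to desk scale), base allele
  frequencies uniform on the configured range, per-breed frequencies
  diverged by a Balding-Nichols model (default $F_{st} = 0.05$, a typical
  between-breed differentiation for cattle). Haplotypes follow a Gaussian
  copula: a latent AR(1) process thresholded at the breed frequency
  quantile, giving adjacent-SNP LD that decays geometrically with
  distance (default tuned so $r^2 \approx 0.3$ at 50 kb, a realistic
  mid-range value for high-density bovine panels) while preserving
  marginal frequencies exactly — hence Hardy-Weinberg holds within breed
  by construction.
* **Cohorts**: a discovery cohort of 1,000 and a validation cohort of
  2,000 animals by default; a configurable fraction (default 10%) of
  validation haplotypes is copied from discovery haplotypes, giving the
  weak cross-cohort relatedness of a bulls-discovery / cows-validation
  design.
* **Phenotypes**: trait value = breed shift + planted QTL effects +
  polygenic value + residual. The polygenic value is a sum of small
  random effects over all non-QTL SNPs with per-SNP effect covariance
  $\Sigma_g / m$, so relatedness and genetic covariance arise from the
  same genotypes the scan uses. Discovery animals get the individual
  residual divided by an effective daughter count (default 40, exposed as
  a parameter because real daughter counts vary and only a lower bound of
  15 is typical), mimicking low-error progeny-mean phenotypes and the
  resulting high bull heritabilities; validation animals get the full
  residual. Default covariances are AR(1)-banded (genetic variance 0.3,
  residual 0.7 per trait) — a simple stand-in for banded trait-panel
  correlations.
* **Planted QTL**: eight loci with multi-trait effect norms of 0.4-0.8 SD
  in two recognizable patterns ("fat up, milk/protein down" and
  "protein up, milk down") plus one broad-effect locus, pinned to exact
  positions with known frequencies and emitted as a truth table.

What it does **not** emulate: realistic cattle LD maps and haplotype
blocks, imputation error, missing phenotypes, the X chromosome,
selection-induced allele-frequency trajectories, or genotype-environment
interaction. Passing tests therefore demonstrate that the pipeline's
inference machinery is correct and calibrated under its stated model, not
that it is robust to every artefact of real livestock data.

## Numerical choices

* Eigenvector signs are fixed by forcing each component's
  largest-magnitude loading positive (signs are otherwise arbitrary);
  repeated eigenvalues are flagged and resolved by trait-order-stable
  sorting.
* REML is profiled over heritability on $[10^{-6}, 1-10^{-6}]$ with
  Brent's method (tolerance $10^{-8}$); the heritability standard error
  comes from the profile curvature at the optimum.
* A SNP whose dosage is (numerically) in the span of the fixed covariates
  — e.g. a lead conditioned on itself — has $x'Px$ below
  $10^{-8}\,\mathrm{median}(x'Wx)$ and is reported as zero effect,
  infinite SE, p = 1.
* $V$ and index covariance matrices are ridge-regularized only when
  numerically needed, by the exact amount needed, and the shrinkage is
  recorded.
* Multi-trait $\chi^2$ p-values are floored at the smallest positive
  double to stay in $(0, 1]$.

## Problem sizes used by the test suite

Unit tests run on studies of 300-800 animals and 1,500-2,500 SNPs;
parameter-recovery checks (heritability, planted effects) use 2,000
animals. The acceptance layer runs 20 full desk-scale studies
(1,000 discovery / 2,000 validation animals, 20,000 SNPs, 25 traits,
8 planted QTL; one study per seed) for the lead-recovery, conditional
soundness and validation-rate checks, and 20,000-SNP synthetic t-value
panels for null calibration. These sizes keep a complete run on a single
CPU in the tens of minutes while leaving every planted QTL comfortably
detectable.

## Known limitations

* The EMMAX approximation and Wald-normal p-values are asymptotic; exact
  per-SNP REML is not implemented (the variance components are fixed at
  the null fit for every SNP, including very large-effect ones).
* Dominance, epistasis, X-dosage and imputation uncertainty are out of
  scope.
* The unadjusted joint-P pruning rule is a weak filter by design; use
  `p_adjust` for a sharp one.
* CT results depend on trait order; the package does not attempt to
  choose a biologically optimal order.
* The second ("beef-like") cohort in the overlap tests is always
  simulated or supplied as summary statistics; no real external cohort is
  bundled.
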