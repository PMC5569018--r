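# pleioscan

Detection and validation of pleiotropic variants by multi-trait GWAS
meta-analysis over correlated **and** orthogonalized phenotypes.

## The problem

A variant with a large effect on one quantitative trait often has smaller
effects on many others. Testing traits one at a time misses this, and
testing correlated traits jointly cannot distinguish genuine pleiotropy
from correlation-induced "cross-phenotype" signal. `pleioscan` implements
the comparative strategy used in large dairy-cattle studies: run the same
multi-trait analysis on three versions of a k-trait panel —

* **RT** — the centred, z-scored raw traits;
* **PC** — principal-component scores `u = T'g`, where `T` holds the
  eigenvectors of the trait correlation matrix, so `Var(u) = D` is
  diagonal;
* **CT** — Cholesky-transformed traits `c = L⁻¹g` with `LL' = COV`, so the
  j-th CT is the j-th trait corrected for the preceding j−1 traits and
  `Var(c) = I`

— and call a locus pleiotropic only when it is significant in all three.
Because PCs and CTs are uncorrelated by construction, a SNP that stays
significant across them affects genuinely independent combinations of
traits.

The per-trait scans are linear mixed models

`y = mean + breed + b·x + a + e`, with `a ~ N(0, σ²_g G)`

where `G` is the genomic relationship matrix (VanRaden centred
cross-product) and variance components are fixed at their null-model REML
estimates (EMMAX-style). Per SNP the signed t-values across the k traits
are combined into the multi-trait statistic

`χ² = t' V⁻¹ t`,  df = k,

where `V` is the k×k correlation matrix of t-values over all scanned SNPs.
False discovery rates use Storey's π₀ estimator. Lead SNPs are picked
greedily per 1-Mb interval (significant in all three sets at
p_m < 1e-5), refined by iterative conditional re-scans and a joint
multi-SNP model, and validated in an independent cohort through
SNP-specific linear trait indices `w = C⁻¹b` (with `C` the covariance of
discovery betas), whose validation slope must agree in direction with
discovery. Effect profiles of the final leads are hierarchically
clustered to expose groups of loci with shared trait patterns.

Because real bull/cow datasets of this kind are proprietary, the package
ships a first-class synthetic-data generator (multi-breed genotypes with
linkage disequilibrium, progeny-mean discovery phenotypes, weakly related
validation cohort, planted pleiotropic QTL with known effect vectors) so
the whole pipeline can be exercised against ground truth.

## Worked example

```r
library(pleioscan)

cfg <- sim_config(n_discovery = 500, n_validation = 600, n_snps = 4000, seed = 3)
run <- run_pipeline(cfg)
run
#> <pleioscan_run> seed 3: 3922 SNPs post-QC, 8 active lead(s), 1 conditional round(s)

run$leads[, c("snp", "chrom", "pos_bp", "score", "status")]
#> # A tibble: 8 x 5
#>   snp       chrom   pos_bp    score status
#> 1 snp_00207     1 25000000 9.59e-32 active
#> 2 snp_03806     5 75000000 8.25e-31 active
#> 3 snp_02786     4 50000000 2.62e-21 active
#> # ...

rep <- pipeline_report(run)
rep$venn
#> region       n        # SNPs significant (p_m < 1e-5) per set and overlap
#> RT           8
#> PC           8
#> CT           8
#> RT&PC&CT     8

rep$validation_summary
#> # A tibble: 3 x 6
#>   set   n_snps n_consistent_direction pct_consistent n_significant pct_significant
#> 1 CT         2                      2            100             2             100
#> 2 PC         5                      5            100             5             100
#> 3 RT         1                      1            100             1             100
```

All 8 planted QTL are recovered as lead SNPs (the `score` column is the
worst meta-analysis p-value across the RT/PC/CT sets), the three
phenotype sets agree perfectly on the significant SNPs, and every lead
validates in the independent cohort with the same effect direction
(`set` is the phenotype set in which each lead was most significant and
hence used for its linear index). `tidy(run$transforms)` gives the
eigenvalue / variance-share table of the fitted components, and
`autoplot(run$meta$RT)` draws the Manhattan plot.

Every stage is also available as a standalone function operating on data
frames — `fit_transforms()`, `qc_filter()`, `compute_grm()`,
`gwas_scan()`, `multitrait_chi2()`, `select_interval_leads()`,
`conditional_rescan()`, `joint_model_prune()`, `pairwise_shared_snps()`,
`build_index()`, `validate_snp()`, `effect_correlation()` — so external
genotype/phenotype tables can be fed through any subset of the pipeline.

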