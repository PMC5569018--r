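Package: pleioscan
Title: Multi-Trait GWAS Meta-Analysis for Detecting Pleiotropic Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects pleiotropic variants across correlated and orthogonalized
    phenotypes. Implements phenotype orthogonalization by principal components
    and Cholesky transformation, single-trait linear mixed-model association
    scans with a genomic relationship matrix, multi-trait chi-square
    meta-analysis of signed t-values with Storey false discovery rate control,
    lead-SNP selection by conditional-and-joint analysis, Fisher overlap tests
    between traits and cohorts, hierarchical clustering of lead-SNP effect
    profiles, and independent-cohort validation through SNP-specific linear
    trait indices. Ships a synthetic-data generator that plants pleiotropic
    QTL in a multi-breed cattle-like population so every stage can be tested
    against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
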