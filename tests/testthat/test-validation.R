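test_that("index weights solve C w = b and match a dense inverse", {
  set.seed(30)
  k <- 5
  B <- matrix(rnorm(400 * k), 400, k)
  st <- make_stats(B)
  st$beta <- B
  idx <- build_index(list(RT = st), st$snp_map$snp[7], set_choice = "RT")
  C <- cov(B)
  expect_equal(idx$weights, as.vector(solve(C) %*% B[7, ]), tolerance = 1e-10)
  # discovery-side index effect is positive unless b = 0
  expect_gt(sum(idx$b * idx$weights), 0)
})

test_that("degenerate indices are rejected or reduce to a single trait", {
  set.seed(31)
  B <- matrix(rnorm(300 * 4), 300, 4)
  st <- make_stats(B)
  st$beta <- B
  zero <- st
  zero$beta[5, ] <- 0
  expect_error(build_index(list(RT = zero), zero$snp_map$snp[5], "RT"),
               "zero effect")
  # with diagonal C the weights are proportional to b: one nonzero beta
  # means the index is that single trait up to scale
  B2 <- matrix(rnorm(5000 * 4), 5000, 4) %*% diag(c(1, 2, 1, 3))
  diagC <- make_stats(B2)
  diagC$beta <- B2
  diagC$beta[9, ] <- c(0, 2, 0, 0)
  idx <- build_index(list(RT = diagC), diagC$snp_map$snp[9], "RT")
  w <- idx$weights / max(abs(idx$weights))
  expect_gt(abs(w[2]), 20 * max(abs(w[-2])))
})

test_that("the set with the smallest discovery p_m is chosen by default", {
  meta <- small_meta()
  stats <- small_stats()
  lead <- select_interval_leads(meta)$snp[1]
  pm <- vapply(meta, function(m) m$p_m[match(lead, m$snp)], numeric(1))
  idx <- build_index(stats, lead, meta_list = meta)
  expect_equal(idx$set, names(which.min(pm)))
})

test_that("a strong planted QTL validates with agreeing direction", {
  st <- small_study()
  meta <- small_meta()
  stats <- small_stats()
  leads <- select_interval_leads(meta)
  val_geno <- subset_genotypes(cohort_genotypes(st$geno, "validation"),
                               snps = st$qc$genotypes$snp_map$snp)
  panels_val <- apply_transforms(st$phen$validation, st$transforms)
  res <- dplyr::bind_rows(lapply(leads$snp[1:3], function(sn) {
    validate_snp(build_index(stats, sn, meta_list = meta), panels_val, val_geno)
  }))
  expect_true(all(res$direction_agrees))
  expect_true(all(res$p_v < 0.05))
})

test_that("validation with the QTL effect removed is null", {
  cfg <- small_config()
  cfg_null <- sim_config(
    n_discovery = 400, n_validation = 400, n_snps = 2500, seed = 42,
    qtl_specs = list()
  )
  # discovery side keeps its QTL; the validation phenotypes come from the
  # no-QTL generator, so the index has nothing to find
  st <- small_study()
  geno0 <- simulate_genotypes(cfg_null)
  phen0 <- simulate_phenotypes(geno0, cfg_null)
  panels0 <- apply_transforms(phen0$validation, st$transforms)
  val_geno0 <- subset_genotypes(cohort_genotypes(geno0, "validation"),
                                snps = st$qc$genotypes$snp_map$snp)
  meta <- small_meta(); stats <- small_stats()
  leads <- select_interval_leads(meta)
  res <- dplyr::bind_rows(lapply(leads$snp, function(sn) {
    validate_snp(build_index(stats, sn, meta_list = meta), panels0, val_geno0)
  }))
  expect_gt(min(res$p_v), 0.001)
  expect_lt(mean(res$direction_agrees), 1)
})

test_that("an in-sample index outperforms the best single trait for a pleiotropic SNP", {
  st <- small_study()
  meta <- small_meta(); stats <- small_stats()
  lead <- select_interval_leads(meta)$snp[1]
  idx <- build_index(stats, lead, meta_list = meta)
  disc_geno <- st$qc$genotypes
  res <- validate_snp(idx, st$panels, disc_geno)
  best_single <- min(stats[[idx$set]]$pval[lead, ])
  expect_lt(res$p_v, best_single)
})

test_that("direction concordance is 1 on identical cohorts and 0.5 on null ones", {
  stats <- small_stats()$RT
  leads <- select_interval_leads(small_meta())$snp[1:3]
  same <- direction_concordance(stats, stats, leads)
  nonzero <- same$by_trait$sign_discovery != 0
  expect_true(all(same$by_trait$concordant[nonzero]))

  set.seed(33)
  a <- make_stats(matrix(rnorm(500 * 10), 500, 10))
  b <- make_stats(matrix(rnorm(500 * 10), 500, 10))
  nul <- direction_concordance(a, b, a$snp_map$snp[1:200])
  expect_lt(abs(mean(nul$by_trait$concordant) - 0.5), 0.05)

  # mismatched trait panels: shared traits used, others skipped with warning
  b2 <- pleioscan:::subset_stats_traits(b, 1:8)
  expect_warning(direction_concordance(a, b2, a$snp_map$snp[1:5]), "skipped")
})
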