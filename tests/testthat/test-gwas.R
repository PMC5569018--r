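test_that("QC removes low-MAF and out-of-HWE SNPs for the stated reasons", {
  set.seed(1)
  # counts (AA, Aa, aa) per SNP: below-MAF; exact HWE; all-heterozygote
  d_maf <- c(rep(0L, 9990), rep(1L, 10), rep(0L, 0))
  d_hwe <- c(rep(0L, 25), rep(1L, 50), rep(2L, 25))
  d_het <- rep(1L, 100)
  g1 <- make_geno(cbind(A = d_maf[1:100], B = d_hwe, C = d_het))
  qc <- qc_filter(g1)
  expect_false("snp_00003" %in% qc$report$kept_snp_ids)  # all-het: chi2 = 100
  expect_true("snp_00002" %in% qc$report$kept_snp_ids)   # chi2 = 0
  g2 <- make_geno(matrix(d_maf, ncol = 1))
  expect_error(qc_filter(g2), "no SNPs left")
  # the 0.0005-MAF SNP is removed by the MAF rule, not HWE
  g3 <- make_geno(cbind(matrix(d_maf, ncol = 1), ok = rbinom(10000, 2, 0.4)))
  r3 <- qc_filter(g3)$report
  expect_equal(r3$n_removed_maf, 1)
  expect_equal(r3$n_removed_hwe, 0)
  expect_equal(r3$n_input_snps,
               r3$n_removed_maf + r3$n_removed_hwe + length(r3$kept_snp_ids))
})

test_that("GRM equals the hand-computed cross-product on a toy", {
  set.seed(1)
  D <- matrix(rbinom(50, 2, 0.4), 5, 10)
  g <- make_geno(D)
  grm <- compute_grm(g)
  p <- colMeans(D) / 2
  Z <- sweep(D, 2, 2 * p)
  G_manual <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) G_manual[i, j] <- sum(Z[i, ] * Z[j, ])
  G_manual <- G_manual / sum(2 * p * (1 - p))
  expect_equal(unname(grm$matrix), G_manual, tolerance = 1e-12)
})

test_that("identical animals share their GRM diagonal; unrelated ones centre at zero", {
  set.seed(2)
  n <- 200
  D <- matrix(rbinom(n * 800, 2, runif(800, 0.1, 0.5)), n, 800, byrow = TRUE)
  D[2, ] <- D[1, ]
  grm <- compute_grm(make_geno(D))$matrix
  expect_equal(grm[1, 2], grm[1, 1], tolerance = 1e-12)
  off <- grm[upper.tri(grm)][-1]
  expect_lt(abs(mean(off)), 0.01)
  expect_error(compute_grm(make_geno(cbind(D, mono = rep(0L, n)))),
               "monomorphic")
})

test_that("scan t-values equal brute-force GLS with a dense inverse", {
  set.seed(7)
  n <- 50; m <- 5
  D <- matrix(rbinom(n * 60, 2, 0.3), n, 60)
  D <- D[, apply(D, 2, var) > 0][, 1:20]
  g <- make_geno(D, breed = rep(c("BreedA", "BreedB"), length.out = n))
  grm <- compute_grm(g)
  y <- rnorm(n) + 0.4 * D[, 3]
  fit <- fit_null_model(y, g$animals$breed, grm, "y")
  panel <- dplyr::bind_cols(g$animals, tibble::tibble(y = y))
  st <- gwas_scan(panel, g, grm, list(y = fit), set = "RT")

  V <- fit$sigma_g2 * grm$matrix + fit$sigma_e2 * diag(n)
  Vi <- solve(V)
  Xb <- cbind(1, as.numeric(g$animals$breed == "BreedB"))
  for (j in c(1, 3, 17)) {
    X <- cbind(Xb, D[, j])
    XtVX <- t(X) %*% Vi %*% X
    b <- solve(XtVX, t(X) %*% Vi %*% y)
    se <- sqrt(diag(solve(XtVX)))
    expect_equal(unname(st$beta[j, 1]), b[3], tolerance = 1e-8)
    expect_equal(unname(st$tval[j, 1]), b[3] / se[3], tolerance = 1e-8)
  }
  expect_equal(st$tval, st$beta / st$se, tolerance = 1e-12)
})

test_that("with zero genetic variance the scan degenerates to OLS", {
  set.seed(8)
  n <- 50
  D <- matrix(rbinom(n * 30, 2, 0.35), n, 30)
  D <- D[, apply(D, 2, var) > 0]
  breed <- rep(c("BreedA", "BreedB"), length.out = n)
  g <- make_geno(D, breed = breed)
  grm <- compute_grm(g)
  y <- rnorm(n)
  fit0 <- lm(y ~ breed)
  null0 <- list(y = list(trait_name = "y", sigma_g2 = 0,
                         sigma_e2 = sum(fit0$residuals^2) / fit0$df.residual,
                         h2 = 0, h2_se = NA))
  panel <- dplyr::bind_cols(g$animals, tibble::tibble(y = y))
  st <- gwas_scan(panel, g, grm, null0, set = "RT")
  for (j in c(2, 9)) {
    ols <- lm(y ~ D[, j] + breed)
    expect_equal(unname(st$beta[j, 1]), unname(coef(ols)[2]), tolerance = 1e-8)
  }
})

test_that("null-trait p-values are uniform and the scan ignores animal order", {
  st <- small_study()
  set.seed(99)
  n <- nrow(st$qc$genotypes$dosages)
  ynull <- rnorm(n)
  panel <- dplyr::bind_cols(st$qc$genotypes$animals, tibble::tibble(y = ynull))
  grm <- small_grm()
  fit <- fit_null_model(ynull, panel$breed, grm, "y")
  sc <- gwas_scan(panel, st$qc$genotypes, grm, list(y = fit), set = "RT")
  ks <- suppressWarnings(ks.test(sc$pval[, 1], "punif"))
  expect_gt(ks$p.value, 0.01)

  perm <- sample(n)
  g_perm <- subset_genotypes(st$qc$genotypes, animals = perm)
  grm_perm <- compute_grm(g_perm)
  fit_p <- fit_null_model(ynull[perm], g_perm$animals$breed, grm_perm, "y")
  sc_p <- gwas_scan(panel[perm, ], g_perm, grm_perm, list(y = fit_p), set = "RT")
  expect_equal(sc_p$tval[, 1], sc$tval[, 1], tolerance = 1e-6)
})

test_that("permuting phenotypes against genotypes destroys heritability", {
  st <- small_study()
  grm <- small_grm()
  y <- st$panels$RT$T01
  fit <- fit_null_model(y, st$panels$RT$breed, grm, "T01")
  expect_gt(fit$h2, 0.5)
  set.seed(11)
  fit_perm <- fit_null_model(sample(y), st$panels$RT$breed, grm, "T01")
  expect_lt(fit_perm$h2, 0.15)
})

test_that("a planted pleiotropic QTL reaches genome-wide significance", {
  stats <- small_stats()$RT
  truth <- small_study()$geno$truth
  q1 <- truth$snp[1]
  expect_lt(min(stats$pval[q1, ]), 1e-6)
})

test_that("summary statistics round-trip through TSV", {
  stats <- small_stats()$RT
  sub <- pleioscan:::subset_stats_traits(stats, 1:3)
  sub$beta <- sub$beta[1:50, ]; sub$se <- sub$se[1:50, ]
  sub$tval <- sub$tval[1:50, ]; sub$pval <- sub$pval[1:50, ]
  sub$snp_map <- sub$snp_map[1:50, ]
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(sub, path)
  back <- read_summary_stats(path)
  expect_equal(back$beta, sub$beta, tolerance = 1e-12)
  expect_equal(back$tval, sub$tval, tolerance = 1e-12)
  expect_equal(back$traits, sub$traits)
})
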