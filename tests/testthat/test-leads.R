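fake_meta <- function(p, chrom, pos) {
  tibble::tibble(snp = sprintf("snp_%05d", seq_along(p)), chrom = chrom,
                 pos_bp = pos, chi2 = 1, df = 3, p_m = p, q = p, set = "X")
}

test_that("greedy interval selection respects the window and tie rules", {
  p <- c(1e-9, 1e-7, 0.5, 1e-12)
  chrom <- c(1L, 1L, 1L, 2L)
  pos <- c(10e6, 10.5e6, 30e6, 5e6)
  ml <- list(RT = fake_meta(p, chrom, pos), PC = fake_meta(p, chrom, pos),
             CT = fake_meta(p, chrom, pos))
  leads <- select_interval_leads(ml)
  # the 0.5-Mb neighbour of the stronger SNP is excluded; chr2 SNP kept
  expect_setequal(leads$snp, c("snp_00001", "snp_00004"))

  one <- lapply(ml, function(m) {m$p_m <- c(1, 1e-8, 1, 1); m})
  l1 <- select_interval_leads(one)
  expect_equal(l1$snp, "snp_00002")

  none <- lapply(ml, function(m) {m$p_m <- rep(0.5, 4); m})
  expect_equal(nrow(select_interval_leads(none)), 0)

  # significant in two of three sets only: not selected in "all" mode
  two <- ml
  two$CT$p_m <- rep(0.9, 4)
  expect_equal(nrow(select_interval_leads(two)), 0)
  expect_gt(nrow(select_interval_leads(two, mode = "any")), 0)

  # exact tie: the smaller coordinate wins
  tie <- lapply(ml, function(m) {m$p_m <- c(1e-8, 1e-8, 1, 1); m})
  lt <- select_interval_leads(tie)
  expect_equal(lt$snp, "snp_00001")
})

test_that("well-separated planted QTL are all selected in round one", {
  leads <- select_interval_leads(small_meta())
  truth <- small_study()$geno$truth
  expect_true(all(lead_is_true(leads, truth)))
  expect_gte(nrow(leads), 6)
  d <- dist_check <- TRUE
  for (ch in unique(leads$chrom)) {
    pp <- sort(leads$pos_bp[leads$chrom == ch])
    if (length(pp) > 1) dist_check <- dist_check && all(diff(pp) >= 1e6)
  }
  expect_true(dist_check)
})

test_that("conditioning on a single QTL removes its signal (fixed point)", {
  cfg <- sim_config(
    n_discovery = 500, n_validation = 0, n_snps = 1500,
    qtl_specs = list(qtl_spec(2, 5e7, c(0.6, -0.5, 0.4, rep(0, 22)), 0.3)),
    seed = 51
  )
  geno <- simulate_genotypes(cfg)
  phen <- simulate_phenotypes(geno, cfg)
  qc <- qc_filter(cohort_genotypes(geno, "discovery"))
  ts <- fit_transforms(phen$discovery)
  panels <- apply_transforms(phen$discovery, ts)
  grm <- compute_grm(qc$genotypes)
  sets <- c("RT", "PC", "CT")
  nf <- lapply(setNames(sets, sets), function(s) fit_null_models(panels[[s]], grm))
  ctx <- scan_context(qc$genotypes, grm)
  stats <- lapply(setNames(sets, sets), function(s) {
    gwas_scan(panels[[s]], qc$genotypes, grm, nf[[s]], set = s, context = ctx)
  })
  meta <- lapply(stats, multitrait_chi2)
  leads <- select_interval_leads(meta)
  expect_equal(nrow(leads), 1)
  expect_equal(leads$snp, geno$truth$snp[1])
  cond <- conditional_rescan(leads, qc$genotypes, panels, grm, nf, context = ctx)
  expect_equal(cond$n_rounds, 1)
  expect_equal(nrow(cond$leads), 1)
  # conditional soundness: nothing else remains significant in all sets
  pm <- vapply(cond$conditional_meta, function(m) m$p_m, numeric(nrow(meta$RT)))
  remaining <- rowSums(pm < 1e-5) == 3
  expect_equal(sum(remaining), 0)
})

test_that("a second QTL inside the window is recovered by a conditional round", {
  cfg <- sim_config(
    n_discovery = 800, n_validation = 0, n_snps = 2000,
    qtl_specs = list(
      qtl_spec(2, 5.00e7, c(0.6, -0.5, 0.4, rep(0, 22)), 0.3),
      qtl_spec(2, 5.04e7, c(0, 0, 0, 0.7, -0.6, 0.5, rep(0, 19)), 0.35)
    ),
    seed = 52
  )
  geno <- simulate_genotypes(cfg)
  phen <- simulate_phenotypes(geno, cfg)
  qc <- qc_filter(cohort_genotypes(geno, "discovery"))
  panels <- apply_transforms(phen$discovery, fit_transforms(phen$discovery))
  grm <- compute_grm(qc$genotypes)
  sets <- c("RT", "PC", "CT")
  nf <- lapply(setNames(sets, sets), function(s) fit_null_models(panels[[s]], grm))
  ctx <- scan_context(qc$genotypes, grm)
  meta <- lapply(setNames(sets, sets), function(s) {
    multitrait_chi2(gwas_scan(panels[[s]], qc$genotypes, grm, nf[[s]],
                              set = s, context = ctx))
  })
  leads <- select_interval_leads(meta)
  expect_equal(nrow(leads), 1)  # both QTL share one 1-Mb interval
  cond <- conditional_rescan(leads, qc$genotypes, panels, grm, nf, context = ctx)
  expect_gte(nrow(cond$leads), 2)
  # both planted positions represented (the exact QTL SNP can be lost to
  # QC by chance, in which case an LD neighbour stands in)
  for (i in 1:2) {
    expect_true(any(cond$leads$chrom == geno$truth$chrom[i] &
                      abs(cond$leads$pos_bp - geno$truth$pos_bp[i]) <= 5e5))
  }
  expect_equal(cond$leads$round_added[2], 2L)
})

test_that("joint pruning drops an injected null lead and keeps true ones", {
  st <- small_study()
  grm <- small_grm()
  nf <- small_null_fits()
  meta <- small_meta()
  leads <- select_interval_leads(meta)
  # inject a null SNP far from every QTL as a fake lead
  truth <- st$geno$truth
  sm <- st$qc$genotypes$snp_map
  far <- sm[sm$chrom == 2 & abs(sm$pos_bp - 8e7) < 2e5, ]
  fake <- leads[1, ]
  fake$snp <- far$snp[1]; fake$chrom <- far$chrom[1]; fake$pos_bp <- far$pos_bp[1]
  withlead <- dplyr::bind_rows(leads, fake)
  # unadjusted: with 75 trait-set tests a null lead usually survives by
  # chance, so true leads must at least stay active
  raw <- joint_model_prune(withlead, st$qc$genotypes, st$panels, grm, nf)
  expect_true(all(raw$leads$status[raw$leads$snp %in% leads$snp] == "active"))
  # bonferroni-adjusted: the null lead is pruned, the true QTL survive
  pruned <- joint_model_prune(withlead, st$qc$genotypes, st$panels, grm, nf,
                              p_adjust = "bonferroni")
  expect_equal(pruned$leads$status[pruned$leads$snp == fake$snp], "pruned")
  expect_true(all(pruned$leads$status[pruned$leads$snp %in% leads$snp] == "active"))

  # joint effect of a true lead covers the planted effect
  q1 <- truth[truth$snp %in% leads$snp, ][1, ]
  je <- pruned$joint_effects
  eff <- q1$effect_vector[[1]]
  tr <- sprintf("T%02d", which.max(abs(eff)))
  row <- je[je$snp == q1$snp & je$set == "RT" & je$trait == tr, ]
  # panels are z-scored, planted effects are on the raw trait scale
  sd_tr <- sd(st$phen$discovery[[tr]])
  expect_lt(abs(row$beta - eff[which.max(abs(eff))] / sd_tr), 1.96 * row$se + 0.05)

  # idempotence
  again <- joint_model_prune(pruned$leads, st$qc$genotypes, st$panels, grm, nf,
                             p_adjust = "bonferroni")
  expect_equal(again$leads$status, pruned$leads$status)
})

test_that("conditioning a lead on itself is caught as degenerate", {
  st <- small_study()
  grm <- small_grm()
  leads <- select_interval_leads(small_meta())
  cond_stats <- gwas_scan(st$panels$RT, st$qc$genotypes, grm,
                          small_null_fits()$RT, set = "RT",
                          lead_snps = leads$snp[1])
  expect_equal(unname(cond_stats$beta[leads$snp[1], ]),
               rep(0, length(cond_stats$traits)))
  expect_equal(unname(cond_stats$pval[leads$snp[1], ]),
               rep(1, length(cond_stats$traits)))
})
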