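# shared fixtures, memoised so expensive simulations run once per session
.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

# a small but complete simulated study: 400 discovery / 400 validation
# animals, 2,500 SNPs, the default 8 planted QTL
small_config <- function(seed = 42) {
  sim_config(n_discovery = 400, n_validation = 400, n_snps = 2500, seed = seed)
}

small_study <- function() {
  memo("small_study", {
    cfg <- small_config()
    geno <- simulate_genotypes(cfg)
    phen <- simulate_phenotypes(geno, cfg)
    qc <- qc_filter(cohort_genotypes(geno, "discovery"))
    ts <- fit_transforms(phen$discovery)
    list(config = cfg, geno = geno, phen = phen, qc = qc, transforms = ts,
         panels = apply_transforms(phen$discovery, ts))
  })
}

small_grm <- function() {
  memo("small_grm", compute_grm(small_study()$qc$genotypes))
}

small_null_fits <- function() {
  memo("small_null_fits", {
    st <- small_study()
    sets <- c("RT", "PC", "CT")
    lapply(setNames(sets, sets), function(s) fit_null_models(st$panels[[s]], small_grm()))
  })
}

small_stats <- function() {
  memo("small_stats", {
    st <- small_study()
    ctx <- scan_context(st$qc$genotypes, small_grm())
    sets <- c("RT", "PC", "CT")
    lapply(setNames(sets, sets), function(s) {
      gwas_scan(st$panels[[s]], st$qc$genotypes, small_grm(),
                small_null_fits()[[s]], set = s, context = ctx)
    })
  })
}

small_meta <- function() {
  memo("small_meta", lapply(small_stats(), multitrait_chi2))
}

# build a summary_stats object directly from a t-value matrix, for
# meta-analysis tests that control the inputs exactly
make_stats <- function(tmat, set = "RT", chrom = NULL, pos_bp = NULL) {
  m <- nrow(tmat)
  k <- ncol(tmat)
  traits <- colnames(tmat)
  if (is.null(traits)) traits <- sprintf("T%02d", seq_len(k))
  if (is.null(chrom)) chrom <- rep(1L, m)
  if (is.null(pos_bp)) pos_bp <- seq_len(m) * 1e4
  snp <- sprintf("snp_%05d", seq_len(m))
  dimnames(tmat) <- list(snp, traits)
  se <- matrix(1, m, k, dimnames = dimnames(tmat))
  structure(
    list(set = set, traits = traits,
         snp_map = tibble::tibble(snp = snp, chrom = chrom, pos_bp = pos_bp,
                                  allele_ref = "A", allele_alt = "C",
                                  base_freq = 0.5),
         beta = tmat, se = se, tval = tmat,
         pval = 2 * pnorm(-abs(tmat)), conditioned_on = NULL),
    class = "summary_stats"
  )
}

# tiny genotype object with explicit dosages, for QC/GRM unit tests
make_geno <- function(dosages, chrom = NULL, pos_bp = NULL, breed = "BreedA",
                      cohort = "discovery") {
  n <- nrow(dosages)
  m <- ncol(dosages)
  if (is.null(chrom)) chrom <- rep(1L, m)
  if (is.null(pos_bp)) pos_bp <- seq_len(m) * 1e5
  snp <- sprintf("snp_%05d", seq_len(m))
  colnames(dosages) <- snp
  structure(
    list(dosages = dosages,
         snp_map = tibble::tibble(snp = snp, chrom = chrom, pos_bp = pos_bp,
                                  allele_ref = "A", allele_alt = "C",
                                  base_freq = colMeans(dosages) / 2),
         animals = tibble::tibble(animal_id = sprintf("an_%05d", seq_len(n)),
                                  breed = rep_len(breed, n),
                                  cohort = rep_len(cohort, n)),
         truth = tibble::tibble(snp = character())),
    class = "geno_matrix"
  )
}

# data frame with exactly the target covariance: whiten empirically, then
# colour by the target's Cholesky factor
panel_with_exact_cov <- function(n, target, seed = 1) {
  set.seed(seed)
  k <- ncol(target)
  X0 <- matrix(rnorm(n * k), n, k)
  X0 <- scale(X0, center = TRUE, scale = FALSE)
  W <- X0 %*% backsolve(chol(cov(X0)), diag(k))
  X <- W %*% chol(target)
  colnames(X) <- sprintf("T%02d", seq_len(k))
  dplyr::bind_cols(
    tibble::tibble(animal_id = sprintf("an_%05d", seq_len(n)),
                   breed = "BreedA", cohort = "discovery"),
    tibble::as_tibble(X)
  )
}

lead_is_true <- function(leads, truth, window_bp = 1e6) {
  vapply(seq_len(nrow(leads)), function(i) {
    any(truth$chrom == leads$chrom[i] &
          abs(truth$pos_bp - leads$pos_bp[i]) <= window_bp)
  }, logical(1))
}
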