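#' SNP quality control by MAF and Hardy-Weinberg equilibrium
#'
#' Removes SNPs with minor allele frequency below `maf_min` or departing
#' from Hardy-Weinberg equilibrium at `hwe_alpha`. The MAF filter is
#' applied first, so the removal reasons are disjoint. HWE is assessed by a
#' 1-df goodness-of-fit chi-square on pooled genotype counts (all breeds
#' together); a within-breed variant is available via `by_breed` for
#' stratified populations, where pooled counts can fail HWE through the
#' Wahlund effect alone.
#'
#' @param genotypes A `geno_matrix`.
#' @param maf_min Minimum minor allele frequency (default 0.01).
#' @param hwe_alpha HWE test significance cutoff (default 0.001).
#' @param by_breed Test HWE within each breed (most stringent breed kept)?
#'   Default `FALSE` (pooled).
#' @return List with `genotypes` (filtered `geno_matrix`) and `report`, a
#'   `qc_report` holding input/removed counts and kept SNP ids.
#' @export
qc_filter <- function(genotypes, maf_min = 0.01, hwe_alpha = 0.001, by_breed = FALSE) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  dos <- genotypes$dosages
  m <- ncol(dos)
  p <- colMeans(dos) / 2
  maf <- pmin(p, 1 - p)
  fail_maf <- maf < maf_min

  hwe_p_pooled <- function(D) {
    n <- nrow(D)
    n2 <- colSums(D == 2L)
    n1 <- colSums(D == 1L)
    n0 <- n - n1 - n2
    ph <- (2 * n2 + n1) / (2 * n)
    e0 <- n * (1 - ph)^2; e1 <- n * 2 * ph * (1 - ph); e2 <- n * ph^2
    chi2 <- (n0 - e0)^2 / pmax(e0, .Machine$double.eps) +
      (n1 - e1)^2 / pmax(e1, .Machine$double.eps) +
      (n2 - e2)^2 / pmax(e2, .Machine$double.eps)
    pchisq(chi2, df = 1, lower.tail = FALSE)
  }

  if (by_breed) {
    pv <- rep(1, m)
    for (br in unique(genotypes$animals$breed)) {
      rows <- genotypes$animals$breed == br
      pv <- pmin(pv, hwe_p_pooled(dos[rows, , drop = FALSE]))
    }
  } else {
    pv <- hwe_p_pooled(dos)
  }
  fail_hwe <- !fail_maf & pv < hwe_alpha
  keep <- !fail_maf & !fail_hwe
  if (!any(keep)) abort("no SNPs left after QC filtering.")
  report <- structure(
    list(n_input_snps = m,
         n_removed_maf = sum(fail_maf),
         n_removed_hwe = sum(fail_hwe),
         kept_snp_ids = genotypes$snp_map$snp[keep],
         hwe_mode = if (by_breed) "within-breed" else "pooled"),
    class = "qc_report"
  )
  list(genotypes = subset_genotypes(genotypes, snps = keep), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d SNPs in; removed %d (MAF), %d (HWE, %s); %d kept\n",
              x$n_input_snps, x$n_removed_maf, x$n_removed_hwe, x$hwe_mode,
              length(x$kept_snp_ids)))
  invisible(x)
}

#' @export
tidy.qc_report <- function(x, ...) {
  tibble::tibble(
    n_input_snps = x$n_input_snps, n_removed_maf = x$n_removed_maf,
    n_removed_hwe = x$n_removed_hwe, n_kept = length(x$kept_snp_ids),
    hwe_mode = x$hwe_mode
  )
}

#' Genomic relationship matrix
#'
#' Centered, frequency-scaled genotype cross-product: `G = Z Z' / s` with
#' `Z = dosage - 2p` and `s = sum(2 p_j (1 - p_j))` over all SNPs
#' (VanRaden method 1). Used as the covariance structure of the polygenic
#' random effect in the mixed-model scan.
#'
#' @param genotypes Post-QC `geno_matrix`.
#' @return Object of class `grm`: `matrix` (n x n), `animal_ids`,
#'   `n_snps_used`. The eigendecomposition is computed lazily and cached.
#' @export
compute_grm <- function(genotypes) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  dos <- genotypes$dosages
  p <- colMeans(dos) / 2
  if (any(p <= 0 | p >= 1)) {
    abort("monomorphic SNP encountered; run qc_filter() first.")
  }
  Z <- sweep(dos, 2, 2 * p)
  s <- sum(2 * p * (1 - p))
  G <- tcrossprod(Z) / s
  structure(
    list(matrix = G, animal_ids = genotypes$animals$animal_id,
         n_snps_used = ncol(dos), cache = new.env(parent = emptyenv())),
    class = "grm"
  )
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("<grm> %d animals from %d SNPs; mean diagonal %.3f\n",
              nrow(x$matrix), x$n_snps_used, mean(diag(x$matrix))))
  invisible(x)
}

grm_eigen <- function(grm) {
  stopifnot(inherits(grm, "grm"))
  if (is.null(grm$cache$eig)) {
    grm$cache$eig <- eigen(grm$matrix, symmetric = TRUE)
  }
  grm$cache$eig
}

breed_design <- function(breeds) {
  lv <- sort(unique(breeds))
  X <- matrix(1, length(breeds), 1, dimnames = list(NULL, "(Intercept)"))
  if (length(lv) > 1) {
    for (b in lv[-1]) X <- cbind(X, as.numeric(breeds == b))
    colnames(X) <- c("(Intercept)", paste0("breed", lv[-1]))
  }
  X
}

# restricted log-likelihood of the one-component animal model at
# heritability h, on GRM-eigenrotated data (up to an additive constant)
reml_ll_h <- function(h, s, yr, Xr) {
  v <- h * s + (1 - h)
  if (any(v <= 0)) return(-Inf)
  w <- 1 / v
  XtWX <- crossprod(Xr, w * Xr)
  XtWy <- crossprod(Xr, w * yr)
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  b <- backsolve(ch, forwardsolve(t(ch), XtWy))
  r <- yr - Xr %*% b
  rss <- sum(w * r^2)
  np <- length(yr) - ncol(Xr)
  -0.5 * (sum(log(v)) + 2 * sum(log(diag(ch))) + np * log(rss / np) + np)
}

#' Fit the null mixed model and estimate SNP heritability
#'
#' REML fit of `y = Xb + a + e` with `a ~ N(0, sigma_g^2 G)` and
#' `e ~ N(0, sigma_e^2 I)`, no SNP term, breed as fixed effects. The GRM
#' eigendecomposition diagonalizes the covariance, so the restricted
#' likelihood is profiled over the heritability `h2 = sigma_g^2 /
#' (sigma_g^2 + sigma_e^2)` in one dimension; one decomposition is reused
#' across all traits. The standard error of `h2` comes from the curvature
#' of the restricted likelihood at the optimum.
#'
#' @param values Numeric phenotype vector, one value per GRM animal.
#' @param breeds Breed label per animal (fixed effects; reference level is
#'   the first breed alphabetically).
#' @param grm A [compute_grm()] object over the same animals.
#' @param trait_name Optional label carried into the result.
#' @return Object of class `null_model_fit`: `sigma_g2`, `sigma_e2`, `h2`,
#'   `h2_se`, `fixed_effects`, `loglik` (restricted, up to a constant).
#' @export
fit_null_model <- function(values, breeds, grm, trait_name = "trait") {
  stopifnot(inherits(grm, "grm"))
  n <- length(values)
  if (n != nrow(grm$matrix)) abort("GRM and trait cover different animals.")
  eig <- grm_eigen(grm)
  U <- eig$vectors; s <- pmax(eig$values, 0)
  yr <- as.vector(crossprod(U, values))
  Xr <- crossprod(U, breed_design(breeds))
  opt <- optimize(reml_ll_h, c(1e-6, 1 - 1e-6), s = s, yr = yr, Xr = Xr,
                  maximum = TRUE, tol = 1e-8)
  if (!is.finite(opt$objective)) {
    abort("REML fit did not converge: restricted likelihood not finite at optimum.")
  }
  h <- opt$maximum
  # profile variance at the optimum
  v <- h * s + (1 - h); w <- 1 / v
  XtWX <- crossprod(Xr, w * Xr)
  b <- solve(XtWX, crossprod(Xr, w * yr))
  r <- yr - Xr %*% b
  sigma_p2 <- sum(w * r^2) / (n - ncol(Xr))
  # curvature-based approximate standard error for h2
  eps <- min(1e-3, h / 2, (1 - h) / 2)
  d2 <- (reml_ll_h(h + eps, s, yr, Xr) - 2 * opt$objective +
           reml_ll_h(h - eps, s, yr, Xr)) / eps^2
  h2_se <- if (is.finite(d2) && d2 < 0) sqrt(-1 / d2) else NA_real_
  structure(
    list(trait_name = trait_name,
         sigma_g2 = h * sigma_p2, sigma_e2 = (1 - h) * sigma_p2,
         h2 = h, h2_se = h2_se,
         fixed_effects = setNames(as.vector(b), colnames(Xr)),
         loglik = opt$objective),
    class = "null_model_fit"
  )
}

#' @export
print.null_model_fit <- function(x, ...) {
  cat(sprintf("<null_model_fit> %s: h2 = %.3f (se %.3f), sigma_g2 = %.3f, sigma_e2 = %.3f\n",
              x$trait_name, x$h2, x$h2_se, x$sigma_g2, x$sigma_e2))
  invisible(x)
}

#' @export
tidy.null_model_fit <- function(x, ...) {
  tibble::tibble(trait = x$trait_name, sigma_g2 = x$sigma_g2,
                 sigma_e2 = x$sigma_e2, h2 = x$h2, h2_se = x$h2_se,
                 loglik = x$loglik)
}

#' Fit null models for every trait of a panel
#'
#' @param panel Trait panel tibble aligned with the GRM animals.
#' @param grm A [compute_grm()] object.
#' @param traits Trait columns to fit; defaults to all.
#' @return Named list of [fit_null_model()] objects.
#' @export
fit_null_models <- function(panel, grm, traits = NULL) {
  if (is.null(traits)) traits <- panel_traits(panel)
  fits <- lapply(traits, function(tr) {
    fit_null_model(panel[[tr]], panel$breed, grm, trait_name = tr)
  })
  setNames(fits, traits)
}

#' Precompute the rotated design shared by all single-trait scans
#'
#' Rotates the genotype dosages and fixed-effect design into the GRM
#' eigenbasis once, so that repeated scans (75 traits, conditional rounds)
#' reuse the expensive matrix products.
#'
#' @param genotypes Post-QC `geno_matrix` for the scanned cohort.
#' @param grm Matching [compute_grm()] object.
#' @param breeds Breed labels (defaults to the genotype object's).
#' @return Opaque `scan_context` list used by [gwas_scan()].
#' @export
scan_context <- function(genotypes, grm, breeds = genotypes$animals$breed) {
  stopifnot(inherits(genotypes, "geno_matrix"), inherits(grm, "grm"))
  dos <- genotypes$dosages
  vv <- colMeans(dos^2) - colMeans(dos)^2
  if (any(vv <= 0)) {
    abort(sprintf("%d SNP(s) with zero variance; run qc_filter() first.", sum(vv <= 0)))
  }
  eig <- grm_eigen(grm)
  U <- eig$vectors
  Zr <- crossprod(U, dos)
  structure(
    list(U = U, s = pmax(eig$values, 0), Zr = Zr, Zr2 = Zr^2,
         X = breed_design(breeds), snp_map = genotypes$snp_map,
         animal_ids = genotypes$animals$animal_id),
    class = "scan_context"
  )
}

# core EMMAX-style generalized-least-squares scan of every SNP for one
# trait, variance components fixed at the null-model REML estimates
scan_one_trait <- function(ctx, y, fit, extra_cov_r = NULL) {
  w <- 1 / (fit$sigma_g2 * ctx$s + fit$sigma_e2)
  Xr <- if (is.null(ctx$U)) ctx$X else crossprod(ctx$U, ctx$X)
  if (!is.null(extra_cov_r)) Xr <- cbind(Xr, extra_cov_r)
  yr <- if (is.null(ctx$U)) y else as.vector(crossprod(ctx$U, y))
  wX <- w * Xr
  XtWX <- crossprod(Xr, wX)
  Ai <- solve(XtWX)
  XtWy <- crossprod(Xr, w * yr)
  ZtWX <- crossprod(ctx$Zr, wX)
  ZtWy <- as.vector(crossprod(ctx$Zr, w * yr))
  ZtWZ <- as.vector(crossprod(ctx$Zr2, w))
  xPx <- ZtWZ - rowSums((ZtWX %*% Ai) * ZtWX)
  xPy <- ZtWy - as.vector(ZtWX %*% (Ai %*% XtWy))
  tol <- 1e-8 * stats::median(ZtWZ)
  degen <- xPx < tol
  xPx[degen] <- NA
  beta <- xPy / xPx
  se <- sqrt(1 / xPx)
  tval <- beta / se
  # SNPs collinear with the covariates (e.g. a lead conditioned on itself)
  # carry no testable effect
  beta[degen] <- 0; se[degen] <- Inf; tval[degen] <- 0
  pval <- 2 * pnorm(-abs(tval))
  list(beta = beta, se = se, t = tval, p = pval)
}

#' Single-trait mixed-model association scan
#'
#' Scans every SNP for every trait of a phenotype panel under the model
#' `y = mean + breed + b x + a + e`, with the polygenic effect
#' `a ~ N(0, sigma_g^2 G)`. Variance components are fixed at the per-trait
#' null-model REML estimates (EMMAX-style approximation), so each SNP
#' requires only a generalized-least-squares fit in the GRM eigenbasis.
#' Reported per SNP and trait: effect `beta`, its standard error, the
#' signed t-value `beta/se`, and the two-sided Wald p-value.
#'
#' @param panel Trait panel for the scanned cohort (e.g. one of the sets
#'   from [apply_transforms()]).
#' @param genotypes Post-QC `geno_matrix` (same animals, same order).
#' @param grm Matching [compute_grm()] object.
#' @param null_fits Named list from [fit_null_models()]; fitted here if
#'   `NULL`.
#' @param set Phenotype-set label stored with the result (`"RT"`, `"PC"`,
#'   `"CT"`, ...).
#' @param lead_snps Optional character vector of SNP ids whose dosages are
#'   fitted as fixed covariates (conditional scan).
#' @param context Optional [scan_context()] to reuse across scans.
#' @return Object of class `summary_stats`: matrices `beta`, `se`, `tval`,
#'   `pval` (SNP x trait), plus `set`, `traits`, `snp_map`. Use [tidy()] for
#'   a long tibble.
#' @export
gwas_scan <- function(panel, genotypes, grm, null_fits = NULL, set = "RT",
                      lead_snps = NULL, context = NULL) {
  if (is.null(context)) context <- scan_context(genotypes, grm)
  traits <- panel_traits(panel)
  if (is.null(null_fits)) null_fits <- fit_null_models(panel, grm, traits)
  if (!all(traits %in% names(null_fits))) {
    abort("null_fits must cover every trait of the panel.")
  }
  extra <- NULL
  if (!is.null(lead_snps) && length(lead_snps)) {
    cols <- match(lead_snps, context$snp_map$snp)
    if (anyNA(cols)) abort("unknown lead SNP id(s) in `lead_snps`.")
    extra <- context$Zr[, cols, drop = FALSE]
  }
  res <- scan_all_traits(context, panel, traits, null_fits, extra_cov_r = extra)
  structure(
    c(list(set = set, traits = traits, snp_map = context$snp_map),
      res, list(conditioned_on = lead_snps)),
    class = "summary_stats"
  )
}

# batched scan: one pass over the rotated dosage matrix serves every
# trait (weights differ per trait, so weighted responses and weighted
# covariate blocks are stacked column-wise before the cross-products)
scan_all_traits <- function(ctx, panel, traits, null_fits, extra_cov_r = NULL) {
  n <- length(ctx$s)
  m <- ncol(ctx$Zr)
  Tn <- length(traits)
  Y <- panel_matrix(panel, traits)
  Yr <- if (is.null(ctx$U)) Y else crossprod(ctx$U, Y)
  Xr <- if (is.null(ctx$U)) ctx$X else crossprod(ctx$U, ctx$X)
  if (!is.null(extra_cov_r)) Xr <- cbind(Xr, extra_cov_r)
  p <- ncol(Xr)
  sg <- vapply(null_fits[traits], `[[`, numeric(1), "sigma_g2")
  se2 <- vapply(null_fits[traits], `[[`, numeric(1), "sigma_e2")
  Wmat <- 1 / (outer(ctx$s, sg) + rep(se2, each = n))    # n x T
  WY <- Wmat * Yr
  ZtWY <- crossprod(ctx$Zr, WY)                          # m x T
  ZtWZ <- crossprod(ctx$Zr2, Wmat)                       # m x T
  WX_all <- matrix(0, n, Tn * p)
  for (t in seq_len(Tn)) WX_all[, (t - 1L) * p + seq_len(p)] <- Wmat[, t] * Xr
  ZtWX_all <- crossprod(ctx$Zr, WX_all)                  # m x (T*p)
  beta <- se <- tval <- matrix(NA_real_, m, Tn, dimnames = list(ctx$snp_map$snp, traits))
  for (t in seq_len(Tn)) {
    cols <- (t - 1L) * p + seq_len(p)
    wX <- WX_all[, cols, drop = FALSE]
    XtWX <- crossprod(Xr, wX)
    Ai <- solve(XtWX)
    XtWy <- crossprod(wX, Yr[, t])
    ZtWX <- ZtWX_all[, cols, drop = FALSE]
    xPx <- ZtWZ[, t] - rowSums((ZtWX %*% Ai) * ZtWX)
    xPy <- ZtWY[, t] - as.vector(ZtWX %*% (Ai %*% XtWy))
    tol <- 1e-8 * stats::median(ZtWZ[, t])
    degen <- xPx < tol
    xPx[degen] <- NA
    beta[, t] <- xPy / xPx
    se[, t] <- sqrt(1 / xPx)
    tval[, t] <- beta[, t] / se[, t]
    beta[degen, t] <- 0; se[degen, t] <- Inf; tval[degen, t] <- 0
  }
  list(beta = beta, se = se, tval = tval, pval = 2 * pnorm(-abs(tval)))
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("<summary_stats> set %s: %d SNPs x %d traits%s\n",
              x$set, nrow(x$beta), length(x$traits),
              if (length(x$conditioned_on))
                sprintf(", conditioned on %d lead(s)", length(x$conditioned_on)) else ""))
  invisible(x)
}

#' @describeIn gwas_scan Long tibble: one row per SNP and trait with
#'   `set, snp, chrom, pos_bp, trait, beta, se, t, p`.
#' @param x A `summary_stats` object.
#' @param ... Unused.
#' @export
tidy.summary_stats <- function(x, ...) {
  long <- tibble::tibble(
    set = x$set,
    snp = rep(x$snp_map$snp, times = length(x$traits)),
    chrom = rep(x$snp_map$chrom, times = length(x$traits)),
    pos_bp = rep(x$snp_map$pos_bp, times = length(x$traits)),
    trait = rep(x$traits, each = nrow(x$beta)),
    beta = as.vector(x$beta), se = as.vector(x$se),
    t = as.vector(x$tval), p = as.vector(x$pval)
  )
  long
}
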