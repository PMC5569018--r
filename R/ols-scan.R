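# fixed-effects-only analogues of the mixed-model scan machinery, used for
# the validation cohort where phenotypes are individual records and no GRM
# is fitted by default

ols_null_fit <- function(y, breeds, trait_name = "trait") {
  X <- breed_design(breeds)
  r <- lm.fit(X, y)$residuals
  list(trait_name = trait_name, sigma_g2 = 0,
       sigma_e2 = sum(r^2) / (length(y) - ncol(X)),
       h2 = 0, h2_se = NA_real_, loglik = NA_real_)
}

ols_context <- function(genotypes, breeds = genotypes$animals$breed) {
  dos <- genotypes$dosages
  vv <- colMeans(dos^2) - colMeans(dos)^2
  if (any(vv <= 0)) {
    abort(sprintf("%d SNP(s) with zero variance; run qc_filter() first.", sum(vv <= 0)))
  }
  Zr <- dos * 1.0
  structure(
    list(U = NULL, s = rep(0, nrow(dos)), Zr = Zr, Zr2 = Zr^2,
         X = breed_design(breeds), snp_map = genotypes$snp_map,
         animal_ids = genotypes$animals$animal_id),
    class = "scan_context"
  )
}

#' Fixed-effects association scan (no polygenic term)
#'
#' Ordinary least-squares scan of every SNP for every trait with breed
#' covariates, the default model for the validation cohort. Equivalent to
#' [gwas_scan()] with the genetic variance forced to zero; the residual
#' variance is taken from the breed-only null fit of each trait, so
#' p-values are Wald-normal like the mixed-model scan's.
#'
#' @param panel Trait panel for the cohort.
#' @param genotypes Matching `geno_matrix`.
#' @param set Phenotype-set label.
#' @param context Optional [ols_context()]-style cache reused across the
#'   phenotype sets of one cohort.
#' @return A `summary_stats` object.
#' @export
ols_scan <- function(panel, genotypes, set = "RT", context = NULL) {
  if (is.null(context)) context <- ols_context(genotypes, panel$breed)
  traits <- panel_traits(panel)
  fits <- lapply(traits, function(tr) ols_null_fit(panel[[tr]], panel$breed, tr))
  names(fits) <- traits
  res <- scan_all_traits(context, panel, traits, fits)
  structure(
    c(list(set = set, traits = traits, snp_map = context$snp_map),
      res, list(conditioned_on = NULL)),
    class = "summary_stats"
  )
}
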