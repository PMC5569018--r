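#' Build a SNP-specific linear trait index
#'
#' For a lead SNP, takes its discovery effect vector `b` (betas over the k
#' traits of the chosen phenotype set) and the k x k covariance `C` of
#' betas across all scanned SNPs in that set, and forms index weights
#' `C^{-1} b`. Applied to an animal's trait values the index concentrates
#' that SNP's multi-trait signal into a single response variable; by
#' construction the discovery-side index effect `b' C^{-1} b` is positive,
#' so a positive validation slope means direction agreement.
#'
#' By default the phenotype set is the one in which the SNP is most
#' significant (smallest discovery meta-analysis p-value).
#'
#' @param stats_list Named list of discovery `summary_stats` (RT/PC/CT).
#' @param snp_id SNP to validate.
#' @param set_choice Set to use; `NULL` picks the most significant via
#'   `meta_list`.
#' @param meta_list Named list of discovery `meta_result`s, required when
#'   `set_choice` is `NULL`.
#' @param ridge Relative ridge added to `C` if it is numerically singular.
#' @return Object of class `linear_index`: `snp_id`, `set`, `b`, `C`,
#'   `weights`.
#' @export
build_index <- function(stats_list, snp_id, set_choice = NULL, meta_list = NULL,
                        ridge = 1e-8) {
  if (is.null(set_choice)) {
    if (is.null(meta_list)) abort("provide `set_choice` or `meta_list`.")
    pm <- vapply(meta_list, function(m) m$p_m[match(snp_id, m$snp)], numeric(1))
    if (anyNA(pm)) abort(sprintf("SNP %s missing from a meta result.", snp_id))
    set_choice <- names(meta_list)[which.min(pm)]
  }
  stats <- stats_list[[set_choice]]
  if (is.null(stats)) abort(sprintf("no summary stats for set %s.", set_choice))
  i <- match(snp_id, stats$snp_map$snp)
  if (is.na(i)) abort(sprintf("SNP %s not in the discovery stats.", snp_id))
  b <- stats$beta[i, ]
  if (all(b == 0)) abort("index undefined: the SNP has zero effect on every trait.")
  C <- cov(stats$beta)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < ridge * max(ev)) {
    lam <- ridge * max(ev)
    C <- C + diag(lam, ncol(C))
    inform(sprintf("beta covariance ridge-regularized (lambda %.2e).", lam))
  }
  w <- solve(C, b)
  structure(
    list(snp_id = snp_id, set = set_choice, b = b, C = C,
         weights = as.vector(w), traits = stats$traits),
    class = "linear_index"
  )
}

#' @export
print.linear_index <- function(x, ...) {
  cat(sprintf("<linear_index> %s on set %s; discovery index effect b'C^-1 b = %.4f\n",
              x$snp_id, x$set, sum(x$b * x$weights)))
  invisible(x)
}

#' Validate a lead SNP with its linear index in an independent cohort
#'
#' Computes the index value for every validation animal from the chosen
#' phenotype set (the validation panel must already be transformed with
#' the discovery-fitted transforms) and regresses it on the lead SNP's
#' dosage with breed covariates. Direction agreement holds when the
#' validation slope is positive on the same allele coding, because the
#' discovery-side index effect is positive by construction.
#'
#' @param index A [build_index()] object.
#' @param panels Named list of validation trait panels (RT/PC/CT) produced
#'   by [apply_transforms()] with the discovery transforms.
#' @param genotypes Validation-cohort `geno_matrix` with the same allele
#'   coding as discovery.
#' @param use_grm Optional validation [compute_grm()]; when supplied the
#'   regression runs as a mixed model, otherwise plain fixed-effects
#'   regression (default).
#' @return One-row `validation_result` tibble: `snp, set, beta, se, t,
#'   p_v, direction_agrees`.
#' @export
validate_snp <- function(index, panels, genotypes, use_grm = NULL) {
  stopifnot(inherits(index, "linear_index"))
  panel <- panels[[index$set]]
  if (is.null(panel)) abort(sprintf("no validation panel for set %s.", index$set))
  i <- match(index$snp_id, genotypes$snp_map$snp)
  if (is.na(i)) abort("lead SNP absent from the validation genotypes (allele map mismatch).")
  Y <- panel_matrix(panel)
  if (ncol(Y) != length(index$weights)) {
    abort("validation panel trait count differs from the index weights.")
  }
  yi <- as.vector(Y %*% index$weights)
  x <- genotypes$dosages[, i]
  if (var(x) == 0) abort("lead SNP is monomorphic in the validation cohort.")
  if (!is.null(use_grm)) {
    fit0 <- fit_null_model(yi, panel$breed, use_grm, trait_name = "index")
    ctx <- list(U = grm_eigen(use_grm)$vectors, s = pmax(grm_eigen(use_grm)$values, 0),
                Zr = crossprod(grm_eigen(use_grm)$vectors, matrix(x, ncol = 1)),
                X = breed_design(panel$breed))
    ctx$Zr2 <- ctx$Zr^2
    res <- scan_one_trait(ctx, yi, fit0)
    beta <- res$beta[1]; se <- res$se[1]; tv <- res$t[1]; pv <- res$p[1]
  } else {
    df <- data.frame(y = yi, x = x, breed = panel$breed)
    fit <- lm(y ~ x + breed, data = df)
    sm <- summary(fit)$coefficients
    beta <- sm["x", 1]; se <- sm["x", 2]; tv <- sm["x", 3]; pv <- sm["x", 4]
  }
  out <- tibble::tibble(
    snp = index$snp_id, set = index$set,
    beta = beta, se = se, t = tv, p_v = pv,
    direction_agrees = beta > 0
  )
  class(out) <- c("validation_result", class(out))
  out
}

#' Per-trait effect-direction concordance between cohorts
#'
#' For each requested SNP and each trait present in both cohorts' scans,
#' reports whether the discovery and validation effect estimates share a
#' sign, plus the per-SNP concordant fraction. Traits missing from either
#' cohort are skipped with a warning.
#'
#' @param discovery_stats,validation_stats `summary_stats` for the two
#'   cohorts (same phenotype set).
#' @param snp_ids SNPs to compare.
#' @return List with `by_trait` (tibble: snp, trait, sign_discovery,
#'   sign_validation, concordant) and `by_snp` (tibble: snp,
#'   n_traits, n_concordant, fraction).
#' @export
direction_concordance <- function(discovery_stats, validation_stats, snp_ids) {
  shared <- intersect(discovery_stats$traits, validation_stats$traits)
  missing <- setdiff(union(discovery_stats$traits, validation_stats$traits), shared)
  if (length(missing)) {
    warn(paste0("trait(s) absent from one cohort, skipped: ",
                paste(missing, collapse = ", ")))
  }
  di <- match(snp_ids, discovery_stats$snp_map$snp)
  vi <- match(snp_ids, validation_stats$snp_map$snp)
  if (anyNA(di) || anyNA(vi)) abort("SNP id(s) missing from a cohort's scan.")
  rows <- lapply(seq_along(snp_ids), function(j) {
    sd_ <- sign(discovery_stats$beta[di[j], shared])
    sv <- sign(validation_stats$beta[vi[j], shared])
    tibble::tibble(
      snp = snp_ids[j], trait = shared,
      sign_discovery = as.vector(sd_), sign_validation = as.vector(sv),
      concordant = as.vector(sd_ == sv & sd_ != 0)
    )
  })
  by_trait <- dplyr::bind_rows(rows)
  by_snp <- by_trait |>
    dplyr::group_by(.data$snp) |>
    dplyr::summarise(n_traits = dplyr::n(),
                     n_concordant = sum(.data$concordant),
                     fraction = mean(.data$concordant), .groups = "drop")
  list(by_trait = by_trait, by_snp = by_snp)
}
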