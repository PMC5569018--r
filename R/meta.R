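#' Correlation matrix of signed t-values across traits
#'
#' The multi-trait chi-square statistic needs the k x k correlation matrix
#' `V` of signed t-values, estimated over all scanned SNP effects. Because
#' polygenic signal can inflate this correlation, an optional
#' null-restricted mode estimates it only from SNPs whose |t| stays below
#' `max_abs_t` on every trait. If the smallest eigenvalue falls below the
#' regularization floor, `V` is shrunk toward the identity just enough to
#' reach it and the shrinkage weight is recorded.
#'
#' @param stats A `summary_stats` object from [gwas_scan()].
#' @param max_abs_t Optional cap; SNPs with any |t| above it are excluded
#'   from the estimate (`NULL` = use all SNPs).
#' @param eigen_floor Minimum eigenvalue enforced by ridge shrinkage.
#' @return Object of class `v_matrix`: `V`, `k`, `set`, `shrinkage`.
#' @export
estimate_v <- function(stats, max_abs_t = NULL, eigen_floor = 1e-6) {
  stopifnot(inherits(stats, "summary_stats"))
  tm <- stats$tval
  if (ncol(tm) < 2) abort("at least 2 traits required to estimate V.")
  if (nrow(tm) < ncol(tm)) abort("fewer SNPs than traits; V would be singular.")
  if (!is.null(max_abs_t)) {
    keep <- rowSums(abs(tm) > max_abs_t) == 0
    if (sum(keep) < ncol(tm)) abort("too few SNPs below `max_abs_t` to estimate V.")
    tm <- tm[keep, , drop = FALSE]
  }
  sds <- apply(tm, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("constant t-value column for trait(s): ",
                 paste(colnames(tm)[sds == 0], collapse = ", ")))
  }
  V <- cor(tm)
  shrink <- 0
  ev_min <- min(eigen(V, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < eigen_floor) {
    shrink <- (eigen_floor - ev_min) / (1 - ev_min)
    V <- (1 - shrink) * V + shrink * diag(ncol(V))
    inform(sprintf("V ridge-regularized toward identity (weight %.2e).", shrink))
  }
  structure(list(V = V, k = ncol(V), set = stats$set, shrinkage = shrink),
            class = "v_matrix")
}

#' @export
print.v_matrix <- function(x, ...) {
  cat(sprintf("<v_matrix> set %s, k = %d, mean |off-diagonal| = %.3f%s\n",
              x$set, x$k, mean(abs(x$V[upper.tri(x$V)])),
              if (x$shrinkage > 0) sprintf(", shrinkage %.1e", x$shrinkage) else ""))
  invisible(x)
}

#' Multi-trait chi-square meta-analysis
#'
#' Combines the per-trait signed t-values of each SNP into
#' `chi2 = t' V^{-1} t`, referred to a chi-square distribution with k
#' degrees of freedom, testing the null that the SNP affects none of the k
#' traits. `V` is solved against, never explicitly inverted. Storey
#' q-values are attached.
#'
#' @param stats A `summary_stats` object.
#' @param v A [estimate_v()] result; estimated from `stats` if `NULL`.
#' @return A `meta_result` tibble: `snp, chrom, pos_bp, chi2, df, p_m, q,
#'   set`, with attributes `pi0` and `v_matrix`.
#' @export
multitrait_chi2 <- function(stats, v = NULL) {
  stopifnot(inherits(stats, "summary_stats"))
  if (is.null(v)) v <- estimate_v(stats)
  stopifnot(inherits(v, "v_matrix"))
  tm <- stats$tval
  if (ncol(tm) != v$k) abort("trait dimension of stats and V differ.")
  if (!all(is.finite(tm))) abort("non-finite t-values in the summary statistics.")
  k <- ncol(tm)
  chi2 <- unname(rowSums(tm * t(solve(v$V, t(tm)))))
  chi2 <- pmax(chi2, 0)
  p_m <- pchisq(chi2, df = k, lower.tail = FALSE)
  p_m <- pmin(pmax(p_m, .Machine$double.xmin), 1)
  st <- storey_qvalue(p_m)
  out <- tibble::tibble(
    snp = stats$snp_map$snp, chrom = stats$snp_map$chrom,
    pos_bp = stats$snp_map$pos_bp,
    chi2 = chi2, df = k, p_m = p_m, q = st$q, set = stats$set
  )
  attr(out, "pi0") <- st$pi0
  attr(out, "v_matrix") <- v
  class(out) <- c("meta_result", class(out))
  out
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 on a lambda grid (0.05 to 0.95 in
#' steps of 0.05) with a cubic smoothing spline evaluated at the largest
#' lambda, then converts p-values to q-values:
#' `q_i = min over {j : p_j >= p_i} of pi0 * m * p_j / rank(p_j)`.
#' With fewer than 100 p-values pi0 estimation is unreliable, so the
#' function warns and falls back to pi0 = 1 (the Benjamini-Hochberg
#' limit).
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return List with `q` (same order as input) and `pi0`.
#' @export
storey_qvalue <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    abort("p-values must lie in (0, 1].")
  }
  m <- length(pvalues)
  if (m < 100) {
    warn("fewer than 100 p-values; using pi0 = 1 (Benjamini-Hochberg limit).")
    pi0 <- 1
  } else {
    lambda <- seq(0.05, 0.95, by = 0.05)
    pi0_l <- vapply(lambda, function(l) mean(pvalues > l) / (1 - l), numeric(1))
    fit <- smooth.spline(lambda, pi0_l, df = 3)
    pi0 <- predict(fit, x = max(lambda))$y
    pi0 <- min(max(pi0, 1e-8), 1)
  }
  o <- order(pvalues, decreasing = TRUE)
  q <- pi0 * m * pvalues[o] / rank(pvalues, ties.method = "max")[o]
  q <- pmin(cummin(q), 1)
  qout <- numeric(m)
  qout[o] <- q
  list(q = qout, pi0 = pi0)
}

subset_stats_traits <- function(stats, idx) {
  out <- stats
  out$traits <- stats$traits[idx]
  out$beta <- stats$beta[, idx, drop = FALSE]
  out$se <- stats$se[, idx, drop = FALSE]
  out$tval <- stats$tval[, idx, drop = FALSE]
  out$pval <- stats$pval[, idx, drop = FALSE]
  out
}

#' Odd/even principal-component pleiotropy confirmation
#'
#' A genuinely pleiotropic SNP spreads its signal over many orthogonal
#' components, so it should stay significant when the multi-trait test is
#' run separately on the odd-numbered and on the even-numbered PCs. Runs
#' the chi-square meta-analysis on each half and flags SNPs significant in
#' both.
#'
#' @param pc_stats `summary_stats` for the PC phenotype set.
#' @param p_threshold Significance threshold for the joint flag.
#' @return List with `odd` and `even` `meta_result`s (df ceil(k/2) and
#'   floor(k/2)) and `joint`, a tibble flagging SNPs significant in both.
#' @export
odd_even_split <- function(pc_stats, p_threshold = 1e-5) {
  stopifnot(inherits(pc_stats, "summary_stats"))
  k <- length(pc_stats$traits)
  if (k < 4) abort("odd/even split needs at least 4 components.")
  odd <- multitrait_chi2(subset_stats_traits(pc_stats, seq(1, k, 2)))
  even <- multitrait_chi2(subset_stats_traits(pc_stats, seq(2, k, 2)))
  joint <- tibble::tibble(
    snp = odd$snp, chrom = odd$chrom, pos_bp = odd$pos_bp,
    p_odd = odd$p_m, p_even = even$p_m,
    significant_both = odd$p_m < p_threshold & even$p_m < p_threshold
  )
  list(odd = odd, even = even, joint = joint)
}
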