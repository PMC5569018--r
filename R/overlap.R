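fisher_overlap <- function(n_universe, n_a, n_b, n_shared) {
  # one-sided (enrichment) Fisher exact test on the 2x2 membership table
  tab <- matrix(c(n_shared, n_a - n_shared,
                  n_b - n_shared, n_universe - n_a - n_b + n_shared), 2, 2)
  if (n_a == 0 || n_b == 0) return(1)
  fisher.test(tab, alternative = "greater")$p.value
}

#' Pairwise sharing of significant SNPs between traits
#'
#' For every unordered trait pair, counts SNPs significant (p below
#' `p_threshold`) in both single-trait scans and tests whether that count
#' exceeds chance with a one-sided Fisher exact test over the universe of
#' all scanned SNPs. The exported matrix convention stores the rounded
#' log2 shared count (`-Inf` sentinel for zero shared).
#'
#' @param stats A `summary_stats` object.
#' @param p_threshold Single-trait significance cutoff, default 0.05.
#' @return An `overlap_result` tibble: `unit_a, unit_b, n_universe, n_a,
#'   n_b, n_shared, log2_shared, p_f` for every unordered pair (including
#'   self-pairs).
#' @export
pairwise_shared_snps <- function(stats, p_threshold = 0.05) {
  stopifnot(inherits(stats, "summary_stats"))
  k <- length(stats$traits)
  if (k < 2) abort("at least 2 traits required.")
  sig <- stats$pval < p_threshold
  m <- nrow(sig)
  counts <- crossprod(sig)  # shared significant SNPs per pair
  n_sig <- unname(diag(counts))
  ut <- which(upper.tri(counts, diag = TRUE), arr.ind = TRUE)
  i <- unname(ut[, 1]); j <- unname(ut[, 2])
  ns <- unname(counts[ut])
  out <- tibble::tibble(
    unit_a = stats$traits[i], unit_b = stats$traits[j],
    n_universe = m, n_a = n_sig[i], n_b = n_sig[j], n_shared = ns,
    log2_shared = ifelse(ns > 0, round(log2(ns)), -Inf),
    p_f = vapply(seq_along(ns), function(r) {
      fisher_overlap(m, n_sig[i[r]], n_sig[j[r]], ns[r])
    }, numeric(1))
  )
  out <- out[order(match(out$unit_a, stats$traits), match(out$unit_b, stats$traits)), ]
  class(out) <- c("overlap_result", class(out))
  out
}

#' Per-chromosome enrichment of a trait's shared significant SNPs
#'
#' Takes the SNPs significant for the focal trait that are also significant
#' for at least one other trait, and asks, chromosome by chromosome,
#' whether they concentrate there relative to the genome-wide SNP
#' distribution (one-sided Fisher exact test). With a single-chromosome
#' genome the test is degenerate and returns p = 1.
#'
#' @param stats A `summary_stats` object.
#' @param focal_trait Trait whose shared SNPs are broken down.
#' @param p_threshold Single-trait significance cutoff.
#' @return An `overlap_result` tibble, one row per chromosome, where
#'   `unit_a` is the focal trait and `unit_b` the chromosome.
#' @export
chromosome_breakdown <- function(stats, focal_trait, p_threshold = 0.05) {
  stopifnot(inherits(stats, "summary_stats"))
  if (!focal_trait %in% stats$traits) abort("unknown focal trait.")
  sig <- stats$pval < p_threshold
  fi <- match(focal_trait, stats$traits)
  shared <- sig[, fi] & rowSums(sig[, -fi, drop = FALSE]) > 0
  chroms <- sort(unique(stats$snp_map$chrom))
  m <- nrow(sig)
  rows <- lapply(chroms, function(ch) {
    on_ch <- stats$snp_map$chrom == ch
    ns <- sum(shared & on_ch)
    pf <- if (length(chroms) == 1) 1 else
      fisher_overlap(m, sum(shared), sum(on_ch), ns)
    tibble::tibble(
      unit_a = focal_trait, unit_b = paste0("chr", ch),
      n_universe = m, n_a = sum(shared), n_b = sum(on_ch), n_shared = ns,
      log2_shared = if (ns > 0) round(log2(ns)) else -Inf, p_f = pf
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("overlap_result", class(out))
  out
}

#' Cross-cohort overlap of significant SNP sets
#'
#' Tests whether SNPs significant in one cohort's multi-trait meta-analysis
#' (at `p_a`) overlap SNPs significant in another cohort's (at `p_b`) more
#' than expected, by a one-sided Fisher exact test over the shared SNP
#' universe. This is the dairy-versus-beef comparison applied to any two
#' cohorts scanned on the same markers.
#'
#' @param meta_a,meta_b `meta_result` tibbles sharing a SNP universe.
#' @param p_a,p_b Significance thresholds for cohorts a and b.
#' @return One-row `overlap_result` tibble.
#' @export
cross_cohort_overlap <- function(meta_a, meta_b, p_a = 1e-5, p_b = 0.05) {
  shared_universe <- intersect(meta_a$snp, meta_b$snp)
  if (!length(shared_universe)) abort("cohorts have disjoint SNP maps.")
  a <- meta_a$snp[meta_a$p_m < p_a]
  b <- meta_b$snp[meta_b$p_m < p_b]
  a <- intersect(a, shared_universe); b <- intersect(b, shared_universe)
  ns <- length(intersect(a, b))
  out <- tibble::tibble(
    unit_a = paste0("cohort_a@", format(p_a)), unit_b = paste0("cohort_b@", format(p_b)),
    n_universe = length(shared_universe),
    n_a = length(a), n_b = length(b), n_shared = ns,
    log2_shared = if (ns > 0) round(log2(ns)) else -Inf,
    p_f = fisher_overlap(length(shared_universe), length(a), length(b), ns)
  )
  class(out) <- c("overlap_result", class(out))
  out
}
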