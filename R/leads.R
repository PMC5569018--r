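merge_meta_sets <- function(meta_list) {
  sets <- names(meta_list)
  base <- meta_list[[1]][, c("snp", "chrom", "pos_bp")]
  P <- vapply(meta_list, function(m) {
    if (!all(m$snp == base$snp)) abort("meta results do not share the SNP map.")
    m$p_m
  }, numeric(nrow(base)))
  colnames(P) <- paste0("p_", sets)
  dplyr::bind_cols(base, tibble::as_tibble(P))
}

# greedy most-significant-first interval selection; `chosen` rows already
# block their 1-Mb neighbourhoods
greedy_pick <- function(cand, chosen, window_bp) {
  picked <- list()
  # stable order: score ascending, then coordinate (tie-break: smaller wins)
  cand <- cand[order(cand$score, cand$chrom, cand$pos_bp), , drop = FALSE]
  occ_chrom <- c(chosen$chrom, integer(0))
  occ_pos <- c(chosen$pos_bp, numeric(0))
  for (i in seq_len(nrow(cand))) {
    ch <- cand$chrom[i]; po <- cand$pos_bp[i]
    same <- occ_chrom == ch
    if (!any(same) || all(abs(occ_pos[same] - po) >= window_bp)) {
      picked[[length(picked) + 1L]] <- cand[i, ]
      occ_chrom <- c(occ_chrom, ch)
      occ_pos <- c(occ_pos, po)
    }
  }
  dplyr::bind_rows(picked)
}

#' Select lead SNPs within non-overlapping 1-Mb intervals
#'
#' A SNP is a lead candidate when its multi-trait meta-analysis p-value is
#' below `p_threshold` in all three phenotype sets (mode `"all"`, the
#' default) or in at least one (mode `"any"`). Candidates are ranked by
#' their worst (largest) p-value across sets and picked greedily, most
#' significant first, each pick excluding a `window_bp` neighbourhood on
#' its chromosome. Ties are broken toward the smaller genomic coordinate.
#'
#' @param meta_list Named list of `meta_result`s (e.g. RT/PC/CT) sharing
#'   one SNP map.
#' @param window_bp Exclusion window, default 1 Mb.
#' @param p_threshold Selection threshold, default 1e-5.
#' @param mode `"all"` (significant in every set) or `"any"`.
#' @param existing_leads Optional tibble of already-chosen leads whose
#'   windows are blocked (used by the conditional rounds).
#' @return Tibble of leads: `snp, chrom, pos_bp`, per-set `p_*`, `score`,
#'   `round_added`, `status`. Empty tibble when nothing is significant.
#' @export
select_interval_leads <- function(meta_list, window_bp = 1e6, p_threshold = 1e-5,
                                  mode = c("all", "any"), existing_leads = NULL) {
  mode <- match.arg(mode)
  tab <- merge_meta_sets(meta_list)
  pcols <- grep("^p_", names(tab), value = TRUE)
  P <- as.matrix(tab[, pcols])
  sig <- if (mode == "all") rowSums(P < p_threshold) == ncol(P)
         else rowSums(P < p_threshold) > 0
  cand <- tab[sig, , drop = FALSE]
  empty <- tibble::tibble(
    snp = character(), chrom = integer(), pos_bp = numeric(),
    score = numeric(), round_added = integer(), status = character()
  )
  if (!nrow(cand)) return(empty)
  cand$score <- apply(as.matrix(cand[, pcols]), 1, max)
  chosen <- if (is.null(existing_leads) || !nrow(existing_leads)) {
    tibble::tibble(chrom = integer(), pos_bp = numeric())
  } else existing_leads[, c("chrom", "pos_bp")]
  picked <- greedy_pick(cand, chosen, window_bp)
  if (!nrow(picked)) return(empty)
  picked$round_added <- 1L
  picked$status <- "active"
  picked
}

lead_dosage_r2 <- function(genotypes, snps) {
  cols <- match(snps, genotypes$snp_map$snp)
  D <- genotypes$dosages[, cols, drop = FALSE]
  suppressWarnings(cor(D)^2)
}

#' Iterative conditional re-scan and lead augmentation
#'
#' Refits every single-trait scan with the current leads' dosages as fixed
#' covariates, re-runs the multi-trait meta-analysis on the conditional
#' t-values, and adds any SNP still significant in all phenotype sets
#' (most significant per 1-Mb interval, outside existing lead windows).
#' Iterates to a fixed point. Newly proposed leads nearly collinear with
#' an existing lead (dosage r-squared > 0.99) are dropped with a warning.
#'
#' @param leads Lead tibble from [select_interval_leads()].
#' @param genotypes Post-QC discovery `geno_matrix`.
#' @param panels Named list of trait panels (RT/PC/CT) for the discovery
#'   cohort.
#' @param grm Discovery [compute_grm()].
#' @param null_fits Named list (per set) of [fit_null_models()] results.
#' @param window_bp,p_threshold,mode As in [select_interval_leads()].
#' @param max_rounds Safety cap on conditional rounds.
#' @param context Optional [scan_context()] to reuse.
#' @return List: `leads` (augmented tibble), `n_rounds`, and
#'   `conditional_meta`, the final-round conditional `meta_result`s (used
#'   to verify that no further SNP is significant).
#' @export
conditional_rescan <- function(leads, genotypes, panels, grm, null_fits,
                               window_bp = 1e6, p_threshold = 1e-5,
                               mode = "all", max_rounds = 10, context = NULL) {
  if (!nrow(leads)) abort("conditional_rescan() needs at least one lead.")
  if (is.null(context)) context <- scan_context(genotypes, grm)
  sets <- names(panels)
  round <- 0L
  repeat {
    round <- round + 1L
    cond_stats <- lapply(sets, function(s) {
      gwas_scan(panels[[s]], genotypes, grm, null_fits[[s]], set = s,
                lead_snps = leads$snp, context = context)
    })
    names(cond_stats) <- sets
    cond_meta <- lapply(cond_stats, multitrait_chi2)
    # new leads are windowed against each other, not against existing leads:
    # a secondary QTL inside an existing window is exactly what the
    # conditional step is meant to recover (the old leads themselves drop
    # out because their conditional signal is zero)
    new <- select_interval_leads(cond_meta, window_bp = window_bp,
                                 p_threshold = p_threshold, mode = mode)
    if (!nrow(new) || round >= max_rounds) {
      return(list(leads = leads, n_rounds = round, conditional_meta = cond_meta))
    }
    # drop new leads collinear with already-selected ones
    r2 <- lead_dosage_r2(genotypes, c(leads$snp, new$snp))
    n_old <- nrow(leads)
    keep <- vapply(seq_len(nrow(new)), function(i) {
      prior <- r2[n_old + i, seq_len(n_old + i - 1L)]
      ok <- all(prior <= 0.99, na.rm = TRUE)
      if (!ok) warn(sprintf("dropping lead %s: dosage r2 > 0.99 with an earlier lead.",
                            new$snp[i]))
      ok
    }, logical(1))
    new <- new[keep, , drop = FALSE]
    if (!nrow(new)) {
      return(list(leads = leads, n_rounds = round, conditional_meta = cond_meta))
    }
    new$round_added <- round + 1L
    leads <- dplyr::bind_rows(leads, new)
  }
}

# generalized-least-squares fit of all leads jointly for one trait,
# variance components fixed at the null fit
joint_fit_one <- function(ctx, y, fit, lead_cols) {
  w <- 1 / (fit$sigma_g2 * ctx$s + fit$sigma_e2)
  Xb <- if (is.null(ctx$U)) ctx$X else crossprod(ctx$U, ctx$X)
  Xr <- cbind(Xb, ctx$Zr[, lead_cols, drop = FALSE])
  yr <- if (is.null(ctx$U)) y else as.vector(crossprod(ctx$U, y))
  XtWX <- crossprod(Xr, w * Xr)
  Ai <- solve(XtWX)
  b <- as.vector(Ai %*% crossprod(Xr, w * yr))
  se <- sqrt(diag(Ai))
  i_lead <- ncol(ctx$X) + seq_along(lead_cols)
  z <- b[i_lead] / se[i_lead]
  list(beta = b[i_lead], se = se[i_lead], p = 2 * pnorm(-abs(z)))
}

#' Joint multi-SNP model and lead pruning
#'
#' Fits all active leads simultaneously (with breed covariates) for every
#' trait of every phenotype set, under the same fixed variance components
#' as the scan. A lead is pruned when its joint p-value is >= `p_joint`
#' for every trait in every set; the joint effect table of the surviving
#' leads feeds the clustering and validation stages.
#'
#' @param leads Lead tibble (active rows are fitted).
#' @param genotypes,panels,grm,null_fits,context As in
#'   [conditional_rescan()].
#' @param p_joint Retention threshold, default 0.05.
#' @param p_adjust Multiplicity adjustment applied to each lead's joint
#'   p-values across all traits and sets before comparing with `p_joint`
#'   (any [stats::p.adjust()] method). Default `"none"`: a lead is kept if
#'   any single raw joint p-value is below the threshold, which with many
#'   traits prunes only leads with essentially no effect anywhere;
#'   `"bonferroni"` or `"BH"` make the filter sharp against chance hits.
#' @return List: `leads` (with `status` updated) and `joint_effects`, a
#'   long tibble `snp, set, trait, beta, se, p`.
#' @export
joint_model_prune <- function(leads, genotypes, panels, grm, null_fits,
                              p_joint = 0.05, p_adjust = "none", context = NULL) {
  if (!nrow(leads)) abort("joint_model_prune() needs at least one lead.")
  if (is.null(context)) context <- scan_context(genotypes, grm)
  active <- leads$status == "active"
  snps <- leads$snp[active]
  n <- length(context$animal_ids)
  if (length(snps) + ncol(context$X) >= n) abort("more leads than animals supports.")
  lead_cols <- match(snps, context$snp_map$snp)
  rows <- list()
  for (s in names(panels)) {
    traits <- panel_traits(panels[[s]])
    for (tr in traits) {
      ft <- joint_fit_one(context, panels[[s]][[tr]], null_fits[[s]][[tr]], lead_cols)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        snp = snps, set = s, trait = tr,
        beta = ft$beta, se = ft$se, p = ft$p
      )
    }
  }
  joint <- dplyr::bind_rows(rows)
  min_p <- joint |>
    dplyr::group_by(.data$snp) |>
    dplyr::summarise(min_p = min(stats::p.adjust(.data$p, method = p_adjust)),
                     .groups = "drop")
  pruned <- min_p$snp[min_p$min_p >= p_joint]
  leads$status[leads$snp %in% pruned] <- "pruned"
  list(leads = leads, joint_effects = joint[!joint$snp %in% pruned, ])
}
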