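#' Pipeline thresholds
#'
#' The significance and quality-control cutoffs used across the stages:
#' single-trait sharing at `p_s`, multi-trait discovery at `p_m`, joint
#' retention at `p_joint`, validation at `p_v`, QC at `maf_min` /
#' `hwe_alpha`, interval width `window_bp`, and the heatmap display mask
#' `mask_abs_t`.
#'
#' @param p_s,p_m,p_joint,p_v,maf_min,hwe_alpha,window_bp,mask_abs_t
#'   Numeric thresholds; see Description.
#' @return Named list of validated thresholds.
#' @export
pipeline_thresholds <- function(p_s = 0.05, p_m = 1e-5, p_joint = 0.05,
                                p_v = 0.05, maf_min = 0.01, hwe_alpha = 0.001,
                                window_bp = 1e6, mask_abs_t = 1) {
  th <- list(p_s = p_s, p_m = p_m, p_joint = p_joint, p_v = p_v,
             maf_min = maf_min, hwe_alpha = hwe_alpha,
             window_bp = window_bp, mask_abs_t = mask_abs_t)
  for (nm in c("p_s", "p_m", "p_joint", "p_v", "hwe_alpha")) {
    if (th[[nm]] <= 0 || th[[nm]] > 1) abort(sprintf("`%s` must be in (0, 1].", nm))
  }
  if (th$maf_min < 0 || th$maf_min >= 0.5) abort("`maf_min` must be in [0, 0.5).")
  if (th$window_bp <= 0) abort("`window_bp` must be positive.")
  th
}

#' Run the pleiotropy-detection pipeline end to end
#'
#' Executes the fixed stage order: simulate -> orthogonalize -> QC/GRM ->
#' single-trait mixed-model scans (RT, PC, CT) -> multi-trait meta-analysis
#' (plus odd/even PC confirmation) -> lead selection with conditional and
#' joint refinement -> trait-pair overlap tests -> validation-cohort index
#' tests and direction concordance -> effect clustering. Later stages never
#' feed back into earlier ones; toggling validation off leaves every
#' discovery output unchanged.
#'
#' @param config A [sim_config()]; the generated data carry their own
#'   ground truth.
#' @param thresholds A [pipeline_thresholds()] list.
#' @param out_dir Optional directory; when given, stage outputs are written
#'   as TSV/JSON alongside a provenance manifest.
#' @param do_odd_even,do_overlap,do_validation,do_cluster Stage toggles.
#' @return Object of class `pleioscan_run`: a list with the data, every
#'   stage's result and the manifest. See [pipeline_report()] for summary
#'   tables.
#' @export
run_pipeline <- function(config = sim_config(),
                         thresholds = pipeline_thresholds(),
                         out_dir = NULL,
                         do_odd_even = TRUE, do_overlap = TRUE,
                         do_validation = TRUE, do_cluster = TRUE) {
  stage <- "simulate"
  res <- list(config = config, thresholds = thresholds)
  emit <- function(x, name) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_tsv_table(x, file.path(out_dir, paste0(name, ".tsv")))
    }
    invisible(x)
  }
  run_stage <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  geno <- run_stage("simulate", simulate_genotypes(config))
  phen <- run_stage("simulate", simulate_phenotypes(geno, config))
  res$truth <- emit(phen$truth[, c("qtl", "snp", "chrom", "pos_bp", "maf")], "truth")
  res$truth$effect_vector <- phen$truth$effect_vector

  res$transforms <- run_stage("transform", fit_transforms(phen$discovery))
  panels_disc <- run_stage("transform", apply_transforms(phen$discovery, res$transforms))

  qc <- run_stage("qc", qc_filter(cohort_genotypes(geno, "discovery"),
                                  maf_min = thresholds$maf_min,
                                  hwe_alpha = thresholds$hwe_alpha))
  res$qc_report <- qc$report
  disc_geno <- qc$genotypes
  res$grm <- run_stage("grm", compute_grm(disc_geno))

  sets <- c("RT", "PC", "CT")
  res$null_fits <- run_stage("null_model", {
    lapply(setNames(sets, sets), function(s) fit_null_models(panels_disc[[s]], res$grm))
  })
  ctx <- run_stage("gwas", scan_context(disc_geno, res$grm))
  res$stats <- run_stage("gwas", {
    lapply(setNames(sets, sets), function(s) {
      gwas_scan(panels_disc[[s]], disc_geno, res$grm, res$null_fits[[s]],
                set = s, context = ctx)
    })
  })
  res$meta <- run_stage("meta", lapply(res$stats, multitrait_chi2))
  for (s in sets) emit(res$meta[[s]], paste0("meta_", s))
  if (do_odd_even) {
    res$odd_even <- run_stage("meta", odd_even_split(res$stats$PC, thresholds$p_m))
  }

  res$leads <- run_stage("leads", select_interval_leads(
    res$meta, window_bp = thresholds$window_bp, p_threshold = thresholds$p_m))
  if (nrow(res$leads)) {
    cond <- run_stage("leads", conditional_rescan(
      res$leads, disc_geno, panels_disc, res$grm, res$null_fits,
      window_bp = thresholds$window_bp, p_threshold = thresholds$p_m,
      context = ctx))
    res$conditional_meta <- cond$conditional_meta
    res$n_conditional_rounds <- cond$n_rounds
    jm <- run_stage("leads", joint_model_prune(
      cond$leads, disc_geno, panels_disc, res$grm, res$null_fits,
      p_joint = thresholds$p_joint, context = ctx))
    res$leads <- jm$leads
    res$joint_effects <- jm$joint_effects
  }
  emit(res$leads, "leads")

  if (do_overlap) {
    res$overlap <- run_stage("overlap", {
      lapply(setNames(sets, sets), function(s) {
        pairwise_shared_snps(res$stats[[s]], p_threshold = thresholds$p_s)
      })
    })
    emit(res$overlap$RT, "overlap_RT")
  }

  active <- res$leads$snp[res$leads$status == "active"]
  if (do_validation && length(active)) {
    val_geno <- run_stage("validate", subset_genotypes(
      cohort_genotypes(geno, "validation"), snps = disc_geno$snp_map$snp))
    panels_val <- run_stage("validate", apply_transforms(phen$validation, res$transforms))
    res$val_stats <- run_stage("validate", {
      vctx <- ols_context(val_geno, panels_val$RT$breed)
      lapply(setNames(sets, sets), function(s) {
        ols_scan(panels_val[[s]], val_geno, set = s, context = vctx)
      })
    })
    res$validation <- run_stage("validate", {
      dplyr::bind_rows(lapply(active, function(sn) {
        idx <- build_index(res$stats, sn, meta_list = res$meta)
        validate_snp(idx, panels_val, val_geno)
      }))
    })
    emit(res$validation, "validation")
    res$concordance <- run_stage("validate", {
      lapply(setNames(sets, sets), function(s) {
        direction_concordance(res$stats[[s]], res$val_stats[[s]], active)
      })
    })
  }

  if (do_cluster && length(active) >= 2) {
    res$clustering <- run_stage("cluster", {
      lapply(setNames(sets, sets), function(s) {
        conc <- if (!is.null(res$concordance)) res$concordance[[s]]$by_trait else NULL
        prof <- effect_profiles(res$stats[[s]], active, conc,
                                mask_abs_t = thresholds$mask_abs_t)
        corr <- effect_correlation(prof)
        list(profiles = prof, correlation = corr,
             tree = hierarchical_cluster(corr))
      })
    })
  }

  res$manifest <- list(
    seed = config$seed,
    config_hash = rlang::hash(config),
    n_snps_post_qc = ncol(disc_geno$dosages),
    n_leads_active = length(active),
    n_conditional_rounds = res$n_conditional_rounds %||% 0L,
    stages = c("simulate", "transform", "qc", "grm", "null_model", "gwas",
               "meta", "leads",
               if (do_overlap) "overlap", if (do_validation) "validate",
               if (do_cluster) "cluster"),
    package_version = as.character(utils::packageVersion("pleioscan")),
    r_version = R.version.string
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
    write_transforms(res$transforms, file.path(out_dir, "transforms.json"))
  }
  structure(res, class = "pleioscan_run")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pleioscan_run <- function(x, ...) {
  cat(sprintf("<pleioscan_run> seed %d: %d SNPs post-QC, %d active lead(s), %d conditional round(s)\n",
              x$config$seed, x$manifest$n_snps_post_qc,
              x$manifest$n_leads_active, x$manifest$n_conditional_rounds))
  invisible(x)
}

#' Summary tables for a completed run
#'
#' Produces the study-shaped summaries: per-trait significant-SNP counts
#' with heritability estimates for each phenotype set, the RT/PC/CT Venn
#' counts of multi-trait significant SNPs, and the per-set validation
#' summary (counts and percentages of direction-consistent and significant
#' leads).
#'
#' @param run A [run_pipeline()] result.
#' @param p_single Per-trait significance threshold for the counts table.
#' @return List of tibbles: `trait_summary`, `venn`, `validation_summary`.
#' @export
pipeline_report <- function(run, p_single = 1e-5) {
  stopifnot(inherits(run, "pleioscan_run"))
  sets <- names(run$stats)
  trait_summary <- dplyr::bind_rows(lapply(sets, function(s) {
    st <- run$stats[[s]]
    tibble::tibble(
      set = s, trait = st$traits,
      n_significant = unname(colSums(st$pval < p_single)),
      h2 = unname(vapply(run$null_fits[[s]], `[[`, numeric(1), "h2")[st$traits]),
      h2_se = unname(vapply(run$null_fits[[s]], `[[`, numeric(1), "h2_se")[st$traits])
    )
  }))
  thr <- run$thresholds$p_m
  sig <- lapply(run$meta, function(m) m$snp[m$p_m < thr])
  venn <- tibble::tibble(
    region = c("RT", "PC", "CT", "RT&PC", "RT&CT", "PC&CT", "RT&PC&CT"),
    n = c(length(sig$RT), length(sig$PC), length(sig$CT),
          length(intersect(sig$RT, sig$PC)),
          length(intersect(sig$RT, sig$CT)),
          length(intersect(sig$PC, sig$CT)),
          length(Reduce(intersect, sig)))
  )
  validation_summary <- NULL
  if (!is.null(run$validation) && nrow(run$validation)) {
    validation_summary <- run$validation |>
      dplyr::group_by(.data$set) |>
      dplyr::summarise(
        n_snps = dplyr::n(),
        n_consistent_direction = sum(.data$direction_agrees),
        pct_consistent = 100 * mean(.data$direction_agrees),
        n_significant = sum(.data$p_v < run$thresholds$p_v),
        pct_significant = 100 * mean(.data$p_v < run$thresholds$p_v),
        .groups = "drop"
      )
  }
  list(trait_summary = trait_summary, venn = venn,
       validation_summary = validation_summary)
}
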