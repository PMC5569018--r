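# symmetric PSD square root via eigendecomposition; tolerates semi-definite
# and zero matrices, which chol() does not
mat_sqrt <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  e$vectors %*% (sqrt(ev) * t(e$vectors))
}

#' Simulate correlated multi-trait phenotypes with planted QTL
#'
#' Builds trait values as breed shift + planted QTL effects + polygenic
#' value + residual. The polygenic value is constructed as the sum of many
#' small random SNP effects over all non-QTL markers (each SNP standardized,
#' per-SNP effect vectors drawn with covariance `genetic_covariance / m`),
#' so the same genotypes that enter the association scan also induce the
#' genetic relatedness among animals - including the weak discovery to
#' validation relationships created by shared haplotypes. Discovery animals
#' receive the progeny-mean residual (`residual_covariance_discovery`,
#' by default the individual residual shrunk by the daughter count),
#' emulating low-error bull phenotypes; validation animals receive the full
#' individual-record residual.
#'
#' @param genotypes A `geno_matrix` from [simulate_genotypes()] built from
#'   the same config.
#' @param config The [sim_config()] used for the genotypes.
#' @return A list with `discovery` and `validation` trait panels (tibbles
#'   with `animal_id`, `breed`, `cohort` and one column per trait) plus the
#'   `truth` tibble carried over from the genotypes.
#' @export
simulate_phenotypes <- function(genotypes, config) {
  stopifnot(inherits(genotypes, "geno_matrix"), inherits(config, "sim_config"))
  k <- config$n_traits
  for (q in config$qtl_specs) {
    if (length(q$effect_vector) != k) {
      abort("QTL effect_vector length does not match the trait count.")
    }
  }
  set.seed(config$seed + 1L)
  dos <- genotypes$dosages
  n <- nrow(dos)
  m <- ncol(dos)
  qtl_cols <- match(genotypes$truth$snp, genotypes$snp_map$snp)
  poly_cols <- setdiff(seq_len(m), qtl_cols)
  m_poly <- length(poly_cols)

  sg_half <- mat_sqrt(config$genetic_covariance)

  # polygenic value: standardized dosages x small random effects, blockwise
  A <- matrix(0, n, k)
  block <- 2000L
  for (start in seq(1L, m_poly, block)) {
    idx <- poly_cols[start:min(start + block - 1L, m_poly)]
    D <- dos[, idx, drop = FALSE]
    mu <- colMeans(D)
    s <- sqrt(pmax(colMeans(D^2) - mu^2, 0))
    keep <- s > 0
    if (!any(keep)) next
    W <- sweep(sweep(D[, keep, drop = FALSE], 2, mu[keep]), 2, s[keep], "/")
    B <- matrix(rnorm(sum(keep) * k), sum(keep), k) %*% sg_half / sqrt(m_poly)
    A <- A + W %*% B
  }

  # planted QTL effects on centered dosages
  Y <- A
  if (length(qtl_cols)) {
    E <- do.call(rbind, lapply(config$qtl_specs, `[[`, "effect_vector"))
    Dq <- scale(dos[, qtl_cols, drop = FALSE], center = TRUE, scale = FALSE)
    Y <- Y + Dq %*% E
  }

  # breed fixed shifts
  breed_levels <- sort(unique(genotypes$animals$breed))
  bi <- match(genotypes$animals$breed, breed_levels)
  Y <- Y + config$breed_effect_matrix[bi, , drop = FALSE]

  # cohort-specific residuals
  disc <- genotypes$animals$cohort == "discovery"
  re_d <- mat_sqrt(config$residual_covariance_discovery)
  re_v <- mat_sqrt(config$residual_covariance_validation)
  Y[disc, ] <- Y[disc, , drop = FALSE] +
    matrix(rnorm(sum(disc) * k), sum(disc), k) %*% re_d
  Y[!disc, ] <- Y[!disc, , drop = FALSE] +
    matrix(rnorm(sum(!disc) * k), sum(!disc), k) %*% re_v

  trait_names <- sprintf("T%02d", seq_len(k))
  colnames(Y) <- trait_names
  panel <- dplyr::bind_cols(genotypes$animals, tibble::as_tibble(Y))
  list(
    discovery = panel[disc, , drop = FALSE],
    validation = panel[!disc, , drop = FALSE],
    truth = genotypes$truth
  )
}

#' Trait columns of a phenotype panel
#'
#' A trait panel is an ordinary tibble whose metadata columns are
#' `animal_id`, `breed` and `cohort`; everything else is a trait.
#'
#' @param panel A trait panel tibble.
#' @return Character vector of trait column names, in panel order.
#' @export
panel_traits <- function(panel) {
  setdiff(names(panel), c("animal_id", "breed", "cohort"))
}

panel_matrix <- function(panel, traits = panel_traits(panel)) {
  as.matrix(panel[, traits, drop = FALSE])
}
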