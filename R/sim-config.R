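#' Specify a planted quantitative trait locus
#'
#' A QTL spec pins one simulated causal variant to a genomic position and
#' gives its allele-substitution effect on every trait, in units of trait
#' standard deviations. The generator assigns the spec to the SNP nearest
#' `pos_bp` on `chrom` and overrides that SNP's allele frequency with `maf`,
#' so the truth table emitted alongside the genotypes identifies the exact
#' marker carrying each planted signal.
#'
#' @param chrom 1-based chromosome index.
#' @param pos_bp 1-based position in base pairs.
#' @param effect_vector Numeric vector, one allele-substitution effect per
#'   trait (trait SD units). Zero entries mean no effect on that trait.
#' @param maf Allele frequency of the effect allele, in (0, 0.5].
#'
#' @return An object of class `qtl_spec`.
#' @export
qtl_spec <- function(chrom, pos_bp, effect_vector, maf) {
  stopifnot(length(chrom) == 1, length(pos_bp) == 1, length(maf) == 1)
  if (maf <= 0 || maf > 0.5) {
    abort("`maf` must lie in (0, 0.5].")
  }
  if (pos_bp < 1) abort("`pos_bp` must be a positive 1-based coordinate.")
  structure(
    list(chrom = as.integer(chrom), pos_bp = as.numeric(pos_bp),
         effect_vector = as.numeric(effect_vector), maf = as.numeric(maf)),
    class = "qtl_spec"
  )
}

#' Default set of planted pleiotropic QTL
#'
#' Eight large-effect pleiotropic loci spread over five synthetic
#' chromosomes. The first four share a "fat up, milk and protein down"
#' effect pattern on the production traits; the next three share a
#' "protein up, milk down" pattern; the last has broad effects on
#' non-production traits. Every locus has a multi-trait effect norm of at
#' least 0.4 SD, so at desk scale each is comfortably detectable while the
#' two patterns give the effect-clustering stage known structure to find.
#'
#' @param n_traits Number of traits the effect vectors must cover.
#' @return A list of [qtl_spec()] objects.
#' @export
default_qtl_specs <- function(n_traits = 25) {
  if (n_traits < 25) {
    abort("`default_qtl_specs()` requires at least 25 traits; pass custom specs for smaller panels.")
  }
  ev <- function(...) {
    x <- numeric(n_traits)
    pairs <- list(...)
    for (p in pairs) x[p[[1]]] <- p[[2]]
    x
  }
  list(
    qtl_spec(1, 25e6, ev(c(1, -0.35), c(2, 0.45), c(3, -0.50), c(4, 0.15), c(18, 0.20)), 0.30),
    qtl_spec(1, 70e6, ev(c(1, -0.30), c(2, 0.40), c(3, -0.45), c(19, 0.15)), 0.25),
    qtl_spec(2, 40e6, ev(c(1, -0.25), c(2, 0.35), c(3, -0.40), c(5, 0.20)), 0.35),
    qtl_spec(3, 15e6, ev(c(1, -0.20), c(2, 0.40), c(3, -0.35), c(12, 0.15)), 0.30),
    qtl_spec(3, 85e6, ev(c(1, 0.45), c(3, -0.40), c(6, 0.20)), 0.25),
    qtl_spec(4, 50e6, ev(c(1, 0.40), c(3, -0.35), c(7, 0.25)), 0.40),
    qtl_spec(5, 30e6, ev(c(1, 0.35), c(3, -0.45), c(9, 0.30)), 0.30),
    qtl_spec(5, 75e6, ev(c(5, -0.30), c(6, -0.35), c(8, 0.20), c(9, 0.30), c(14, 0.25), c(20, 0.20)), 0.35)
  )
}

#' Default genetic correlation structure
#'
#' Traits are given an autoregressive correlation pattern (`rho^|i-j|`),
#' a simple stand-in for the banded genetic correlations seen among
#' recorded dairy traits: neighbouring traits in the panel order are the
#' most correlated, distant ones nearly independent.
#'
#' @param n_traits Number of traits.
#' @param variance Per-trait variance on the diagonal.
#' @param rho Adjacent-trait correlation.
#' @return An `n_traits` x `n_traits` covariance matrix.
#' @export
ar1_covariance <- function(n_traits, variance = 1, rho = 0.5) {
  idx <- seq_len(n_traits)
  variance * rho^abs(outer(idx, idx, "-"))
}

default_breed_effects <- function(n_breeds, n_traits) {
  b <- matrix(0, n_breeds, n_traits)
  if (n_breeds >= 2) b[2, seq_len(min(5, n_traits))] <- 0.3
  if (n_breeds >= 3) b[3, intersect(6:10, seq_len(n_traits))] <- -0.3
  b
}

check_psd <- function(m, name) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    abort(paste0("`", name, "` must be a square matrix."))
  }
  if (max(abs(m - t(m))) > 1e-8) {
    abort(paste0("`", name, "` must be symmetric."))
  }
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    abort(paste0("`", name, "` must be positive semi-definite."))
  }
  invisible(m)
}

#' Configure the synthetic cattle-like study
#'
#' Bundles every knob of the synthetic-data generator: cohort sizes, genome
#' layout, allele-frequency and linkage-disequilibrium models, breed
#' structure, the planted QTL, and the genetic / residual covariance of the
#' trait panel. The defaults describe the desk-scale study the package is
#' tested at: 1,000 discovery animals with progeny-mean phenotypes, 2,000
#' validation animals with individual records, 20,000 SNPs on 5 synthetic
#' chromosomes, 3 breeds, 25 correlated traits, and 8 planted pleiotropic
#' QTL.
#'
#' @param n_discovery,n_validation Cohort sizes.
#' @param n_snps Total SNP count across the genome.
#' @param n_chromosomes Number of chromosomes; SNPs are split evenly.
#' @param chrom_length_bp Length of every chromosome in bp.
#' @param maf_range Range the base allele frequencies are drawn from
#'   (uniform), in (0, 0.5].
#' @param n_breeds Number of breeds.
#' @param breed_proportions Simplex vector of breed sizes.
#' @param n_traits Number of traits `k`.
#' @param qtl_specs List of [qtl_spec()] objects (ground truth).
#' @param genetic_covariance k x k PSD genetic covariance of the polygenic
#'   component, trait-SD scale.
#' @param residual_covariance_validation k x k PSD residual covariance of an
#'   individual record.
#' @param residual_covariance_discovery k x k PSD residual covariance of a
#'   discovery (progeny-mean) phenotype. Defaults to
#'   `residual_covariance_validation / n_daughters`, mimicking a bull
#'   phenotype formed as the mean deviation of `n_daughters` daughters.
#' @param n_daughters Effective number of progeny behind each discovery
#'   phenotype; only used to derive the default discovery residual.
#' @param breed_effect_matrix breeds x k matrix of fixed trait shifts.
#' @param breed_fst Balding-Nichols differentiation of per-breed allele
#'   frequencies around the base frequency (0 disables divergence).
#' @param ld_r2_50kb Target r-squared between SNPs 50 kb apart; linkage
#'   disequilibrium decays geometrically with distance.
#' @param validation_relatedness Probability that a validation haplotype is
#'   copied from a random discovery haplotype, giving the two cohorts weak,
#'   controllable genetic links.
#' @param seed Integer seed; every artifact of the generator is a pure
#'   function of the config, including this seed.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_discovery = 1000,
                       n_validation = 2000,
                       n_snps = 20000,
                       n_chromosomes = 5,
                       chrom_length_bp = 1e8,
                       maf_range = c(0.05, 0.5),
                       n_breeds = 3,
                       breed_proportions = NULL,
                       n_traits = 25,
                       qtl_specs = default_qtl_specs(n_traits),
                       genetic_covariance = ar1_covariance(n_traits, 0.3, 0.5),
                       residual_covariance_validation = ar1_covariance(n_traits, 0.7, 0.3),
                       residual_covariance_discovery = NULL,
                       n_daughters = 40,
                       breed_effect_matrix = default_breed_effects(n_breeds, n_traits),
                       breed_fst = 0.05,
                       ld_r2_50kb = 0.3,
                       validation_relatedness = 0.1,
                       seed = 1) {
  if (is.null(breed_proportions)) {
    breed_proportions <- if (n_breeds == 3) c(0.6, 0.25, 0.15) else rep(1 / n_breeds, n_breeds)
  }
  if (length(breed_proportions) != n_breeds ||
      abs(sum(breed_proportions) - 1) > 1e-8 || any(breed_proportions <= 0)) {
    abort("`breed_proportions` must be a positive vector of length `n_breeds` summing to 1.")
  }
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    abort("`maf_range` must be an increasing pair within (0, 0.5].")
  }
  check_psd(genetic_covariance, "genetic_covariance")
  check_psd(residual_covariance_validation, "residual_covariance_validation")
  if (is.null(residual_covariance_discovery)) {
    residual_covariance_discovery <- residual_covariance_validation / n_daughters
  }
  check_psd(residual_covariance_discovery, "residual_covariance_discovery")
  k <- n_traits
  if (nrow(genetic_covariance) != k || nrow(residual_covariance_validation) != k ||
      nrow(residual_covariance_discovery) != k) {
    abort("covariance matrices must be `n_traits` x `n_traits`.")
  }
  if (!is.matrix(breed_effect_matrix) || nrow(breed_effect_matrix) != n_breeds ||
      ncol(breed_effect_matrix) != k) {
    abort("`breed_effect_matrix` must be `n_breeds` x `n_traits`.")
  }
  if (length(qtl_specs) > n_snps) abort("`n_snps` must be at least the number of QTL.")
  for (q in qtl_specs) {
    if (!inherits(q, "qtl_spec")) abort("`qtl_specs` must be a list of qtl_spec objects.")
    if (length(q$effect_vector) != k) {
      abort("every `effect_vector` must have length `n_traits`.")
    }
    if (q$chrom < 1 || q$chrom > n_chromosomes) {
      abort("QTL `chrom` outside the simulated genome.")
    }
    if (q$pos_bp > chrom_length_bp) abort("QTL `pos_bp` beyond `chrom_length_bp`.")
  }
  structure(
    list(
      n_discovery = as.integer(n_discovery),
      n_validation = as.integer(n_validation),
      n_snps = as.integer(n_snps),
      n_chromosomes = as.integer(n_chromosomes),
      chrom_length_bp = as.numeric(chrom_length_bp),
      maf_range = as.numeric(maf_range),
      n_breeds = as.integer(n_breeds),
      breed_proportions = as.numeric(breed_proportions),
      n_traits = as.integer(k),
      qtl_specs = qtl_specs,
      genetic_covariance = genetic_covariance,
      residual_covariance_validation = residual_covariance_validation,
      residual_covariance_discovery = residual_covariance_discovery,
      n_daughters = as.numeric(n_daughters),
      breed_effect_matrix = breed_effect_matrix,
      breed_fst = as.numeric(breed_fst),
      ld_r2_50kb = as.numeric(ld_r2_50kb),
      validation_relatedness = as.numeric(validation_relatedness),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  discovery %d, validation %d animals; %d breeds\n",
              x$n_discovery, x$n_validation, x$n_breeds))
  cat(sprintf("  %d SNPs on %d chromosomes of %.0f bp\n",
              x$n_snps, x$n_chromosomes, x$chrom_length_bp))
  cat(sprintf("  %d traits, %d planted QTL, seed %d\n",
              x$n_traits, length(x$qtl_specs), x$seed))
  invisible(x)
}

#' Serialize or restore a simulation config
#'
#' @param config A [sim_config()] object.
#' @param path File path for the JSON key-value representation.
#' @return `write_sim_config()` returns `path` invisibly;
#'   `read_sim_config()` returns the restored `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  x$qtl_specs <- lapply(x$qtl_specs, unclass)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  qtl <- lapply(seq_len(nrow(x$qtl_specs)), function(i) {
    row <- x$qtl_specs[i, ]
    qtl_spec(row$chrom, row$pos_bp, row$effect_vector[[1]], row$maf)
  })
  sim_config(
    n_discovery = x$n_discovery, n_validation = x$n_validation,
    n_snps = x$n_snps, n_chromosomes = x$n_chromosomes,
    chrom_length_bp = x$chrom_length_bp, maf_range = x$maf_range,
    n_breeds = x$n_breeds, breed_proportions = x$breed_proportions,
    n_traits = x$n_traits, qtl_specs = qtl,
    genetic_covariance = as.matrix(x$genetic_covariance),
    residual_covariance_validation = as.matrix(x$residual_covariance_validation),
    residual_covariance_discovery = as.matrix(x$residual_covariance_discovery),
    n_daughters = x$n_daughters,
    breed_effect_matrix = as.matrix(x$breed_effect_matrix),
    breed_fst = x$breed_fst, ld_r2_50kb = x$ld_r2_50kb,
    validation_relatedness = x$validation_relatedness, seed = x$seed
  )
}
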