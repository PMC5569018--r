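#' Simulate multi-breed genotypes with linkage disequilibrium
#'
#' Draws biallelic genotypes for the discovery and validation cohorts under
#' a Gaussian-copula haplotype model: each haplotype carries a latent AR(1)
#' process along every chromosome and an allele is present wherever the
#' latent value falls below the breed-specific frequency threshold. This
#' preserves per-SNP allele frequencies exactly (so Hardy-Weinberg holds
#' within breed) while giving adjacent SNPs tunable linkage disequilibrium.
#' Per-breed frequencies diverge around the base frequency under a
#' Balding-Nichols model with differentiation `breed_fst`. A configurable
#' fraction of validation haplotypes is copied from discovery haplotypes,
#' creating the weak cross-cohort relatedness typical of a bull discovery
#' population validated in cows.
#'
#' QTL from `config$qtl_specs` are pinned to the nearest simulated SNP,
#' which takes the exact QTL position and allele frequency; the mapping is
#' returned as the `truth` tibble so downstream tests can compare detected
#' leads against planted loci.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `geno_matrix`: a list with `dosages`
#'   (animal x SNP integer matrix of alt-allele counts), `snp_map` (tibble:
#'   snp, chrom, pos_bp, allele_ref, allele_alt, base_freq), `animals`
#'   (tibble: animal_id, breed, cohort) and `truth` (tibble of planted QTL
#'   with their assigned SNP ids).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- config$n_snps
  n_chr <- config$n_chromosomes
  n_animals <- config$n_discovery + config$n_validation
  n_hap <- 2L * n_animals

  # genome layout: SNPs spread uniformly, remainder on the first chromosomes
  m_per <- rep(m %/% n_chr, n_chr) + c(rep(1L, m %% n_chr), rep(0L, n_chr - m %% n_chr))
  chrom <- rep(seq_len(n_chr), m_per)
  pos <- unlist(lapply(m_per, function(mc) sort(sample.int(config$chrom_length_bp, mc))))

  base_freq <- runif(m, config$maf_range[1], config$maf_range[2])

  # pin each QTL to the nearest SNP on its chromosome
  truth_rows <- vector("list", length(config$qtl_specs))
  qtl_idx <- integer(length(config$qtl_specs))
  for (i in seq_along(config$qtl_specs)) {
    q <- config$qtl_specs[[i]]
    on_chr <- which(chrom == q$chrom)
    j <- on_chr[which.min(abs(pos[on_chr] - q$pos_bp))]
    pos[j] <- q$pos_bp
    base_freq[j] <- q$maf
    qtl_idx[i] <- j
  }
  # re-sort in case moving a QTL position broke local order
  ord <- order(chrom, pos)
  pos <- pos[ord]; base_freq <- base_freq[ord]
  qtl_idx <- match(qtl_idx, ord)

  snp_id <- sprintf("snp_%05d", seq_len(m))
  for (i in seq_along(qtl_idx)) {
    truth_rows[[i]] <- tibble::tibble(
      qtl = i, snp = snp_id[qtl_idx[i]],
      chrom = chrom[qtl_idx[i]], pos_bp = pos[qtl_idx[i]],
      maf = base_freq[qtl_idx[i]],
      effect_vector = list(config$qtl_specs[[i]]$effect_vector)
    )
  }

  # breed-divergent allele frequencies (Balding-Nichols), common at QTL
  fst <- config$breed_fst
  freq_breed <- matrix(rep(base_freq, each = config$n_breeds), config$n_breeds, m)
  if (fst > 0 && config$n_breeds > 1) {
    a <- base_freq * (1 - fst) / fst
    b <- (1 - base_freq) * (1 - fst) / fst
    for (br in seq_len(config$n_breeds)) {
      freq_breed[br, ] <- pmin(pmax(rbeta(m, a, b), 1e-4), 1 - 1e-4)
    }
    freq_breed[, qtl_idx] <- matrix(rep(base_freq[qtl_idx], each = config$n_breeds),
                                    config$n_breeds)
  }

  breed_names <- paste0("Breed", LETTERS[seq_len(config$n_breeds)])
  breed_idx <- sample.int(config$n_breeds, n_animals, replace = TRUE,
                          prob = config$breed_proportions)
  cohort <- rep(c("discovery", "validation"),
                c(config$n_discovery, config$n_validation))

  # validation haplotypes optionally copied from discovery haplotypes
  hap_breed <- rep(breed_idx, each = 2L)
  n_hap_disc <- 2L * config$n_discovery
  copy_src <- rep(NA_integer_, n_hap)
  if (config$validation_relatedness > 0 && config$n_validation > 0) {
    val_haps <- (n_hap_disc + 1L):n_hap
    copied <- val_haps[runif(length(val_haps)) < config$validation_relatedness]
    copy_src[copied] <- sample.int(n_hap_disc, length(copied), replace = TRUE)
  }

  rho50 <- sqrt(config$ld_r2_50kb)
  dos <- matrix(0L, n_animals, m, dimnames = list(NULL, snp_id))
  odd <- seq(1L, n_hap, 2L)
  thr <- qnorm(freq_breed)

  col0 <- 0L
  for (cc in seq_len(n_chr)) {
    mc <- m_per[cc]
    cols <- col0 + seq_len(mc)
    gap <- diff(pos[cols])
    rho <- if (rho50 > 0) c(0, rho50^(gap / 5e4)) else rep(0, mc)
    # latent AR(1) per haplotype, thresholded column-wise against the
    # breed-specific frequency quantiles
    alle <- matrix(FALSE, n_hap, mc)
    thr_c <- thr[, cols, drop = FALSE]
    sc <- sqrt(1 - rho^2)
    z <- rnorm(n_hap)
    for (jj in seq_len(mc)) {
      if (jj > 1L) z <- rho[jj] * z + sc[jj] * rnorm(n_hap)
      alle[, jj] <- z < thr_c[hap_breed, jj]
    }
    copied <- which(!is.na(copy_src))
    if (length(copied)) alle[copied, ] <- alle[copy_src[copied], , drop = FALSE]
    dos[, cols] <- alle[odd, , drop = FALSE] + alle[odd + 1L, , drop = FALSE]
    col0 <- col0 + mc
  }

  structure(
    list(
      dosages = dos,
      snp_map = tibble::tibble(
        snp = snp_id, chrom = chrom, pos_bp = pos,
        allele_ref = "A", allele_alt = "C", base_freq = base_freq
      ),
      animals = tibble::tibble(
        animal_id = sprintf("an_%05d", seq_len(n_animals)),
        breed = breed_names[breed_idx],
        cohort = cohort
      ),
      truth = if (length(truth_rows)) dplyr::bind_rows(truth_rows) else
        tibble::tibble(qtl = integer(), snp = character(), chrom = integer(),
                       pos_bp = numeric(), maf = numeric(),
                       effect_vector = list())
    ),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d animals x %d SNPs, %d chromosomes, %d planted QTL\n",
              nrow(x$dosages), ncol(x$dosages),
              length(unique(x$snp_map$chrom)), nrow(x$truth)))
  invisible(x)
}

#' Subset a genotype matrix by animals and/or SNPs
#'
#' @param geno A `geno_matrix`.
#' @param animals Logical/integer index or animal ids.
#' @param snps Logical/integer index or SNP ids.
#' @return A `geno_matrix` restricted to the selection.
#' @export
subset_genotypes <- function(geno, animals = NULL, snps = NULL) {
  stopifnot(inherits(geno, "geno_matrix"))
  ai <- seq_len(nrow(geno$dosages))
  si <- seq_len(ncol(geno$dosages))
  if (!is.null(animals)) {
    ai <- if (is.character(animals)) match(animals, geno$animals$animal_id) else ai[animals]
  }
  if (!is.null(snps)) {
    si <- if (is.character(snps)) match(snps, geno$snp_map$snp) else si[snps]
  }
  out <- geno
  out$dosages <- geno$dosages[ai, si, drop = FALSE]
  out$animals <- geno$animals[ai, ]
  out$snp_map <- geno$snp_map[si, ]
  out$truth <- geno$truth[geno$truth$snp %in% out$snp_map$snp, ]
  out
}

#' Extract one cohort from a genotype matrix
#'
#' @param geno A `geno_matrix`.
#' @param cohort `"discovery"` or `"validation"`.
#' @return A `geno_matrix` for the cohort's animals.
#' @export
cohort_genotypes <- function(geno, cohort = c("discovery", "validation")) {
  cohort <- match.arg(cohort)
  subset_genotypes(geno, animals = geno$animals$cohort == cohort)
}
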