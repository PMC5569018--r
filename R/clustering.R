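#' Lead-SNP effect profiles with validation masking
#'
#' Assembles the lead SNP x trait matrix of signed t-values for one
#' phenotype set, together with the two masks used downstream: the
#' validation mask (entries whose effect direction agrees between
#' discovery and validation) and the display mask (additionally |t| >= 1),
#' mirroring how validated effects are highlighted in heatmaps.
#'
#' @param stats Discovery `summary_stats` for one set.
#' @param snp_ids Lead SNP ids (rows of the profile matrix).
#' @param concordance Optional `by_trait` tibble from
#'   [direction_concordance()]; without it every entry is treated as
#'   validated.
#' @param mask_abs_t Display-mask threshold on |t|, default 1.
#' @return Object of class `effect_profiles`: `t` (matrix), `validated`
#'   and `display` (logical matrices), `set`.
#' @export
effect_profiles <- function(stats, snp_ids, concordance = NULL, mask_abs_t = 1) {
  idx <- match(snp_ids, stats$snp_map$snp)
  if (anyNA(idx)) abort("unknown lead SNP id(s).")
  tm <- stats$tval[idx, , drop = FALSE]
  rownames(tm) <- snp_ids
  validated <- matrix(TRUE, nrow(tm), ncol(tm), dimnames = dimnames(tm))
  if (!is.null(concordance)) {
    validated[] <- FALSE
    conc <- concordance[concordance$concordant, , drop = FALSE]
    keep <- conc$snp %in% snp_ids & conc$trait %in% colnames(tm)
    conc <- conc[keep, , drop = FALSE]
    validated[cbind(match(conc$snp, rownames(tm)), match(conc$trait, colnames(tm)))] <- TRUE
  }
  structure(
    list(t = tm, validated = validated,
         display = validated & abs(tm) >= mask_abs_t, set = stats$set),
    class = "effect_profiles"
  )
}

#' Correlation of lead-SNP effect profiles
#'
#' Pearson correlation between each pair of lead SNPs over the traits
#' where both entries pass the validation mask. Pairs sharing fewer than
#' `min_shared` unmasked traits are undefined (NA); an all-masked SNP is
#' excluded with a warning.
#'
#' @param profiles An [effect_profiles()] object.
#' @param use_mask Correlate only mutually validated entries (default) or
#'   the full profiles.
#' @param min_shared Minimum unmasked traits per pair, default 3.
#' @return SNP x SNP correlation matrix (possibly with NA entries).
#' @export
effect_correlation <- function(profiles, use_mask = TRUE, min_shared = 3) {
  stopifnot(inherits(profiles, "effect_profiles"))
  tm <- profiles$t
  mask <- if (use_mask) profiles$validated else
    matrix(TRUE, nrow(tm), ncol(tm), dimnames = dimnames(tm))
  ok <- rowSums(mask) > 0
  if (!all(ok)) {
    warn(paste0("excluding all-masked lead(s): ",
                paste(rownames(tm)[!ok], collapse = ", ")))
    tm <- tm[ok, , drop = FALSE]; mask <- mask[ok, , drop = FALSE]
  }
  n <- nrow(tm)
  if (n < 2) abort("at least 2 leads required for effect correlation.")
  R <- matrix(NA_real_, n, n, dimnames = list(rownames(tm), rownames(tm)))
  diag(R) <- 1
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sh <- mask[i, ] & mask[j, ]
      if (sum(sh) >= min_shared) {
        r <- suppressWarnings(cor(tm[i, sh], tm[j, sh]))
        R[i, j] <- R[j, i] <- r
      }
    }
  }
  R
}

#' Hierarchical clustering of lead SNPs by effect correlation
#'
#' Agglomerative clustering on the distance `1 - r` with average linkage
#' (configurable). Undefined correlations are imputed as distance 1
#' (uninformative) with a warning. Flat clusters are cut at
#' `cut_height`.
#'
#' @param correlations SNP x SNP correlation matrix from
#'   [effect_correlation()].
#' @param linkage Agglomeration method passed to [hclust()].
#' @param cut_height Distance at which flat clusters are formed,
#'   default 1 (i.e. positively correlated groups).
#' @return Object of class `effect_clustering`: `hclust` (the tree),
#'   `clusters` (named integer vector), `distance` (the matrix used).
#' @export
hierarchical_cluster <- function(correlations, linkage = "average", cut_height = 1) {
  D <- 1 - correlations
  if (anyNA(D)) {
    warn("undefined effect correlations imputed as distance 1.")
    D[is.na(D)] <- 1
  }
  diag(D) <- 0
  hc <- hclust(as.dist(D), method = linkage)
  structure(
    list(hclust = hc, clusters = cutree(hc, h = cut_height), distance = D),
    class = "effect_clustering"
  )
}

#' @export
print.effect_clustering <- function(x, ...) {
  cat(sprintf("<effect_clustering> %d leads in %d flat clusters\n",
              length(x$clusters), length(unique(x$clusters))))
  invisible(x)
}

#' Export a lead-SNP dendrogram as Newick text
#'
#' @param clustering An [hierarchical_cluster()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(clustering, path) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("the 'ape' package is required for Newick export.")
  }
  phy <- ape::as.phylo(clustering$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}
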