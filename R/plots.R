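#' Manhattan plot of a multi-trait meta-analysis
#'
#' @param object A `meta_result` tibble.
#' @param p_threshold Genome-wide line, default 1e-5.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.meta_result <- function(object, p_threshold = 1e-5, ...) {
  df <- tibble::as_tibble(object)
  offs <- df |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(len = max(.data$pos_bp), .groups = "drop") |>
    dplyr::mutate(offset = dplyr::lag(cumsum(.data$len), default = 0))
  df <- dplyr::left_join(df, offs[, c("chrom", "offset")], by = "chrom")
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$pos_bp + .data$offset) / 1e6,
                                   y = -log10(.data$p_m),
                                   colour = factor(.data$chrom %% 2))) +
    ggplot2::geom_point(size = 0.4, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(p_threshold),
                        linetype = "dashed", colour = "blue") +
    ggplot2::scale_colour_manual(values = c("grey35", "steelblue")) +
    ggplot2::labs(x = "genome position (Mb)", y = expression(-log[10](p[m])),
                  title = sprintf("Multi-trait meta-analysis (%s)", object$set[1])) +
    ggplot2::theme_minimal()
}

#' Scree plot of the fitted principal components
#'
#' @param object A `transform_set`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.transform_set <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = seq_along(.data$eigenvalue),
                                   y = .data$eigenvalue)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "principal component", y = "eigenvalue",
                  title = "Variance of standardized traits by component") +
    ggplot2::theme_minimal()
}

#' Heatmap of masked lead-SNP effect profiles
#'
#' Displays the signed t-values of the lead SNPs across traits, blanking
#' entries that fail the display mask (non-validated direction or
#' |t| below the mask threshold), with rows ordered by the clustering
#' tree.
#'
#' @param object An `effect_profiles` object.
#' @param clustering Optional [hierarchical_cluster()] result for row
#'   ordering.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.effect_profiles <- function(object, clustering = NULL, ...) {
  tm <- object$t
  tm[!object$display] <- NA
  ord <- if (!is.null(clustering)) clustering$hclust$order else seq_len(nrow(tm))
  df <- tidyr::expand_grid(snp = rownames(tm)[ord], trait = colnames(tm)) |>
    dplyr::mutate(t = as.vector(t(tm[ord, , drop = FALSE])))
  df$snp <- factor(df$snp, levels = rownames(tm)[ord])
  df$trait <- factor(df$trait, levels = colnames(tm))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trait, y = .data$snp, fill = .data$t)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Lead-SNP effects (%s), validated & |t| >= mask", object$set)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
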