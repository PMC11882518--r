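#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_tile
#'   geom_segment labs theme_minimal scale_fill_gradient2 facet_wrap
#' @export
ggplot2::autoplot

#' Lollipop plot of an enrichment ranking
#'
#' Ranked miRNAs against `-log10(p)`, the standard over-representation
#' summary view.
#'
#' @param object A `mirarch_enrichment` from [mirna_set_enrichment()].
#' @param top Show at most this many top-ranked miRNAs.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mirarch_enrichment <- function(object, top = 20, ...) {
  df <- utils::head(tidy(object), top)
  df$mirna_id <- stats::reorder(df$mirna_id, -df$rank)
  ggplot(df, aes(x = -log10(.data$p_hyper), y = .data$mirna_id)) +
    geom_segment(aes(x = 0, xend = -log10(.data$p_hyper),
                     yend = .data$mirna_id), colour = "grey70") +
    geom_point(aes(size = .data$fold_enrichment), colour = "#2c7fb8") +
    labs(x = expression(-log[10](italic(p))), y = NULL,
         size = "Fold\nenrichment",
         title = "miRNA target-set enrichment ranking") +
    theme_minimal()
}

#' Per-criterion outcome plot for a hairpin filter report
#'
#' @param object A `mirarch_filter_report` from [evaluate_candidates()].
#' @param ... Unused.
#' @return A ggplot object: candidates per criterion, coloured by decision.
#' @export
autoplot.mirarch_filter_report <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$criterion, fill = .data$pass)) +
    geom_col(aes(y = 1), position = "stack", colour = "white",
             linewidth = 0.2) +
    labs(x = NULL, y = "Candidates",
         fill = "Pass", title = "Novel pre-miRNA filter outcomes") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Heatmap of row z-scores
#'
#' @param zscores Tibble from [row_zscore()] (`gene_id` + one column per
#'   library).
#' @return A ggplot tile plot, genes by libraries.
#' @export
plot_zscore_heatmap <- function(zscores) {
  df <- tidyr::pivot_longer(zscores, -"gene_id",
                            names_to = "library_id", values_to = "z")
  ggplot(df, aes(x = .data$library_id, y = .data$gene_id, fill = .data$z)) +
    geom_tile() +
    scale_fill_gradient2(low = "#313695", mid = "white", high = "#a50026") +
    labs(x = NULL, y = NULL, fill = "z-score") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Bar plot of exclusive overlap patterns
#'
#' @param overlaps Tibble from [overlap_counts()].
#' @return A ggplot object.
#' @export
plot_overlap_counts <- function(overlaps) {
  df <- dplyr::arrange(overlaps, dplyr::desc(.data$count))
  df$pattern <- factor(df$pattern, levels = df$pattern)
  ggplot(df, aes(x = .data$pattern, y = .data$count)) +
    geom_col(fill = "#2c7fb8") +
    labs(x = NULL, y = "Genes", title = "Exclusive set-membership patterns") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
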