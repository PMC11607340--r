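#' Dissimilarity score distributions by clinical group
#'
#' Violin + box plot of scaled dissimilarity scores per condition, faceted
#' by cell type when present.
#'
#' @param scores A `dissim_result` (or tibble with `cell`, `scaled`).
#' @param cells Per-cell metadata with `cell` and `condition`.
#' @return A ggplot object.
#' @export
plot_dissimilarity <- function(scores, cells) {
  df <- dplyr::inner_join(tibble::as_tibble(scores), cells, by = "cell")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$scaled,
                                        fill = .data$condition)) +
    ggplot2::geom_violin(scale = "width", alpha = 0.6) +
    ggplot2::geom_boxplot(width = 0.15, outlier.size = 0.3, fill = "white") +
    ggplot2::labs(x = NULL, y = "dissimilarity score") +
    ggplot2::theme_classic() +
    ggplot2::theme(legend.position = "none")
  if ("cell_type" %in% names(df)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$cell_type))
  }
  p
}

#' @export
autoplot.dissim_result <- function(object, cells = NULL, ...) {
  if (is.null(cells)) {
    df <- tibble::as_tibble(object)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$scaled)) +
      ggplot2::geom_histogram(bins = 40, fill = "grey40") +
      ggplot2::labs(x = "dissimilarity score", y = "cells") +
      ggplot2::theme_classic()
    if ("cell_type" %in% names(df)) {
      p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$cell_type))
    }
    return(p)
  }
  plot_dissimilarity(object, cells)
}

#' Predicted cell-state fractions per clinical group
#'
#' Bar plot of mean state fractions by group with SEM error bars.
#'
#' @param fractions Result of [state_fractions_by_group()].
#' @return A ggplot object.
#' @export
plot_state_fractions <- function(fractions) {
  pg <- fractions$per_group
  ggplot2::ggplot(pg, ggplot2::aes(x = .data$condition, y = .data$mean_fraction,
                                   fill = .data$state)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_fraction - .data$sem,
                   ymax = .data$mean_fraction + .data$sem),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2) +
    ggplot2::labs(x = NULL, y = "fraction of cells", fill = "state") +
    ggplot2::theme_classic()
}

#' Genome-wide CNV-like profiles per subpopulation
#'
#' Smoothed relative-expression profile along genome order, chromosomes
#' alternately shaded, one panel per subpopulation.
#'
#' @param profiles A `cnv_profiles` tibble from [cnv_profile()].
#' @return A ggplot object.
#' @export
plot_cnv_profile <- function(profiles) {
  df <- tibble::as_tibble(profiles)
  df$chrom_parity <- factor(as.integer(df$chromosome) %% 2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$value,
                                   colour = .data$chrom_parity)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(size = 0.3) +
    ggplot2::scale_colour_manual(values = c("grey30", "steelblue"), guide = "none") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$subpop)) +
    ggplot2::labs(x = "genome position (gene order)",
                  y = "smoothed expression deviation") +
    ggplot2::theme_classic()
}

#' Per-sample malignancy scores
#'
#' @param scores Tibble from [malignancy_scores()].
#' @return A ggplot object.
#' @export
plot_malignancy_scores <- function(scores) {
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$sample,
                                       y = .data$malignancy_score)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::labs(x = NULL, y = "malignant PC fraction of total PCs") +
    ggplot2::theme_classic() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Clonotype tracking across samples
#'
#' Frequencies of the reference's top clonotypes across samples as
#' connected lines, one per clonotype.
#'
#' @param tracking Tibble from [track_top_clonotypes()].
#' @return A ggplot object.
#' @export
plot_clonotype_tracking <- function(tracking) {
  long <- tidyr::pivot_longer(tracking, -c("cdr3aa", "rank"),
                              names_to = "sample", values_to = "freq")
  long$sample <- factor(long$sample, levels = setdiff(names(tracking),
                                                      c("cdr3aa", "rank")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$freq,
                                     group = .data$cdr3aa,
                                     colour = .data$cdr3aa)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = NULL, y = "clonotype frequency", colour = "CDR3aa") +
    ggplot2::theme_classic() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
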