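#' Cell-type compositional analysis across clinical groups
#'
#' Computes per-sample cell-type fractions after removing excluded types
#' (plasma cells and erythroid progenitors are evaluated separately in the
#' analysis design), the log2 fold-change of each patient sample's fraction
#' against the healthy-control mean fraction, and per-cell-type unpaired
#' two-sided Wilcoxon rank-sum tests of each diseased group against
#' healthy, Benjamini-Hochberg adjusted across cell types within a group.
#'
#' No pseudocount is added: a cell type absent from all healthy samples
#' gets an undefined (missing) log2FC with a warning.
#'
#' @param annotations Per-cell tibble with `sample`, `condition`,
#'   `cell_type`.
#' @param exclude Cell types removed before fractions are computed.
#' @return A list: `fractions` (sample x cell type tibble with `n`,
#'   `fraction`, `log2fc`) and `tests` (cell type x diseased-group tibble
#'   with `p`, `p_adj`).
#' @export
composition_analysis <- function(annotations, exclude = c("Plasma", "Erythroid")) {
  df <- tibble::as_tibble(annotations)
  stopifnot(all(c("sample", "condition", "cell_type") %in% names(df)))
  df <- df[!df$cell_type %in% exclude, ]
  types <- sort(unique(df$cell_type))
  counts <- dplyr::count(df, .data$sample, .data$condition, .data$cell_type)
  grid <- tidyr::expand_grid(dplyr::distinct(df, .data$sample, .data$condition),
                             cell_type = types)
  fractions <- grid |>
    dplyr::left_join(counts, by = c("sample", "condition", "cell_type")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    dplyr::group_by(.data$sample) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  healthy_mean <- fractions |>
    dplyr::filter(.data$condition == "Healthy") |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::summarise(healthy_mean = mean(.data$fraction), .groups = "drop")
  fractions <- fractions |>
    dplyr::left_join(healthy_mean, by = "cell_type") |>
    dplyr::mutate(log2fc = dplyr::if_else(
      .data$condition != "Healthy" & .data$healthy_mean > 0 & .data$fraction > 0,
      log2(.data$fraction / .data$healthy_mean),
      NA_real_))
  if (any(healthy_mean$healthy_mean == 0)) {
    warning("Cell type(s) absent from all healthy samples: log2FC reported missing.",
            call. = FALSE)
  }
  diseased <- setdiff(unique(df$condition), "Healthy")
  tests <- purrr::map_dfr(diseased, function(grp) {
    purrr::map_dfr(types, function(tp) {
      x <- fractions$fraction[fractions$condition == "Healthy" &
                                fractions$cell_type == tp]
      y <- fractions$fraction[fractions$condition == grp &
                                fractions$cell_type == tp]
      p <- if (length(x) >= 2 && length(y) >= 2) {
        suppressWarnings(stats::wilcox.test(y, x, alternative = "two.sided")$p.value)
      } else NA_real_
      tibble::tibble(cell_type = tp, group = grp, p = p)
    }) |>
      dplyr::mutate(p_adj = stats::p.adjust(.data$p, method = "BH"))
  })
  list(fractions = fractions, tests = tests)
}

#' Continuous differential-abundance score from opposing gene programs
#'
#' The module score of the upregulated program minus the module score of
#' the downregulated program, each z-scaled across all cells of the
#' analysed compartment (min-max scaling available by flag). By
#' construction the score is antisymmetric under swapping the two lists.
#'
#' @param m A log-normalized [cell_matrix()].
#' @param up_genes,down_genes Non-empty gene lists (programs up/down in
#'   differentially abundant cells).
#' @param scaling `"z"` (default) or `"minmax"`.
#' @param n_bins,n_ctrl,seed Passed to [module_score()].
#' @return A tibble `cell`, `da_score`.
#' @export
da_continuous_score <- function(m, up_genes, down_genes, scaling = c("z", "minmax"),
                                n_bins = 24, n_ctrl = 100, seed = 1L) {
  scaling <- match.arg(scaling)
  if (!length(up_genes) || !length(down_genes)) {
    stop("Both gene lists must be non-empty.", call. = FALSE)
  }
  up <- module_score(m, gene_signature("up", up_genes),
                     n_bins = n_bins, n_ctrl = n_ctrl, seed = seed)
  dn <- module_score(m, gene_signature("down", down_genes),
                     n_bins = n_bins, n_ctrl = n_ctrl, seed = seed)
  rescale <- function(v) {
    if (scaling == "z") {
      s <- stats::sd(v)
      if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
    } else {
      r <- range(v)
      if (r[1] == r[2]) rep(0, length(v)) else (v - r[1]) / (r[2] - r[1])
    }
  }
  tibble::tibble(cell = up$cell,
                 da_score = rescale(up$score) - rescale(dn$score))
}

#' Apply the differential-abundance selection threshold to external scores
#'
#' When ingesting per-cell DA measures produced by an external multiscale
#' tool, cells with a measure above `threshold` or below `-threshold` are
#' flagged as differentially abundant.
#'
#' @param da_scores Tibble with `cell` and `da_measure` columns (e.g. read
#'   from CSV).
#' @param threshold Selection threshold (default 0.95).
#' @return The tibble with a logical `differentially_abundant` column.
#' @export
apply_da_threshold <- function(da_scores, threshold = 0.95) {
  df <- tibble::as_tibble(da_scores)
  stopifnot(all(c("cell", "da_measure") %in% names(df)))
  df$differentially_abundant <- df$da_measure > threshold | df$da_measure < -threshold
  df
}
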