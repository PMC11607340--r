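#' Gene signature container
#'
#' @param name Signature name.
#' @param genes Character vector of gene symbols.
#' @param note Optional provenance note (e.g. "bulk-derived CXCR3+ module").
#' @return A `gene_signature` list.
#' @export
gene_signature <- function(name, genes, note = NULL) {
  genes <- unique(as.character(genes))
  stopifnot(length(name) == 1, length(genes) >= 1)
  structure(list(name = name, genes = genes, note = note),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> %s: %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' Shipped CD8 T-cell subset signatures
#'
#' The custom marker programs used to annotate CD8 subsets: naive,
#' effector/central memory and cytotoxic.
#'
#' @return Named list of [gene_signature()] objects.
#' @export
cd8_subset_signatures <- function() {
  list(
    naive = gene_signature("naive", c("CCR7", "TCF7", "LEF1", "SELL")),
    memory = gene_signature("memory", c("GPR183", "CCR7", "SELL", "IL7R", "CD27",
                                        "CD28", "GZMA", "CCL5", "S1PR1", "GZMK",
                                        "CXCR4", "CXCR3", "CD44")),
    cytotoxic = gene_signature("cytotoxic", c("EOMES", "TBX21", "GZMB", "PRF1",
                                              "FASLG", "GZMH", "GZMA"))
  )
}

#' Read gene-set collections from a GMT file
#'
#' @param path Path to a `.gmt` file (one set per line: name, description,
#'   genes, tab-separated).
#' @return Named list of [gene_signature()] objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(f) {
    gene_signature(f[1], f[-(1:2)], note = f[2])
  })
  stats::setNames(sets, vapply(sets, `[[`, character(1), "name"))
}

#' Binned-control gene-module score
#'
#' Per-cell score of a gene set against expression-matched controls: all
#' genes are binned into `n_bins` by average log-normalized expression; for
#' each signature gene, `n_ctrl` control genes are sampled from its bin
#' (seeded); the score is the mean expression of the signature genes minus
#' the mean expression of the pooled control genes. Matching controls by
#' expression bin makes the score invariant to adding a constant to every
#' gene and centres random signatures at zero.
#'
#' @param m A log-normalized [cell_matrix()].
#' @param sig A [gene_signature()]; genes absent from the matrix are
#'   dropped (the intersection size is recorded in the result attributes;
#'   an empty intersection is an error).
#' @param n_bins Expression bins (default 24).
#' @param n_ctrl Control genes sampled per signature gene (default 100).
#' @param seed Sampling seed.
#' @return A tibble `cell`, `score`; attributes `signature`, `n_used`,
#'   `control_genes`.
#' @export
module_score <- function(m, sig, n_bins = 24, n_ctrl = 100, seed = 1L) {
  stopifnot(inherits(m, "cell_matrix"), inherits(sig, "gene_signature"))
  ln <- logcounts_layer(m)
  used <- intersect(sig$genes, rownames(ln))
  if (!length(used)) {
    stop(sprintf("Signature '%s' shares no genes with the matrix.", sig$name),
         call. = FALSE)
  }
  avg <- Matrix::rowMeans(ln)
  n_bins <- min(n_bins, length(unique(avg)))
  bins <- if (n_bins < 2) rep(1L, length(avg)) else
    cut(rank(avg, ties.method = "first"), breaks = n_bins, labels = FALSE)
  ctrl <- withr::with_seed(seed, {
    unlist(lapply(used, function(g) {
      pool <- setdiff(which(bins == bins[match(g, rownames(ln))]),
                      match(g, rownames(ln)))
      if (!length(pool)) pool <- which(bins == bins[match(g, rownames(ln))])
      sample(pool, min(n_ctrl, length(pool)))
    }))
  })
  sig_mean <- Matrix::colMeans(ln[used, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(ln[ctrl, , drop = FALSE])
  out <- tibble::tibble(cell = colnames(ln),
                        score = as.numeric(sig_mean - ctrl_mean))
  attr(out, "signature") <- sig$name
  attr(out, "n_used") <- length(used)
  attr(out, "control_genes") <- rownames(ln)[ctrl]
  out
}

#' Module scores summarised by clinical group and predicted cell state
#'
#' Per sample x group x state mean scores; a paired two-sided Wilcoxon
#' signed-rank test compares aberrant-like against healthy-like per-sample
#' means within samples carrying both states (skipped with a notice when
#' fewer than two such samples exist). The healthy-control mean score is
#' reported as baseline.
#'
#' @param scores Tibble `cell`, `score` from [module_score()].
#' @param states Tibble `cell`, `state` (predicted cell states).
#' @param cells Per-cell metadata (`cell`, `sample`, `condition`).
#' @return A list: `summary` tibble, `healthy_baseline` (numeric), and
#'   `paired_p` (aberrant-like vs healthy-like within samples; `NA` when
#'   skipped).
#' @export
score_by_state <- function(scores, states, cells) {
  df <- tibble::as_tibble(scores) |>
    dplyr::inner_join(tibble::as_tibble(states)[, c("cell", "state")], by = "cell") |>
    dplyr::inner_join(cells, by = "cell")
  summary <- df |>
    dplyr::group_by(.data$sample, .data$condition, .data$state) |>
    dplyr::summarise(mean_score = mean(.data$score), n_cells = dplyr::n(),
                     .groups = "drop")
  healthy_baseline <- mean(df$score[df$condition == "Healthy"])
  wide <- summary |>
    dplyr::filter(.data$state %in% c("aberrant-like", "healthy-like")) |>
    tidyr::pivot_wider(id_cols = c("sample", "condition"),
                       names_from = "state", values_from = "mean_score") |>
    dplyr::filter(!is.na(.data$`aberrant-like`) & !is.na(.data$`healthy-like`))
  paired_p <- NA_real_
  if (nrow(wide) >= 2) {
    paired_p <- if (all(wide$`aberrant-like` == wide$`healthy-like`)) 1 else
      suppressWarnings(stats::wilcox.test(
        wide$`aberrant-like`, wide$`healthy-like`,
        paired = TRUE, alternative = "two.sided")$p.value)
  } else {
    message("Fewer than 2 samples with both states: paired test skipped.")
  }
  list(summary = summary, healthy_baseline = healthy_baseline,
       paired_p = paired_p)
}
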