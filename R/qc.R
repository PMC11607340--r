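#' QC filter configuration
#'
#' Thresholds for per-cell quality filtering. Two presets cover the two analysis
#' compartments: `"bm"` (whole bone marrow: 200-40,000 UMIs, 400-6,000 features,
#' fewer than 10% mitochondrial reads) and `"tcell"` (T-cell compartment:
#' 500-20,000 UMIs, 300-4,000 features, <10% mitochondrial). UMI and
#' feature bounds are inclusive; the mitochondrial bound is strict.
#'
#' @param preset `"bm"` or `"tcell"`; individual arguments override preset
#'   values.
#' @param umi_min,umi_max Inclusive total-UMI bounds.
#' @param feature_min,feature_max Inclusive detected-feature bounds.
#' @param mito_max Strict upper bound on the mitochondrial read fraction.
#' @return A `qc_config` list.
#' @export
qc_config <- function(preset = c("bm", "tcell"),
                      umi_min = NULL, umi_max = NULL,
                      feature_min = NULL, feature_max = NULL,
                      mito_max = NULL) {
  preset <- match.arg(preset)
  def <- switch(preset,
    bm = list(umi_min = 200, umi_max = 40000, feature_min = 400,
              feature_max = 6000, mito_max = 0.10),
    tcell = list(umi_min = 500, umi_max = 20000, feature_min = 300,
                 feature_max = 4000, mito_max = 0.10)
  )
  cfg <- list(
    preset = preset,
    umi_min = umi_min %||% def$umi_min,
    umi_max = umi_max %||% def$umi_max,
    feature_min = feature_min %||% def$feature_min,
    feature_max = feature_max %||% def$feature_max,
    mito_max = mito_max %||% def$mito_max
  )
  stopifnot(cfg$umi_min < cfg$umi_max, cfg$feature_min < cfg$feature_max,
            cfg$mito_max > 0, cfg$mito_max <= 1)
  structure(cfg, class = "qc_config")
}

#' Filter cells on UMI, feature and mitochondrial thresholds
#'
#' Retains cells with `umi_min <= UMI <= umi_max`,
#' `feature_min <= features <= feature_max` and mitochondrial fraction
#' strictly below `mito_max`. The attached QC report attributes each removed
#' cell to the first criterion it fails (UMI, then features, then
#' mitochondrial), so report counts sum to the number of cells removed.
#'
#' @param m A [cell_matrix()].
#' @param cfg A [qc_config()].
#' @return The filtered `cell_matrix`, with the report tibble in
#'   `attr(, "qc_report")`.
#' @export
qc_filter <- function(m, cfg = qc_config("bm")) {
  stopifnot(inherits(m, "cell_matrix"), inherits(cfg, "qc_config"))
  qc <- cell_qc_stats(m)
  fail_umi <- qc$n_umi < cfg$umi_min | qc$n_umi > cfg$umi_max
  fail_feat <- qc$n_features < cfg$feature_min | qc$n_features > cfg$feature_max
  fail_mito <- qc$mito_frac >= cfg$mito_max
  keep <- !(fail_umi | fail_feat | fail_mito)
  report <- tibble::tibble(
    criterion = c("umi", "features", "mito", "retained"),
    n_cells = c(sum(fail_umi),
                sum(fail_feat & !fail_umi),
                sum(fail_mito & !fail_umi & !fail_feat),
                sum(keep))
  )
  if (!any(keep)) warning("qc_filter removed every cell.", call. = FALSE)
  out <- subset_cells(m, cells = keep)
  attr(out, "qc_report") <- report
  out
}

#' Library-size log-normalization
#'
#' Divides each cell's counts by its total, multiplies by `scale_factor`
#' and applies `log1p` — the standard log-normalization of droplet scRNA-seq
#' counts. The per-cell total-count vector is preserved in the cell
#' metadata (`total_counts`).
#'
#' @param m A [cell_matrix()] of raw counts.
#' @param scale_factor Scale applied after library-size division (default
#'   `1e4`, the ecosystem convention).
#' @return The `cell_matrix` with a sparse `logcounts` layer added.
#' @export
log_normalize <- function(m, scale_factor = 1e4) {
  stopifnot(inherits(m, "cell_matrix"), scale_factor > 0)
  tot <- Matrix::colSums(m$counts)
  if (any(tot == 0)) {
    stop("Zero-count cell encountered; run qc_filter() first.", call. = FALSE)
  }
  ln <- m$counts %*% Matrix::Diagonal(x = scale_factor / tot)
  ln@x <- log1p(ln@x)
  dimnames(ln) <- dimnames(m$counts)
  m$logcounts <- methods::as(ln, "CsparseMatrix")
  m$cells$total_counts <- as.numeric(tot)
  m
}

#' Rank genes by dispersion of normalized expression
#'
#' Genes are ranked by the dispersion statistic variance/mean computed on
#' library-size-normalized counts (the log layer back-transformed with
#' `expm1`); for Poisson noise this is flat in the mean, so overdispersed
#' genes — planted programs, bimodal states — rise to the top. The top
#' `n_top` gene symbols are returned. Deterministic: ties are broken by
#' gene order.
#'
#' @param m A log-normalized [cell_matrix()].
#' @param n_top Number of genes to return; if it exceeds the gene count all
#'   genes are returned with a warning.
#' @return Character vector of gene symbols, most variable first.
#' @export
rank_variable_genes <- function(m, n_top = 1000) {
  ln <- logcounts_layer(m)
  nc <- ln
  nc@x <- expm1(nc@x)
  mu <- Matrix::rowMeans(nc)
  ex2 <- Matrix::rowMeans(nc^2)
  v <- (ex2 - mu^2) * ncol(nc) / max(1, ncol(nc) - 1)
  disp <- ifelse(mu > 0, v / mu, 0)
  if (n_top > length(disp)) {
    warning("`n_top` exceeds the number of genes; returning all genes.",
            call. = FALSE)
    n_top <- length(disp)
  }
  ord <- order(-disp, seq_along(disp))
  rownames(ln)[ord[seq_len(n_top)]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
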