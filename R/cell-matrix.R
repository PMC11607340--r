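#' Construct a cell matrix container
#'
#' Bundles a sparse gene x cell UMI count matrix with per-cell and per-gene
#' metadata. This is the object every stage of the pipeline consumes: QC
#' filtering, normalization, dissimilarity scoring, CNV profiling and module
#' scoring all operate on a `cell_matrix`.
#'
#' @param counts A genes x cells matrix (coerced to sparse `dgCMatrix`) of
#'   non-negative UMI counts, with gene symbols as rownames and cell barcodes
#'   as colnames.
#' @param cells A data frame of per-cell metadata, one row per column of
#'   `counts`, with at least a `cell` column matching `colnames(counts)`.
#'   Conventional columns: `sample`, `condition` (`"Healthy"`, `"ID"`,
#'   `"LTS"`), `patient`, `cell_type`.
#' @param genes A data frame of per-gene metadata, one row per row of
#'   `counts`, with at least a `gene` column matching `rownames(counts)`.
#'   Conventional columns: `chromosome` (character; `"1"`-`"22"`, `"MT"`,
#'   ...), `position` (genome-wide ordinal), `is_mito`, `is_light_chain`.
#'
#' @return A `cell_matrix` object: a list with elements `counts`, `cells`,
#'   `genes` and (after [log_normalize()]) `logcounts`.
#' @export
cell_matrix <- function(counts, cells = NULL, genes = NULL) {
  counts <- if (methods::is(counts, "sparseMatrix")) {
    methods::as(methods::as(counts, "generalMatrix"), "CsparseMatrix")
  } else {
    methods::as(Matrix::Matrix(as.matrix(counts) * 1, sparse = TRUE),
                "CsparseMatrix")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must carry gene rownames and cell colnames.", call. = FALSE)
  }
  if (any(counts@x < 0)) stop("`counts` must be non-negative.", call. = FALSE)
  if (is.null(cells)) cells <- tibble::tibble(cell = colnames(counts))
  if (is.null(genes)) genes <- tibble::tibble(gene = rownames(counts))
  cells <- tibble::as_tibble(cells)
  genes <- tibble::as_tibble(genes)
  stopifnot(nrow(cells) == ncol(counts), nrow(genes) == nrow(counts))
  if (!identical(cells$cell, colnames(counts))) {
    stop("`cells$cell` must match colnames(counts) in order.", call. = FALSE)
  }
  if (!identical(genes$gene, rownames(counts))) {
    stop("`genes$gene` must match rownames(counts) in order.", call. = FALSE)
  }
  # mark mitochondrial genes by the MT- prefix convention when no flag given
  if (!"is_mito" %in% names(genes)) genes$is_mito <- startsWith(genes$gene, "MT-")
  structure(
    list(counts = counts, cells = cells, genes = genes, logcounts = NULL),
    class = "cell_matrix"
  )
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf(
    "<cell_matrix> %d genes x %d cells%s\n",
    nrow(x$counts), ncol(x$counts),
    if (!is.null(x$logcounts)) " (log-normalized)" else ""
  ))
  extra <- setdiff(names(x$cells), "cell")
  if (length(extra)) cat("  cell metadata: ", paste(extra, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.cell_matrix <- function(x) dim(x$counts)

#' Number of cells / genes in a cell matrix
#' @param m A [cell_matrix()].
#' @return Integer count.
#' @export
n_cells <- function(m) ncol(m$counts)

#' @rdname n_cells
#' @export
n_genes <- function(m) nrow(m$counts)

#' Subset a cell matrix by cells and/or genes
#'
#' @param m A [cell_matrix()].
#' @param cells Logical, integer or character (barcode) selector of cells.
#' @param genes Logical, integer or character (symbol) selector of genes.
#' @return A `cell_matrix` restricted to the selection; metadata and any
#'   log-normalized layer are subset consistently.
#' @export
subset_cells <- function(m, cells = NULL, genes = NULL) {
  stopifnot(inherits(m, "cell_matrix"))
  ci <- if (is.null(cells)) seq_len(ncol(m$counts)) else cells
  gi <- if (is.null(genes)) seq_len(nrow(m$counts)) else genes
  if (is.character(ci)) ci <- match(ci, colnames(m$counts))
  if (is.character(gi)) gi <- match(gi, rownames(m$counts))
  out <- m
  out$counts <- m$counts[gi, ci, drop = FALSE]
  out$cells <- m$cells[if (is.logical(ci)) which(ci) else ci, , drop = FALSE]
  out$genes <- m$genes[if (is.logical(gi)) which(gi) else gi, , drop = FALSE]
  if (!is.null(m$logcounts)) out$logcounts <- m$logcounts[gi, ci, drop = FALSE]
  out
}

#' Per-cell QC statistics
#'
#' Computes total UMIs, detected features and the mitochondrial read
#' fraction for every cell, using the `is_mito` gene flag (set from the
#' `MT-` symbol prefix on import when absent).
#'
#' @param m A [cell_matrix()].
#' @return A tibble with columns `cell`, `n_umi`, `n_features`, `mito_frac`.
#' @export
cell_qc_stats <- function(m) {
  stopifnot(inherits(m, "cell_matrix"))
  tot <- Matrix::colSums(m$counts)
  nft <- Matrix::colSums(m$counts > 0)
  mito <- m$genes$is_mito
  mt <- if (any(mito)) Matrix::colSums(m$counts[mito, , drop = FALSE]) else rep(0, ncol(m$counts))
  tibble::tibble(
    cell = m$cells$cell,
    n_umi = as.numeric(tot),
    n_features = as.integer(nft),
    mito_frac = ifelse(tot > 0, mt / tot, 0)
  )
}

#' Read / write a cohort as 10x-style MTX triplets plus metadata CSVs
#'
#' `write_cell_matrix()` writes `matrix.mtx`, `features.tsv`, `barcodes.tsv`
#' plus `cells.csv` and `genes.csv`; `read_cell_matrix()` reads them back.
#'
#' @param m A [cell_matrix()].
#' @param dir Directory to write to / read from.
#' @return `read_cell_matrix()` returns a [cell_matrix()];
#'   `write_cell_matrix()` returns `dir` invisibly.
#' @export
write_cell_matrix <- function(m, dir) {
  stopifnot(inherits(m, "cell_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(m$counts, file.path(dir, "matrix.mtx"))
  readr::write_tsv(tibble::tibble(gene = m$genes$gene), file.path(dir, "features.tsv"),
                   col_names = FALSE)
  readr::write_tsv(tibble::tibble(cell = m$cells$cell), file.path(dir, "barcodes.tsv"),
                   col_names = FALSE)
  readr::write_csv(m$cells, file.path(dir, "cells.csv"))
  readr::write_csv(m$genes, file.path(dir, "genes.csv"))
  invisible(dir)
}

#' @rdname write_cell_matrix
#' @export
read_cell_matrix <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  feats <- readr::read_tsv(file.path(dir, "features.tsv"), col_names = "gene",
                           show_col_types = FALSE)
  bars <- readr::read_tsv(file.path(dir, "barcodes.tsv"), col_names = "cell",
                          show_col_types = FALSE)
  rownames(counts) <- feats$gene
  colnames(counts) <- bars$cell
  cells_path <- file.path(dir, "cells.csv")
  genes_path <- file.path(dir, "genes.csv")
  cells <- if (file.exists(cells_path)) readr::read_csv(cells_path, show_col_types = FALSE) else NULL
  genes <- if (file.exists(genes_path)) readr::read_csv(genes_path, show_col_types = FALSE) else NULL
  cell_matrix(counts, cells = cells, genes = genes)
}

# internal: the normalized layer, failing loudly if absent
logcounts_layer <- function(m) {
  if (is.null(m$logcounts)) {
    stop("cell_matrix has no log-normalized layer; run log_normalize() first.",
         call. = FALSE)
  }
  m$logcounts
}
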