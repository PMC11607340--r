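#' Dissimilarity scoring configuration
#'
#' Parameters of the per-cell dissimilarity score: each cell's k-nearest
#' reference neighbours are counted by condition in a PCA embedding, the
#' reference being a balanced subsample of the baseline ("Healthy") and
#' perturbed ("ID") conditions, iterated with changing seeds.
#'
#' @param k Neighbour count (default 30).
#' @param n_iterations Balanced-subsampling iterations (default 100).
#' @param n_dims Embedding dimensionality (default 20).
#' @param reference Ordered pair `(baseline, perturbed)` of condition
#'   labels; all other conditions (e.g. `"LTS"`) are scored as queries only.
#' @param master_seed Iteration `t` uses seed `master_seed + t`.
#' @return A `dissim_config` list.
#' @export
dissim_config <- function(k = 30, n_iterations = 100, n_dims = 20,
                          reference = c("Healthy", "ID"), master_seed = 1L) {
  stopifnot(k >= 1, n_iterations >= 1, n_dims >= 1,
            length(reference) == 2, reference[1] != reference[2])
  structure(list(k = as.integer(k), n_iterations = as.integer(n_iterations),
                 n_dims = as.integer(n_dims), reference = reference,
                 master_seed = as.integer(master_seed)),
            class = "dissim_config")
}

#' PCA embedding of a cell population
#'
#' Centers and unit-scales the top variable genes across cells (values
#' clipped at +/-10), then computes deterministic principal-component
#' coordinates with a fixed sign convention (the largest-magnitude loading
#' of each component is positive).
#'
#' @param m A log-normalized [cell_matrix()], typically restricted to one
#'   cell type.
#' @param n_dims Number of components; reduced with a warning when the
#'   population is too small.
#' @param n_variable Number of variable genes used (see
#'   [rank_variable_genes()]).
#' @return A cells x `n_dims` coordinate matrix with cell barcodes as
#'   rownames.
#' @export
embed_cells <- function(m, n_dims = 20, n_variable = 1000) {
  ln <- logcounts_layer(m)
  genes <- rank_variable_genes(m, min(n_variable, nrow(ln)))
  x <- t(as.matrix(ln[genes, , drop = FALSE]))
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0] <- 1 # constant genes stay centered at zero
  x <- sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
  x[x > 10] <- 10
  x[x < -10] <- -10
  max_dims <- min(nrow(x) - 1L, ncol(x))
  if (n_dims > max_dims) {
    warning(sprintf("n_dims reduced from %d to %d (population size).",
                    n_dims, max_dims), call. = FALSE)
    n_dims <- max_dims
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_dims)
  coords <- pc$x[, seq_len(n_dims), drop = FALSE]
  for (j in seq_len(ncol(coords))) {
    piv <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[piv, j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- colnames(ln)
  coords
}

#' Per-cell dissimilarity to the healthy reference
#'
#' For every iteration `t` (seed `master_seed + t`), both reference
#' conditions are subsampled to the smaller group's size to form a balanced
#' reference set; every cell (all conditions) is scored as the fraction of
#' its `k` nearest reference neighbours (Euclidean, self excluded, distance
#' ties broken by lowest cell index) that carry the perturbed condition.
#' Each cell gets the median over iterations, min-max scaled to `[0, 1]`
#' across all scored cells of the population.
#'
#' @param coords Cells x dims embedding (see [embed_cells()]).
#' @param conditions Condition label per row of `coords`.
#' @param cfg A [dissim_config()].
#' @param cell_type Optional population name used in error messages and the
#'   result.
#' @return A `dissim_result` tibble: `cell`, `raw_median` (median
#'   neighbour fraction), `scaled` (in `[0, 1]`), `n_scored`; scaling
#'   bounds in `attr(, "scaling")`.
#' @export
dissimilarity_scores <- function(coords, conditions, cfg = dissim_config(),
                                 cell_type = NULL) {
  stopifnot(is.matrix(coords), length(conditions) == nrow(coords))
  i0 <- cfg$reference[1]; i1 <- cfg$reference[2]
  idx0 <- which(conditions == i0)
  idx1 <- which(conditions == i1)
  if (!length(idx0) || !length(idx1)) {
    stop("Both reference conditions must be present.", call. = FALSE)
  }
  n_ref_each <- min(length(idx0), length(idx1))
  if (2L * n_ref_each < cfg$k + 1L) {
    stop(sprintf("Reference set (%d cells%s) smaller than k + 1 = %d.",
                 2L * n_ref_each,
                 if (is.null(cell_type)) "" else paste0(" for cell type ", cell_type),
                 cfg$k + 1L), call. = FALSE)
  }
  n <- nrow(coords)
  q2 <- rowSums(coords^2)
  raw <- matrix(NA_real_, n, cfg$n_iterations)
  for (t in seq_len(cfg$n_iterations)) {
    sub <- withr::with_seed(cfg$master_seed + t, {
      c(sample(idx0, n_ref_each), sample(idx1, n_ref_each))
    })
    ref <- sort(sub)                      # column order = cell-index order
    is_pert <- conditions[ref] == i1
    rc <- coords[ref, , drop = FALSE]
    d2 <- outer(q2, rowSums(rc^2), "+") - 2 * coords %*% t(rc)
    self <- match(seq_len(n), ref)        # exclude self-matches
    has_self <- which(!is.na(self))
    d2[cbind(has_self, self[has_self])] <- Inf
    k <- cfg$k
    raw[, t] <- vapply(seq_len(n), function(q) {
      nb <- order(d2[q, ], method = "radix")[seq_len(k)]
      sum(is_pert[nb]) / k
    }, numeric(1))
  }
  med <- apply(raw, 1, stats::median)
  lo <- min(med); hi <- max(med)
  scaled <- if (hi > lo) (med - lo) / (hi - lo) else rep(0, n)
  out <- tibble::tibble(
    cell = rownames(coords) %||% as.character(seq_len(n)),
    raw_median = med,
    scaled = scaled,
    n_scored = cfg$n_iterations
  )
  if (!is.null(cell_type)) out$cell_type <- cell_type
  attr(out, "scaling") <- c(min = lo, max = hi)
  attr(out, "config") <- cfg
  class(out) <- c("dissim_result", class(out))
  out
}

#' Run embedding + dissimilarity scoring per cell type
#'
#' Convenience pipeline: for each cell type of a log-normalized
#' [cell_matrix()], embeds the population ([embed_cells()]) and computes
#' dissimilarity scores ([dissimilarity_scores()]), returning one combined
#' tibble. The analysis is per cell type to keep the neighbourhoods free of
#' between-type transcriptional differences.
#'
#' @param m A log-normalized [cell_matrix()] with `condition` and
#'   `cell_type` cell metadata.
#' @param cfg A [dissim_config()].
#' @param n_variable Variable genes per population for the embedding.
#' @param cell_types Cell types to score (default: all present).
#' @return A `dissim_result` tibble over all scored cells with a
#'   `cell_type` column.
#' @export
dissimilarity_by_celltype <- function(m, cfg = dissim_config(),
                                      n_variable = 1000, cell_types = NULL) {
  stopifnot(inherits(m, "cell_matrix"))
  types <- cell_types %||% unique(m$cells$cell_type)
  res <- purrr::map(types, function(tp) {
    sub <- subset_cells(m, cells = m$cells$cell_type == tp)
    coords <- embed_cells(sub, n_dims = cfg$n_dims, n_variable = n_variable)
    dissimilarity_scores(coords, sub$cells$condition, cfg, cell_type = tp)
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("dissim_result", class(out))
  out
}

#' Per-sample score summaries and group tests
#'
#' Summarises scaled dissimilarity scores per sample and tests clinical
#' groups: unpaired two-sided Wilcoxon rank-sum for Healthy-vs-ID and
#' Healthy-vs-LTS, paired two-sided Wilcoxon signed-rank for ID-vs-LTS on
#' per-sample means (matched by patient), Benjamini-Hochberg adjusted
#' across the three tests. Groups with fewer than two samples are skipped
#' with a message.
#'
#' @param scores A tibble with a `scaled` column (e.g. a `dissim_result`).
#' @param cells Per-cell metadata with `cell`, `sample`, `condition`,
#'   `patient`, joined onto `scores` by `cell`.
#' @return A list with `sample_means` (tibble) and `tests` (tibble:
#'   comparison, paired flag, p, p_adj).
#' @export
score_distribution_summary <- function(scores, cells) {
  df <- dplyr::inner_join(tibble::as_tibble(scores)[, c("cell", "scaled")],
                          cells, by = "cell")
  if (!"patient" %in% names(df)) df$patient <- NA_character_
  sm <- df |>
    dplyr::group_by(.data$sample, .data$condition, .data$patient) |>
    dplyr::summarise(mean_score = mean(.data$scaled), n_cells = dplyr::n(),
                     .groups = "drop")
  get <- function(cond) sm$mean_score[sm$condition == cond]
  test_row <- function(a, b, paired) {
    x <- get(a); y <- get(b)
    if (paired) {
      pa <- sm[sm$condition == a, c("patient", "mean_score")]
      pb <- sm[sm$condition == b, c("patient", "mean_score")]
      both <- dplyr::inner_join(pa, pb, by = "patient", suffix = c("_a", "_b"))
      x <- both$mean_score_a; y <- both$mean_score_b
    }
    if (length(x) < 2 || length(y) < 2) {
      message(sprintf("Skipping %s vs %s: fewer than 2 samples per group.", a, b))
      return(NA_real_)
    }
    if (paired && all(x == y)) return(1) # no paired differences at all
    suppressWarnings(stats::wilcox.test(x, y, paired = paired,
                                        alternative = "two.sided")$p.value)
  }
  tests <- tibble::tibble(
    comparison = c("Healthy vs ID", "Healthy vs LTS", "ID vs LTS"),
    paired = c(FALSE, FALSE, TRUE),
    p = c(test_row("Healthy", "ID", FALSE),
          test_row("Healthy", "LTS", FALSE),
          test_row("ID", "LTS", TRUE))
  )
  tests$p_adj <- stats::p.adjust(tests$p, method = "BH")
  list(sample_means = sm, tests = tests)
}

#' @export
tidy.dissim_result <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- class(tibble::tibble())
  out
}

#' @export
glance.dissim_result <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x),
    n_cell_types = if ("cell_type" %in% names(x)) length(unique(x$cell_type)) else 1L,
    mean_raw = mean(x$raw_median),
    mean_scaled = mean(x$scaled)
  )
}
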