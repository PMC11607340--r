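#' Rule-based T-cell lineage gating
#'
#' Applies the fixed gating rules on normalized expression:
#' \itemize{
#'   \item CD4:  `CD4 > 1.5 & CD8A == 0 & CD8B == 0 & TRDC == 0`
#'   \item CD8:  `(CD8A > 1.5 | CD8B > 1.5) & CD4 == 0 & TRDC == 0`
#'   \item gdT:  `TRDC > 1.5 & CD8A == 0 & CD8B == 0 & CD4 == 0`
#' }
#' `== 0` means exactly zero normalized expression (zero counts). The three
#' rules are mutually exclusive by construction; cells matching none are
#' `unassigned`.
#'
#' @param m A log-normalized [cell_matrix()] containing CD4, CD8A, CD8B and
#'   TRDC.
#' @return A tibble `cell`, `lineage` with lineage in
#'   `{"CD4", "CD8", "gdT", "unassigned"}`.
#' @export
gate_tcells <- function(m) {
  ln <- logcounts_layer(m)
  need <- c("CD4", "CD8A", "CD8B", "TRDC")
  missing <- setdiff(need, rownames(ln))
  if (length(missing)) {
    stop("Required gating gene(s) missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  e <- as.matrix(ln[need, , drop = FALSE])
  cd4 <- e["CD4", ]; cd8a <- e["CD8A", ]; cd8b <- e["CD8B", ]; trdc <- e["TRDC", ]
  lineage <- dplyr::case_when(
    cd4 > 1.5 & cd8a == 0 & cd8b == 0 & trdc == 0 ~ "CD4",
    (cd8a > 1.5 | cd8b > 1.5) & cd4 == 0 & trdc == 0 ~ "CD8",
    trdc > 1.5 & cd8a == 0 & cd8b == 0 & cd4 == 0 ~ "gdT",
    .default = "unassigned"
  )
  tibble::tibble(cell = colnames(ln), lineage = lineage)
}

#' Annotate CD8 clusters by signature module scores
#'
#' Each supplied cluster is assigned the signature with the highest mean
#' module score across its cells; a cluster whose mean KLRB1 expression
#' exceeds every other cluster's by at least `klrb1_margin` is labeled
#' `"KLRB1+"` regardless. Empty clusters are skipped.
#'
#' @param m A log-normalized [cell_matrix()] of CD8 cells.
#' @param clusters Named vector (names = barcodes) or vector aligned with
#'   cells: cluster label per cell.
#' @param signatures List of [gene_signature()]s (default
#'   [cd8_subset_signatures()]).
#' @param klrb1_margin KLRB1 override: a cluster is KLRB1+ when its mean
#'   KLRB1 expression is at least this multiple of the next-highest
#'   cluster's (default 2).
#' @param n_bins,n_ctrl,seed Passed to [module_score()].
#' @return A tibble `cluster`, `subset`, `mean_klrb1`.
#' @export
annotate_cd8_clusters <- function(m, clusters, signatures = cd8_subset_signatures(),
                                  klrb1_margin = 2, n_bins = 24, n_ctrl = 100,
                                  seed = 1L) {
  ln <- logcounts_layer(m)
  if (is.null(names(clusters))) names(clusters) <- colnames(ln)
  clusters <- clusters[colnames(ln)]
  scores <- purrr::map(signatures, function(s) {
    module_score(m, s, n_bins = n_bins, n_ctrl = n_ctrl, seed = seed)$score
  })
  klrb1 <- if ("KLRB1" %in% rownames(ln)) as.numeric(ln["KLRB1", ]) else
    rep(0, ncol(ln))
  labs <- sort(unique(stats::na.omit(as.character(clusters))))
  per_cluster <- purrr::map_dfr(labs, function(cl) {
    ix <- which(clusters == cl)
    if (!length(ix)) return(NULL)
    mean_scores <- vapply(scores, function(v) mean(v[ix]), numeric(1))
    tibble::tibble(cluster = cl,
                   subset = names(signatures)[which.max(mean_scores)],
                   mean_klrb1 = mean(klrb1[ix]))
  })
  if (nrow(per_cluster) > 1) {
    top <- which.max(per_cluster$mean_klrb1)
    next_best <- max(per_cluster$mean_klrb1[-top])
    if (per_cluster$mean_klrb1[top] >= klrb1_margin * next_best &&
        per_cluster$mean_klrb1[top] > 0) {
      per_cluster$subset[top] <- "KLRB1+"
    }
  }
  per_cluster
}
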