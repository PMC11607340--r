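#' Read / write clonotype tables
#'
#' Clonotype TSVs carry columns `cdr3aa`, `v_gene`, `j_gene`, `count`; the
#' clonotype key is the CDR3 amino-acid sequence (V/J-aware keying by
#' flag in the metric functions). Frequencies are recomputed from counts on
#' read.
#'
#' @param path TSV path.
#' @param sample Sample ID attached to the table (defaults to the file
#'   name).
#' @return A tibble `sample`, `cdr3aa`, `v_gene`, `j_gene`, `count`,
#'   `freq`.
#' @export
read_repertoire <- function(path, sample = NULL) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("cdr3aa", "count") %in% names(tab)))
  tab$sample <- sample %||% sub("\\.tsv$", "", basename(path))
  tab$freq <- tab$count / sum(tab$count)
  dplyr::relocate(tab, "sample")
}

#' @rdname read_repertoire
#' @param r A repertoire tibble.
#' @export
write_repertoire <- function(r, path) {
  readr::write_tsv(r[, intersect(c("cdr3aa", "v_gene", "j_gene", "count"),
                                 names(r))], path)
  invisible(path)
}

rep_keys <- function(r, by_vj = FALSE) {
  if (by_vj) paste(r$cdr3aa, r$v_gene, r$j_gene, sep = "|") else r$cdr3aa
}

rep_freqs <- function(r) {
  f <- if ("freq" %in% names(r)) r$freq else r$count / sum(r$count)
  if (any(f == 0)) {
    warning("Zero-frequency clonotype records dropped.", call. = FALSE)
    f <- f[f > 0]
  }
  f / sum(f)
}

#' TCR repertoire clonality
#'
#' `1 - H / ln(S)` where `H` is the Shannon-Wiener entropy of the clonotype
#' frequencies and `S` the clonotype count: 0 for a perfectly even
#' repertoire, 1 for a monoclonal one (the `S = 1` case is defined as 1).
#'
#' @param r A repertoire tibble (columns `cdr3aa`, `count` and/or `freq`).
#' @return Clonality in `[0, 1]`.
#' @export
clonality <- function(r) {
  f <- rep_freqs(r)
  s <- length(f)
  if (s == 0) stop("Empty repertoire.", call. = FALSE)
  if (s == 1) return(1)
  h <- -sum(f * log(f))
  1 - h / log(s)
}

#' Pairwise Jaccard overlap of repertoires
#'
#' `J(A, B) = |keys(A) \cap keys(B)| / |keys(A) \cup keys(B)|` on clonotype
#' key sets (CDR3 amino-acid sequence by default), diagonal 1. An empty
#' repertoire has overlap 0 with any non-identical sample (warning).
#'
#' @param rs Named list of repertoire tibbles.
#' @param by_vj Key clonotypes by CDR3aa + V + J instead of CDR3aa alone.
#' @return A symmetric named matrix of Jaccard indices.
#' @export
jaccard_matrix <- function(rs, by_vj = FALSE) {
  stopifnot(length(rs) >= 2)
  keys <- lapply(rs, rep_keys, by_vj = by_vj)
  if (any(lengths(keys) == 0)) {
    warning("Empty repertoire(s): Jaccard defined as 0 against them.",
            call. = FALSE)
  }
  n <- length(keys)
  J <- matrix(0, n, n, dimnames = list(names(rs), names(rs)))
  for (i in seq_len(n)) {
    J[i, i] <- 1
    for (j in seq_len(i - 1)) {
      u <- length(union(keys[[i]], keys[[j]]))
      J[i, j] <- J[j, i] <- if (u == 0) 0 else
        length(intersect(keys[[i]], keys[[j]])) / u
    }
  }
  J
}

#' Hierarchical clustering of repertoires by overlap
#'
#' Agglomerative clustering (complete linkage) on the distance `1 - J`;
#' leaf order is deterministic given the input order.
#'
#' @param J A Jaccard matrix from [jaccard_matrix()].
#' @return An `hclust` object.
#' @export
cluster_repertoires <- function(J) {
  if (nrow(J) < 2) stop("Need at least 2 samples to cluster.", call. = FALSE)
  stats::hclust(stats::as.dist(1 - J), method = "complete")
}

#' Export a repertoire dendrogram as Newick
#'
#' @param hc An `hclust` from [cluster_repertoires()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Track the reference sample's top clonotypes across samples
#'
#' The `n` most abundant CDR3aa keys of the reference repertoire (ties at
#' the boundary broken lexicographically), with each key's frequency in
#' every sample (0 when absent).
#'
#' @param reference The reference repertoire tibble.
#' @param others Named list of repertoire tibbles to track into.
#' @param n Number of top clonotypes (default 10).
#' @return A tibble `cdr3aa`, `rank`, then one frequency column per sample
#'   (reference first).
#' @export
track_top_clonotypes <- function(reference, others, n = 10) {
  stopifnot(n <= nrow(reference))
  ref <- reference
  ref$freq <- ref$count / sum(ref$count)
  ord <- order(-ref$freq, ref$cdr3aa)
  top <- ref$cdr3aa[ord[seq_len(n)]]
  ref_name <- ref$sample[1] %||% "reference"
  freq_in <- function(r) {
    f <- r$count / sum(r$count)
    out <- f[match(top, r$cdr3aa)]
    dplyr::coalesce(out, 0)
  }
  out <- tibble::tibble(cdr3aa = top, rank = seq_len(n))
  out[[ref_name]] <- freq_in(ref)
  for (nm in names(others)) out[[nm]] <- freq_in(others[[nm]])
  out
}
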