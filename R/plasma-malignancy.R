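#' Genome gene order for CNV profiling
#'
#' Restricts a gene table to chromosomes 1-22, drops genes whose symbol
#' starts with IGH, IGL or IGK (their differential expression in plasma
#' cells would mimic copy-number signal), derives a p/q arm from the
#' position halves when absent, and orders genes along the genome.
#'
#' @param genes A tibble with `gene`, `chromosome` (character) and
#'   `position` (genome-wide ordinal), e.g. the `genes` table of a
#'   [cell_matrix()] or a `genes.csv`.
#' @return An ordered tibble `gene`, `chromosome`, `arm`, `position`.
#' @export
genome_order <- function(genes) {
  g <- tibble::as_tibble(genes)
  stopifnot(all(c("gene", "chromosome", "position") %in% names(g)))
  g <- g[g$chromosome %in% as.character(1:22), ]
  g <- g[!grepl("^IG[HLK]", g$gene), ]
  g <- g[order(as.integer(g$chromosome), g$position), ]
  if (!"arm" %in% names(g) || all(is.na(g$arm))) {
    g$arm <- unlist(lapply(split(seq_len(nrow(g)), as.integer(g$chromosome)),
                           function(ix) {
                             half <- ceiling(length(ix) / 2)
                             rep(c("p", "q"), c(half, length(ix) - half))
                           }), use.names = FALSE)
  }
  stopifnot(!anyDuplicated(g$position))
  g[, c("gene", "chromosome", "arm", "position")]
}

# centered moving average per chromosome; the half-window shrinks
# symmetrically at chromosome boundaries, never crossing chromosomes
smooth_by_chromosome <- function(values, chromosome, window) {
  half <- (window - 1) %/% 2
  out <- numeric(length(values))
  for (ix in split(seq_along(values), factor(chromosome, unique(chromosome)))) {
    v <- values[ix]
    n <- length(v)
    cs <- cumsum(c(0, v))
    i <- seq_len(n)
    h <- pmin(half, i - 1L, n - i)
    out[ix] <- (cs[i + h + 1L] - cs[i - h]) / (2 * h + 1)
  }
  out
}

#' Genome-windowed relative expression profiles per subpopulation
#'
#' A simplified copy-number surrogate: per gene, the difference between a
#' query subpopulation's mean log-normalized expression and the healthy
#' reference mean, smoothed along genome order by a centered moving average
#' within each chromosome. Contiguous stretches of elevated (depleted)
#' profile mark candidate copy-number gains (losses).
#'
#' @param m A log-normalized [cell_matrix()] of plasma cells.
#' @param subpops Named character vector: subpopulation ID per query cell
#'   (names are cell barcodes); see [plasma_subpopulations()]. Query cells
#'   must be disjoint from the reference.
#' @param reference_cells Barcodes of healthy reference plasma cells.
#' @param window Moving-average window in genes (odd; default 51). Windows
#'   larger than a chromosome shrink to it with a warning.
#' @return A `cnv_profiles` tibble: `subpop`, `gene`, `chromosome`, `arm`,
#'   `position`, `value`.
#' @export
cnv_profile <- function(m, subpops, reference_cells, window = 51) {
  stopifnot(inherits(m, "cell_matrix"), window >= 1)
  ln <- logcounts_layer(m)
  ord <- genome_order(m$genes)
  if (any(names(subpops) %in% reference_cells)) {
    stop("Query cells must be disjoint from the reference.", call. = FALSE)
  }
  chrom_sizes <- table(ord$chromosome)
  if (window > min(chrom_sizes)) {
    warning(sprintf(
      "window (%d) exceeds the smallest chromosome (%d genes); shrunk per chromosome.",
      window, min(chrom_sizes)), call. = FALSE)
  }
  lnq <- ln[ord$gene, , drop = FALSE]
  ref_mean <- Matrix::rowMeans(lnq[, reference_cells, drop = FALSE])
  profs <- purrr::map(split(names(subpops), subpops), function(cl) {
    delta <- Matrix::rowMeans(lnq[, cl, drop = FALSE]) - ref_mean
    smooth_by_chromosome(delta, ord$chromosome, window)
  })
  out <- purrr::imap(profs, function(v, nm) {
    tibble::tibble(subpop = nm, gene = ord$gene, chromosome = ord$chromosome,
                   arm = ord$arm, position = ord$position, value = v)
  }) |> dplyr::bind_rows()
  attr(out, "window") <- window
  class(out) <- c("cnv_profiles", class(out))
  out
}

#' Detect plasma-cell subpopulations from CNV-like signal
#'
#' Automates the subclustering step upstream of malignancy calling. Per
#' patient (pooling that patient's samples, as per-patient CNV inference
#' workflows do): (1) the patient-vs-reference windowed profile is computed and
#' chromosome arms whose mean deviation exceeds `candidate_cutoff` are
#' flagged; (2) if any, each cell is scored by a matched filter — the
#' projection of its per-gene deviation onto the patient profile over the
#' candidate arms — and the scores are split by exact 1-D 2-means; cells
#' of healthy-sample donors or patients without candidate arms form a
#' single subpopulation.
#'
#' @param m A log-normalized [cell_matrix()] of plasma cells (reference
#'   included).
#' @param reference_cells Barcodes of the healthy reference plasma cells.
#' @param window Smoothing window (see [cnv_profile()]).
#' @param candidate_cutoff Arm-mean deviation flagging candidate arms
#'   (default half the calling cutoff of [call_subpopulations()]).
#' @return Named character vector: subpopulation ID (`"<group>.1"`,
#'   `"<group>.2"`) per non-reference cell.
#' @export
plasma_subpopulations <- function(m, reference_cells, window = 51,
                                  candidate_cutoff = 0.075) {
  stopifnot(inherits(m, "cell_matrix"))
  ln <- logcounts_layer(m)
  ord <- genome_order(m$genes)
  lnq <- as.matrix(ln[ord$gene, , drop = FALSE])
  ref_mean <- rowMeans(lnq[, reference_cells, drop = FALSE])
  query <- setdiff(colnames(lnq), reference_cells)
  meta <- m$cells[match(query, m$cells$cell), ]
  group <- ifelse(is.na(meta$patient), meta$sample, meta$patient)
  arm_key <- paste(ord$chromosome, ord$arm)
  out <- character(0)
  for (g in unique(group)) {
    cl <- query[group == g]
    delta_mean <- rowMeans(lnq[, cl, drop = FALSE]) - ref_mean
    prof <- smooth_by_chromosome(delta_mean, ord$chromosome, window)
    arm_means <- tapply(prof, arm_key, mean)
    cand_arms <- names(arm_means)[abs(arm_means) > candidate_cutoff]
    if (!length(cand_arms) || length(cl) < 4) {
      ids <- stats::setNames(rep(paste0(g, ".1"), length(cl)), cl)
    } else {
      sel <- arm_key %in% cand_arms
      w <- prof[sel]
      w <- w / sqrt(sum(w^2))
      score <- as.numeric(crossprod(lnq[sel, cl, drop = FALSE] - ref_mean[sel], w))
      cluster <- split_1d_2means(score)
      # subpop 1 = the cluster nearer the reference (lower mean |score|)
      m1 <- abs(mean(score[cluster == 1])); m2 <- abs(mean(score[cluster == 2]))
      if (m2 < m1) cluster <- 3L - cluster
      ids <- stats::setNames(paste0(g, ".", cluster), cl)
    }
    out <- c(out, ids)
  }
  out[query]
}

# exact 1-D 2-means: scan all split points of the sorted values and pick
# the one minimising within-cluster sum of squares; deterministic
split_1d_2means <- function(x) {
  n <- length(x)
  o <- order(x, seq_len(n))
  xs <- x[o]
  cs <- cumsum(xs); cs2 <- cumsum(xs^2)
  i <- seq_len(n - 1)
  ss_left <- cs2[i] - cs[i]^2 / i
  ss_right <- (cs2[n] - cs2[i]) - (cs[n] - cs[i])^2 / (n - i)
  cut <- which.min(ss_left + ss_right)
  cl <- integer(n)
  cl[o] <- rep(1:2, c(cut, n - cut))
  cl
}

#' Call subpopulations malignant, healthy or unclear
#'
#' A subpopulation is malignant when any chromosome-arm mean of its profile
#' deviates from zero by more than `cutoff`, healthy when all arms stay
#' below, and unclear when its maximal arm deviation lies within `margin`
#' of the cutoff.
#'
#' @param profiles A `cnv_profiles` tibble from [cnv_profile()].
#' @param cutoff Arm-mean deviation cutoff on the log-normalized scale
#'   (default 0.15).
#' @param margin Half-width of the unclear band around the cutoff (default
#'   20% of the cutoff).
#' @return A tibble `subpop`, `max_abs_arm`, `call`; per-arm means in
#'   `attr(, "arm_means")`.
#' @export
call_subpopulations <- function(profiles, cutoff = 0.15, margin = 0.2 * cutoff) {
  arm_means <- profiles |>
    dplyr::group_by(.data$subpop, .data$chromosome, .data$arm) |>
    dplyr::summarise(arm_mean = mean(.data$value), .groups = "drop")
  calls <- arm_means |>
    dplyr::group_by(.data$subpop) |>
    dplyr::summarise(max_abs_arm = max(abs(.data$arm_mean)), .groups = "drop") |>
    dplyr::mutate(call = dplyr::case_when(
      abs(.data$max_abs_arm - cutoff) <= margin ~ "unclear",
      .data$max_abs_arm > cutoff ~ "malignant",
      .default = "healthy"
    ))
  attr(calls, "arm_means") <- arm_means
  calls
}

#' Assemble per-cell plasma calls
#'
#' Joins subpopulation-level calls back onto cells, yielding the per-cell
#' call table that light-chain refinement and malignancy scoring consume.
#'
#' @param m The plasma [cell_matrix()] (for cell metadata).
#' @param subpops Named subpopulation vector from [plasma_subpopulations()].
#' @param calls Subpopulation calls from [call_subpopulations()].
#' @return A `plasma_calls` tibble: `cell`, `sample`, `condition`,
#'   `patient`, `subpop`, `call`, `refined` (all `FALSE` initially).
#' @export
plasma_calls <- function(m, subpops, calls) {
  meta <- m$cells[match(names(subpops), m$cells$cell), ]
  out <- tibble::tibble(
    cell = names(subpops),
    sample = meta$sample,
    condition = meta$condition,
    patient = meta$patient,
    subpop = unname(subpops)
  ) |>
    dplyr::left_join(calls[, c("subpop", "call")], by = "subpop") |>
    dplyr::mutate(refined = FALSE)
  class(out) <- c("plasma_calls", class(out))
  out
}

#' Patient-wise major immunoglobulin light chain
#'
#' For each patient with at least one malignant cell, the light-chain gene
#' (IGKC, IGLC1-IGLC7) with the highest mean log-normalized expression
#' among that patient's malignant cells. Ties are broken by the fixed gene
#' order with a warning.
#'
#' @param m The plasma [cell_matrix()] (log-normalized).
#' @param calls A `plasma_calls` tibble.
#' @return A tibble `patient`, `major_chain`; patients without malignant
#'   cells are omitted.
#' @export
major_light_chain <- function(m, calls) {
  ln <- logcounts_layer(m)
  lc <- intersect(light_chain_genes(), rownames(ln))
  mal <- calls[calls$call == "malignant" & !is.na(calls$patient), ]
  purrr::map_dfr(split(mal$cell, mal$patient), function(cl) {
    mu <- Matrix::rowMeans(ln[lc, cl, drop = FALSE])
    top <- which(mu == max(mu))
    if (length(top) > 1) {
      warning("Light-chain tie; broken by fixed gene order.", call. = FALSE)
    }
    tibble::tibble(major_chain = lc[top[1]])
  }, .id = "patient")
}

#' Refine malignant calls by light-chain restriction
#'
#' A putatively malignant cell is forced to healthy when its patient's
#' major light chain is expressed below `low_factor` times the
#' subpopulation mean AND some other light-chain gene exceeds
#' `high_factor` times the subpopulation mean — i.e. the cell carries the
#' wrong chain for its patient's clone. Healthy and unclear calls are
#' never touched, so refinement can only lower the malignancy score.
#'
#' @param m The plasma [cell_matrix()] (log-normalized).
#' @param calls A `plasma_calls` tibble.
#' @param major Tibble `patient`, `major_chain` from [major_light_chain()].
#' @param low_factor,high_factor The 0.5x / 1.5x factors of the rule.
#' @return The refined `plasma_calls` tibble (`refined` flags set).
#' @export
refine_calls <- function(m, calls, major, low_factor = 0.5, high_factor = 1.5) {
  stopifnot(low_factor < 1, high_factor > 1)
  ln <- logcounts_layer(m)
  lc <- intersect(light_chain_genes(), rownames(ln))
  lx <- as.matrix(ln[lc, calls$cell, drop = FALSE])
  sub_mean <- t(apply(lx, 1, function(v) stats::ave(v, calls$subpop)))
  major_of <- major$major_chain[match(calls$patient, major$patient)]
  refine <- rep(FALSE, nrow(calls))
  idx <- which(calls$call == "malignant" & !is.na(major_of))
  for (i in idx) {
    mi <- match(major_of[i], lc)
    low_major <- lx[mi, i] < low_factor * sub_mean[mi, i]
    other_hi <- any(lx[-mi, i] > high_factor * sub_mean[-mi, i])
    refine[i] <- low_major && other_hi
  }
  single <- names(which(table(calls$subpop) == 1))
  if (length(single) && any(calls$subpop[idx] %in% single)) {
    message("Subpopulation(s) of size 1: refinement rule vacuous there.")
  }
  calls$call[refine] <- "healthy"
  calls$refined <- refine
  calls
}

#' Per-sample malignancy scores
#'
#' Malignancy score = malignant plasma cells / total plasma cells per
#' sample (unclear cells count in the denominator only), plus the malignant
#' plasma fraction of all BM cells when full cohort metadata is supplied.
#'
#' @param calls A `plasma_calls` tibble.
#' @param all_cells Optional full-cohort cell metadata (`cell`, `sample`)
#'   used for the fraction-of-all-BM-cells column.
#' @return A tibble `sample`, `n_plasma`, `n_malignant`, `malignancy_score`
#'   (`NA` when a sample has no plasma cells), and `malignant_bm_fraction`
#'   when `all_cells` is given.
#' @export
malignancy_scores <- function(calls, all_cells = NULL) {
  out <- calls |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(
      n_plasma = dplyr::n(),
      n_malignant = sum(.data$call == "malignant"),
      malignancy_score = ifelse(dplyr::n() > 0,
                                sum(.data$call == "malignant") / dplyr::n(),
                                NA_real_),
      .groups = "drop"
    )
  if (!is.null(all_cells)) {
    tot <- dplyr::count(all_cells, .data$sample, name = "n_bm_cells")
    out <- dplyr::left_join(out, tot, by = "sample") |>
      dplyr::mutate(malignant_bm_fraction = .data$n_malignant / .data$n_bm_cells)
  }
  out
}

#' Spearman correlation of malignancy scores against an external truth
#'
#' Helper for comparing recovered per-sample scores with an external
#' per-sample burden measurement (e.g. an MRD analogue or planted truth).
#'
#' @param scores Tibble with `sample`, `malignancy_score`.
#' @param truth Tibble with `sample` and a truth column (second column).
#' @return Spearman's rho (numeric scalar).
#' @export
malignancy_score_correlation <- function(scores, truth) {
  truth <- tibble::as_tibble(truth)
  names(truth)[2] <- "truth_score"
  df <- dplyr::inner_join(scores, truth[, 1:2], by = "sample")
  stats::cor(df$malignancy_score, df$truth_score, method = "spearman")
}

#' Within-patient transcriptional stability of malignant plasma cells
#'
#' Per patient with at least two malignant cells in each clinical state,
#' computes the Euclidean distance between the ID-cell centroid and the
#' LTS-cell centroid in a shared embedding, and the distance from the ID
#' centroid to the nearest other patient's ID centroid. A one-sided paired
#' Wilcoxon signed-rank test asks whether clones stay closer to themselves
#' over time than to the nearest other patient (skipped below 3 eligible
#' patients).
#'
#' @param coords Shared cells x dims embedding (barcodes as rownames).
#' @param meta Tibble `cell`, `patient`, `condition` for malignant cells.
#' @return A list: `distances` tibble (`patient`, `within_patient`,
#'   `nearest_neighbor`) and `p_value` (`NA` when skipped).
#' @export
stability_distance <- function(coords, meta) {
  meta <- meta[meta$condition %in% c("ID", "LTS") & meta$cell %in% rownames(coords), ]
  wide <- meta |>
    dplyr::count(.data$patient, .data$condition) |>
    tidyr::pivot_wider(names_from = "condition", values_from = "n",
                       values_fill = 0L)
  eligible <- if (all(c("ID", "LTS") %in% names(wide))) {
    wide$patient[wide$ID >= 2 & wide$LTS >= 2 & !is.na(wide$patient)]
  } else character(0)
  centroid <- function(p, cond) {
    cl <- meta$cell[meta$patient == p & meta$condition == cond]
    colMeans(coords[cl, , drop = FALSE])
  }
  dist_tab <- purrr::map_dfr(eligible, function(p) {
    cid <- centroid(p, "ID")
    clts <- centroid(p, "LTS")
    others <- setdiff(eligible, p)
    nn <- if (length(others)) {
      min(vapply(others, function(q) sqrt(sum((cid - centroid(q, "ID"))^2)),
                 numeric(1)))
    } else NA_real_
    tibble::tibble(patient = p,
                   within_patient = sqrt(sum((cid - clts)^2)),
                   nearest_neighbor = nn)
  })
  p_value <- NA_real_
  if (length(eligible) >= 3) {
    p_value <- suppressWarnings(stats::wilcox.test(
      dist_tab$within_patient, dist_tab$nearest_neighbor,
      paired = TRUE, alternative = "less")$p.value)
  } else {
    message("Fewer than 3 eligible patients: stability test skipped.")
  }
  list(distances = dist_tab, p_value = p_value)
}
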