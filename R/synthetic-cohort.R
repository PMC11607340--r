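#' Specify a synthetic bone-marrow cohort
#'
#' Defines the statistical structure of a simulated myeloma cohort: a few
#' healthy donors plus patients sampled at initial diagnosis (ID) and at a
#' long-term survival timepoint (LTS), several cell types with marker
#' programs, a planted transcriptionally shifted ("aberrant") subpopulation
#' in every diseased sample, clonal plasma cells carrying chromosome-arm
#' copy-number events and single light-chain restriction, and per-sample TCR
#' repertoires with controllable cross-sample sharing.
#'
#' Counts are negative binomial with variance `mu + mu^2 / dispersion`
#' (mean/dispersion parameterization, the standard scRNA-seq count model).
#'
#' @param n_healthy_samples Number of healthy donor samples.
#' @param n_patients Number of patients; each contributes one ID and one LTS
#'   sample.
#' @param cell_types Tibble with columns `name`, `mean_cells` (expected
#'   cells/sample), `n_markers` (identity marker genes per type) and
#'   `n_program` (planted aberrant-program genes per type; 0 disables the
#'   aberrant subpopulation for that type). An optional `markers`
#'   list-column names the marker genes explicitly (they are added to the
#'   gene universe), which is how T-cell subset fixtures are built.
#' @param n_genes Size of the gene universe (includes the fixed special
#'   genes: light chains IGKC and IGLC1-IGLC7, and 13 mitochondrial genes).
#' @param baseline_mean Median NB mean of an expressed gene; per-gene means
#'   are lognormal around it (sdlog 1).
#' @param dispersion NB dispersion theta (variance `mu + mu^2/theta`).
#' @param marker_effect log2 fold-change applied to a type's marker genes in
#'   cells of that type.
#' @param aberrant_fraction Fraction of each diseased sample's cells, per
#'   perturbed cell type, carrying the aberrant program shift.
#' @param aberrant_effect log2 fold-change applied to program genes in
#'   aberrant cells.
#' @param plasma_spec As returned by [plasma_spec()].
#' @param tcr_spec As returned by [tcr_spec()].
#' @param seed Integer seed; a fixed seed gives bit-identical cohorts.
#'
#' @return A validated `cohort_spec` object.
#' @seealso [generate_cohort()], [generate_repertoires()]
#' @export
cohort_spec <- function(n_healthy_samples = 3,
                        n_patients = 3,
                        cell_types = default_cell_types(),
                        n_genes = 2000,
                        baseline_mean = 0.3,
                        dispersion = 2,
                        marker_effect = 2,
                        aberrant_fraction = 0.3,
                        aberrant_effect = 2,
                        plasma_spec = marrowscape::plasma_spec(n_clones = n_patients),
                        tcr_spec = marrowscape::tcr_spec(),
                        seed = 1L) {
  cell_types <- tibble::as_tibble(cell_types)
  stopifnot(
    n_healthy_samples >= 1, n_patients >= 1,
    all(c("name", "mean_cells", "n_markers", "n_program") %in% names(cell_types)),
    baseline_mean > 0, dispersion > 0,
    is.finite(marker_effect), is.finite(aberrant_effect)
  )
  if (aberrant_fraction < 0 || aberrant_fraction > 1) {
    stop("`aberrant_fraction` must be in [0, 1].", call. = FALSE)
  }
  named <- if ("markers" %in% names(cell_types)) {
    length(unique(unlist(cell_types$markers)))
  } else 0L
  n_special <- length(light_chain_genes()) + length(mito_genes())
  n_needed <- sum(cell_types$n_markers) + sum(cell_types$n_program)
  if (n_needed + n_special + named > n_genes) {
    stop("Impossible spec: more marker/program genes than genes available.",
         call. = FALSE)
  }
  spec <- list(
    n_healthy_samples = as.integer(n_healthy_samples),
    n_patients = as.integer(n_patients),
    cell_types = cell_types,
    n_genes = as.integer(n_genes),
    baseline_mean = baseline_mean,
    dispersion = dispersion,
    marker_effect = marker_effect,
    aberrant_fraction = aberrant_fraction,
    aberrant_effect = aberrant_effect,
    plasma_spec = plasma_spec,
    tcr_spec = tcr_spec,
    seed = as.integer(seed)
  )
  validate_plasma_spec(plasma_spec, n_patients)
  validate_tcr_spec(tcr_spec)
  structure(spec, class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> %d healthy + %d patients (ID/LTS pairs), %d cell types, %d genes, seed %d\n",
    x$n_healthy_samples, x$n_patients, nrow(x$cell_types), x$n_genes, x$seed
  ))
  invisible(x)
}

#' Default cell-type table of the synthetic cohort
#'
#' Five bone-marrow compartments; plasma cells carry no aberrant program
#' (their perturbation is the clonal CNV/light-chain structure instead).
#' @return Tibble accepted by [cohort_spec()].
#' @export
default_cell_types <- function() {
  tibble::tibble(
    name = c("T", "NK", "B", "Mono", "Plasma"),
    mean_cells = c(60, 35, 35, 55, 35),
    n_markers = 20L,
    n_program = c(150L, 150L, 150L, 150L, 0L)
  )
}

#' Plasma-cell clone specification
#'
#' Each patient hosts one clone. Default clones mimic common myeloma
#' karyotypes: hyperdiploid-like whole-chromosome gains (fold 1.5, three
#' copies) plus one whole-chromosome loss (fold 0.5), with a single
#' restricted light chain per clone (kappa twice as common as lambda).
#'
#' @param n_clones Number of clones (one per patient).
#' @param clones Optional tibble with columns `clone`, `light_chain` and a
#'   list-column `arms` of tibbles `(chromosome, arm, fold)`; overrides the
#'   defaults.
#' @param malignant_fraction_id,malignant_fraction_lts Per-patient fractions
#'   of plasma cells that are malignant at ID / LTS (recycled to
#'   `n_clones`). Defaults span a realistic burden range: high at diagnosis,
#'   residual at long-term survival.
#' @param chain_mean NB mean of the expressed light-chain gene in a plasma
#'   cell.
#' @param chain_leak_mean NB mean of the unexpressed light-chain genes.
#' @param kappa_prob Probability that a healthy plasma cell is a kappa
#'   (IGKC) carrier.
#' @return A `plasma_spec` list.
#' @export
plasma_spec <- function(n_clones = 3,
                        clones = NULL,
                        malignant_fraction_id = seq(0.95, 0.7, length.out = n_clones),
                        malignant_fraction_lts = seq(0.5, 0.15, length.out = n_clones),
                        chain_mean = 20,
                        chain_leak_mean = 0.005,
                        kappa_prob = 2 / 3) {
  if (is.null(clones)) clones <- default_plasma_clones(n_clones)
  out <- list(
    clones = tibble::as_tibble(clones),
    malignant_fraction_id = rep_len(malignant_fraction_id, n_clones),
    malignant_fraction_lts = rep_len(malignant_fraction_lts, n_clones),
    chain_mean = chain_mean,
    chain_leak_mean = chain_leak_mean,
    kappa_prob = kappa_prob
  )
  structure(out, class = "plasma_spec")
}

default_plasma_clones <- function(n_clones) {
  # hyperdiploid-like karyotypes: trisomies of several odd chromosomes
  # (fold 1.5) plus one monosomy (fold 0.5), the commonest myeloma pattern
  gain_sets <- list(c(3, 5, 9, 15, 19), c(3, 7, 11, 15, 19), c(5, 9, 11, 15, 21),
                    c(3, 7, 9, 19, 21), c(3, 5, 11, 15, 19))
  loss_sets <- c(13, 16, 17, 13, 14)
  chains <- c("IGKC", "IGLC2", "IGKC", "IGLC1", "IGKC")
  idx <- ((seq_len(n_clones) - 1) %% length(gain_sets)) + 1
  tibble::tibble(
    clone = seq_len(n_clones),
    light_chain = chains[idx],
    arms = lapply(idx, function(i) {
      chr <- c(gain_sets[[i]], loss_sets[i])
      fold <- c(rep(1.5, length(gain_sets[[i]])), 0.5)
      tibble::tibble(
        chromosome = as.character(rep(chr, each = 2)),
        arm = rep(c("p", "q"), length(chr)),
        fold = rep(fold, each = 2)
      )
    })
  )
}

validate_plasma_spec <- function(ps, n_patients) {
  stopifnot(inherits(ps, "plasma_spec"))
  fr <- c(ps$malignant_fraction_id, ps$malignant_fraction_lts)
  if (any(fr < 0 | fr > 1)) stop("Malignant fractions must be in [0, 1].", call. = FALSE)
  if (!all(ps$clones$light_chain %in% light_chain_genes())) {
    stop("Clone light chains must be one of ", paste(light_chain_genes(), collapse = ", "),
         call. = FALSE)
  }
  folds <- unlist(lapply(ps$clones$arms, function(a) a$fold))
  if (!all(is.finite(folds)) || any(folds <= 0)) {
    stop("Arm fold-changes must be finite and positive.", call. = FALSE)
  }
  invisible(ps)
}

#' TCR repertoire specification
#'
#' Per sample, clonotype frequencies follow an exponential rank decay
#' `p_i \propto exp(-decay * (i - 1))`; `decay = 0` gives a perfectly even
#' repertoire. Each patient contributes a designated sample pair (bone
#' marrow / peripheral blood analogues) that shares `sharing` of its CDR3
#' amino-acid keys; shared clonotypes occupy the top ranks, emulating
#' persistent expanded clones.
#'
#' @param n_clonotypes Clonotypes per sample.
#' @param decay Exponential rank-decay rate of clone sizes (>= 0).
#' @param sharing Fraction of CDR3aa keys shared within a designated sample
#'   pair, in `[0, 1]`.
#' @param depth Sequencing depth used to convert frequencies to counts.
#' @return A `tcr_spec` list.
#' @export
tcr_spec <- function(n_clonotypes = 100, decay = 0.05, sharing = 0.5, depth = 2e4) {
  structure(
    list(n_clonotypes = as.integer(n_clonotypes), decay = decay,
         sharing = sharing, depth = depth),
    class = "tcr_spec"
  )
}

validate_tcr_spec <- function(ts) {
  stopifnot(inherits(ts, "tcr_spec"))
  if (ts$sharing < 0 || ts$sharing > 1) {
    stop("`sharing` must be in [0, 1].", call. = FALSE)
  }
  if (ts$decay < 0) stop("`decay` must be >= 0.", call. = FALSE)
  if (ts$n_clonotypes < 1) stop("Need at least one clonotype per sample.", call. = FALSE)
  invisible(ts)
}

#' Immunoglobulin light-chain gene universe
#' @return Character vector: IGKC and IGLC1-IGLC7.
#' @export
light_chain_genes <- function() c("IGKC", paste0("IGLC", 1:7))

mito_genes <- function() {
  c("MT-ND1", "MT-ND2", "MT-ND3", "MT-ND4", "MT-ND4L", "MT-ND5", "MT-ND6",
    "MT-CO1", "MT-CO2", "MT-CO3", "MT-ATP6", "MT-ATP8", "MT-CYB")
}

# Gene universe: autosomal genes spread evenly over chromosomes 1-22 (half
# "p", half "q" per chromosome), light chains placed on their true
# chromosomes (IGKC: 2, IGLC: 22), mitochondrial genes on "MT".
build_gene_table <- function(spec) {
  lc <- light_chain_genes()
  mt <- mito_genes()
  n_auto <- spec$n_genes - length(mt)
  n_generic <- n_auto - length(lc)
  generic <- sprintf("G%05d", seq_len(n_generic))
  chr_of <- rep(as.character(1:22), length.out = n_auto)
  chr_of <- sort(as.integer(chr_of)) # even contiguous blocks 1..22
  chr_of <- as.character(chr_of)
  genes <- character(n_auto)
  # slot light chains into their chromosome blocks, generic genes elsewhere
  idx2 <- which(chr_of == "2")[1]
  idx22 <- which(chr_of == "22")[seq_along(lc[-1])]
  lc_pos <- c(idx2, idx22)
  genes[lc_pos] <- lc
  genes[-lc_pos] <- generic
  arm <- unlist(lapply(split(seq_len(n_auto), factor(chr_of, levels = as.character(1:22))),
                       function(ix) {
                         half <- ceiling(length(ix) / 2)
                         rep(c("p", "q"), c(half, length(ix) - half))
                       }), use.names = FALSE)
  tibble::tibble(
    gene = c(genes, mt),
    chromosome = c(chr_of, rep("MT", length(mt))),
    arm = c(arm, rep(NA_character_, length(mt))),
    position = seq_len(spec$n_genes),
    is_mito = c(rep(FALSE, n_auto), rep(TRUE, length(mt))),
    is_light_chain = c(genes %in% lc, rep(FALSE, length(mt)))
  )
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws a full cell x gene UMI matrix plus metadata from a [cohort_spec()],
#' together with the planted ground truth every recovery test compares
#' against: per-cell aberrant/malignant flags and clone IDs, per-gene
#' marker/program/CNV-arm membership, and per-sample planted malignancy
#' scores (exactly malignant / total plasma cells as realized).
#'
#' @param spec A [cohort_spec()].
#' @return A list with elements `matrix` (a [cell_matrix()]) and `truth`
#'   (list of tibbles `cells`, `genes`, `samples`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::local_seed(spec$seed)

  gene_tab <- build_gene_table(spec)
  n_g <- nrow(gene_tab)
  mu_base <- stats::rlnorm(n_g, meanlog = log(spec$baseline_mean), sdlog = 1)
  mu_base <- pmin(mu_base, 50 * spec$baseline_mean)
  lc <- light_chain_genes()
  lc_idx <- match(lc, gene_tab$gene)
  mu_base[lc_idx] <- 0.002                       # background outside plasma cells
  mu_base[gene_tab$is_mito] <- 1.5               # ~4% mitochondrial fraction

  # assign marker and program gene sets (disjoint). Programs and markers are
  # planted in detectably expressed genes (baseline mean at or above the
  # cohort median), mirroring how real marker/DE programs are defined from
  # genes the assay can see; the pool widens if a spec demands more genes.
  ct <- spec$cell_types
  eligible <- !gene_tab$is_mito & !gene_tab$is_light_chain
  pool <- which(eligible & mu_base >= spec$baseline_mean)
  n_needed <- sum(ct$n_markers) + sum(ct$n_program)
  if (length(pool) < n_needed) {
    extra <- setdiff(which(eligible)[order(-mu_base[eligible])], pool)
    pool <- c(pool, extra[seq_len(n_needed - length(pool))])
  }
  marker_sets <- vector("list", nrow(ct))
  program_sets <- vector("list", nrow(ct))
  for (i in seq_len(nrow(ct))) {
    if ("markers" %in% names(ct) && !is.null(ct$markers[[i]])) {
      named <- ct$markers[[i]]
      missing <- setdiff(named, gene_tab$gene)
      if (length(missing)) { # graft named markers onto generic slots
        slots <- pool[seq_along(missing)]
        gene_tab$gene[slots] <- missing
        pool <- setdiff(pool, slots)
      }
      marker_sets[[i]] <- match(named, gene_tab$gene)
      pool <- setdiff(pool, marker_sets[[i]])
    } else if (ct$n_markers[i] > 0) {
      marker_sets[[i]] <- sort(sample(pool, ct$n_markers[i]))
      pool <- setdiff(pool, marker_sets[[i]])
    } else marker_sets[[i]] <- integer()
    if (ct$n_program[i] > 0) {
      program_sets[[i]] <- sort(sample(pool, ct$n_program[i]))
      pool <- setdiff(pool, program_sets[[i]])
    } else program_sets[[i]] <- integer()
  }

  ps <- spec$plasma_spec
  clone_arm_idx <- lapply(ps$clones$arms, function(a) {
    key <- paste(gene_tab$chromosome, gene_tab$arm)
    lapply(seq_len(nrow(a)), function(r) which(key == paste(a$chromosome[r], a$arm[r])))
  })

  samples <- tibble::tibble(
    sample = c(sprintf("H%d", seq_len(spec$n_healthy_samples)),
               as.vector(rbind(sprintf("P%d-ID", seq_len(spec$n_patients)),
                               sprintf("P%d-LTS", seq_len(spec$n_patients))))),
    condition = c(rep("Healthy", spec$n_healthy_samples),
                  rep(c("ID", "LTS"), spec$n_patients)),
    patient = c(rep(NA_character_, spec$n_healthy_samples),
                rep(sprintf("P%d", seq_len(spec$n_patients)), each = 2))
  )

  blocks <- list()   # each: list(mu, n, meta)
  for (s in seq_len(nrow(samples))) {
    cond <- samples$condition[s]
    pat <- samples$patient[s]
    pat_i <- if (is.na(pat)) NA_integer_ else as.integer(sub("^P", "", pat))
    for (i in seq_len(nrow(ct))) {
      n_cells_i <- stats::rpois(1, ct$mean_cells[i])
      if (n_cells_i == 0) next
      mu_type <- mu_base
      mu_type[marker_sets[[i]]] <- mu_type[marker_sets[[i]]] * 2^spec$marker_effect
      is_plasma <- ct$name[i] == "Plasma"
      if (!is_plasma) {
        n_ab <- if (cond != "Healthy" && length(program_sets[[i]])) {
          round(spec$aberrant_fraction * n_cells_i)
        } else 0L
        if (n_cells_i - n_ab > 0) {
          blocks[[length(blocks) + 1]] <- list(
            mu = mu_type, n = n_cells_i - n_ab,
            meta = list(sample = samples$sample[s], condition = cond, patient = pat,
                        cell_type = ct$name[i], is_aberrant = FALSE,
                        is_malignant = FALSE, clone = NA_integer_))
        }
        if (n_ab > 0) {
          mu_ab <- mu_type
          mu_ab[program_sets[[i]]] <- mu_ab[program_sets[[i]]] * 2^spec$aberrant_effect
          blocks[[length(blocks) + 1]] <- list(
            mu = mu_ab, n = n_ab,
            meta = list(sample = samples$sample[s], condition = cond, patient = pat,
                        cell_type = ct$name[i], is_aberrant = TRUE,
                        is_malignant = FALSE, clone = NA_integer_))
        }
      } else {
        mal_frac <- if (cond == "ID") ps$malignant_fraction_id[pat_i]
                    else if (cond == "LTS") ps$malignant_fraction_lts[pat_i]
                    else 0
        n_mal <- round(mal_frac * n_cells_i)
        n_heal <- n_cells_i - n_mal
        if (n_heal > 0) { # healthy plasma: polyclonal mix of kappa/lambda carriers
          chains <- ifelse(stats::runif(n_heal) < ps$kappa_prob, "IGKC",
                           sample(paste0("IGLC", 1:7), n_heal, replace = TRUE))
          for (ch in unique(chains)) {
            mu_pc <- mu_type
            mu_pc[lc_idx] <- ps$chain_leak_mean
            mu_pc[match(ch, gene_tab$gene)] <- ps$chain_mean
            blocks[[length(blocks) + 1]] <- list(
              mu = mu_pc, n = sum(chains == ch),
              meta = list(sample = samples$sample[s], condition = cond, patient = pat,
                          cell_type = "Plasma", is_aberrant = FALSE,
                          is_malignant = FALSE, clone = NA_integer_))
          }
        }
        if (n_mal > 0) {
          clone_i <- ((pat_i - 1) %% nrow(ps$clones)) + 1
          mu_mal <- mu_type
          a <- ps$clones$arms[[clone_i]]
          for (r in seq_len(nrow(a))) {
            ix <- clone_arm_idx[[clone_i]][[r]]
            mu_mal[ix] <- mu_mal[ix] * a$fold[r]
          }
          mu_mal[lc_idx] <- ps$chain_leak_mean
          mu_mal[match(ps$clones$light_chain[clone_i], gene_tab$gene)] <- ps$chain_mean
          blocks[[length(blocks) + 1]] <- list(
            mu = mu_mal, n = n_mal,
            meta = list(sample = samples$sample[s], condition = cond, patient = pat,
                        cell_type = "Plasma", is_aberrant = FALSE,
                        is_malignant = TRUE, clone = clone_i))
        }
      }
    }
  }

  n_cells_tot <- sum(vapply(blocks, function(b) as.integer(b$n), 0L))
  counts <- matrix(0, nrow = n_g, ncol = n_cells_tot)
  meta <- vector("list", length(blocks))
  col0 <- 0L
  for (b in seq_along(blocks)) {
    nb <- blocks[[b]]$n
    counts[, col0 + seq_len(nb)] <- stats::rnbinom(n_g * nb, mu = blocks[[b]]$mu,
                                                   size = spec$dispersion)
    meta[[b]] <- tibble::as_tibble(blocks[[b]]$meta)[rep(1, nb), ]
    col0 <- col0 + nb
  }
  cells <- dplyr::bind_rows(meta)
  # shuffle cells so block structure is not encoded in column order
  ord <- sample.int(n_cells_tot)
  counts <- counts[, ord, drop = FALSE]
  cells <- cells[ord, ]
  cells <- dplyr::mutate(
    cells,
    cell = sprintf("%s_c%04d", sample,
                   as.integer(stats::ave(seq_len(n_cells_tot), sample,
                                         FUN = seq_along))),
    .before = 1
  )
  rownames(counts) <- gene_tab$gene
  colnames(counts) <- cells$cell

  truth_genes <- gene_tab
  truth_genes$program <- NA_character_
  truth_genes$marker <- NA_character_
  for (i in seq_len(nrow(ct))) {
    truth_genes$program[program_sets[[i]]] <- ct$name[i]
    truth_genes$marker[marker_sets[[i]]] <- ct$name[i]
  }
  truth_samples <- cells |>
    dplyr::filter(.data$cell_type == "Plasma") |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(planted_malignancy_score = mean(.data$is_malignant),
                     n_plasma = dplyr::n(), .groups = "drop")

  m <- cell_matrix(counts,
                   cells = dplyr::select(cells, "cell", "sample", "condition",
                                         "patient", "cell_type"),
                   genes = gene_tab)
  qc <- cell_qc_stats(m)
  m$cells <- dplyr::left_join(m$cells, qc, by = "cell")

  truth_cells <- dplyr::select(cells, "cell", "sample", "condition", "patient",
                               "cell_type", "is_aberrant", "is_malignant", "clone")
  list(matrix = m,
       truth = list(cells = truth_cells, genes = truth_genes, samples = truth_samples))
}

#' Generate synthetic TCR repertoires
#'
#' One clonotype table per sample: each patient contributes a designated
#' BM/PB pair sharing `sharing` of its CDR3aa keys (shared clones at the top
#' ranks). Frequencies follow the exponential rank decay of the
#' [tcr_spec()] and sum to 1 per sample.
#'
#' @param spec A [cohort_spec()] (its `tcr_spec` and `n_patients` are used).
#' @return A named list of tibbles with columns `sample`, `cdr3aa`,
#'   `v_gene`, `j_gene`, `count`, `freq`.
#' @export
generate_repertoires <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  ts <- spec$tcr_spec
  validate_tcr_spec(ts)
  withr::local_seed(spec$seed + 1L)
  S <- ts$n_clonotypes
  p <- exp(-ts$decay * (seq_len(S) - 1))
  p <- p / sum(p)
  counts <- pmax(1L, round(p * ts$depth))
  n_shared <- round(ts$sharing * S)
  out <- list()
  for (pat in seq_len(spec$n_patients)) {
    shared <- random_cdr3(n_shared)
    for (site in c("BM", "PB")) {
      own <- random_cdr3(S - n_shared)
      keys <- c(shared, own) # shared keys occupy the most abundant ranks
      tab <- tibble::tibble(
        sample = sprintf("P%d-%s", pat, site),
        cdr3aa = keys,
        v_gene = sample(sprintf("TRBV%d", 1:30), S, replace = TRUE),
        j_gene = sample(sprintf("TRBJ%d-%d", rep(1:2, c(6, 7)), c(1:6, 1:7)), S,
                        replace = TRUE),
        count = counts
      )
      tab$freq <- tab$count / sum(tab$count)
      out[[tab$sample[1]]] <- tab
    }
  }
  out
}

random_cdr3 <- function(n, len_range = c(6L, 12L)) {
  if (n == 0) return(character())
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(seq_len(n), function(i) {
    len <- sample(seq(len_range[1], len_range[2]), 1)
    paste0("CASS", paste(sample(aa, len, replace = TRUE), collapse = ""), "F")
  }, character(1))
}

#' Write a generated cohort to disk as plain-text files
#'
#' Writes the count matrix as a 10x-style MTX triplet with `cells.csv` and
#' `genes.csv`, ground truth as `ground_truth.csv`, and each repertoire as a
#' TSV (`cdr3aa`, `v_gene`, `j_gene`, `count`).
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory.
#' @param repertoires Optional result of [generate_repertoires()].
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, repertoires = NULL) {
  write_cell_matrix(cohort$matrix, dir)
  readr::write_csv(cohort$truth$cells, file.path(dir, "ground_truth.csv"))
  if (!is.null(repertoires)) {
    for (nm in names(repertoires)) {
      readr::write_tsv(
        dplyr::select(repertoires[[nm]], "cdr3aa", "v_gene", "j_gene", "count"),
        file.path(dir, paste0("repertoire_", nm, ".tsv"))
      )
    }
  }
  invisible(dir)
}
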