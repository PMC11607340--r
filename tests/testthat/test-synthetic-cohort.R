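test_that("cohort generation is deterministic and honours planted structure", {
  spec <- small_spec(seed = 11)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(as.matrix(a$matrix$counts), as.matrix(b$matrix$counts))
  expect_identical(a$truth$cells, b$truth$cells)

  # planted malignancy score equals malignant / total plasma cells exactly
  per_sample <- a$truth$cells |>
    dplyr::filter(cell_type == "Plasma") |>
    dplyr::group_by(sample) |>
    dplyr::summarise(frac = mean(is_malignant))
  joined <- dplyr::inner_join(per_sample, a$truth$samples, by = "sample")
  expect_equal(joined$frac, joined$planted_malignancy_score)

  # healthy samples contain no aberrant or malignant cells
  healthy <- a$truth$cells[a$truth$cells$condition == "Healthy", ]
  expect_false(any(healthy$is_aberrant))
  expect_false(any(healthy$is_malignant))
})

test_that("zero aberrant fraction plants no aberrant cells", {
  coh <- generate_cohort(small_spec(seed = 3, aberrant_fraction = 0))
  expect_false(any(coh$truth$cells$is_aberrant))
})

test_that("aberrant fractions per diseased sample sit in the binomial range", {
  coh <- small_cohort()
  frac <- coh$truth$cells |>
    dplyr::filter(condition != "Healthy", cell_type == "T") |>
    dplyr::group_by(sample) |>
    dplyr::summarise(f = mean(is_aberrant), n = dplyr::n())
  # planted by rounding 0.3 * n, so within 1/(2n) of the target
  expect_true(all(abs(frac$f - 0.3) <= 0.5 / frac$n + 1e-9))
})

test_that("counts follow the NB mean/variance parameterization", {
  # one homogeneous block: healthy T cells from a one-type cohort
  spec <- cohort_spec(
    n_healthy_samples = 3, n_patients = 1,
    cell_types = tibble::tibble(name = "T", mean_cells = 400,
                                n_markers = 0L, n_program = 10L),
    n_genes = 300, dispersion = 2, seed = 99
  )
  coh <- generate_cohort(spec)
  keep <- coh$truth$cells$condition == "Healthy"
  x <- as.matrix(coh$matrix$counts[, keep])
  gi <- order(-rowMeans(x))[1:25]      # best-powered genes
  mu_hat <- rowMeans(x[gi, ])
  v_hat <- apply(x[gi, ], 1, stats::var)
  v_exp <- mu_hat + mu_hat^2 / 2
  # Monte-Carlo agreement at n > 10^3 cells: variance ratio near 1
  expect_true(all(abs(v_hat / v_exp - 1) < 0.35))
  expect_gt(stats::cor(v_hat, v_exp), 0.95)
})

test_that("malignant plasma cells are light-chain restricted", {
  coh <- small_cohort()
  counts <- coh$matrix$counts
  tc <- coh$truth$cells
  ps <- small_spec()$plasma_spec
  for (cl in unique(stats::na.omit(tc$clone))) {
    cells <- tc$cell[!is.na(tc$clone) & tc$clone == cl]
    own <- ps$clones$light_chain[ps$clones$clone == cl]
    other <- setdiff(light_chain_genes(), own)
    det_own <- mean(counts[own, cells] > 0)
    det_other <- mean(as.matrix(counts[other, cells]) > 0)
    expect_gt(det_own, 0.99)
    expect_lt(det_other, 0.01)
  }
  # healthy plasma cells mix kappa and lambda carriers
  hp <- tc$cell[tc$cell_type == "Plasma" & tc$condition == "Healthy"]
  expect_gt(sum(counts["IGKC", hp] > 5), 0)
  expect_gt(sum(Matrix::colSums(counts[paste0("IGLC", 1:7), hp]) > 5), 0)
})

test_that("impossible specs are rejected", {
  expect_error(
    cohort_spec(cell_types = tibble::tibble(name = "T", mean_cells = 10,
                                            n_markers = 600L, n_program = 600L),
                n_genes = 1000),
    "Impossible spec"
  )
  expect_error(cohort_spec(aberrant_fraction = 1.2), "aberrant_fraction")
  expect_error(cohort_spec(tcr_spec = tcr_spec(sharing = 1.5)), "sharing")
})

test_that("repertoires follow the decay law and share planted keys", {
  spec <- small_spec(seed = 5)
  reps <- generate_repertoires(spec)
  expect_length(reps, 2 * spec$n_patients)
  for (r in reps) {
    expect_equal(sum(r$freq), 1, tolerance = 1e-9)
    expect_false(anyDuplicated(r$cdr3aa) > 0)
    # frequencies follow exp(-decay * (rank - 1)) up to count rounding
    p <- exp(-spec$tcr_spec$decay * (seq_len(nrow(r)) - 1))
    p <- p / sum(p)
    expect_lt(max(abs(r$freq - p)), 1e-3)
    expect_true(all(diff(r$freq) <= 0))
  }
  # designated pairs share the configured key fraction
  shared <- length(intersect(reps[["P1-BM"]]$cdr3aa, reps[["P1-PB"]]$cdr3aa))
  expect_equal(shared / nrow(reps[["P1-BM"]]), spec$tcr_spec$sharing)
  # non-designated samples share nothing by construction
  expect_length(intersect(reps[["P1-BM"]]$cdr3aa, reps[["P2-BM"]]$cdr3aa), 0)
})

test_that("full sharing and monoclonal edge cases propagate downstream", {
  spec1 <- cohort_spec(n_patients = 1, tcr_spec = tcr_spec(sharing = 1), seed = 8)
  reps1 <- generate_repertoires(spec1)
  J <- jaccard_matrix(reps1)
  expect_equal(unname(J["P1-BM", "P1-PB"]), 1)

  mono <- cohort_spec(n_patients = 1, tcr_spec = tcr_spec(n_clonotypes = 1),
                      seed = 8)
  expect_equal(clonality(generate_repertoires(mono)[[1]]), 1)

  unif <- cohort_spec(n_patients = 1,
                      tcr_spec = tcr_spec(n_clonotypes = 100, decay = 0),
                      seed = 8)
  expect_equal(clonality(generate_repertoires(unif)[[1]]), 0)
})

test_that("cohorts round-trip through the MTX triplet format", {
  coh <- generate_cohort(cohort_spec(
    n_patients = 1,
    cell_types = tibble::tibble(name = c("T", "Plasma"), mean_cells = c(30, 15),
                                n_markers = 5L, n_program = c(20L, 0L)),
    n_genes = 400, plasma_spec = plasma_spec(n_clones = 1), seed = 21
  ))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir, repertoires = NULL)
  back <- read_cell_matrix(dir)
  expect_equal(as.matrix(back$counts), as.matrix(coh$matrix$counts))
  expect_equal(back$cells$sample, coh$matrix$cells$sample)
  expect_equal(back$genes$chromosome, coh$matrix$genes$chromosome)
})
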