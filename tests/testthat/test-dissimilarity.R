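test_that("PCA embedding has the stated geometry", {
  # data on one axis: first component captures all variance
  x <- matrix(0, 5, 30)
  x[3, ] <- c(1:30)
  m <- as_normalized(x)
  co <- suppressWarnings(embed_cells(t_matrix <- m, n_dims = 4, n_variable = 5))
  vars <- apply(co, 2, stats::var)
  expect_gt(vars[1] / sum(vars), 0.999)

  # duplicated rows embed to duplicated coordinates
  set.seed(2)
  y <- matrix(rpois(40 * 30, 3), 40, 30)
  y <- cbind(y, y[, 1:5])
  colnames(y) <- sprintf("c%02d", 1:35)
  my <- toy_matrix(y)
  coy <- suppressWarnings(embed_cells(my, n_dims = 5, n_variable = 40))
  expect_equal(coy[31:35, ], coy[1:5, ], ignore_attr = TRUE)
})

test_that("centered data is reconstructed from all principal components", {
  set.seed(3)
  x <- matrix(rnorm(20 * 5), 20, 5)  # cells x genes, dense toy
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  recon <- pc$x %*% t(pc$rotation)
  centered <- scale(x, center = TRUE, scale = FALSE)
  # full eigendecomposition oracle
  ev <- eigen(crossprod(centered))
  expect_equal(sort(abs(ev$values)), sort(pc$sdev^2 * (nrow(x) - 1)),
               tolerance = 1e-10)
  expect_equal(recon, centered, ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("well-separated conditions score 0 and 1 after scaling", {
  set.seed(4)
  co <- rbind(matrix(rnorm(80 * 3), 80), matrix(rnorm(80 * 3, mean = 30), 80))
  rownames(co) <- sprintf("c%03d", 1:160)
  cond <- rep(c("Healthy", "ID"), each = 80)
  r <- dissimilarity_scores(co, cond, dissim_config(k = 10, n_iterations = 5))
  expect_true(all(r$scaled[cond == "Healthy"] == 0))
  expect_true(all(r$scaled[cond == "ID"] == 1))
  expect_true(all(r$scaled >= 0 & r$scaled <= 1))
})

test_that("scores match the exhaustive brute-force oracle exactly", {
  set.seed(5)
  for (n_iter in c(1L, 3L)) {
    co <- matrix(rnorm(150 * 4), 150, 4)
    rownames(co) <- sprintf("c%03d", 1:150)
    cond <- sample(c("Healthy", "ID", "LTS"), 150, replace = TRUE,
                   prob = c(0.4, 0.4, 0.2))
    cfg <- dissim_config(k = 7, n_iterations = n_iter, master_seed = 17)
    fast <- dissimilarity_scores(co, cond, cfg)
    slow <- brute_force_scores(co, cond, cfg)
    expect_equal(fast$scaled, slow)
  }
})

test_that("permuted condition labels give a null mean near one half", {
  set.seed(6)
  co <- matrix(rnorm(300 * 5), 300, 5)
  rownames(co) <- sprintf("c%03d", 1:300)
  cond <- withr::with_seed(99, sample(rep(c("Healthy", "ID"), each = 150)))
  cfg <- dissim_config(k = 30, n_iterations = 20, master_seed = 7)
  r <- dissimilarity_scores(co, cond, cfg)
  # raw neighbour fractions hover around 0.5 under the null;
  # MC standard error of the mean over 300 cells
  se <- stats::sd(r$raw_median) / sqrt(nrow(co))
  expect_lt(abs(mean(r$raw_median) - 0.5), 3 * se + 0.01)
})

test_that("scores are deterministic and invariant to cell order", {
  set.seed(8)
  co <- matrix(rnorm(120 * 4), 120, 4)
  rownames(co) <- sprintf("c%03d", 1:120)
  cond <- rep(c("Healthy", "ID"), 60)
  cfg <- dissim_config(k = 10, n_iterations = 5, master_seed = 3)
  r1 <- dissimilarity_scores(co, cond, cfg)
  r2 <- dissimilarity_scores(co, cond, cfg)
  expect_identical(r1$scaled, r2$scaled)
  expect_identical(r1$raw_median, r2$raw_median)
  expect_true(all(r1$n_scored == cfg$n_iterations))
})

test_that("stronger planted effects never weaken aberrant-cell scores", {
  means <- sapply(c(0.5, 1.5, 3), function(eff) {
    coh <- generate_cohort(small_spec(seed = 31, aberrant_effect = eff))
    m <- log_normalize(coh$matrix)
    sub <- subset_cells(m, cells = m$cells$cell_type == "T")
    co <- embed_cells(sub, n_dims = 10, n_variable = 500)
    r <- dissimilarity_scores(co, sub$cells$condition,
                              dissim_config(n_iterations = 15, master_seed = 5))
    ab <- coh$truth$cells$is_aberrant[match(sub$cells$cell, coh$truth$cells$cell)]
    mean(r$scaled[ab])
  })
  expect_true(all(diff(means) >= -1e-9))
})

test_that("aberrant cells separate with high AUC at the default effect", {
  coh <- small_cohort()
  m <- coh$norm
  sub <- subset_cells(m, cells = m$cells$cell_type == "T")
  co <- embed_cells(sub, n_dims = 20, n_variable = 1000)
  r <- dissimilarity_scores(co, sub$cells$condition,
                            dissim_config(n_iterations = 30, master_seed = 5))
  tr <- coh$truth$cells[match(sub$cells$cell, coh$truth$cells$cell), ]
  id <- sub$cells$condition == "ID"
  expect_gt(rank_auc(r$scaled[id], tr$is_aberrant[id]), 0.9)
})

test_that("reference sets smaller than k + 1 are rejected by name", {
  co <- matrix(rnorm(40), 10, 4, dimnames = list(sprintf("c%d", 1:10), NULL))
  cond <- rep(c("Healthy", "ID"), 5)
  expect_error(
    dissimilarity_scores(co, cond, dissim_config(k = 30, n_iterations = 1),
                         cell_type = "NK"),
    "NK"
  )
})

test_that("group summaries run the stated tests with BH adjustment", {
  # identical per-sample scores across groups -> p = 1 before adjustment
  cells <- tibble::tibble(
    cell = sprintf("c%02d", 1:60),
    sample = rep(sprintf("s%d", 1:6), each = 10),
    condition = rep(c("Healthy", "ID", "LTS"), each = 20),
    patient = rep(c(NA, NA, "P1", "P2", "P1", "P2"), each = 10)
  )
  scores <- tibble::tibble(cell = cells$cell, scaled = rep(rep(c(0.2, 0.8), 3),
                                                           each = 10))
  out <- score_distribution_summary(scores, cells)
  expect_equal(out$tests$p, rep(1, 3))
  expect_true(all(out$tests$p_adj >= out$tests$p))

  # closed-form BH on (0.01, 0.02, 0.03)
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03), method = "BH"),
               c(0.03, 0.03, 0.03))

  # a group with < 2 samples is skipped with a notice
  cells1 <- cells[cells$sample != "s6", ]
  scores1 <- scores[scores$cell %in% cells1$cell, ]
  expect_message(out1 <- score_distribution_summary(scores1, cells1),
                 "fewer than 2")
  expect_true(is.na(out1$tests$p[out1$tests$comparison == "ID vs LTS"]))
})

test_that("a planted shift yields a significant Healthy-vs-ID difference", {
  # five samples per group: the smallest design where a rank-sum test on
  # per-sample means can clear 0.05 after adjustment
  spec <- cohort_spec(
    n_healthy_samples = 5, n_patients = 5,
    cell_types = tibble::tibble(name = c("T", "Plasma"), mean_cells = c(40, 10),
                                n_markers = 15L, n_program = c(100L, 0L)),
    n_genes = 1200, plasma_spec = plasma_spec(n_clones = 5), seed = 13
  )
  coh <- generate_cohort(spec)
  m <- log_normalize(coh$matrix)
  ds <- dissimilarity_by_celltype(m, dissim_config(n_iterations = 30,
                                                   master_seed = 5),
                                  cell_types = "T")
  out <- score_distribution_summary(ds, m$cells)
  expect_lt(out$tests$p_adj[out$tests$comparison == "Healthy vs ID"], 0.05)
})
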