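# plasma-rich cohort at the full gene count: chromosome arms need enough
# genes and cells for arm-level noise to sit clearly below the call cutoff
plasma_fixture <- function() {
  with_fixture("plasma_fixture", {
    spec <- cohort_spec(
      n_healthy_samples = 3, n_patients = 3,
      cell_types = tibble::tibble(name = c("T", "Plasma"),
                                  mean_cells = c(25, 40),
                                  n_markers = 10L, n_program = c(50L, 0L)),
      n_genes = 2000, seed = 42
    )
    coh <- generate_cohort(spec)
    coh$norm <- log_normalize(coh$matrix)
    pc <- subset_cells(coh$norm, cells = coh$norm$cells$cell_type == "Plasma")
    ref <- pc$cells$cell[pc$cells$condition == "Healthy"]
    sub <- plasma_subpopulations(pc, ref)
    prof <- cnv_profile(pc, sub, ref)
    calls <- plasma_calls(pc, sub, call_subpopulations(prof))
    list(spec = spec, coh = coh, pc = pc, ref = ref, sub = sub, prof = prof,
         calls = calls)
  })
}

test_that("genome order excludes IG genes and non-autosomes", {
  genes <- tibble::tibble(
    gene = c("A", "IGHM", "IGKC", "IGLC2", "B", "MTG"),
    chromosome = c("1", "14", "2", "22", "22", "MT"),
    position = 1:6
  )
  ord <- genome_order(genes)
  expect_setequal(ord$gene, c("A", "B"))
  expect_true(all(ord$chromosome %in% as.character(1:22)))
  expect_true(all(c("p", "q") %in% c(genome_order(
    tibble::tibble(gene = letters[1:10], chromosome = "3", position = 1:10))$arm)))
})

test_that("window 1 smoothing is the identity and windows stay in-chromosome", {
  v <- c(1, 5, 3, 8, 2, 9)
  chrom <- c("1", "1", "1", "2", "2", "2")
  expect_equal(marrowscape:::smooth_by_chromosome(v, chrom, 1), v)
  # window 3: chromosome edges shrink symmetrically, no cross-talk
  sm <- marrowscape:::smooth_by_chromosome(v, chrom, 3)
  expect_equal(sm, c(1, 3, 3, 8, (8 + 2 + 9) / 3, 9))
})

test_that("a reference-identical subpopulation profiles near zero", {
  fx <- plasma_fixture()
  pc <- fx$pc
  # score healthy plasma cells from one healthy sample against the others
  h1 <- pc$cells$cell[pc$cells$sample == "H1"]
  ref <- pc$cells$cell[pc$cells$condition == "Healthy" &
                         pc$cells$sample != "H1"]
  prof <- cnv_profile(pc, stats::setNames(rep("h1", length(h1)), h1), ref)
  calls <- call_subpopulations(prof)
  expect_equal(calls$call, "healthy")
  expect_lt(calls$max_abs_arm, 0.15)
})

test_that("planted arm events are recovered and flat elsewhere", {
  fx <- plasma_fixture()
  spec <- fx$spec
  arm_means <- attr(call_subpopulations(fx$prof), "arm_means")
  truth_cells <- fx$coh$truth$cells
  for (pat in c("P1", "P2", "P3")) {
    clone <- unique(stats::na.omit(truth_cells$clone[truth_cells$patient == pat]))
    planted <- spec$plasma_spec$clones$arms[[clone]]
    planted_key <- paste(planted$chromosome, planted$arm)
    # the malignant subpopulation of this patient
    mal_sub <- fx$calls$subpop[fx$calls$patient == pat &
                                 fx$calls$call == "malignant"][1]
    am <- arm_means[arm_means$subpop == mal_sub, ]
    am$key <- paste(am$chromosome, am$arm)
    gain_means <- am$arm_mean[match(planted_key[planted$fold > 1], am$key)]
    loss_means <- am$arm_mean[match(planted_key[planted$fold < 1], am$key)]
    off_event <- am$arm_mean[!am$key %in% planted_key]
    # gains elevated, losses depressed, everything else flat
    expect_gt(mean(gain_means), 0.15)
    expect_lt(mean(loss_means), -0.15)
    expect_gt(min(gain_means), max(abs(off_event)))
    expect_true(all(abs(off_event) < 0.15))
  }
})

test_that("subpopulation calls follow the cutoff and margin rules", {
  mk_prof <- function(vals) {
    tibble::tibble(subpop = "s", gene = sprintf("g%d", seq_along(vals)),
                   chromosome = "1", arm = "p", position = seq_along(vals),
                   value = vals)
  }
  expect_equal(call_subpopulations(mk_prof(rep(0, 10)))$call, "healthy")
  expect_equal(call_subpopulations(mk_prof(rep(0.4, 10)))$call, "malignant")
  # exactly at the cutoff margin -> unclear
  expect_equal(call_subpopulations(mk_prof(rep(0.15, 10)))$call, "unclear")
  expect_equal(call_subpopulations(mk_prof(rep(0.13, 10)))$call, "unclear")
  expect_equal(call_subpopulations(mk_prof(rep(0.11, 10)))$call, "healthy")
})

test_that("the major light chain is determined per patient", {
  fx <- plasma_fixture()
  maj <- major_light_chain(fx$pc, fx$calls)
  spec <- fx$spec
  truth_cells <- fx$coh$truth$cells
  for (i in seq_len(nrow(maj))) {
    clone <- unique(stats::na.omit(
      truth_cells$clone[truth_cells$patient == maj$patient[i]]))
    expect_equal(maj$major_chain[i],
                 spec$plasma_spec$clones$light_chain[clone])
  }
})

test_that("the light-chain refinement rule matches its worked examples", {
  # subpopulation of 5 malignant cells; cell 1 violates the restriction
  lc <- c("IGKC", "IGLC2")
  vals <- matrix(0, 4, 5,
                 dimnames = list(c(lc, "g1", "g2"), sprintf("c%d", 1:5)))
  vals["IGKC", ] <- c(0.4, 1.1, 1.1, 1.1, 1.3)   # mean 0.98; c1 at 0.41x
  vals["IGLC2", ] <- c(1.0, 0.1, 0.1, 0.1, 0.1)  # mean 0.28; c1 at 3.6x
  m <- as_normalized(vals)
  m$cells$sample <- "P9-ID"; m$cells$condition <- "ID"; m$cells$patient <- "P9"
  calls <- tibble::tibble(
    cell = sprintf("c%d", 1:5), sample = "P9-ID", condition = "ID",
    patient = "P9", subpop = "P9.2", call = "malignant", refined = FALSE
  )
  maj <- tibble::tibble(patient = "P9", major_chain = "IGKC")
  out <- refine_calls(m, calls, maj)
  expect_equal(out$call, c("healthy", rep("malignant", 4)))
  expect_equal(out$refined, c(TRUE, rep(FALSE, 4)))

  # conjunction fails: low major chain but no other chain elevated
  vals2 <- vals
  vals2["IGLC2", 1] <- 0.1
  m2 <- as_normalized(vals2)
  out2 <- refine_calls(m2, calls, maj)
  expect_equal(out2$call, rep("malignant", 5))

  # the rule never touches healthy-called cells
  calls3 <- dplyr::mutate(calls, call = "healthy")
  out3 <- refine_calls(m, calls3, maj)
  expect_equal(out3$call, rep("healthy", 5))
  expect_false(any(out3$refined))
})

test_that("refinement can only lower the malignancy score", {
  fx <- plasma_fixture()
  maj <- major_light_chain(fx$pc, fx$calls)
  before <- malignancy_scores(fx$calls)
  after <- malignancy_scores(refine_calls(fx$pc, fx$calls, maj))
  j <- dplyr::inner_join(before, after, by = "sample")
  expect_true(all(j$malignancy_score.y <= j$malignancy_score.x + 1e-12))
})

test_that("malignancy scores are the malignant fraction of plasma cells", {
  calls <- tibble::tibble(
    cell = sprintf("c%d", 1:100), sample = "s1", condition = "ID",
    patient = "P1", subpop = "P1.2",
    call = c(rep("malignant", 40), rep("healthy", 55), rep("unclear", 5)),
    refined = FALSE
  )
  sc <- malignancy_scores(calls)
  expect_equal(sc$malignancy_score, 0.4)   # unclear in denominator only
  sc0 <- malignancy_scores(dplyr::mutate(calls, call = "healthy"))
  expect_equal(sc0$malignancy_score, 0)
})

test_that("planted malignancy scores are recovered across samples", {
  fx <- plasma_fixture()
  maj <- major_light_chain(fx$pc, fx$calls)
  refined <- refine_calls(fx$pc, fx$calls, maj)
  sc <- malignancy_scores(refined)
  cmp <- dplyr::inner_join(sc, fx$coh$truth$samples, by = "sample")
  expect_true(all(abs(cmp$malignancy_score - cmp$planted_malignancy_score) <= 0.05))
  expect_gt(stats::cor(cmp$malignancy_score, cmp$planted_malignancy_score,
                       method = "spearman"), 0.95)
})

test_that("light-chain genes never enter CNV profiles", {
  fx <- plasma_fixture()
  expect_length(intersect(unique(fx$prof$gene), light_chain_genes()), 0)
  expect_false(any(grepl("^IG[HLK]", unique(fx$prof$gene))))
})

test_that("stability distances behave on constructed geometries", {
  # LTS cells identical to ID cells -> within-patient distance 0
  co <- matrix(rnorm(40), 20, 2,
               dimnames = list(sprintf("c%d", 1:20), NULL))
  co[11:20, ] <- co[1:10, ]
  meta <- tibble::tibble(
    cell = rownames(co),
    patient = rep(c("P1", "P2"), each = 5, times = 2),
    condition = rep(c("ID", "LTS"), each = 10)
  )
  expect_message(out <- stability_distance(co, meta), "skipped")
  expect_equal(out$distances$within_patient, c(0, 0))
  expect_true(is.na(out$p_value))

  # well-separated patient clusters with small temporal drift
  # six patients: the smallest size where a one-sided signed-rank test can
  # clear 0.05 with every pair in the expected direction
  set.seed(12)
  n_pat <- 6
  centers <- 50 * cbind(c(0, 1, 0, 1, 2, 2), c(0, 0, 1, 1, 0, 1))
  cells <- list(); metas <- list()
  for (p in seq_len(n_pat)) {
    id <- sweep(matrix(rnorm(10 * 2, sd = 0.5), 10, 2), 2, centers[p, ], "+")
    lts <- id + matrix(rnorm(10 * 2, sd = 0.5), 10, 2) + 1
    cells[[p]] <- rbind(id, lts)
    metas[[p]] <- tibble::tibble(
      cell = sprintf("p%d_%02d", p, 1:20),
      patient = sprintf("P%d", p),
      condition = rep(c("ID", "LTS"), each = 10)
    )
  }
  co2 <- do.call(rbind, cells)
  meta2 <- dplyr::bind_rows(metas)
  rownames(co2) <- meta2$cell
  out2 <- stability_distance(co2, meta2)
  expect_true(all(out2$distances$within_patient <
                    out2$distances$nearest_neighbor))
  expect_lt(out2$p_value, 0.05)
})
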