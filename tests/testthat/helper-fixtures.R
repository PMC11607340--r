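# Shared fixtures, built once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

with_fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures)
}

# A reduced two-compartment cohort: one perturbed immune type plus plasma
# cells, enough for every recovery check while staying fast.
small_spec <- function(seed = 42, ...) {
  cohort_spec(
    n_healthy_samples = 3, n_patients = 3,
    cell_types = tibble::tibble(
      name = c("T", "Plasma"),
      mean_cells = c(60, 30),
      n_markers = 15L,
      n_program = c(100L, 0L)
    ),
    n_genes = 1200,
    seed = seed,
    ...
  )
}

small_cohort <- function() {
  with_fixture("small_cohort", {
    coh <- generate_cohort(small_spec())
    coh$norm <- log_normalize(coh$matrix)
    coh
  })
}

# dense toy counts -> log-normalized cell_matrix
toy_matrix <- function(counts, normalize = TRUE) {
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("c%03d", seq_len(ncol(counts)))
  m <- cell_matrix(counts)
  if (normalize) m <- log_normalize(m)
  m
}

# treat the given values directly as the normalized layer (for rule tests
# stated on normalized expression)
as_normalized <- function(values) {
  if (is.null(rownames(values))) rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- sprintf("c%03d", seq_len(ncol(values)))
  m <- cell_matrix(values)
  m$logcounts <- methods::as(Matrix::Matrix(values, sparse = TRUE), "CsparseMatrix")
  m
}

rank_auc <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive); n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Independent O(n^2) oracle: plain loops over an explicit distance matrix,
# replicating only the documented seeding contract for the balanced
# reference subsample.
brute_force_scores <- function(coords, conditions, cfg) {
  n <- nrow(coords)
  i0 <- cfg$reference[1]; i1 <- cfg$reference[2]
  idx0 <- which(conditions == i0); idx1 <- which(conditions == i1)
  n_each <- min(length(idx0), length(idx1))
  raw <- matrix(NA_real_, n, cfg$n_iterations)
  d <- as.matrix(stats::dist(coords))
  for (t in seq_len(cfg$n_iterations)) {
    sub <- withr::with_seed(cfg$master_seed + t,
                            c(sample(idx0, n_each), sample(idx1, n_each)))
    ref <- sort(sub)
    for (q in seq_len(n)) {
      dv <- d[q, ref]
      dv[ref == q] <- Inf
      nb <- ref[order(dv, seq_along(dv))][seq_len(cfg$k)]
      raw[q, t] <- sum(conditions[nb] == i1) / cfg$k
    }
  }
  med <- apply(raw, 1, stats::median)
  (med - min(med)) / (max(med) - min(med))
}

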