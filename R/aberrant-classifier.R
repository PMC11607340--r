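#' Classifier configuration for aberrant/healthy-like cell states
#'
#' @param healthy_quantile Calibration quantile: the dissimilarity threshold
#'   is set so that this fraction of healthy-control cells falls at or below
#'   it (default 0.99).
#' @param train_fraction Training share of the stratified split (default
#'   0.8).
#' @param n_variable_genes Expression features used by the classifier
#'   (default 500; 500-1000 is the usual range).
#' @param prob_threshold Minimum class probability for a defined call
#'   (default 0.66); cells below it are `undefined`.
#' @param seed Controls the split and model fit.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(healthy_quantile = 0.99, train_fraction = 0.8,
                              n_variable_genes = 500, prob_threshold = 0.66,
                              seed = 1L) {
  stopifnot(healthy_quantile > 0, healthy_quantile < 1,
            train_fraction > 0, train_fraction < 1,
            prob_threshold >= 0.5, prob_threshold <= 1,
            n_variable_genes >= 1)
  structure(list(healthy_quantile = healthy_quantile,
                 train_fraction = train_fraction,
                 n_variable_genes = as.integer(n_variable_genes),
                 prob_threshold = prob_threshold, seed = as.integer(seed)),
            class = "classifier_config")
}

#' Calibrate the dissimilarity threshold on healthy-control cells
#'
#' The threshold is the empirical `q`-quantile of the healthy-control
#' scores, taken as the inverse empirical CDF (quantile type 1:
#' `x_(ceil(nq))`), which guarantees that at least a fraction `q` of
#' healthy cells lies at or below it on any input — the definitional
#' calibration of the healthy-like state. Interpolating quantile types do
#' not carry this guarantee.
#'
#' @param healthy_scores Scaled dissimilarity scores of healthy-control
#'   cells.
#' @param q Calibration quantile (default 0.99).
#' @return The threshold (numeric scalar).
#' @export
calibrate_threshold <- function(healthy_scores, q = 0.99) {
  healthy_scores <- healthy_scores[!is.na(healthy_scores)]
  if (!length(healthy_scores)) stop("No healthy-control scores.", call. = FALSE)
  if (length(healthy_scores) < 100) {
    warning("Fewer than 100 healthy cells; the calibration quantile is coarse.",
            call. = FALSE)
  }
  unname(stats::quantile(healthy_scores, probs = q, type = 1))
}

#' Assign training labels from condition and calibrated threshold
#'
#' Healthy-condition cells at or below the threshold become `healthy-like`;
#' ID cells above it become `aberrant-like`; every other cell (including
#' all LTS cells) is `unlabeled` and enters only at prediction time.
#'
#' @param scores Scaled dissimilarity score per cell.
#' @param conditions Condition label per cell.
#' @param threshold From [calibrate_threshold()].
#' @return A tibble `cell` (index or names), `training_label`.
#' @export
assign_training_labels <- function(scores, conditions, threshold) {
  stopifnot(length(scores) == length(conditions))
  lab <- dplyr::case_when(
    conditions == "Healthy" & scores <= threshold ~ "healthy-like",
    conditions == "ID" & scores > threshold ~ "aberrant-like",
    .default = "unlabeled"
  )
  tibble::tibble(cell = names(scores) %||% as.character(seq_along(scores)),
                 training_label = lab)
}

#' Train the state classifier and predict all cells
#'
#' A ridge-regularised logistic regression (the package's reference choice
#' of probabilistic binary classifier) is trained on the labeled cells'
#' top-variable-gene expression after a stratified train/test split; the F1
#' score is reported on the held-out split, and every cell — labeled or not
#' — receives a predicted state: `healthy-like` or `aberrant-like` by
#' larger class probability, or `undefined` when the larger probability is
#' below `prob_threshold`.
#'
#' @param m A log-normalized [cell_matrix()] of the analysed population.
#' @param labels Tibble from [assign_training_labels()], aligned with the
#'   cells of `m`.
#' @param cfg A [classifier_config()].
#' @return An `aberrant_fit` list: `states` tibble (`cell`,
#'   `training_label`, `split`, `prob_aberrant`, `state`), `f1`, and the
#'   held-out `confusion` matrix.
#' @export
train_and_predict <- function(m, labels, cfg = classifier_config()) {
  stopifnot(inherits(m, "cell_matrix"))
  ln <- logcounts_layer(m)
  stopifnot(nrow(labels) == ncol(ln))
  genes <- rank_variable_genes(m, min(cfg$n_variable_genes, nrow(ln)))
  x <- t(as.matrix(ln[genes, , drop = FALSE]))

  lab <- labels$training_label
  pos <- lab == "aberrant-like"
  neg <- lab == "healthy-like"
  if (!any(pos) || !any(neg)) {
    stop("Both training classes must be non-empty.", call. = FALSE)
  }
  split <- rep(NA_character_, length(lab))
  withr::with_seed(cfg$seed, {
    for (cls in list(which(pos), which(neg))) { # stratified split
      n_tr <- max(1L, round(cfg$train_fraction * length(cls)))
      tr <- sample(cls, n_tr)
      split[tr] <- "train"
      split[setdiff(cls, tr)] <- "test"
    }
  })
  y <- ifelse(pos, 1, 0)
  tr_i <- which(split == "train")
  te_i <- which(split == "test")
  # ridge fit along an explicit decreasing penalty path (glmnet's automatic
  # ridge path never reaches light penalties, and single-lambda fits are
  # numerically unstable); predictions taken at a light penalty so class
  # probabilities stay sharp enough for the defined/undefined rule
  lam_path <- exp(seq(log(100), log(1e-3), length.out = 60))
  fit <- glmnet::glmnet(x[tr_i, , drop = FALSE], y[tr_i], family = "binomial",
                        alpha = 0, lambda = lam_path, standardize = TRUE)
  prob <- as.numeric(stats::predict(fit, newx = x, type = "response", s = 0.01))

  pred_class <- ifelse(prob >= 0.5, "aberrant-like", "healthy-like")
  state <- ifelse(pmax(prob, 1 - prob) < cfg$prob_threshold, "undefined", pred_class)

  truth_te <- factor(ifelse(pos[te_i], "aberrant-like", "healthy-like"),
                     levels = c("healthy-like", "aberrant-like"))
  pred_te <- factor(pred_class[te_i], levels = c("healthy-like", "aberrant-like"))
  confusion <- table(truth = truth_te, predicted = pred_te)
  tp <- confusion["aberrant-like", "aberrant-like"]
  fp <- confusion["healthy-like", "aberrant-like"]
  fn <- confusion["aberrant-like", "healthy-like"]
  f1 <- if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)

  states <- tibble::tibble(
    cell = labels$cell,
    training_label = lab,
    split = split,
    prob_aberrant = prob,
    state = state
  )
  structure(list(states = states, f1 = unname(f1), confusion = confusion,
                 genes = genes, config = cfg),
            class = "aberrant_fit")
}

#' @export
print.aberrant_fit <- function(x, ...) {
  cat(sprintf("<aberrant_fit> %d cells, held-out F1 = %.3f\n",
              nrow(x$states), x$f1))
  print(table(x$states$state))
  invisible(x)
}

#' @export
tidy.aberrant_fit <- function(x, ...) x$states

#' @export
glance.aberrant_fit <- function(x, ...) {
  tibble::tibble(
    f1 = x$f1,
    n_train = sum(x$states$split == "train", na.rm = TRUE),
    n_test = sum(x$states$split == "test", na.rm = TRUE),
    frac_undefined = mean(x$states$state == "undefined"),
    prob_threshold = x$config$prob_threshold
  )
}

#' Predicted state fractions per clinical group
#'
#' Per sample, the fractions of healthy-like / aberrant-like / undefined
#' cells (summing to 1), with per-group mean and standard error of the mean
#' across samples. A group with a single sample gets SEM 0 with a notice.
#'
#' @param states Tibble with `cell` and `state` (e.g. from
#'   [train_and_predict()]`$states`).
#' @param cells Per-cell metadata (`cell`, `sample`, `condition`).
#' @return A list: `per_sample` and `per_group` tibbles.
#' @export
state_fractions_by_group <- function(states, cells) {
  df <- dplyr::inner_join(tibble::as_tibble(states)[, c("cell", "state")],
                          cells, by = "cell")
  state_levels <- c("healthy-like", "aberrant-like", "undefined")
  counts <- dplyr::count(df, .data$sample, .data$condition, .data$state)
  grid <- tidyr::expand_grid(dplyr::distinct(df, .data$sample, .data$condition),
                             state = state_levels)
  per_sample <- grid |>
    dplyr::left_join(counts, by = c("sample", "condition", "state")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    dplyr::group_by(.data$sample) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$sample, .data$state)
  per_group <- per_sample |>
    dplyr::group_by(.data$condition, .data$state) |>
    dplyr::summarise(
      mean_fraction = mean(.data$fraction),
      sem = if (dplyr::n() > 1) stats::sd(.data$fraction) / sqrt(dplyr::n()) else 0,
      n_samples = dplyr::n(), .groups = "drop"
    )
  if (any(per_group$n_samples == 1)) {
    message("Group(s) with a single sample: SEM reported as 0.")
  }
  list(per_sample = per_sample, per_group = per_group)
}
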