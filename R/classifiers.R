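# Validation schemes (grouped holdout and leave-one-well-out x replicates),
# risk aggregation from window probabilities to well and concentration
# calls, and the SVM baselines (linear on image features; one-class and
# multi-class on time-series / burst-parameter vectors). The well is the
# biological unit: a well's windows never appear on both sides of a split.

#' Grouped train/validation/test split
#'
#' Test wells are held out entirely; the windows of the remaining (training)
#' wells are split at random into a training and a validation partition.
#'
#' @param wells Character vector, one entry per window, naming its well.
#' @param test_wells Wells excluded from training (may be empty).
#' @param train_fraction Fraction of training-well windows used for fitting
#'   (default 0.75; the rest is the validation partition for early
#'   stopping). Must lie strictly between 0 and 1 -- a 1.0 fraction leaves
#'   no validation partition and is an error.
#' @param seed Seed of the window shuffle.
#' @return An object of class `dataset_split` with `train_idx`, `val_idx`,
#'   `test_idx`, `train_wells`, `test_wells`.
#' @export
make_dataset_split <- function(wells, test_wells = character(),
                               train_fraction = 0.75, seed = 1) {
  .assert(train_fraction > 0 && train_fraction < 1,
          "train_fraction must be in (0, 1): a validation partition is required")
  wells <- as.character(wells)
  train_wells <- setdiff(unique(wells), test_wells)
  .assert(length(train_wells) >= 1, "no training wells left")
  cand <- which(wells %in% train_wells)
  perm <- withr::with_seed(seed, sample(cand))
  ntr <- round(train_fraction * length(cand))
  ntr <- min(max(ntr, 1L), length(cand) - 1L)
  split <- structure(list(train_idx = sort(perm[seq_len(ntr)]),
                          val_idx = sort(perm[-seq_len(ntr)]),
                          test_idx = which(wells %in% test_wells),
                          train_wells = train_wells,
                          test_wells = test_wells),
                     class = "dataset_split")
  assert_no_leakage(split, wells)
  split
}

#' Assert that a split leaks no test well into training
#'
#' @param split A [make_dataset_split()] (or compatible list).
#' @param wells Character vector, one entry per window.
#' @return Invisibly `TRUE`; otherwise a hard failure naming the leaked
#'   wells.
#' @export
assert_no_leakage <- function(split, wells) {
  wells <- as.character(wells)
  leak <- intersect(unique(wells[c(split$train_idx, split$val_idx)]),
                    split$test_wells)
  .assert(length(leak) == 0,
          "leakage: test well(s) %s appear in the training partitions",
          paste(leak, collapse = ", "))
  leak2 <- intersect(split$train_wells, split$test_wells)
  .assert(length(leak2) == 0, "leakage: well(s) %s in both train and test sets",
          paste(leak2, collapse = ", "))
  invisible(TRUE)
}

#' Aggregate window probabilities into well and concentration risk
#'
#' Window-level positive probabilities are aggregated per well and
#' concentration: in `"proportion"` mode (default) a well's risk is the
#' fraction of its windows called positive at the window threshold; in
#' `"mean_prob"` mode it is the mean positive probability. The
#' concentration-level risk is the mean of its wells' risks, and the final
#' call is positive when that risk reaches the call threshold (50%).
#'
#' @param p_pos Numeric vector of per-window positive-class probabilities.
#' @param meta Data frame (same rows) with `well`, `compound`,
#'   `concentration`, and `is_vehicle`.
#' @param mode `"proportion"` or `"mean_prob"`.
#' @param window_threshold Window-level positive call threshold
#'   (default 0.5).
#' @param call_threshold Risk call threshold (default 0.5).
#' @return An object of class `risk_prediction`: list of data frames
#'   `wells` (per well x concentration) and `concentrations` (per compound
#'   x concentration with `risk` and logical `call`).
#' @export
aggregate_risk <- function(p_pos, meta, mode = c("proportion", "mean_prob"),
                           window_threshold = 0.5, call_threshold = 0.5) {
  mode <- match.arg(mode)
  .assert(length(p_pos) == nrow(meta), "one probability per window required")
  .assert(length(p_pos) > 0, "empty prediction set")
  .assert(all(p_pos >= 0 & p_pos <= 1), "probabilities must lie in [0, 1]")
  g <- interaction(meta$compound, meta$concentration, meta$is_vehicle,
                   meta$well, drop = TRUE)
  wl <- lapply(split(seq_along(p_pos), g), function(i) {
    risk <- if (mode == "proportion") mean(p_pos[i] >= window_threshold)
            else mean(p_pos[i])
    data.frame(well = meta$well[i[1]], compound = meta$compound[i[1]],
               concentration = meta$concentration[i[1]],
               is_vehicle = meta$is_vehicle[i[1]],
               n_windows = length(i), risk = risk)
  })
  wells <- do.call(rbind, wl)
  rownames(wells) <- NULL
  g2 <- interaction(wells$compound, wells$concentration, wells$is_vehicle,
                    drop = TRUE)
  cl <- lapply(split(seq_len(nrow(wells)), g2), function(i) {
    data.frame(compound = wells$compound[i[1]],
               concentration = wells$concentration[i[1]],
               is_vehicle = wells$is_vehicle[i[1]],
               n_wells = length(i), risk = mean(wells$risk[i]))
  })
  conc <- do.call(rbind, cl)
  conc$call <- conc$risk >= call_threshold
  conc <- conc[order(conc$compound, !conc$is_vehicle, conc$concentration), ]
  rownames(conc) <- NULL
  structure(list(wells = wells, concentrations = conc, mode = mode),
            class = "risk_prediction")
}

#' Holdout training and prediction on unlearned wells
#'
#' Fits a pattern network with a 75/25 window split inside the training
#' wells and predicts the windows of wells held out entirely.
#'
#' @param x Feature matrix (rows = windows).
#' @param y Window labels.
#' @param wells Well of each window.
#' @param test_wells Held-out wells (must be disjoint from training wells).
#' @param spec A [pattern_net_spec()].
#' @param train_fraction Window split inside training wells (default 0.75).
#' @param seed Split seed (defaults to the spec seed).
#' @param split Optional pre-built [make_dataset_split()]; it is checked for
#'   leakage before any training.
#' @return List with the trained `model`, the `split`, and `test_probs`
#'   (probability matrix of the test-well windows).
#' @export
run_holdout <- function(x, y, wells, test_wells, spec,
                        train_fraction = 0.75, seed = spec$seed,
                        split = NULL) {
  if (is.null(split))
    split <- make_dataset_split(wells, test_wells, train_fraction, seed)
  assert_no_leakage(split, wells)
  model <- train_pattern_net(x, y, split, spec)
  probs <- if (length(split$test_idx))
    predict_windows(model, x[split$test_idx, , drop = FALSE]) else NULL
  list(model = model, split = split, test_probs = probs,
       test_idx = split$test_idx)
}

#' Leave-one-well-out cross-validation with replicate models
#'
#' Each well is held out in turn; `replicates` models (differing only in
#' seed, hence initialization and window shuffling) are trained on the other
#' wells with a 75/25 window split, so `W x replicates` models are trained
#' in total. The held-out well's per-window class distribution is the
#' element-wise mean over its replicate models.
#'
#' @param x Feature matrix.
#' @param y Window labels.
#' @param wells Well of each window.
#' @param spec A [pattern_net_spec()].
#' @param replicates Replicate models per held-out well (default 5).
#' @param train_fraction Window split inside training wells.
#' @param seed Base seed; each (well, replicate) derives its own seed.
#' @return List with `probs` (per-window mean class-probability matrix, row
#'   order matching `x`), `wells`, `n_models` (= W x replicates), and
#'   `per_model_probs` when `keep_replicates = TRUE`.
#' @param keep_replicates Keep each replicate's prediction matrices.
#' @export
run_leave_one_well_out <- function(x, y, wells, spec, replicates = 5,
                                   train_fraction = 0.75, seed = 1,
                                   keep_replicates = FALSE) {
  .assert(replicates >= 1, "replicates must be >= 1")
  wells <- as.character(wells)
  uw <- unique(wells)
  .assert(length(uw) >= 2, "leave-one-well-out needs at least 2 wells")
  y <- factor(y)
  probs <- matrix(NA_real_, nrow(x), nlevels(y),
                  dimnames = list(NULL, levels(y)))
  reps <- if (keep_replicates) list() else NULL
  n_models <- 0L
  for (wi in seq_along(uw)) {
    w <- uw[wi]
    idx <- which(wells == w)
    acc <- matrix(0, length(idx), nlevels(y))
    for (r in seq_len(replicates)) {
      s <- .child_seed(seed, wi, r)
      spec_r <- spec; spec_r$seed <- s
      fit <- run_holdout(x, y, wells, test_wells = w, spec = spec_r,
                         train_fraction = train_fraction, seed = s)
      acc <- acc + fit$test_probs
      n_models <- n_models + 1L
      if (keep_replicates)
        reps[[sprintf("%s_rep%d", w, r)]] <- fit$test_probs
    }
    probs[idx, ] <- acc / replicates
  }
  list(probs = probs, wells = wells, n_models = n_models,
       per_model_probs = reps)
}

#' Aggregate drug-identification probabilities per concentration
#'
#' @param probs Per-window class-probability matrix (e.g. from
#'   [run_leave_one_well_out()]).
#' @param meta Data frame (same rows) with `well`, `compound`,
#'   `concentration`, `is_vehicle`.
#' @return An object of class `drug_id_prediction`: data frame per
#'   (compound, concentration) with the mean class distribution (columns
#'   `p.<class>`), the `predicted` class (argmax; ties broken by class
#'   order), and window counts.
#' @export
aggregate_drug_id <- function(probs, meta) {
  .assert(nrow(probs) == nrow(meta), "one probability row per window required")
  g <- interaction(meta$compound, meta$concentration, meta$is_vehicle,
                   drop = TRUE)
  rows <- lapply(split(seq_len(nrow(probs)), g), function(i) {
    p <- colMeans(probs[i, , drop = FALSE])
    out <- data.frame(compound = meta$compound[i[1]],
                      concentration = meta$concentration[i[1]],
                      is_vehicle = meta$is_vehicle[i[1]],
                      n_windows = length(i),
                      predicted = colnames(probs)[which.max(p)])
    out[paste0("p.", colnames(probs))] <- as.list(p)
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$compound, !out$is_vehicle, out$concentration), ]
  rownames(out) <- NULL
  class(out) <- c("drug_id_prediction", "data.frame")
  out
}

#' Linear SVM baseline on image features
#'
#' Maximum-margin linear separator on the same 4096-d features as the
#' pattern network; the signed decision values are exported as ROC scores
#' oriented toward `positive_class`.
#'
#' @param x Feature matrix.
#' @param y Binary labels.
#' @param train_idx,test_idx Row indices for fitting and scoring.
#' @param positive_class Level treated as positive (default: first level).
#' @param cost Soft-margin cost (default 1).
#' @return List with the fitted `model`, `scores` (decision values of
#'   `test_idx`), `predicted` labels, and `positive_class`.
#' @export
train_linear_svm <- function(x, y, train_idx, test_idx,
                             positive_class = NULL, cost = 1) {
  y <- factor(y)
  .assert(nlevels(droplevels(y[train_idx])) == 2,
          "linear SVM baseline needs two classes in the training data")
  positive_class <- positive_class %||% levels(y)[1]
  .assert(positive_class %in% levels(y), "unknown positive_class")
  model <- e1071::svm(x[train_idx, , drop = FALSE],
                      droplevels(y[train_idx]),
                      kernel = "linear", scale = FALSE, cost = cost)
  pred <- stats::predict(model, x[test_idx, , drop = FALSE],
                         decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  # e1071 orients the decision value toward the class named first in the
  # "A/B" column label
  first <- strsplit(colnames(dv)[1], "/")[[1]][1]
  scores <- if (identical(first, positive_class)) dv[, 1] else -dv[, 1]
  list(model = model, scores = unname(scores),
       predicted = as.character(pred), positive_class = positive_class)
}

#' Time-series feature vector of one well epoch
#'
#' 34 summary parameters of a 600-s epoch: the mean firing frequency and
#' mean inter-spike interval (ISI) of the pooled well, then the same pair
#' for each of the 16 electrodes. A train with fewer than 2 spikes has no
#' ISI; the epoch duration is used as its upper-bound code (recorded in the
#' `n_isi_missing` attribute).
#'
#' @param rec A [well_recording()].
#' @return Named numeric vector of length 34 (`pooled_rate_hz`,
#'   `pooled_isi_s`, then `e<k>_rate_hz` / `e<k>_isi_s` for k = 0..15).
#' @export
compute_timeseries_features <- function(rec) {
  .assert(inherits(rec, "well_recording"), "well_recording required")
  dur <- rec$duration_s
  isi_of <- function(times) if (length(times) >= 2) mean(diff(times)) else NA_real_
  pool <- .pool_spikes(rec)
  vals <- c(pooled_rate_hz = nrow(pool) / dur,
            pooled_isi_s = isi_of(pool$time))
  for (e in 0:15) {
    tt <- rec$spike_trains[[e + 1]]$times
    v <- c(length(tt) / dur, isi_of(tt))
    names(v) <- sprintf(c("e%02d_rate_hz", "e%02d_isi_s"), e)
    vals <- c(vals, v)
  }
  n_miss <- sum(is.na(vals))
  vals[is.na(vals)] <- dur  # missing-ISI code: the epoch duration
  attr(vals, "n_isi_missing") <- n_miss
  vals
}

#' One-class SVM risk baseline
#'
#' A radial-basis one-class SVM trained only on negative (vehicle /
#' seizure-free) feature vectors; test vectors whose decision score falls
#' below 0 are outliers and flagged as at seizure risk.
#'
#' @param train_x Negative-class training matrix (rows = samples).
#' @param test_x Test matrix.
#' @param nu One-class nu parameter (default 0.1).
#' @param gamma RBF width; `"scale"` (default) uses
#'   `1 / (ncol(train_x) * var(train_x))`.
#' @return Data frame with `score` (decision value; negative = outlier) and
#'   logical `at_risk` per test row, plus the fitted model as attribute
#'   `"model"`.
#' @export
one_class_risk_baseline <- function(train_x, test_x, nu = 0.1,
                                    gamma = "scale") {
  .assert(is.matrix(train_x) && nrow(train_x) >= 1,
          "non-empty negative training set required")
  if (identical(gamma, "scale")) {
    v <- stats::var(as.vector(train_x))
    gamma <- 1 / (ncol(train_x) * max(v, 1e-12))
  }
  model <- e1071::svm(train_x, y = NULL, type = "one-classification",
                      kernel = "radial", nu = nu, gamma = gamma,
                      scale = FALSE)
  pred <- stats::predict(model, test_x, decision.values = TRUE)
  dv <- as.numeric(attr(pred, "decision.values"))
  out <- data.frame(score = dv, at_risk = dv < 0)
  attr(out, "model") <- model
  out
}

#' Multi-class SVM drug identification with leave-one-well-out
#'
#' Linear multi-class SVM (one-vs-one voting) on summary feature vectors;
#' one model per held-out well (no replicates). Held-out windows are
#' aggregated per (compound, concentration) by majority vote with ties
#' broken by class order.
#'
#' @param x Feature matrix (e.g. time-series or burst-parameter vectors).
#' @param y Compound labels.
#' @param wells Well of each row.
#' @param meta Data frame (same rows) with `compound`, `concentration`,
#'   `is_vehicle`.
#' @param cost Soft-margin cost.
#' @return List with `predictions` (per concentration: `predicted`
#'   compound), `window_pred` (per-row held-out predictions), and
#'   `n_models` (= number of wells).
#' @export
multiclass_svm_drug_id <- function(x, y, wells, meta, cost = 1) {
  y <- factor(y)
  wells <- as.character(wells)
  uw <- unique(wells)
  .assert(length(uw) >= 2, "leave-one-well-out needs at least 2 wells")
  window_pred <- character(nrow(x))
  for (w in uw) {
    tr <- which(wells != w)
    te <- which(wells == w)
    .assert(nlevels(droplevels(y[tr])) >= 2, "training folds need >= 2 classes")
    model <- e1071::svm(x[tr, , drop = FALSE], droplevels(y[tr]),
                        kernel = "linear", scale = FALSE, cost = cost)
    window_pred[te] <- as.character(stats::predict(model, x[te, , drop = FALSE]))
  }
  g <- interaction(meta$compound, meta$concentration, meta$is_vehicle,
                   drop = TRUE)
  rows <- lapply(split(seq_len(nrow(x)), g), function(i) {
    votes <- table(factor(window_pred[i], levels = levels(y)))
    data.frame(compound = meta$compound[i[1]],
               concentration = meta$concentration[i[1]],
               is_vehicle = meta$is_vehicle[i[1]],
               predicted = names(votes)[which.max(votes)],  # first = class order
               n_windows = length(i))
  })
  predictions <- do.call(rbind, rows)
  rownames(predictions) <- NULL
  list(predictions = predictions, window_pred = window_pred,
       n_models = length(uw))
}
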