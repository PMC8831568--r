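test_that("grouped splits keep held-out wells out of training", {
  wells <- rep(c("w1", "w2", "w3", "w4"), each = 10)
  s <- make_dataset_split(wells, test_wells = c("w4"), seed = 1)
  expect_length(s$test_idx, 10)
  expect_length(intersect(c(s$train_idx, s$val_idx), s$test_idx), 0)
  expect_equal(length(s$train_idx), 22)  # round(0.75 * 30)
  expect_equal(length(s$val_idx), 8)

  expect_error(make_dataset_split(wells, "w4", train_fraction = 1),
               "validation partition")
  expect_error(make_dataset_split(wells, unique(wells)), "no training wells")

  # deliberately corrupted split triggers the leakage contract
  bad <- s
  bad$train_idx <- c(bad$train_idx, s$test_idx[1])
  expect_error(assert_no_leakage(bad, wells), "leakage")
})

test_that("risk aggregation follows the stated arithmetic in both modes", {
  meta1 <- data.frame(well = "w1", compound = "d", concentration = 1,
                      is_vehicle = FALSE)[rep(1, 3), ]
  probs <- c(0.2, 0.4, 0.6)
  expect_equal(aggregate_risk(probs, meta1, "proportion")$wells$risk, 1 / 3)
  expect_equal(aggregate_risk(probs, meta1, "mean_prob")$wells$risk, 0.4)

  # all windows at probability 1 -> risk 100%, positive call
  r1 <- aggregate_risk(rep(1, 3), meta1)
  expect_equal(r1$concentrations$risk, 1)
  expect_true(r1$concentrations$call)

  # two wells with risks 0.4 and 0.8 average to 0.6 -> positive
  meta2 <- data.frame(well = rep(c("w1", "w2"), each = 5), compound = "d",
                      concentration = 1, is_vehicle = FALSE)
  p2 <- c(rep(c(0.9, 0.1), c(2, 3)), rep(c(0.9, 0.1), c(4, 1)))
  r2 <- aggregate_risk(p2, meta2, "proportion")
  expect_equal(sort(r2$wells$risk), c(0.4, 0.8))
  expect_equal(r2$concentrations$risk, 0.6)
  expect_true(r2$concentrations$call)

  # aggregation is invariant to window order
  o <- withr::with_seed(4, sample(nrow(meta2)))
  r3 <- aggregate_risk(p2[o], meta2[o, ], "proportion")
  expect_equal(r3$concentrations$risk, r2$concentrations$risk)

  expect_error(aggregate_risk(numeric(), meta2[0, ]), "empty")
  expect_error(aggregate_risk(c(0.5, 1.2), meta1[1:2, ]), "\\[0, 1\\]")
})

test_that("holdout trains within wells and predicts unlearned wells", {
  fx <- separable_fixture(80, seed = 40)
  wells <- rep(rep(c("w1", "w2", "w3", "w4"), length.out = 80), 2)
  fit <- run_holdout(fx$x, fx$y, wells, test_wells = "w4",
                     spec = pattern_net_spec(seed = 2))
  expect_false("w4" %in% wells[c(fit$split$train_idx, fit$split$val_idx)])
  pred <- colnames(fit$test_probs)[max.col(fit$test_probs)]
  expect_equal(mean(pred == as.character(fx$y[fit$test_idx])), 1.0)

  bad <- fit$split
  bad$train_idx <- c(bad$train_idx, fit$split$test_idx[1])
  expect_error(run_holdout(fx$x, fx$y, wells, "w4",
                           pattern_net_spec(seed = 2), split = bad),
               "leakage")
})

test_that("leave-one-well-out trains W x R models and averages replicates", {
  fx <- separable_fixture(30, seed = 50)
  wells <- rep(rep(c("w1", "w2", "w3"), length.out = 30), 2)
  loo <- run_leave_one_well_out(fx$x, fx$y, wells,
                                pattern_net_spec(seed = 3, max_iterations = 40),
                                replicates = 2, keep_replicates = TRUE)
  expect_equal(loo$n_models, 6)  # W = 3, R = 2
  expect_false(any(is.na(loo$probs)))
  # the held-out distribution is the element-wise mean of the replicates
  idx <- which(wells == "w2")
  manual <- (loo$per_model_probs$w2_rep1 + loo$per_model_probs$w2_rep2) / 2
  expect_equal(loo$probs[idx, ], manual, ignore_attr = TRUE)

  expect_error(run_leave_one_well_out(fx$x, fx$y, wells,
                                      pattern_net_spec(seed = 1),
                                      replicates = 0), "replicates")
  expect_error(run_leave_one_well_out(fx$x, fx$y, rep("w1", 60),
                                      pattern_net_spec(seed = 1)),
               "at least 2 wells")
})

test_that("linear SVM separates the fixture and orients its ROC scores", {
  fx <- separable_fixture(60, seed = 60)
  tr <- seq(1, 120, by = 2); te <- seq(2, 120, by = 2)
  sv <- train_linear_svm(fx$x, fx$y, tr, te, positive_class = "a")
  expect_equal(mean(sv$predicted == as.character(fx$y[te])), 1.0)
  expect_true(all(sv$scores[fx$y[te] == "a"] > 0))
  expect_true(all(sv$scores[fx$y[te] == "b"] < 0))
  sv2 <- train_linear_svm(fx$x, fx$y, tr, te, positive_class = "a")
  expect_identical(sv$scores, sv2$scores)

  # 1-d two-support-point case: the margin midpoint is at the origin, so
  # the decision value sign matches the side of the midpoint
  x1 <- matrix(c(-1, 1, -1.2, 0.9, -0.8, 1.1), ncol = 1)
  y1 <- factor(c("neg", "pos", "neg", "pos", "neg", "pos"))
  sv3 <- train_linear_svm(x1, y1, 1:2, 3:6, positive_class = "pos")
  expect_equal(sv3$scores > 0, c(FALSE, TRUE, FALSE, TRUE))

  expect_error(train_linear_svm(fx$x, factor(rep("a", 120)), tr, te),
               "two classes")
})

test_that("time-series features encode pooled and per-electrode activity", {
  f0 <- compute_timeseries_features(empty_rec())
  expect_length(f0, 34)
  expect_equal(unname(f0[["pooled_rate_hz"]]), 0)
  expect_equal(unname(f0[["e00_isi_s"]]), 600)  # missing-ISI upper-bound code
  expect_equal(attr(f0, "n_isi_missing"), 17)

  # every electrode firing regularly at 1 Hz
  df <- do.call(rbind, lapply(0:15, function(e)
    data.frame(electrode = e, time = seq(0.6 + e * 1e-3, 599.5, by = 1))))
  f1 <- compute_timeseries_features(rec_from_df(df))
  expect_equal(unname(f1[["e07_rate_hz"]]), 599 / 600)
  expect_equal(unname(f1[["e07_isi_s"]]), 1, tolerance = 1e-9)
  expect_equal(unname(f1[["pooled_rate_hz"]]), 16 * 599 / 600)
})

test_that("one-class SVM flags far outliers and keeps training centroids", {
  x <- withr::with_seed(70, matrix(rnorm(200 * 10), 200))
  centroid <- matrix(colMeans(x), 1)
  far <- matrix(10, 1, 10)  # ~10 sd outside in every dimension
  res <- one_class_risk_baseline(x, rbind(centroid, far))
  expect_false(res$at_risk[1])
  expect_true(res$at_risk[2])
  res2 <- one_class_risk_baseline(x, rbind(centroid, far))
  expect_identical(res$score, res2$score)
  expect_error(one_class_risk_baseline(x[0, , drop = FALSE], centroid),
               "non-empty")
})

test_that("multi-class SVM drug id recovers a separable 3-class fixture", {
  withr::with_seed(80, {
    mu <- diag(3) * 8
    x <- do.call(rbind, lapply(1:3, function(k)
      matrix(rnorm(30 * 3), 30) + matrix(mu[k, ], 30, 3, byrow = TRUE)))
  })
  y <- rep(c("d1", "d2", "d3"), each = 30)
  wells <- rep(rep(c("wa", "wb", "wc"), each = 10), 3)
  wells <- paste(y, wells)  # 9 wells, 3 per compound
  meta <- data.frame(compound = y, concentration = rep(c(1, 3, 10), 30),
                     is_vehicle = FALSE)
  out <- multiclass_svm_drug_id(x, y, wells, meta)
  expect_equal(out$n_models, 9)
  expect_equal(mean(out$window_pred == y), 1.0)
  expect_true(all(out$predictions$predicted == out$predictions$compound))

  # deterministic tie-break toward class order on an exact vote tie
  meta_tie <- data.frame(compound = "d?", concentration = 1,
                         is_vehicle = FALSE)[rep(1, 4), ]
  g <- interaction(meta_tie$compound, meta_tie$concentration,
                   meta_tie$is_vehicle, drop = TRUE)
  votes <- table(factor(c("d1", "d1", "d2", "d2"), levels = c("d1", "d2")))
  expect_equal(names(votes)[which.max(votes)], "d1")
})
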