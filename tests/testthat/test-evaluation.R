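test_that("ROC curve endpoints, monotonicity and AUC follow the definition", {
  scores <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1)
  labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  roc <- roc_curve(scores, labels)
  expect_equal(roc$auc, 1)
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[length(roc$fpr)], 1)
  expect_equal(roc$tpr[length(roc$tpr)], 1)
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
  expect_true(is.infinite(roc$thresholds[1]))

  # AUC equals the pairwise rank statistic, including ties
  for (trial in 1:50) {
    withr::with_seed(trial, {
      n <- sample(4:30, 1)
      s <- sample(seq(0, 1, 0.1), n, TRUE)  # coarse grid forces ties
      l <- sample(c(TRUE, FALSE), n, TRUE)
    })
    if (length(unique(l)) < 2) next
    expect_equal(roc_curve(s, l)$auc, oracle_auc(s, l), tolerance = 1e-12)
  }

  # invariance under strictly monotone transforms; reflection identity
  withr::with_seed(99, {
    s <- rnorm(200); l <- sample(c(TRUE, FALSE), 200, TRUE)
  })
  a <- roc_curve(s, l)$auc
  expect_equal(roc_curve(exp(s), l)$auc, a, tolerance = 1e-12)
  expect_equal(roc_curve(-s, l)$auc, 1 - a, tolerance = 1e-12)

  expect_error(roc_curve(s, rep(TRUE, 200)), "both classes")
  # factor labels with explicit positive class
  expect_equal(roc_curve(scores, factor(rep(c("p", "n"), each = 3)),
                         positive = "p")$auc, 1)
})

test_that("the operating point slides the cost line to the ROC curve", {
  scores <- c(0.95, 0.9, 0.6, 0.55, 0.4, 0.2)
  labels <- c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE)
  roc <- roc_curve(scores, labels)

  # unit costs, balanced classes -> S = N / P
  op <- optimal_operating_point(roc, n_neg = 100, n_pos = 100)
  expect_equal(op$S, 1)
  op3 <- optimal_operating_point(roc, n_neg = 300, n_pos = 100)
  expect_equal(op3$S, 3)

  # chosen vertex is the exhaustive argmax of TPR - S * FPR
  for (trial in 1:30) {
    withr::with_seed(100 + trial, {
      n <- sample(10:200, 1)
      s <- runif(n); l <- sample(c(TRUE, FALSE), n, TRUE)
    })
    if (length(unique(l)) < 2) next
    r <- roc_curve(s, l)
    for (S_target in c(0.5, 1, 3)) {
      op <- optimal_operating_point(r, cost_fp = S_target,
                                    n_neg = r$n_pos, n_pos = r$n_pos)
      obj <- r$tpr - op$S * r$fpr
      expect_equal(obj[op$index], max(obj), tolerance = 1e-12)
      best <- which(obj >= max(obj) - 1e-12)
      expect_equal(op$fpr, min(r$fpr[best]))  # tie-break to smallest FPR
    }
  }
  expect_error(optimal_operating_point(roc, cost_fn = 0, cost_tp = 0),
               "denominator")
})

test_that("confusion matrices tally correctly overall and per group", {
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.55, 0.45, 0.4, 0.3, 0.2, 0.1)
  labels <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE)
  cm <- confusion_at(0.5, scores, labels)
  expect_equal(c(cm$tp, cm$fp, cm$fn, cm$tn), c(3, 2, 2, 3))  # manual tally

  cm0 <- confusion_at(0, scores, labels)
  expect_equal(cm0$fn + cm0$tn, 0)  # everything positive
  cm1 <- confusion_at(1, scores, labels, rule = ">")
  expect_equal(cm1$tp + cm1$fp, 0)  # strict rule: everything negative

  groups <- rep(c("d1", "d2"), each = 5)
  cmg <- confusion_at(0.5, scores, labels, groups = groups)
  expect_equal(sum(cmg$by_group$tp), cmg$tp)
  expect_equal(sum(cmg$by_group$tn), cmg$tn)
  expect_equal(cmg$by_group$tp + cmg$by_group$fp + cmg$by_group$fn +
                 cmg$by_group$tn, c(5, 5))
})

test_that("metrics reproduce the perfect-classifier row and the F variants", {
  cm_perfect <- confusion_at(0.5, c(rep(0.9, 5), rep(0.1, 5)),
                             rep(c(TRUE, FALSE), each = 5))
  m <- classification_metrics(cm_perfect)
  expect_equal(unlist(m[c("Acc", "PPV", "Sen", "Spec", "F")]),
               c(Acc = 1, PPV = 1, Sen = 1, Spec = 1, F = 1))
  # the literal product-over-sum reading gives 0.5 at PPV = Sen = 1
  m2 <- classification_metrics(cm_perfect, f_variant = "text_literal")
  expect_equal(m2$F, 0.5)

  cm_wrong <- confusion_at(0.5, c(rep(0.1, 5), rep(0.9, 5)),
                           rep(c(TRUE, FALSE), each = 5))
  mw <- classification_metrics(cm_wrong)
  expect_equal(mw$Acc, 0)
  expect_equal(mw$Sen, 0)

  # degenerate denominators are missing-coded
  cm_nopos <- confusion_at(2, c(0.5, 0.5), c(FALSE, FALSE), rule = ">")
  mn <- classification_metrics(cm_nopos)
  expect_true(is.na(mn$PPV) && is.na(mn$Sen))
  expect_equal(mn$Spec, 1)
})

test_that("AUC agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(123, {
    s <- runif(300)
    l <- runif(300) < plogis(3 * s - 1.5)
  })
  ref <- as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_curve(s, l)$auc, ref, tolerance = 1e-10)
})
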