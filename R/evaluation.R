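# ROC analysis, the cost-slope optimal operating point, confusion matrices,
# and the classification metrics (Acc, PPV, Sen, Spec, F).

#' ROC curve and AUC
#'
#' The curve is traced over all distinct score thresholds (plus a sentinel
#' above the maximum), sweeping the positive-call rule `score >= threshold`
#' from everything-negative to everything-positive; the AUC is the
#' trapezoidal area, which equals the pairwise concordance statistic
#' (concordant pairs plus half ties over P x N pairs).
#'
#' @param scores Numeric classifier scores (larger = more positive).
#' @param labels Logical vector, or factor/character with `positive` naming
#'   the positive class.
#' @param positive Positive label when `labels` is not logical.
#' @return An object of class `roc_curve`: `thresholds` (descending,
#'   starting at `Inf`), `fpr`, `tpr` (non-decreasing, from (0,0) to
#'   (1,1)), `auc`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels, positive = NULL) {
  if (!is.logical(labels)) {
    .assert(!is.null(positive), "positive class required for non-logical labels")
    labels <- labels == positive
  }
  .assert(length(scores) == length(labels), "scores and labels differ in length")
  .assert(all(is.finite(scores)), "non-finite scores")
  P <- sum(labels); N <- sum(!labels)
  .assert(P > 0 && N > 0, "both classes must be present to trace a ROC curve")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  tp <- cumsum(l); fp <- cumsum(!l)
  last <- c(s[-1] != s[-length(s)], TRUE)  # keep last index of each tied score
  thr <- c(Inf, s[last])
  tpr <- c(0, tp[last]) / P
  fpr <- c(0, fp[last]) / N
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(thresholds = thr, fpr = fpr, tpr = tpr, auc = auc,
                 n_pos = P, n_neg = N),
            class = "roc_curve")
}

#' Cost-slope optimal operating point of a ROC curve
#'
#' The slope is `S = (Cost(P|N) - Cost(N|N)) / (Cost(N|P) - Cost(P|P)) *
#' N / P`, where `Cost(P|N)` is the cost of calling a negative positive and
#' `Cost(N|P)` the cost of calling a positive negative. Moving a line of
#' slope S down from the upper-left corner (FPR 0, TPR 1) until it touches
#' the curve selects the vertex maximizing `TPR - S * FPR`; ties are broken
#' toward the smallest FPR (conservative toward false positives).
#'
#' @param roc A [roc_curve()].
#' @param cost_fp Cost(P|N), misclassifying a negative as positive
#'   (default 1).
#' @param cost_tn Cost(N|N) (default 0).
#' @param cost_fn Cost(N|P), misclassifying a positive as negative
#'   (default 1).
#' @param cost_tp Cost(P|P) (default 0).
#' @param n_neg,n_pos Class totals N and P (default: taken from the curve).
#' @return An object of class `operating_point`: `S`, `threshold`, `fpr`,
#'   `tpr`, the costs, and the vertex `index` into the curve.
#' @export
optimal_operating_point <- function(roc, cost_fp = 1, cost_tn = 0,
                                    cost_fn = 1, cost_tp = 0,
                                    n_neg = roc$n_neg, n_pos = roc$n_pos) {
  .assert(inherits(roc, "roc_curve"), "roc_curve required")
  .assert(cost_fp > cost_tn, "Cost(P|N) must exceed Cost(N|N)")
  .assert(cost_fn > cost_tp, "Cost(N|P) must exceed Cost(P|P) (zero denominator otherwise)")
  S <- (cost_fp - cost_tn) / (cost_fn - cost_tp) * n_neg / n_pos
  obj <- roc$tpr - S * roc$fpr
  best <- which(obj >= max(obj) - 1e-12)
  idx <- best[which.min(roc$fpr[best])]
  structure(list(S = S, threshold = roc$thresholds[idx],
                 fpr = roc$fpr[idx], tpr = roc$tpr[idx], index = idx,
                 costs = c(cost_fp = cost_fp, cost_tn = cost_tn,
                           cost_fn = cost_fn, cost_tp = cost_tp),
                 n_neg = n_neg, n_pos = n_pos),
            class = "operating_point")
}

#' Confusion matrix at a threshold
#'
#' @param threshold Positive-call threshold on the scores.
#' @param scores Numeric scores.
#' @param labels Logical labels (or factor with `positive`).
#' @param groups Optional grouping vector (e.g. compound per window); when
#'   given, per-group matrices are returned alongside the overall one (they
#'   sum to it).
#' @param rule `">="` (default: call positive when `score >= threshold`) or
#'   `">"` (strict).
#' @param positive Positive class when `labels` is not logical.
#' @return An object of class `confusion_matrix`: `tp`, `fp`, `fn`, `tn`,
#'   `threshold`, and `by_group` (data frame or `NULL`).
#' @export
confusion_at <- function(threshold, scores, labels, groups = NULL,
                         rule = c(">=", ">"), positive = NULL) {
  rule <- match.arg(rule)
  if (!is.logical(labels)) {
    .assert(!is.null(positive), "positive class required for non-logical labels")
    labels <- labels == positive
  }
  pred <- if (rule == ">=") scores >= threshold else scores > threshold
  tally <- function(sel) {
    c(tp = sum(pred[sel] & labels[sel]), fp = sum(pred[sel] & !labels[sel]),
      fn = sum(!pred[sel] & labels[sel]), tn = sum(!pred[sel] & !labels[sel]))
  }
  all_counts <- tally(rep(TRUE, length(pred)))
  by_group <- NULL
  if (!is.null(groups)) {
    rows <- lapply(split(seq_along(pred), groups), tally)
    by_group <- data.frame(group = names(rows),
                           do.call(rbind, rows), row.names = NULL)
  }
  structure(c(as.list(all_counts),
              list(threshold = threshold, by_group = by_group)),
            class = "confusion_matrix")
}

#' Classification metrics from a confusion matrix
#'
#' `Acc = (TP + TN) / total`, `PPV = TP / (TP + FP)`,
#' `Sen = TP / (TP + FN)`, `Spec = TN / (TN + FP)`. The F measure defaults
#' to the standard F1, `2 * PPV * Sen / (PPV + Sen)`; the `"text_literal"`
#' variant is the plain product-over-sum `PPV * Sen / (PPV + Sen)` (which
#' equals half of F1 and yields 0.5 for a perfect classifier) and is kept
#' for fidelity to a definition occasionally printed in the field.
#' Degenerate denominators yield `NA`.
#'
#' @param cm A [confusion_at()] result.
#' @param f_variant `"standard_f1"` (default) or `"text_literal"`.
#' @return Named list of class `metrics_report`: `Acc`, `PPV`, `Sen`,
#'   `Spec`, `F`, `f_variant`.
#' @export
classification_metrics <- function(cm, f_variant = c("standard_f1",
                                                     "text_literal")) {
  f_variant <- match.arg(f_variant)
  .assert(inherits(cm, "confusion_matrix"), "confusion_matrix required")
  div <- function(a, b) if (b > 0) a / b else NA_real_
  ppv <- div(cm$tp, cm$tp + cm$fp)
  sen <- div(cm$tp, cm$tp + cm$fn)
  f <- if (is.na(ppv) || is.na(sen) || ppv + sen == 0) NA_real_
       else (if (f_variant == "standard_f1") 2 else 1) * ppv * sen / (ppv + sen)
  structure(list(Acc = div(cm$tp + cm$tn, cm$tp + cm$fp + cm$fn + cm$tn),
                 PPV = ppv, Sen = sen,
                 Spec = div(cm$tn, cm$tn + cm$fp),
                 F = f, f_variant = f_variant),
            class = "metrics_report")
}
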