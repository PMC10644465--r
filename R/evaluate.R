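#' Imbalance-aware evaluation: sensitivity, specificity, pairwise AUC
#'
#' Scores are decision values (signed margins); a score `>= 0` predicts the
#' positive class. Sensitivity is `TP / P`, specificity `TN / N`, and AUC is
#' the fraction of (positive, negative) score pairs ranked correctly, with
#' ties counted 0.5 — so `auc(scores) + auc(-scores) = 1` always holds.
#'
#' @param labels Binary labels (0/1 or -1/+1); both classes must be present.
#' @param scores Numeric decision scores, one per label.
#' @return An `eval_report`: list with `sen`, `spe`, `auc`, the counts `TP`,
#'   `TN`, `P`, `N`, and the score vectors `P_score`, `N_score`.
#' @export
evaluate <- function(labels, scores) {
  y <- as_pm1(labels)
  if (length(y) != length(scores)) abort("`labels` and `scores` lengths differ")
  if (length(unique(y)) < 2) {
    abort("evaluation requires both classes among `labels`")
  }
  ps <- scores[y == 1]
  ns <- scores[y == -1]
  P <- length(ps); N <- length(ns)
  TP <- sum(ps >= 0)
  TN <- sum(ns < 0)
  # Pairwise comparison of every positive score with every negative score.
  auc <- (sum(outer(ps, ns, ">")) + 0.5 * sum(outer(ps, ns, "=="))) / (P * N)
  structure(
    list(sen = TP / P, spe = TN / N, auc = auc,
         TP = TP, TN = TN, P = P, N = N,
         P_score = ps, N_score = ns),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> Sen = %.3f  Spe = %.3f  AUC = %.3f  (P = %d, N = %d)\n",
              x$sen, x$spe, x$auc, x$P, x$N))
  invisible(x)
}

#' @export
glance.eval_report <- function(x, ...) {
  tibble(sen = x$sen, spe = x$spe, auc = x$auc,
         TP = x$TP, TN = x$TN, P = x$P, N = x$N)
}

#' ROC curve points
#'
#' One `(fpr, tpr)` point per distinct score threshold, suitable for TSV
#' export or plotting.
#'
#' @inheritParams evaluate
#' @return A tibble with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(labels, scores) {
  y <- as_pm1(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  P <- sum(y == 1); N <- sum(y == -1)
  tibble(
    threshold = thr,
    tpr = vapply(thr, function(t) sum(scores >= t & y == 1), 0) / P,
    fpr = vapply(thr, function(t) sum(scores >= t & y == -1), 0) / N
  )
}
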