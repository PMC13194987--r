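#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the unique scores, records one
#' (FPR, TPR) point per threshold, and integrates by the trapezoid rule.
#' Tied scores are grouped into a single threshold step, which makes the
#' trapezoidal AUC equal to the pairwise concordance probability with ties
#' counted one half.
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels 0/1 labels, both classes present.
#' @return List with `points` (data.frame `threshold, fpr, tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stopf("scores and labels differ in length")
  P <- sum(labels == 1L); N <- sum(labels == 0L)
  if (P == 0 || N == 0) stopf("both classes must be present for a ROC curve")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # one point per unique score value (ties collapse into one step)
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last_of_group]
  fp <- cumsum(1 - y)[last_of_group]
  points <- data.frame(threshold = s[last_of_group],
                       fpr = fp / N, tpr = tp / P)
  fpr <- c(0, points$fpr); tpr <- c(0, points$tpr)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(points = points, auc = auc)
}

#' Confusion matrix and derived rates
#'
#' Counts TP/FP/TN/FN at the given threshold and derives accuracy, the
#' positive predictive value TP/(TP+FP) and the negative predictive value
#' TN/(TN+FN). An undefined PPV or NPV (empty denominator) is reported as
#' `NA`, never as 0.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels.
#' @param threshold decision threshold (default 0.5).
#' @return List with `tp, fp, tn, fn, accuracy, ppv, npv`.
#' @export
confusion_counts <- function(scores, labels, threshold = 0.5) {
  pred <- as.integer(scores >= threshold)
  labels <- as.integer(labels)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  tn <- sum(pred == 0L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       accuracy = (tp + tn) / (tp + fp + tn + fn),
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
}

#' Friedman rank test over a block x treatment grid
#'
#' Ranks the treatments within each block (mean ranks on ties), then
#' computes `Q = 12 n / (k (k + 1)) * sum_j (Rbar_j - (k + 1)/2)^2` with
#' `n` blocks and `k` treatments, `df = k - 1`, and the p-value from the
#' chi-square upper tail. Used to compare classifiers across the sensor
#' input types, with significance reported at both alpha = 0.05 and 0.01.
#'
#' @param score_grid numeric matrix, blocks (e.g. participants) in rows and
#'   treatments (e.g. input types) in columns.
#' @return An object of class `friedman_result`: list with `Q`, `df`, `p`,
#'   `mean_ranks`, and logical `significant_05`, `significant_01`.
#' @export
friedman_rank_test <- function(score_grid) {
  g <- as.matrix(score_grid)
  n <- nrow(g); k <- ncol(g)
  if (n < 2 || k < 2) stopf("need at least 2 blocks and 2 treatments")
  if (anyNA(g)) stopf("score grid must be complete")
  ranks <- t(apply(g, 1, rank))
  rbar <- colMeans(ranks)
  Q <- 12 * n / (k * (k + 1)) * sum((rbar - (k + 1) / 2)^2)
  df <- k - 1
  p <- pchisq(Q, df, lower.tail = FALSE)
  structure(list(Q = Q, df = df, p = p, mean_ranks = rbar,
                 significant_05 = p < 0.05, significant_01 = p < 0.01),
            class = "friedman_result")
}

#' @export
print.friedman_result <- function(x, ...) {
  cat(sprintf("Friedman rank test: Q = %.5f, df = %d, p = %.6g%s\n",
              x$Q, x$df, x$p,
              if (x$significant_01) " (significant at 0.01)"
              else if (x$significant_05) " (significant at 0.05)" else ""))
  invisible(x)
}
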