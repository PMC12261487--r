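# The eight classification metrics: AUC-ROC, AUC-PR, ACC, BACC, F1,
# precision, recall, Cohen's kappa.

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) estimator with the standard tie correction,
#' equivalent to trapezoidal integration of the ROC curve.
#'
#' @param probs Numeric scores.
#' @param labels Binary labels in \{0, 1\}.
#' @return AUC-ROC in `[0, 1]`, or `NA` if only one class is present.
#' @export
auc_roc <- function(probs, labels) {
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    warning("AUC-ROC undefined with a single class", call. = FALSE)
    return(NA_real_)
  }
  r <- rank(probs, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Average precision with tied scores grouped: precision is evaluated once
#' per distinct threshold and weighted by the recall gained there.
#'
#' @inheritParams auc_roc
#' @return AUC-PR in `[0, 1]`, or `NA` if only one class is present.
#' @export
auc_pr <- function(probs, labels) {
  n_pos <- sum(labels == 1)
  if (n_pos == 0 || all(labels == 1)) {
    warning("AUC-PR undefined with a single class", call. = FALSE)
    return(NA_real_)
  }
  ord <- order(probs, decreasing = TRUE)
  p <- probs[ord]
  y <- labels[ord]
  grp <- cumsum(!duplicated(p))
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  last <- which(!duplicated(grp, fromLast = TRUE))  # last index of each tie group
  tp <- tp[last]
  fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  drec <- diff(c(0, rec))
  sum(prec * drec)
}

#' Compute the eight evaluation metrics for binary predictions
#'
#' Threshold-free metrics (AUC-ROC, AUC-PR) are computed from the scores;
#' the remaining six apply `threshold` (predicted positive when the score is
#' at least the threshold). Precision, recall, and F1 are defined as 0 when
#' their denominator is empty.
#'
#' @param probs Predicted probabilities of the positive class.
#' @param labels Binary labels in \{0, 1\}.
#' @param threshold Classification threshold (default 0.5).
#' @return One-row tibble with columns `auc_roc`, `auc_pr`, `acc`, `bacc`,
#'   `f1`, `precision`, `recall`, `kappa`, `n`.
#' @examples
#' compute_metrics(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))
#' @export
compute_metrics <- function(probs, labels, threshold = 0.5) {
  stopifnot(length(probs) == length(labels), all(labels %in% c(0, 1)))
  pred <- as.integer(probs >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  n <- length(labels)

  acc <- (tp + tn) / n
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  bacc <- mean(c(sens, spec), na.rm = TRUE)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  p_o <- acc
  p_e <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (p_e < 1) (p_o - p_e) / (1 - p_e) else 0

  tibble::tibble(
    auc_roc = auc_roc(probs, labels),
    auc_pr = auc_pr(probs, labels),
    acc = acc, bacc = bacc, f1 = f1,
    precision = precision, recall = recall, kappa = kappa,
    n = n
  )
}

#' Metrics from an explicit confusion matrix
#'
#' Convenience wrapper for the six thresholded metrics when only the
#' confusion counts are known; AUCs are `NA`.
#'
#' @param tn,fp,fn,tp Confusion-matrix counts.
#' @return One-row tibble as in [compute_metrics()] with `NA` AUCs.
#' @export
metrics_from_confusion <- function(tn, fp, fn, tp) {
  probs <- c(rep(0, tn), rep(1, fp), rep(0, fn), rep(1, tp))
  labels <- c(rep(0, tn + fp), rep(1, fn + tp))
  out <- suppressWarnings(compute_metrics(probs, labels))
  out$auc_roc <- NA_real_
  out$auc_pr <- NA_real_
  out
}
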