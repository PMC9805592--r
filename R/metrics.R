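#' @title Ranking and classification performance metrics
#' @description Metrics for evaluating scoring functions over sets of docking
#'   models: ROC AUC, hit rate and per-complex success rate for ranking, the
#'   standard confusion-matrix ratios for classification, and Spearman rank
#'   correlation. Ranking ties are broken by a stable sort on model id so that
#'   top-N metrics are deterministic.
#' @name metrics
NULL

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic (rank-sum with average ranks for
#' ties), equivalent to the trapezoidal integral of the ROC curve: 1 for an
#' ideal classifier, 0.5 for a random one.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels 0/1 labels, both classes present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    grappi_stop("AUC requires both classes present", "grappi_usage_error")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points (descending-score sweep)
#'
#' @inheritParams roc_auc
#' @return data.frame with `fpr` and `tpr` columns, starting at (0,0) and
#'   ending at (1,1); tied scores advance as one step.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  o <- order(-scores)
  s <- scores[o]; y <- labels[o]
  keep <- c(s[-1] != s[-length(s)], TRUE)   # last index of each tie group
  tp <- cumsum(y)[keep]; fp <- cumsum(1 - y)[keep]
  data.frame(fpr = c(0, fp / max(sum(1 - labels), 1)),
             tpr = c(0, tp / max(sum(labels), 1)))
}

#' Average a set of per-complex ROC curves on a fixed FPR grid
#'
#' The TPR of each complex's curve is linearly interpolated at the grid
#' points and averaged across complexes.
#'
#' @param curves List of data.frames from [roc_curve()].
#' @param fpr_grid Numeric grid in \[0, 1\].
#' @return data.frame with `fpr`, mean `tpr` and its standard deviation.
#' @export
average_roc <- function(curves, fpr_grid = seq(0, 1, by = 0.01)) {
  tprs <- vapply(curves, function(cv)
    stats::approx(cv$fpr, cv$tpr, xout = fpr_grid, ties = max,
                  yleft = 0, yright = 1)$y,
    numeric(length(fpr_grid)))
  tprs <- matrix(tprs, nrow = length(fpr_grid))
  data.frame(fpr = fpr_grid, tpr = rowMeans(tprs),
             tpr_sd = apply(tprs, 1, stats::sd))
}

#' Rank model labels by score (deterministic tie-break on id)
#'
#' @param scores Numeric scores, higher first.
#' @param labels Labels aligned with `scores`.
#' @param ids Optional ids used as a stable tie-break.
#' @return `labels` reordered by decreasing score.
#' @export
rank_labels <- function(scores, labels, ids = seq_along(scores)) {
  labels[order(-scores, ids)]
}

#' Hit rate: percentage of all positives retrieved in the top N
#'
#' @param ranked_labels 0/1 labels in rank order (best first), e.g. from
#'   [rank_labels()].
#' @param N Top ranks to consider (vectorized).
#' @return Percentage(s) in \[0, 100\].
#' @export
hit_rate <- function(ranked_labels, N) {
  ranked_labels <- as.integer(ranked_labels)
  tot <- sum(ranked_labels)
  if (tot == 0)
    grappi_stop("hit rate undefined without positives", "grappi_usage_error")
  vapply(N, function(k)
    100 * sum(ranked_labels[seq_len(min(k, length(ranked_labels)))]) / tot,
    numeric(1))
}

#' Success rate: percentage of complexes with a positive in their top N
#'
#' @param rankings List (one element per complex) of 0/1 labels in rank
#'   order, best first.
#' @param N Top ranks to consider (vectorized).
#' @return Percentage(s) in \[0, 100\].
#' @export
success_rate <- function(rankings, N) {
  if (!length(rankings))
    grappi_stop("no complexes", "grappi_usage_error")
  vapply(N, function(k) {
    hit <- vapply(rankings, function(rl)
      sum(as.integer(rl)[seq_len(min(k, length(rl)))]) > 0, logical(1))
    100 * mean(hit)
  }, numeric(1))
}

#' Accuracy, specificity, sensitivity and precision of binary predictions
#'
#' Cells whose denominator is zero (e.g. precision with no predicted
#' positives) are reported as `NA` (undefined), not 0.
#'
#' @param predictions 0/1 predicted labels.
#' @param labels 0/1 true labels.
#' @return Named list: `accuracy`, `specificity`, `sensitivity`, `precision`,
#'   and the confusion counts `tp`, `fp`, `tn`, `fn`.
#' @export
classification_report <- function(predictions, labels) {
  stopifnot(length(predictions) == length(labels))
  p <- as.integer(predictions); y <- as.integer(labels)
  tp <- sum(p == 1 & y == 1); fp <- sum(p == 1 & y == 0)
  tn <- sum(p == 0 & y == 0); fn <- sum(p == 0 & y == 1)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  list(accuracy = ratio(tp + tn, tp + tn + fp + fn),
       specificity = ratio(tn, tn + fp),
       sensitivity = ratio(tp, tp + fn),
       precision = ratio(tp, tp + fp),
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Spearman rank correlation
#'
#' Pearson correlation of rank-transformed values with average ranks for
#' ties.
#'
#' @param scores,targets Equal-length numeric vectors.
#' @return rho in \[-1, 1\].
#' @export
spearman_rho <- function(scores, targets) {
  stopifnot(length(scores) == length(targets))
  stats::cor(scores, targets, method = "spearman")
}
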