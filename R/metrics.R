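# Evaluation metrics and score aggregation.

#' ROC AUC
#'
#' The probability that a uniformly random positive outranks a uniformly
#' random negative, with ties counting one half -- the normalised rank-sum
#' (Mann-Whitney) statistic.
#'
#' @param labels Binary labels (0/1 or logical).
#' @param scores Numeric scores, higher = more positive.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.numeric(labels)
  check_two_classes(labels)
  r <- rank(scores, ties.method = "average")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' PR AUC (average precision)
#'
#' Step-wise average precision: the sum over positives, in decreasing score
#' order, of precision at each recall increment; no interpolation. Tied
#' scores are treated as a single threshold.
#'
#' @inheritParams roc_auc
#' @return Average precision in \[0, 1\].
#' @export
pr_auc <- function(labels, scores) {
  labels <- as.numeric(labels)
  check_two_classes(labels)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]; s <- scores[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  # keep only the last row of each tied-score block
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[last]; fp <- fp[last]
  n_pos <- sum(y)
  prec <- tp / (tp + fp)
  recall <- tp / n_pos
  d_recall <- diff(c(0, recall))
  sum(prec * d_recall)
}

check_two_classes <- function(labels) {
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  if (length(unique(labels)) < 2L) {
    stop("metric undefined: both classes must be present")
  }
  invisible(TRUE)
}

#' Aggregate per-structure scores to per-loop scores
#'
#' Evaluation on crystal-structure ensembles uses the mean prediction score
#' over the structures of a loop; evaluation on conformational ensembles
#' (e.g. simulation snapshots) uses the maximum score.
#'
#' @param records data.frame with columns `group_key` and `score` (as from
#'   [predict_scores()]).
#' @param mode `"mean"` or `"max"`.
#' @return data.frame with one row per group: `group_key`, `score`,
#'   `n_structures`, `aggregated = TRUE`.
#' @export
aggregate_scores <- function(records, mode = c("mean", "max")) {
  mode <- match.arg(mode)
  if (nrow(records) == 0L) stop("no prediction records to aggregate")
  f <- if (mode == "mean") mean else max
  agg <- stats::aggregate(score ~ group_key, data = records, FUN = f)
  n <- stats::aggregate(score ~ group_key, data = records, FUN = length)
  out <- data.frame(group_key = agg$group_key, score = agg$score,
                    n_structures = n$score, aggregated = TRUE,
                    stringsAsFactors = FALSE)
  out[match(unique(records$group_key), out$group_key), , drop = FALSE]
}

#' Metric report for aggregated predictions
#'
#' @param labels Per-group binary labels.
#' @param scores Per-group aggregated scores.
#' @param aggregation Aggregation mode used (recorded in the report).
#' @return List of class `MetricReport`: `pr_auc`, `roc_auc`, `n_positives`,
#'   `n_negatives`, `aggregation`.
#' @export
metric_report <- function(labels, scores, aggregation = "mean") {
  labels <- as.numeric(labels)
  structure(list(pr_auc = pr_auc(labels, scores),
                 roc_auc = roc_auc(labels, scores),
                 n_positives = sum(labels == 1),
                 n_negatives = sum(labels == 0),
                 aggregation = aggregation),
            class = "MetricReport")
}

#' @export
print.MetricReport <- function(x, ...) {
  cat(sprintf("PR AUC %.4f | ROC AUC %.4f (%d positives, %d negatives, %s aggregation)\n",
              x$pr_auc, x$roc_auc, x$n_positives, x$n_negatives,
              x$aggregation))
  invisible(x)
}
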