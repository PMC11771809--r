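# Link-prediction metric suite and noise-discrimination scoring.

#' Confusion counts at a probability threshold
#'
#' Predicts positive iff `score >= threshold` and tallies TP, FP, TN, FN
#' against the 0/1 labels.
#'
#' @param scores numeric scores in \[0, 1\].
#' @param labels 0/1 labels.
#' @param threshold classification threshold (default 0.5).
#' @return named list with tp, fp, tn, fn.
#' @export
confusion_counts <- function(scores, labels, threshold = 0.5) {
  if (length(scores) == 0) stopf_("empty input")
  if (length(scores) != length(labels)) stopf_("scores/labels length mismatch")
  if (!all(labels %in% c(0, 1))) stopf_("labels must be 0/1")
  pred <- as.integer(scores >= threshold)
  list(tp = sum(pred == 1 & labels == 1),
       fp = sum(pred == 1 & labels == 0),
       tn = sum(pred == 0 & labels == 0),
       fn = sum(pred == 0 & labels == 1))
}

# rank (Mann-Whitney) AUC with half credit for ties
auc_roc_rank_ <- function(scores, labels) {
  r <- rank(scores, ties.method = "average")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# trapezoidal integration of the ROC curve (independent formulation)
auc_roc_trapezoid_ <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]; sc <- scores[o]
  n_pos <- sum(lab == 1); n_neg <- sum(lab == 0)
  # cumulative counts at each distinct threshold
  keep <- c(sc[-1] != sc[-length(sc)], TRUE)
  tp <- cumsum(lab == 1)[keep]
  fp <- cumsum(lab == 0)[keep]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}

# precision-recall points at distinct descending thresholds
pr_points_ <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]; sc <- scores[o]
  keep <- c(sc[-1] != sc[-length(sc)], TRUE)
  tp <- cumsum(lab == 1)[keep]
  fp <- cumsum(lab == 0)[keep]
  n_pos <- sum(lab == 1)
  list(precision = tp / (tp + fp), recall = tp / n_pos)
}

# average precision: step-sum of (R_n - R_{n-1}) * P_n
average_precision_ <- function(scores, labels) {
  pr <- pr_points_(scores, labels)
  sum(diff(c(0, pr$recall)) * pr$precision)
}

# area under the PR curve by trapezoidal integration
auc_prc_ <- function(scores, labels) {
  pr <- pr_points_(scores, labels)
  prec <- c(pr$precision[1], pr$precision)
  rec <- c(0, pr$recall)
  sum(diff(rec) * (head(prec, -1) + prec[-1]) / 2)
}

#' Compute the link-prediction metric report
#'
#' AUC-ROC by the rank (Mann-Whitney) formulation with half credit for
#' ties; average precision by the step sum over descending-score
#' thresholds; AUC-PRC by trapezoidal integration of the precision-recall
#' curve; accuracy and F1 from the confusion counts at `threshold`.
#'
#' @inheritParams confusion_counts
#' @return list of class `metrics_report` with auc_roc, accuracy, f1,
#'   auc_prc, average_precision, tp, fp, tn, fn, n_pos, n_neg, threshold.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels)) stopf_("scores/labels length mismatch")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0) stopf_("no positive labels present")
  if (n_neg == 0) stopf_("no negative labels present")
  cc <- confusion_counts(scores, labels, threshold)
  precision <- if (cc$tp + cc$fp > 0) cc$tp / (cc$tp + cc$fp) else 0
  recall <- cc$tp / (cc$tp + cc$fn)
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  structure(list(
    auc_roc = auc_roc_rank_(scores, labels),
    accuracy = (cc$tp + cc$tn) / length(labels),
    f1 = f1,
    auc_prc = auc_prc_(scores, labels),
    average_precision = average_precision_(scores, labels),
    tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn,
    n_pos = n_pos, n_neg = n_neg, threshold = threshold
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("<metrics_report> AUC-ROC %.3f  ACC %.3f  F1 %.3f  ",
                     "AUC-PRC %.3f  AP %.3f  (%d pos / %d neg)\n"),
              x$auc_roc, x$accuracy, x$f1, x$auc_prc, x$average_precision,
              x$n_pos, x$n_neg))
  invisible(x)
}

#' Evaluate a trained model on a positive/negative pair set
#'
#' @param trained a `trained_model`.
#' @param x_expr,x_img node features used in training.
#' @param pos_pairs,neg_pairs m x 2 matrices of cell index pairs.
#' @param threshold classification threshold.
#' @return a `metrics_report`.
#' @export
evaluate_model <- function(trained, x_expr, x_img, pos_pairs, neg_pairs,
                           threshold = 0.5) {
  pairs <- rbind(pos_pairs, neg_pairs)
  labels <- c(rep(1, nrow(pos_pairs)), rep(0, nrow(neg_pairs)))
  scores <- predict_scores(trained, x_expr, x_img, pairs)
  compute_metrics(scores, labels, threshold)
}

#' Score the model's discrimination of injected false edges
#'
#' Treats the injected false edges (ground truth 0, presented to training
#' as positives) as the negative class and the true training positives as
#' the positive class, scores both with the trained model's decoder, and
#' returns the metric report of that discrimination task.
#'
#' @param trained a `trained_model`.
#' @param x_expr,x_img node features used in training.
#' @param split the `edge_split` carrying `injected_false`.
#' @return a `metrics_report`.
#' @export
score_noise_discrimination <- function(trained, x_expr, x_img, split) {
  if (nrow(split$injected_false) == 0) {
    stopf_("split has no injected false edges")
  }
  evaluate_model(trained, x_expr, x_img,
                 pos_pairs = split$train_pos,
                 neg_pairs = split$injected_false)
}
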