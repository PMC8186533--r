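#' Classification metrics from scores
#'
#' Computes the 2 x 2 confusion matrix (rows: true ASD/TD, columns:
#' predicted ASD/TD), accuracy, sensitivity (recall of the ASD class),
#' specificity (recall of the TD class), the ROC curve swept over the
#' ASD-probability threshold, and its trapezoid-rule AUC. The predicted
#' class is the argmax probability, i.e. ASD when `score > 0.5`.
#'
#' @param truth character vector of `"ASD"`/`"TD"` labels.
#' @param scores ASD-class probabilities.
#' @return a `tk_metrics` list: `confusion`, `accuracy`, `sensitivity`,
#'   `specificity`, `roc` (`data.table` of `threshold`, `fpr`, `tpr`),
#'   `auc`, `n`.
#' @export
compute_metrics <- function(truth, scores) {
  bad <- setdiff(unique(truth), c("ASD", "TD"))
  if (length(bad)) tk_stop("touchkin_label_error", "unknown label(s): %s", paste(bad, collapse = ", "))
  pred <- ifelse(scores > 0.5, "ASD", "TD")
  conf <- matrix(0L, 2, 2, dimnames = list(true = c("ASD", "TD"), pred = c("ASD", "TD")))
  for (tv in c("ASD", "TD")) for (pv in c("ASD", "TD")) {
    conf[tv, pv] <- sum(truth == tv & pred == pv)
  }
  n_asd <- sum(truth == "ASD"); n_td <- sum(truth == "TD")
  roc <- roc_curve(truth, scores)
  structure(list(
    confusion = conf,
    accuracy = (conf["ASD", "ASD"] + conf["TD", "TD"]) / length(truth),
    sensitivity = if (n_asd > 0) conf["ASD", "ASD"] / n_asd else NA_real_,
    specificity = if (n_td > 0) conf["TD", "TD"] / n_td else NA_real_,
    roc = roc, auc = trapezoid_auc(roc$fpr, roc$tpr), n = length(truth)
  ), class = "tk_metrics")
}

# ROC by sweeping the decision threshold over the observed scores:
# points run from (0,0) (threshold above max) to (1,1) (threshold below min).
roc_curve <- function(truth, scores) {
  ord <- order(scores, decreasing = TRUE)
  pos <- truth[ord] == "ASD"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  # collapse tied scores into single steps
  s <- scores[ord]
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- c(0, cumsum(pos)[keep] / max(n_pos, 1))
  fpr <- c(0, cumsum(!pos)[keep] / max(n_neg, 1))
  data.table::data.table(threshold = c(Inf, s[keep]), fpr = fpr, tpr = tpr)
}

trapezoid_auc <- function(fpr, tpr) {
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

#' Evaluate a trained model on a (standardized) feature table
#'
#' @param model trained `mlp_model`.
#' @param table `feature_table` standardized with the model's scaler.
#' @return a `tk_metrics` object, see [compute_metrics()].
#' @export
evaluate <- function(model, table) {
  compute_metrics(table$label, predict_scores(model, table))
}

#' @export
print.tk_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.3f | sensitivity %.3f | specificity %.3f | AUC %.3f (n = %d)\n",
              x$accuracy, x$sensitivity, x$specificity, x$auc, x$n))
  print(x$confusion)
  invisible(x)
}
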