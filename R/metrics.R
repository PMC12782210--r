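# Per-target classification metrics and their median/IQR aggregation.

#' Confusion counts and classification metrics for one target
#'
#' Conventions (chosen to match degenerate one-vs-rest outcomes): precision
#' is 0 when no positives are predicted, recall is 0 when no positives
#' exist, and F1 is 0 when precision + recall = 0.
#'
#' @param truth Binary vector (1 = window truly belongs to the target).
#' @param decisions Binary vector of model decisions, same length.
#' @return An object of class `metrics_set`: a list with counts `tp`, `fp`,
#'   `tn`, `fn` and metrics `precision`, `recall`, `f1`, `accuracy`.
#' @export
#' @examples
#' compute_metrics(c(1, 1, 0, 0), c(1, 0, 0, 1))
compute_metrics <- function(truth, decisions) {
  if (length(truth) != length(decisions))
    stopf("truth and decisions must have equal length")
  if (length(truth) < 1L) stopf("cannot compute metrics on empty vectors")
  truth <- as.integer(truth); decisions <- as.integer(decisions)
  if (any(!truth %in% 0:1) || any(!decisions %in% 0:1))
    stopf("truth and decisions must be binary (0/1)")
  tp <- sum(truth == 1L & decisions == 1L)
  fp <- sum(truth == 0L & decisions == 1L)
  tn <- sum(truth == 0L & decisions == 0L)
  fn <- sum(truth == 1L & decisions == 0L)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         precision = precision, recall = recall, f1 = f1,
         accuracy = (tp + tn) / length(truth)),
    class = "metrics_set"
  )
}

#' @export
print.metrics_set <- function(x, ...) {
  cat(sprintf("<metrics_set> TP=%d FP=%d TN=%d FN=%d | P=%.3f R=%.3f F1=%.3f acc=%.3f\n",
              x$tp, x$fp, x$tn, x$fn, x$precision, x$recall, x$f1, x$accuracy))
  invisible(x)
}

#' Median and interquartile range of metrics across targets
#'
#' Aggregates per-target metric sets the way per-user model performance is
#' reported: the median and the 25th/75th percentiles over targets, using
#' linear-interpolation percentiles (R quantile type 7).
#'
#' @param metrics_list Non-empty list of [compute_metrics()] results, one
#'   per target.
#' @return A `metrics_summary`: a data.frame with one row per metric
#'   (`precision`, `recall`, `f1`, `accuracy`) and columns `median`, `q25`,
#'   `q75`, `n_targets`, plus the per-target values in
#'   `attr(, "per_target")`.
#' @export
summarize_metrics <- function(metrics_list) {
  if (length(metrics_list) < 1L) stopf("no metric sets to summarize")
  stopifnot(all(vapply(metrics_list, inherits, logical(1), "metrics_set")))
  metric_names <- c("precision", "recall", "f1", "accuracy")
  per_target <- vapply(metrics_list,
                       function(m) unlist(m[metric_names]),
                       numeric(length(metric_names)))
  per_target <- t(per_target)  # targets x metrics
  qs <- apply(per_target, 2, stats::quantile,
              probs = c(0.25, 0.5, 0.75), type = 7)
  out <- data.frame(metric = metric_names,
                    median = qs[2, ], q25 = qs[1, ], q75 = qs[3, ],
                    n_targets = nrow(per_target),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "per_target") <- per_target
  class(out) <- c("metrics_summary", "data.frame")
  out
}
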