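#' Classification metrics for scored drug-target pairs
#'
#' AUROC is computed by the Mann-Whitney rank formula (the probability that
#' a random positive outscores a random negative, ties counted half).
#' AUPRC is the step-interpolated area under the precision-recall curve
#' (average precision). Sensitivity `TP/(TP+FN)` and specificity
#' `TN/(TN+FP)` are taken at the classification threshold.
#'
#' @param scores Numeric vector of predicted probabilities.
#' @param labels 0/1 vector of the same length; both classes must occur.
#' @param threshold Classification threshold (default 0.5).
#' @return Named list: `auroc`, `auprc`, `sensitivity`, `specificity`.
#' @export
#' @examples
#' compute_metrics(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))
compute_metrics <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  labels <- as.integer(labels)
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  if (npos == 0L || nneg == 0L) {
    stop("both classes must be present to compute metrics", call. = FALSE)
  }
  r <- rank(scores)
  auroc <- (sum(r[labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
  ord <- order(-scores)
  y <- labels[ord]
  tp <- cumsum(y)
  prec <- tp / seq_along(y)
  rec <- tp / npos
  auprc <- sum(prec * diff(c(0, rec)))
  pred <- as.integer(scores >= threshold)
  sens <- sum(pred == 1L & labels == 1L) / npos
  spec <- sum(pred == 0L & labels == 0L) / nneg
  list(auroc = auroc, auprc = auprc, sensitivity = sens, specificity = spec)
}

#' Aggregate per-run metrics into a report
#'
#' @param runs Data frame with one row per run and the four metric columns.
#' @return A `metric_report`: the per-run table plus mean and standard
#'   deviation per metric.
#' @export
metric_report <- function(runs) {
  metrics <- c("auroc", "auprc", "sensitivity", "specificity")
  stopifnot(all(metrics %in% names(runs)))
  structure(list(
    runs = runs,
    mean = vapply(runs[metrics], mean, numeric(1)),
    sd = vapply(runs[metrics], stats::sd, numeric(1)),
    n_runs = nrow(runs)
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("Metric report over %d run(s):\n", x$n_runs))
  for (m in names(x$mean)) {
    cat(sprintf("  %-12s %.4f +/- %.4f\n", m, x$mean[m],
                if (is.na(x$sd[m])) 0 else x$sd[m]))
  }
  invisible(x)
}
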