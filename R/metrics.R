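#' Confusion counts at a threshold
#'
#' @param labels Binary 0/1 truth vector.
#' @param predictions Binary 0/1 predictions (or probabilities already
#'   thresholded by the caller).
#' @return Named list with `TP`, `FP`, `TN`, `FN`, `TPR`, `FPR`,
#'   `recall`, `precision` (rates are `NaN` when undefined).
#' @export
confusion_counts <- function(labels, predictions) {
  if (length(labels) == 0) stop2("empty input")
  if (length(labels) != length(predictions)) stop2("length mismatch")
  if (!all(labels %in% c(0, 1))) stop2("labels must be binary 0/1")
  tp <- sum(labels == 1 & predictions == 1)
  fp <- sum(labels == 0 & predictions == 1)
  tn <- sum(labels == 0 & predictions == 0)
  fn <- sum(labels == 1 & predictions == 0)
  list(TP = tp, FP = fp, TN = tn, FN = fn,
       TPR = tp / (tp + fn), FPR = fp / (fp + tn),
       recall = tp / (tp + fn), precision = tp / (tp + fp))
}

#' ROC and precision-recall curves with AUROC / AUPRC
#'
#' Sweeps the decision threshold over the unique scores (samples with tied
#' scores enter the confusion table together), producing the ROC curve from
#' (0,0) to (1,1) and the PR curve. AUROC is the trapezoidal area under the
#' ROC curve; AUPRC uses the step-wise rule
#' `sum((recall_i - recall_{i-1}) * precision_i)` (no linear interpolation
#' of precision, which is known to be optimistic).
#'
#' @param labels Binary 0/1 truth vector containing both classes.
#' @param scores Finite numeric scores; larger means more positive.
#' @return An object of class `eval_result`: list with `roc` (data.frame
#'   `fpr`, `tpr`, `threshold`), `pr` (data.frame `recall`, `precision`,
#'   `threshold`), `auroc`, `auprc`, `n_pos`, `n_neg`, plus the inputs.
#' @export
roc_pr_curves <- function(labels, scores) {
  if (length(labels) != length(scores)) stop2("length mismatch")
  if (!all(is.finite(scores))) stop2("scores must be finite")
  if (!all(labels %in% c(0, 1))) stop2("labels must be binary 0/1")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop2("both classes must be present; AUROC/AUPRC undefined otherwise")
  }
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  # group tied scores: keep the cumulative counts at the last index of each
  # tie block
  last_of_tie <- c(s[-length(s)] != s[-1], TRUE)
  tp <- cumsum(y)[last_of_tie]
  fp <- cumsum(1 - y)[last_of_tie]
  thr <- s[last_of_tie]
  tpr <- tp / n_pos
  fpr <- fp / n_neg
  recall <- tpr
  precision <- tp / (tp + fp)

  roc <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr),
                    threshold = c(Inf, thr))
  auroc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  pr <- data.frame(recall = recall, precision = precision, threshold = thr)
  auprc <- sum(diff(c(0, recall)) * precision)

  structure(list(roc = roc, pr = pr, auroc = auroc, auprc = auprc,
                 n_pos = n_pos, n_neg = n_neg,
                 labels = labels, scores = scores),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("eval_result: %d positives / %d negatives\n", x$n_pos, x$n_neg))
  cat(sprintf("  AUROC %.4f | AUPRC %.4f (prevalence %.4f)\n",
              x$auroc, x$auprc, x$n_pos / (x$n_pos + x$n_neg)))
  invisible(x)
}

#' Plot ROC and PR curves
#' @param x An `eval_result`.
#' @param which `"roc"`, `"pr"` or `"both"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.eval_result <- function(x, which = c("both", "roc", "pr"), ...) {
  which <- match.arg(which)
  if (which == "both") {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
  }
  if (which %in% c("both", "roc")) {
    graphics::plot(x$roc$fpr, x$roc$tpr, type = "l", xlim = c(0, 1),
                   ylim = c(0, 1), xlab = "FPR", ylab = "TPR",
                   main = sprintf("ROC (AUROC %.3f)", x$auroc), ...)
    graphics::abline(0, 1, lty = 3)
  }
  if (which %in% c("both", "pr")) {
    graphics::plot(x$pr$recall, x$pr$precision, type = "s", xlim = c(0, 1),
                   ylim = c(0, 1), xlab = "recall", ylab = "precision",
                   main = sprintf("PR (AUPRC %.3f)", x$auprc), ...)
    graphics::abline(h = x$n_pos / (x$n_pos + x$n_neg), lty = 3)
  }
  invisible(x)
}

#' Per-regulator performance summary
#'
#' AUROC/AUPRC and class counts computed separately within each
#' `tf_group` block. Groups with a single class get `NA` metrics and a
#' `flag`.
#'
#' @param labels,scores As in [roc_pr_curves()].
#' @param tf_group Character vector of regulator blocks, same length.
#' @return data.frame with one row per group: `tf_group`, `auroc`,
#'   `auprc`, `n_pos`, `n_neg`, `flag`.
#' @export
per_tf_summary <- function(labels, scores, tf_group) {
  stopifnot(length(labels) == length(scores),
            length(labels) == length(tf_group))
  groups <- sort(unique(tf_group))
  rows <- lapply(groups, function(g) {
    sel <- tf_group == g
    y <- labels[sel]; s <- scores[sel]
    n_pos <- sum(y == 1); n_neg <- sum(y == 0)
    if (n_pos == 0 || n_neg == 0) {
      data.frame(tf_group = g, auroc = NA_real_, auprc = NA_real_,
                 n_pos = n_pos, n_neg = n_neg, flag = "single_class",
                 stringsAsFactors = FALSE)
    } else {
      ev <- roc_pr_curves(y, s)
      data.frame(tf_group = g, auroc = ev$auroc, auprc = ev$auprc,
                 n_pos = n_pos, n_neg = n_neg, flag = "",
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Write an evaluation report as TSV
#'
#' Writes the summary metrics and, optionally, the curve points for
#' external plotting.
#'
#' @param result An `eval_result`.
#' @param path Output TSV path for the summary; curve files are written
#'   next to it with suffixes `_roc.tsv` and `_pr.tsv` when
#'   `curves = TRUE`.
#' @param curves Also export curve points.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(result, path, curves = FALSE) {
  summary_df <- data.frame(metric = c("auroc", "auprc", "n_pos", "n_neg"),
                           value = c(result$auroc, result$auprc,
                                     result$n_pos, result$n_neg))
  utils::write.table(summary_df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (curves) {
    base <- sub("\\.tsv$", "", path)
    utils::write.table(result$roc, paste0(base, "_roc.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(result$pr, paste0(base, "_pr.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
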