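#' Regulator-held-out cross-validation
#'
#' Runs the TF-disjoint k-fold protocol: TFs are partitioned into folds
#' (see [make_tf_folds()]), each fold's samples are held out as the test
#' set while a model is fitted on the remaining samples (with a sample-
#' level validation carve-out for checkpoint selection), and test
#' probabilities are scored against truth. Because every sample of a
#' regulator sits in exactly one fold, test performance measures
#' generalization to unseen regulators.
#'
#' @param samples `pair_samples` with a `tf_group` column.
#' @param expr An [expression_matrix()].
#' @param n_folds Number of folds (default 3).
#' @param val_fraction Validation fraction within each training part.
#' @param seed Integer seed for fold assignment shuffles and training.
#' @param keep_models Keep each fold's fitted model in the result.
#' @param verbose Print per-fold progress.
#' @param ... Hyperparameters passed to [gemgrn()] (window, epochs, ...).
#' @return An object of class `gemgrn_cv`: list with `folds` (per fold:
#'   `split`, `eval`, `scores`, `labels`, optionally `model`), `pooled`
#'   (an `eval_result` over all held-out samples) and `summary`
#'   (data.frame of per-fold AUROC/AUPRC).
#' @export
gemgrn_crossval <- function(samples, expr, n_folds = 3, val_fraction = 0.2,
                            seed = 1L, keep_models = FALSE, verbose = FALSE,
                            ...) {
  splits <- make_tf_folds(samples, n_folds = n_folds,
                          val_fraction = val_fraction, seed = seed)
  folds <- lapply(splits, function(sp) {
    if (verbose) message("fold ", sp$fold_id)
    fit <- gemgrn(split_part(samples, sp, "train"), expr,
                  val_samples = split_part(samples, sp, "val"),
                  seed = seed + sp$fold_id, verbose = verbose, ...)
    test <- split_part(samples, sp, "test")
    scores <- predict(fit, test, expr)
    ev <- roc_pr_curves(test$label, scores)
    out <- list(split = sp, eval = ev, scores = scores, labels = test$label)
    if (keep_models) out$model <- fit
    out
  })
  all_scores <- unlist(lapply(folds, `[[`, "scores"))
  all_labels <- unlist(lapply(folds, `[[`, "labels"))
  pooled <- roc_pr_curves(all_labels, all_scores)
  summary <- data.frame(fold = seq_along(folds),
                        auroc = vapply(folds, function(f) f$eval$auroc, 0),
                        auprc = vapply(folds, function(f) f$eval$auprc, 0),
                        n_test = vapply(folds, function(f) length(f$labels), 0L))
  structure(list(folds = folds, pooled = pooled, summary = summary),
            class = "gemgrn_cv")
}

#' @export
print.gemgrn_cv <- function(x, ...) {
  cat(sprintf("gemgrn_cv: %d regulator-disjoint folds\n", nrow(x$summary)))
  print(x$summary, row.names = FALSE)
  cat(sprintf("pooled: AUROC %.4f | AUPRC %.4f\n",
              x$pooled$auroc, x$pooled$auprc))
  invisible(x)
}
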