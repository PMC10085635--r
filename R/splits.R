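#' Stratified 3:1:1 split for network reconstruction
#'
#' Partitions gene-pair samples into train/validation/test sets with a
#' 3:1:1 ratio, stratified by label so each part keeps the global
#' positive-to-negative ratio to within one sample per class. Used for the
#' reconstruction task, where the same regulators may appear in all parts.
#'
#' @param samples A `pair_samples` data.frame.
#' @param seed Integer seed; the same seed reproduces the same partition.
#' @return A `split_spec`: list with integer index vectors `train`, `val`,
#'   `test` (a partition of `seq_len(nrow(samples))`), plus `strategy`,
#'   `fold_id`, `seed`.
#' @export
split_gene_gene <- function(samples, seed = 1L) {
  y <- samples$label
  n_by <- table(factor(y, levels = c(0, 1)))
  if (any(n_by < 5)) {
    stop2("each class needs at least 5 samples for a 3:1:1 split")
  }
  with_seed(seed, {
    train <- val <- test <- integer(0)
    for (cl in c(0L, 1L)) {
      idx <- sample(which(y == cl))
      n <- length(idx)
      n_tr <- round(3 * n / 5)
      n_va <- round(n / 5)
      if (n - n_tr - n_va < 1 || n_va < 1 || n_tr < 1) {
        stop2("class too small to appear in every part")
      }
      train <- c(train, idx[seq_len(n_tr)])
      val <- c(val, idx[n_tr + seq_len(n_va)])
      test <- c(test, idx[(n_tr + n_va + 1):n])
    }
    new_split_spec(sort(train), sort(val), sort(test),
                   strategy = "gene_gene_311", fold_id = NA_integer_,
                   seed = seed)
  })
}

new_split_spec <- function(train, val, test, strategy, fold_id, seed) {
  structure(list(train = train, val = val, test = test,
                 strategy = strategy, fold_id = fold_id, seed = seed),
            class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("split_spec (%s%s): %d train / %d val / %d test\n",
              x$strategy,
              if (!is.na(x$fold_id)) paste0(", fold ", x$fold_id) else "",
              length(x$train), length(x$val), length(x$test)))
  invisible(x)
}

#' Regulator-disjoint k-fold splits for TF-gene prediction
#'
#' Partitions the distinct `tf_group` values into `n_folds` folds so that
#' every sample of a given transcription factor lands in exactly one fold
#' -- the anti-leakage guarantee of regulator-held-out evaluation. Each
#' fold in turn is the test set; the remaining samples are split
#' (1 - `val_fraction`) / `val_fraction` into train and validation at the
#' sample level, stratified by label. Fold sizes are unequal whenever TFs
#' regulate different numbers of targets; assignment is greedy (largest TF
#' block first, into the currently smallest fold) so fold sample counts
#' never differ by more than the largest single TF block.
#'
#' @param samples A `pair_samples` data.frame with a `tf_group` column.
#' @param n_folds Number of folds (default 3).
#' @param val_fraction Fraction of each fold's non-test samples used for
#'   validation (default 0.2).
#' @param seed Integer seed for the train/validation shuffle.
#' @return List of `n_folds` `split_spec` objects with
#'   `strategy = "tf_3fold"` and `fold_id` set.
#' @export
make_tf_folds <- function(samples, n_folds = 3, val_fraction = 0.2, seed = 1L) {
  tfs <- unique(samples$tf_group)
  if (length(tfs) < n_folds) {
    stop2(sprintf("need at least %d distinct TFs, got %d", n_folds, length(tfs)))
  }
  cnt <- table(samples$tf_group)
  ord <- names(cnt)[order(-as.integer(cnt), names(cnt), method = "radix")]
  fold_of <- integer(0)
  fold_sizes <- numeric(n_folds)
  for (tf in ord) {
    f <- which.min(fold_sizes)
    fold_of[tf] <- f
    fold_sizes[f] <- fold_sizes[f] + cnt[[tf]]
  }
  lapply(seq_len(n_folds), function(f) {
    test <- which(samples$tf_group %in% names(fold_of)[fold_of == f])
    rest <- setdiff(seq_len(nrow(samples)), test)
    with_seed(seed + f, {
      val <- integer(0)
      for (cl in unique(samples$label[rest])) {
        idx <- sample(rest[samples$label[rest] == cl])
        val <- c(val, idx[seq_len(floor(val_fraction * length(idx)))])
      }
      train <- setdiff(rest, val)
      new_split_spec(sort(train), sort(val), sort(test),
                     strategy = "tf_3fold", fold_id = f, seed = seed)
    })
  })
}

#' Subset pair samples by a split component
#'
#' @param samples A `pair_samples` data.frame.
#' @param split A `split_spec`.
#' @param part `"train"`, `"val"` or `"test"`.
#' @return The corresponding rows of `samples`.
#' @export
split_part <- function(samples, split, part = c("train", "val", "test")) {
  part <- match.arg(part)
  samples[split[[part]], , drop = FALSE]
}
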