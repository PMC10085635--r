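# splits and the optimization loop

make_samples <- function(n_pos, n_neg, n_tfs = 3) {
  data.frame(gene_a = rep(sprintf("tf%d", seq_len(n_tfs)),
                          length.out = n_pos + n_neg),
             gene_b = sprintf("g%d", seq_len(n_pos + n_neg)),
             label = c(rep(1L, n_pos), rep(0L, n_neg)),
             task = "gene_gene",
             tf_group = rep(sprintf("tf%d", seq_len(n_tfs)),
                            length.out = n_pos + n_neg),
             stringsAsFactors = FALSE)
}

test_that("3:1:1 split is stratified to within one sample per class", {
  s <- make_samples(300, 1500)
  sp <- split_gene_gene(s, seed = 7)
  counts <- function(idx) table(factor(s$label[idx], levels = 0:1))
  tr <- counts(sp$train); va <- counts(sp$val); te <- counts(sp$test)
  # exact stratified arithmetic for 300 + 1500
  expect_equal(as.vector(tr), c(900, 180))
  expect_equal(as.vector(va), c(300, 60))
  expect_equal(as.vector(te), c(300, 60))
  # partition
  all_idx <- sort(c(sp$train, sp$val, sp$test))
  expect_identical(all_idx, seq_len(nrow(s)))
  # determinism
  sp2 <- split_gene_gene(s, seed = 7)
  expect_identical(sp, sp2)
  expect_false(identical(sp$train, split_gene_gene(s, seed = 8)$train))
})

test_that("stratification holds for awkward class sizes", {
  for (np in c(7, 13, 29)) {
    for (nn in c(11, 40)) {
      s <- make_samples(np, nn)
      sp <- split_gene_gene(s, seed = np * nn)
      glob <- np / (np + nn)
      for (part in list(sp$train, sp$val, sp$test)) {
        n1 <- sum(s$label[part] == 1)
        # within +/- 1 sample of the proportional count per class
        expect_lte(abs(n1 - glob * length(part)), 1 + 1e-9)
        expect_gte(min(table(factor(s$label[part], levels = 0:1))), 1)
      }
    }
  }
  expect_error(split_gene_gene(make_samples(4, 100)), "at least 5")
})

test_that("TF folds hold out every regulator's block exactly once", {
  gemgrn:::with_seed(10, {
    for (rep in 1:5) {
      n_tfs <- sample(4:8, 1)
      blocks <- sample(2:12, n_tfs, replace = TRUE) * 2
      s <- do.call(rbind, lapply(seq_len(n_tfs), function(i) {
        data.frame(gene_a = sprintf("tf%d", i),
                   gene_b = sprintf("tf%d_g%d", i, seq_len(blocks[i])),
                   label = rep(0:1, blocks[i] / 2), task = "x",
                   tf_group = sprintf("tf%d", i), stringsAsFactors = FALSE)
      }))
      folds <- make_tf_folds(s, n_folds = 3, seed = rep)
      test_union <- integer(0)
      for (f in folds) {
        # anti-leakage: no TF appears on both sides
        expect_length(intersect(s$tf_group[f$test],
                                s$tf_group[c(f$train, f$val)]), 0)
        expect_identical(sort(c(f$train, f$val, f$test)), seq_len(nrow(s)))
        test_union <- c(test_union, f$test)
        # validation carve-out ~20% of the non-test samples
        expect_lt(abs(length(f$val) / (length(f$val) + length(f$train)) - 0.2),
                  0.08)
      }
      # the 3 test sets partition all samples
      expect_identical(sort(test_union), seq_len(nrow(s)))
      # greedy size balancing: fold spread bounded by the largest TF block
      sizes <- vapply(folds, function(f) length(f$test), integer(1))
      expect_lte(max(sizes) - min(sizes), max(blocks))
    }
  })
  expect_error(make_tf_folds(make_samples(4, 4, n_tfs = 2), n_folds = 3),
               "at least 3")
})

test_that("training solves a separable toy problem and epochs = 0 is a no-op", {
  # labels are a threshold of one input coordinate: the first cell of gene_a
  gemgrn:::with_seed(50, {
    n <- 200; k <- 8
    vals <- matrix(rexp(n * k), n, k,
                   dimnames = list(sprintf("g%03d", 1:n), NULL))
    em <- expression_matrix(vals)
    s <- data.frame(gene_a = sprintf("g%03d", 1:(n / 2)),
                    gene_b = sprintf("g%03d", (n / 2 + 1):n),
                    label = as.integer(vals[1:(n / 2), 1] >
                                         median(vals[1:(n / 2), 1])),
                    task = "toy", tf_group = "tf1", stringsAsFactors = FALSE)
  })
  sp <- split_gene_gene(s, seed = 1)
  fit <- gemgrn(split_part(s, sp, "train"), em,
                val_samples = split_part(s, sp, "val"),
                window = 4, d_ff = 16, head_hidden = 8, dropout = 0,
                epochs = 100, batch_size = 8, warmup_epochs = 2, seed = 1)
  expect_gte(max(fit$history$val_auroc, na.rm = TRUE), 0.95)
  # best-so-far train loss envelope is non-increasing
  env <- cummin(fit$history$train_loss)
  expect_true(all(diff(env) <= 1e-12))

  fit0 <- gemgrn(split_part(s, sp, "train"), em, window = 4, epochs = 0,
                 seed = 1)
  expect_equal(nrow(fit0$history), 0)
  expect_equal(fit0$best_epoch, 0)
  # an untrained model still produces valid probabilities, reproducibly
  p1 <- predict(fit0, split_part(s, sp, "test"), em)
  p2 <- predict(fit0, split_part(s, sp, "test"), em)
  expect_identical(p1, p2)
  expect_true(all(p1 > 0 & p1 < 1))
})

test_that("permuted labels give chance-level validation performance", {
  gemgrn:::with_seed(51, {
    n <- 120; k <- 12
    vals <- matrix(rexp(n * k), n, k,
                   dimnames = list(sprintf("g%03d", 1:n), NULL))
    em <- expression_matrix(vals)
    s <- data.frame(gene_a = sprintf("g%03d", 1:(n / 2)),
                    gene_b = sprintf("g%03d", (n / 2 + 1):n),
                    label = rep(0:1, n / 4), task = "toy", tf_group = "tf1",
                    stringsAsFactors = FALSE)
  })
  sp <- split_gene_gene(s, seed = 2)
  fit <- gemgrn(split_part(s, sp, "train"), em,
                val_samples = split_part(s, sp, "val"),
                window = 4, d_ff = 16, head_hidden = 8, dropout = 0,
                epochs = 10, batch_size = 16, warmup_epochs = 2, seed = 2)
  te <- split_part(s, sp, "test")
  auc <- roc_pr_curves(te$label, predict(fit, te, em))$auroc
  expect_gt(auc, 0.2); expect_lt(auc, 0.8)
})

test_that("fitting is reproducible from the seed", {
  em <- rand_expr(20, 10, seed = 60)
  s <- data.frame(gene_a = sprintf("g%03d", 1:10),
                  gene_b = sprintf("g%03d", 11:20),
                  label = rep(0:1, 5), task = "toy", tf_group = "tf1",
                  stringsAsFactors = FALSE)
  f1 <- gemgrn(s, em, window = 3, d_ff = 8, head_hidden = 4, epochs = 3,
               batch_size = 4, seed = 9)
  f2 <- gemgrn(s, em, window = 3, d_ff = 8, head_hidden = 4, epochs = 3,
               batch_size = 4, seed = 9)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$history, f2$history)
})
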