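# synthetic data generator with planted regulatory structure

test_that("degenerate spec copies the TF profile into its targets exactly", {
  sp <- simulation_spec(n_tfs = 1, targets_per_tf = 2, n_noise_genes = 1,
                        k_cells = 40, sync_spans = list(c(0, 40)),
                        coupling = 1, dropout_rate = 0, noise_sd = 0, seed = 5)
  sim <- simulate_dataset(sp)
  v <- sim$expr$values
  expect_equal(v["tf01_tg01", ], v["tf01", ], ignore_attr = TRUE)
  expect_equal(v["tf01_tg02", ], v["tf01", ], ignore_attr = TRUE)
  expect_false(isTRUE(all.equal(unname(v["noise001", ]), unname(v["tf01", ]))))
})

test_that("zero coupling leaves targets uncorrelated with their TF", {
  rs <- replicate(200, NA_real_)
  for (i in seq_along(rs)) {
    sp <- simulation_spec(n_tfs = 1, targets_per_tf = 1, n_noise_genes = 0,
                          k_cells = 60, sync_spans = list(c(0, 60)),
                          coupling = 0, dropout_rate = 0, noise_sd = 0.1,
                          seed = i)
    sim <- simulate_dataset(sp)
    rs[i] <- cor(log1p(sim$expr$values["tf01", ]),
                 log1p(sim$expr$values["tf01_tg01", ]))
  }
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("coupling raises within-span correlation above outside-span", {
  sp <- simulation_spec(n_tfs = 3, targets_per_tf = 10, n_noise_genes = 0,
                        k_cells = 300, sync_spans = rep(list(c(0, 150)), 3),
                        coupling = 0.9, dropout_rate = 0, noise_sd = 0.2,
                        seed = 2)
  sim <- simulate_dataset(sp)
  lv <- log1p(sim$expr$values)
  inside <- outside <- numeric(0)
  for (i in seq_len(nrow(sim$net))) {
    a <- sim$net$regulator[i]; b <- sim$net$target[i]
    inside <- c(inside, cor(lv[a, 1:150], lv[b, 1:150]))
    outside <- c(outside, cor(lv[a, 151:300], lv[b, 151:300]))
  }
  expect_lt(t.test(inside, outside, alternative = "greater")$p.value, 1e-6)
  expect_gt(mean(inside), 0.6)
  expect_lt(abs(mean(outside)), 0.25)
})

test_that("realized dropout rate is within binomial tolerance of the spec", {
  sp <- simulation_spec(n_tfs = 2, targets_per_tf = 5, n_noise_genes = 20,
                        k_cells = 200, dropout_rate = 0.3, seed = 3)
  sim <- simulate_dataset(sp)
  n <- length(sim$expr$values)
  rate <- mean(sim$expr$values == 0)
  expect_lt(abs(rate - 0.3), 4 * sqrt(0.3 * 0.7 / n))
})

test_that("simulation is reproducible and emits consistent metadata", {
  sp <- simulation_spec(seed = 11, k_cells = 100, n_tfs = 2,
                        targets_per_tf = 3, n_noise_genes = 5)
  s1 <- simulate_dataset(sp)
  s2 <- simulate_dataset(sp)
  expect_identical(s1$expr$values, s2$expr$values)
  expect_equal(nrow(s1$net), 2 * 3)
  expect_equal(nrow(s1$spans), 2)
  expect_true(all(s1$spans$start >= 0 & s1$spans$end <= 100))
  expect_equal(s1$expr$cell_order_kind, "pseudotime")
  expect_true(all(s1$expr$values >= 0))
  # matrix round-trips through the io layer
  path <- withr::local_tempfile(fileext = ".csv")
  write_expression_matrix(s1$expr, path)
  expect_identical(read_expression_matrix(path)$values, s1$expr$values)
})

test_that("spec validation rejects bad spans and parameters", {
  expect_error(simulation_spec(coupling = 1.5), "coupling")
  expect_error(simulation_spec(n_tfs = 2, sync_spans = list(c(0, 10))),
               "one entry per TF")
  expect_error(simulation_spec(n_tfs = 1, k_cells = 50,
                               sync_spans = list(c(10, 60))), "within")
})

test_that("task fixtures compose samples and splits; causality flips labels on swap", {
  sp <- simulation_spec(n_tfs = 3, targets_per_tf = 4, n_noise_genes = 10,
                        k_cells = 80, seed = 21)
  expect_message(fx <- make_task_fixture(sp, "causality"), "tf_scale")
  expect_equal(nrow(fx$samples), 2 * 3 * 4)
  pos <- fx$samples[fx$samples$label == 1, ]
  neg <- fx$samples[fx$samples$label == 0, ]
  # swapping direction is exactly the label-0 set
  expect_setequal(paste(pos$gene_b, pos$gene_a), paste(neg$gene_a, neg$gene_b))
  # TFs get the raised expression scale
  expect_gt(mean(fx$expr$values["tf01", ]) /
              mean(fx$expr$values["tf01_tg01", ]), 1.5)

  fxg <- make_task_fixture(simulation_spec(n_tfs = 2, targets_per_tf = 5,
                                           n_noise_genes = 10, k_cells = 60,
                                           seed = 22), "gene_gene")
  expect_s3_class(fxg$split, "split_spec")
  n_genes <- 2 + 10 + 10
  expect_equal(nrow(fxg$samples), 2 * (n_genes - 1))
  # interaction fixtures are balanced
  fxi <- make_task_fixture(simulation_spec(n_tfs = 2, targets_per_tf = 5,
                                           n_noise_genes = 10, k_cells = 60,
                                           seed = 23), "interaction")
  expect_equal(sum(fxi$samples$label == 1), sum(fxi$samples$label == 0))
})
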