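# network mechanics against brute-force oracles

softmax_oracle <- function(z) { e <- exp(z - max(z)); e / sum(e) }

# O(L^2 d) triple-loop scaled dot-product attention
attention_oracle <- function(Q, K, V, scale) {
  L <- nrow(Q); dh <- ncol(V)
  out <- matrix(0, L, dh)
  for (i in seq_len(L)) {
    scores <- numeric(L)
    for (j in seq_len(L)) scores[j] <- sum(Q[i, ] * K[j, ]) / scale
    w <- softmax_oracle(scores)
    for (c in seq_len(dh)) out[i, c] <- sum(w * V[, c])
  }
  out
}

sdp_attention <- function(Q, K, V, scale) {
  gemgrn:::softmax_rows(Q %*% t(K) / scale) %*% V
}

test_that("scaled dot-product attention agrees with a triple-loop oracle", {
  gemgrn:::with_seed(21, {
    for (rep in 1:50) {
      L <- sample(2:8, 1); dh <- sample(2:6, 1)
      Q <- matrix(rnorm(L * dh), L); K <- matrix(rnorm(L * dh), L)
      V <- matrix(rnorm(L * dh), L)
      sc <- sqrt(dh)
      expect_equal(sdp_attention(Q, K, V, sc), attention_oracle(Q, K, V, sc),
                   tolerance = 1e-5)
    }
  })
})

test_that("attention degenerates correctly for constant V and zero scores", {
  gemgrn:::with_seed(22, {
    Q <- matrix(rnorm(20), 5); K <- matrix(rnorm(20), 5)
    V <- matrix(rep(c(1, 2, 3, 4), each = 5), 5)   # constant across rows
    out <- sdp_attention(Q, K, V, 2)
    expect_equal(out, V, tolerance = 1e-12)
    # zero Q, K: uniform weights -> column means of V
    V2 <- matrix(rnorm(20), 5)
    out2 <- sdp_attention(matrix(0, 5, 4), matrix(0, 5, 4), V2, 2)
    expect_equal(out2, matrix(rep(colMeans(V2), each = 5), 5), tolerance = 1e-12)
    # softmax rows sum to 1
    A <- gemgrn:::softmax_rows(Q %*% t(K) / 2)
    expect_equal(rowSums(A), rep(1, 5))
  })
})

test_that("forward pass attention rows sum to one for every head", {
  cfg <- tiny_cfg()
  X <- gemgrn:::with_seed(3, matrix(rnorm(2 * 4 * cfg$d_model), 8))
  params <- gemgrn:::with_seed(5, gemgrn:::nn_init(cfg))
  fwd <- gemgrn:::nn_forward(params, X, cfg, L = 4, train = FALSE)
  expect_length(fwd$attn, 2 * cfg$n_heads)
  for (A in fwd$attn) {
    expect_equal(dim(A), c(4, 4))
    expect_equal(rowSums(A), rep(1, 4), tolerance = 1e-12)
  }
  expect_true(all(fwd$prob > 0 & fwd$prob < 1))
})

test_that("layer norm rows have mean 0 and unit variance within eps", {
  X <- gemgrn:::with_seed(6, matrix(rnorm(60, 5, 3), 10))
  ln <- gemgrn:::ln_fwd(X, g = rep(1, 6), b = rep(0, 6))
  expect_equal(rowMeans(ln$Y), rep(0, 10), tolerance = 1e-10)
  # population variance (divides by d), eps = 1e-5 loosens it slightly
  expect_equal(apply(ln$Y, 1, function(r) mean(r^2)), rep(1, 10),
               tolerance = 1e-3)
})

test_that("average pooling equals a per-column loop and sigmoid midpoint is half", {
  cfg <- tiny_cfg()
  B <- 3; L <- 4
  X <- gemgrn:::with_seed(7, matrix(rnorm(B * L * cfg$d_model), B * L))
  params <- gemgrn:::with_seed(8, gemgrn:::nn_init(cfg))
  fwd <- gemgrn:::nn_forward(params, X, cfg, L, train = TRUE)
  pool_oracle <- matrix(0, B, cfg$d_model)
  for (b in seq_len(B)) {
    for (cc in seq_len(cfg$d_model)) {
      pool_oracle[b, cc] <- mean(fwd$cache$x_enc[((b - 1) * L + 1):(b * L), cc])
    }
  }
  expect_equal(fwd$cache$pooled, pool_oracle, tolerance = 1e-12)
  expect_equal(plogis(0), 0.5)
})

test_that("analytic gradients match finite differences in both architecture modes", {
  y <- c(1, 0, 1, 0)
  for (mode in c("standard", "literal")) {
    cfg <- if (mode == "standard") tiny_cfg() else
      tiny_cfg(pe_divisor = "window", attn_scale = "window",
               post_ffn_ln = FALSE)
    L <- 3
    X <- gemgrn:::with_seed(42, matrix(rnorm(4 * L * cfg$d_model), 4 * L))
    params <- gemgrn:::with_seed(43, gemgrn:::nn_init(cfg))
    fwd <- gemgrn:::nn_forward(params, X, cfg, L, train = TRUE)
    grads <- gemgrn:::nn_backward(params, fwd, y, cfg)
    loss_at <- function(p) {
      f <- gemgrn:::nn_forward(p, X, cfg, L, train = FALSE, keep_cache = FALSE)
      gemgrn:::bce_loss(f$prob, y)
    }
    eps <- 1e-6
    idx_of <- function(v) if (length(v) > 12)
      gemgrn:::with_seed(44, sample(seq_along(v), 12)) else seq_along(v)
    for (nm in names(params)) {
      for (i in idx_of(params[[nm]])) {
        p2 <- params; p2[[nm]][i] <- p2[[nm]][i] + eps
        p3 <- params; p3[[nm]][i] <- p3[[nm]][i] - eps
        gnum <- (loss_at(p2) - loss_at(p3)) / (2 * eps)
        expect_equal(grads[[nm]][i], gnum, tolerance = 1e-4,
                     label = sprintf("%s grad %s[%d]", mode, nm, i))
      }
    }
  }
})

test_that("pooled output is permutation-invariant without positional encoding only", {
  cfg_nope <- tiny_cfg(positional = FALSE)
  cfg_pe <- tiny_cfg(positional = TRUE)
  L <- 5
  X <- gemgrn:::with_seed(31, matrix(rnorm(L * cfg_pe$d_model), L))
  params <- gemgrn:::with_seed(32, gemgrn:::nn_init(cfg_pe))
  perm <- c(3, 1, 5, 2, 4)
  f1 <- gemgrn:::nn_forward(params, X, cfg_nope, L, keep_cache = FALSE)
  f2 <- gemgrn:::nn_forward(params, X[perm, ], cfg_nope, L, keep_cache = FALSE)
  expect_equal(f1$prob, f2$prob, tolerance = 1e-10)
  # per-position outputs permute along (equivariance)
  expect_equal(f1$x_enc[perm, ], f2$x_enc, tolerance = 1e-10)
  # with positional encoding the invariance breaks
  g1 <- gemgrn:::nn_forward(params, X, cfg_pe, L, keep_cache = FALSE)
  g2 <- gemgrn:::nn_forward(params, X[perm, ], cfg_pe, L, keep_cache = FALSE)
  expect_gt(abs(g1$prob - g2$prob), 1e-8)
})

test_that("batched forward equals one-by-one forward passes", {
  cfg <- tiny_cfg()
  L <- 4; B <- 5
  X <- gemgrn:::with_seed(33, matrix(rnorm(B * L * cfg$d_model), B * L))
  params <- gemgrn:::with_seed(34, gemgrn:::nn_init(cfg))
  batch <- gemgrn:::nn_forward(params, X, cfg, L, keep_cache = FALSE)
  single <- vapply(seq_len(B), function(b) {
    rows <- ((b - 1) * L + 1):(b * L)
    gemgrn:::nn_forward(params, X[rows, , drop = FALSE], cfg, L,
                        keep_cache = FALSE)$prob
  }, numeric(1))
  expect_equal(batch$prob, single, tolerance = 1e-12)
})

test_that("config enforces its invariants and default structure", {
  expect_error(gemgrn_config(window = 3, n_heads = 4), "divisible")
  expect_error(gemgrn_config(dropout = 1), "dropout")
  cfg <- gemgrn_config(window = 100)
  expect_equal(cfg$d_model, 200)
  expect_equal(cfg$n_heads, 2)
  expect_equal(cfg$n_encoder_layers, 1)
  expect_equal(cfg$d_ff, 400)
})

test_that("single-head attention with identity-like projections reduces to plain attention", {
  cfg <- gemgrn_config(window = 2, n_heads = 1, d_ff = 8, head_hidden = 3,
                       dropout = 0, positional = FALSE, warmup_epochs = 0)
  d <- cfg$d_model
  params <- gemgrn:::with_seed(35, gemgrn:::nn_init(cfg))
  params$at_Wq <- diag(d); params$at_Wk <- diag(d); params$at_Wv <- diag(d)
  params$at_bq <- params$at_bk <- params$at_bv <- numeric(d)
  L <- 4
  X <- gemgrn:::with_seed(36, matrix(rnorm(L * d), L))
  fwd <- gemgrn:::nn_forward(params, X, cfg, L, train = TRUE)
  expect_equal(fwd$cache$O, sdp_attention(X, X, X, sqrt(d)), tolerance = 1e-12)
})
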