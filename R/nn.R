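# Transformer encoder core: batched forward pass, backpropagation and Adam.
#
# All batched activations are stored as (B*L) x d matrices with sample-major
# rows: rows (i-1)*L + 1:L hold the L sub-vector positions of sample i.
# Linear layers, layer norm and the FFN act row-wise on that layout; only
# the attention score computation loops over (sample, head) blocks, which
# are small (L x L).

addb <- function(M, b) sweep(M, 2, b, "+")

softmax_rows <- function(Z) {
  Z <- exp(Z - apply(Z, 1, max))
  Z / rowSums(Z)
}

ln_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu                      # mu recycles down columns
  sd <- sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc / sd
  list(Y = addb(sweep(xhat, 2, g, "*"), b), xhat = xhat, sd = sd)
}

ln_bwd <- function(dY, xhat, sd, g) {
  dxhat <- sweep(dY, 2, g, "*")
  list(dX = (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) / sd,
       dg = colSums(dY * xhat),
       db = colSums(dY))
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

# Parameter initialization; consumes the current RNG stream so the caller
# controls the seed via with_seed().
nn_init <- function(cfg) {
  d <- cfg$d_model
  list(
    at_Wq = glorot(d, d), at_bq = numeric(d),
    at_Wk = glorot(d, d), at_bk = numeric(d),
    at_Wv = glorot(d, d), at_bv = numeric(d),
    at_Wo = glorot(d, d), at_bo = numeric(d),
    ln1_g = rep(1, d), ln1_b = numeric(d),
    ff_W1 = glorot(d, cfg$d_ff), ff_b1 = numeric(cfg$d_ff),
    ff_W2 = glorot(cfg$d_ff, d), ff_b2 = numeric(d),
    ln2_g = rep(1, d), ln2_b = numeric(d),
    hd_W1 = glorot(d, cfg$head_hidden), hd_b1 = numeric(cfg$head_hidden),
    hd_W2 = glorot(cfg$head_hidden, 1), hd_b2 = 0
  )
}

attn_scale_value <- function(cfg) {
  if (cfg$attn_scale == "window") cfg$window else sqrt(cfg$d_head)
}

pe_matrix <- function(cfg, L) {
  d_pe <- if (cfg$pe_divisor == "window") cfg$window else cfg$d_model
  positional_encoding(L, cfg$d_model, d_pe = d_pe)
}

# Forward pass. X: (B*L) x d_model GEM batch. Returns prob (length B) and,
# when keep_cache, everything backprop needs; dropout masks are drawn only
# when train = TRUE and cfg$dropout > 0.
nn_forward <- function(params, X, cfg, L, train = FALSE, keep_cache = train) {
  n_row <- nrow(X)
  B <- n_row / L
  d <- cfg$d_model
  H <- cfg$n_heads
  dh <- cfg$d_head
  p <- params

  Xp <- if (cfg$positional) X + pe_matrix(cfg, L)[rep(seq_len(L), B), ] else X

  Q <- addb(Xp %*% p$at_Wq, p$at_bq)
  K <- addb(Xp %*% p$at_Wk, p$at_bk)
  V <- addb(Xp %*% p$at_Wv, p$at_bv)
  scale <- attn_scale_value(cfg)

  O <- matrix(0, n_row, d)
  attn <- if (keep_cache || TRUE) vector("list", B * H) else NULL
  for (b in seq_len(B)) {
    rows <- ((b - 1) * L + 1):(b * L)
    for (h in seq_len(H)) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      A <- softmax_rows(Q[rows, cols, drop = FALSE] %*%
                          t(K[rows, cols, drop = FALSE]) / scale)
      O[rows, cols] <- A %*% V[rows, cols, drop = FALSE]
      attn[[(b - 1) * H + h]] <- A
    }
  }

  attn_out <- addb(O %*% p$at_Wo, p$at_bo)
  use_drop <- train && cfg$dropout > 0
  mask1 <- if (use_drop) {
    matrix((stats::runif(n_row * d) >= cfg$dropout) / (1 - cfg$dropout), n_row, d)
  } else NULL
  a_do <- if (use_drop) attn_out * mask1 else attn_out

  l1 <- ln_fwd(Xp + a_do, p$ln1_g, p$ln1_b)
  x_att <- l1$Y

  h_pre <- addb(x_att %*% p$ff_W1, p$ff_b1)
  h_act <- pmax(h_pre, 0)
  ffn <- addb(h_act %*% p$ff_W2, p$ff_b2)
  mask2 <- if (use_drop) {
    matrix((stats::runif(n_row * d) >= cfg$dropout) / (1 - cfg$dropout), n_row, d)
  } else NULL
  f_do <- if (use_drop) ffn * mask2 else ffn

  if (cfg$post_ffn_ln) {
    l2 <- ln_fwd(x_att + f_do, p$ln2_g, p$ln2_b)
    x_enc <- l2$Y
  } else {
    l2 <- NULL
    x_enc <- f_do
  }

  pooled <- unname(rowsum(x_enc, group = rep(seq_len(B), each = L),
                          reorder = FALSE)) / L
  hh_pre <- addb(pooled %*% p$hd_W1, p$hd_b1)
  hh_act <- pmax(hh_pre, 0)
  logit <- drop(hh_act %*% p$hd_W2) + p$hd_b2
  prob <- stats::plogis(logit)

  out <- list(prob = prob, logit = logit, attn = attn)
  if (keep_cache) {
    out$cache <- list(Xp = Xp, Q = Q, K = K, V = V, O = O,
                      mask1 = mask1, l1 = l1, x_att = x_att,
                      h_pre = h_pre, h_act = h_act, mask2 = mask2,
                      l2 = l2, x_enc = x_enc, pooled = pooled,
                      hh_pre = hh_pre, hh_act = hh_act,
                      B = B, L = L)
  } else {
    out$x_enc <- x_enc
    out$pooled <- pooled
    out$x_att <- x_att
    out$Xp <- Xp
  }
  out
}

bce_loss <- function(prob, y) {
  pr <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  -mean(y * log(pr) + (1 - y) * log(1 - pr))
}

# Backward pass for mean BCE over the batch. Returns gradients with the
# same names/shapes as the parameter list.
nn_backward <- function(params, fwd, y, cfg) {
  cc <- fwd$cache
  B <- cc$B; L <- cc$L
  d <- cfg$d_model; H <- cfg$n_heads; dh <- cfg$d_head
  p <- params
  g <- list()

  dlogit <- matrix((fwd$prob - y) / B, ncol = 1)
  g$hd_W2 <- t(cc$hh_act) %*% dlogit
  g$hd_b2 <- sum(dlogit)
  d_hh <- dlogit %*% t(p$hd_W2)
  d_hh[cc$hh_pre <= 0] <- 0
  g$hd_W1 <- t(cc$pooled) %*% d_hh
  g$hd_b1 <- colSums(d_hh)
  d_pool <- d_hh %*% t(p$hd_W1)

  d_enc <- d_pool[rep(seq_len(B), each = L), , drop = FALSE] / L

  if (cfg$post_ffn_ln) {
    bw2 <- ln_bwd(d_enc, cc$l2$xhat, cc$l2$sd, p$ln2_g)
    g$ln2_g <- bw2$dg; g$ln2_b <- bw2$db
    d_x_att <- bw2$dX
    d_fdo <- bw2$dX
  } else {
    g$ln2_g <- numeric(d); g$ln2_b <- numeric(d)
    d_x_att <- matrix(0, B * L, d)
    d_fdo <- d_enc
  }
  d_ffn <- if (!is.null(cc$mask2)) d_fdo * cc$mask2 else d_fdo
  g$ff_W2 <- t(cc$h_act) %*% d_ffn
  g$ff_b2 <- colSums(d_ffn)
  d_hact <- d_ffn %*% t(p$ff_W2)
  d_hact[cc$h_pre <= 0] <- 0
  g$ff_W1 <- t(cc$x_att) %*% d_hact
  g$ff_b1 <- colSums(d_hact)
  d_x_att <- d_x_att + d_hact %*% t(p$ff_W1)

  bw1 <- ln_bwd(d_x_att, cc$l1$xhat, cc$l1$sd, p$ln1_g)
  g$ln1_g <- bw1$dg; g$ln1_b <- bw1$db
  d_Xp <- bw1$dX                      # residual branch
  d_ado <- bw1$dX
  d_attn_out <- if (!is.null(cc$mask1)) d_ado * cc$mask1 else d_ado

  g$at_Wo <- t(cc$O) %*% d_attn_out
  g$at_bo <- colSums(d_attn_out)
  dO <- d_attn_out %*% t(p$at_Wo)

  scale <- attn_scale_value(cfg)
  dQ <- matrix(0, B * L, d)
  dK <- matrix(0, B * L, d)
  dV <- matrix(0, B * L, d)
  for (b in seq_len(B)) {
    rows <- ((b - 1) * L + 1):(b * L)
    for (h in seq_len(H)) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      A <- fwd$attn[[(b - 1) * H + h]]
      dOb <- dO[rows, cols, drop = FALSE]
      Vb <- cc$V[rows, cols, drop = FALSE]
      dA <- dOb %*% t(Vb)
      dV[rows, cols] <- t(A) %*% dOb
      dZ <- A * (dA - rowSums(dA * A))
      dQ[rows, cols] <- dZ %*% cc$K[rows, cols, drop = FALSE] / scale
      dK[rows, cols] <- t(dZ) %*% cc$Q[rows, cols, drop = FALSE] / scale
    }
  }
  g$at_Wq <- t(cc$Xp) %*% dQ; g$at_bq <- colSums(dQ)
  g$at_Wk <- t(cc$Xp) %*% dK; g$at_bk <- colSums(dK)
  g$at_Wv <- t(cc$Xp) %*% dV; g$at_bv <- colSums(dV)
  g
}

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  decay_nm <- grepl("_W", names(params))   # weights only, not biases/LN
  for (nm in names(params)) {
    gn <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gn
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gn * gn
    step <- lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
    if (weight_decay > 0 && decay_nm[match(nm, names(params))]) {
      step <- step + lr * weight_decay * params[[nm]]
    }
    params[[nm]] <- params[[nm]] - step
  }
  list(params = params, state = state)
}

# rank-based AUROC used for per-epoch model selection (fast; ties averaged)
auroc_rank <- function(labels, scores) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Training loop: mini-batch Adam on BCE, per-epoch validation, returns the
# checkpoint with the best validation AUROC (falls back to lowest val loss
# when the validation set is single-class, and to the final epoch when no
# validation data is supplied).
nn_train <- function(Xtr, ytr, Xval, yval, cfg, L, verbose = FALSE) {
  n <- length(ytr)
  params <- nn_init(cfg)
  state <- adam_init(params)
  hist <- vector("list", cfg$epochs)
  best <- list(params = params, crit = -Inf, epoch = 0L)
  has_val <- !is.null(Xval) && length(yval) > 0
  # bias-corrected exponential moving average of the weights; validation and
  # the returned checkpoint use the averaged weights, which damps
  # step-to-step noise of small-batch Adam
  ema_decay <- cfg$ema_decay %||% 0.99
  ema <- if (ema_decay > 0) lapply(params, function(x) x * 0) else NULL
  ema_steps <- 0L

  row_block <- function(idx) {
    rep((idx - 1L) * L, each = L) + rep(seq_len(L), length(idx))
  }

  # linear learning-rate warmup over the first warmup_epochs: the post-LN
  # encoder layout is unstable under Adam at full step size from a cold start
  n_batch_per_ep <- length(seq(1, n, by = cfg$batch_size))
  warmup_steps <- max(1, (cfg$warmup_epochs %||% 0) * n_batch_per_ep)
  step_no <- 0L

  for (ep in seq_len(cfg$epochs)) {
    perm <- sample.int(n)
    starts <- seq(1, n, by = cfg$batch_size)
    ep_loss <- 0
    for (st in starts) {
      idx <- perm[st:min(st + cfg$batch_size - 1, n)]
      fwd <- nn_forward(params, Xtr[row_block(idx), , drop = FALSE],
                        cfg, L, train = TRUE)
      loss <- bce_loss(fwd$prob, ytr[idx])
      if (!is.finite(loss)) {
        stop2(sprintf("non-finite loss at epoch %d (batch starting at %d)", ep, st))
      }
      ep_loss <- ep_loss + loss * length(idx)
      grads <- nn_backward(params, fwd, ytr[idx], cfg)
      step_no <- step_no + 1L
      lr_t <- cfg$lr * min(1, step_no / warmup_steps)
      upd <- adam_step(params, grads, state, lr_t,
                       weight_decay = cfg$weight_decay %||% 0)
      params <- upd$params; state <- upd$state
      if (!is.null(ema)) {
        ema_steps <- ema_steps + 1L
        for (nm in names(params)) {
          ema[[nm]] <- ema_decay * ema[[nm]] + (1 - ema_decay) * params[[nm]]
        }
      }
    }
    ep_loss <- ep_loss / n
    eval_params <- if (is.null(ema)) params else
      lapply(ema, function(x) x / (1 - ema_decay^ema_steps))

    val_loss <- NA_real_; val_auroc <- NA_real_
    if (has_val) {
      vf <- nn_forward(eval_params, Xval, cfg, L, train = FALSE, keep_cache = FALSE)
      val_loss <- bce_loss(vf$prob, yval)
      val_auroc <- auroc_rank(yval, vf$prob)
      crit <- if (is.na(val_auroc)) -val_loss else val_auroc
      if (crit > best$crit) {
        best <- list(params = eval_params, crit = crit, epoch = ep)
      }
    }
    hist[[ep]] <- data.frame(epoch = ep, train_loss = ep_loss,
                             val_loss = val_loss, val_auroc = val_auroc)
    if (verbose) {
      message(sprintf("epoch %3d  train_loss %.4f  val_loss %s  val_auroc %s",
                      ep, ep_loss,
                      ifelse(is.na(val_loss), "-", sprintf("%.4f", val_loss)),
                      ifelse(is.na(val_auroc), "-", sprintf("%.4f", val_auroc))))
    }
  }

  history <- if (cfg$epochs > 0) do.call(rbind, hist) else
    data.frame(epoch = integer(0), train_loss = numeric(0),
               val_loss = numeric(0), val_auroc = numeric(0))
  final <- if (has_val && best$epoch > 0) best$params else if (is.null(ema)) {
    params
  } else if (ema_steps > 0) {
    lapply(ema, function(x) x / (1 - ema_decay^ema_steps))
  } else {
    params
  }
  list(params = final, history = history,
       best_epoch = if (has_val) best$epoch else cfg$epochs)
}
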