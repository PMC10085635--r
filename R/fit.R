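#' Fit a gene-pair transformer classifier
#'
#' Trains the motif-sequence transformer on labelled gene-pair samples.
#' Each pair is encoded as a gene expression motif (see [encode_pair()]):
#' the two genes' expression vectors are cut into `L = ceiling(k/s)` aligned
#' windows of `s` cells and concatenated position-wise into a sequence of
#' `2s`-wide sub-vectors. The network is a sinusoidal positional encoding,
#' one transformer encoder layer (multi-head scaled dot-product
#' self-attention and a ReLU feed-forward network, each with residual
#' connection and layer normalization), average pooling over positions, and
#' a two-layer ReLU classification head with sigmoid output. Weights are
#' trained by backpropagation of the binary cross-entropy loss with the
#' Adam optimizer; when validation samples are supplied, the checkpoint
#' with the best validation AUROC is returned.
#'
#' @param samples Training `pair_samples` (see [build_gene_gene_samples()],
#'   [build_interaction_samples()], [build_causality_samples()]).
#' @param expr An [expression_matrix()] resolving every sample gene.
#' @param val_samples Optional validation `pair_samples` used for per-epoch
#'   monitoring and best-checkpoint selection.
#' @param window Cells per sub-vector half (`s`). Clamped to the number of
#'   cells with a message when larger.
#' @param n_heads Number of attention heads (default 2). Must divide
#'   `d_model = 2 * window`.
#' @param d_ff Feed-forward hidden width; default `2 * d_model`.
#' @param head_hidden Classification-head hidden width; default `window`.
#' @param dropout Dropout probability in `[0, 1)`, applied after the
#'   attention block and after the FFN during training.
#' @param weight_decay Decoupled L2 penalty applied to weight matrices
#'   (not biases or layer-norm parameters) at each Adam step.
#' @param lr,epochs,batch_size Adam learning rate, epoch budget, mini-batch
#'   size.
#' @param warmup_epochs Epochs over which the learning rate ramps linearly
#'   from 0 to `lr`; stabilizes the post-layer-norm encoder under Adam.
#' @param ema_decay Per-step decay of the exponential moving average of the
#'   weights; validation and the returned checkpoint use the averaged
#'   weights. `0` disables averaging.
#' @param positional Add the sinusoidal positional encoding (disable to
#'   ablate position information).
#' @param pe_divisor Exponent divisor of the positional encoding:
#'   `"d_model"` (standard) or `"window"` (literal published formulation).
#' @param attn_scale Attention score scale: `"sqrt_d_head"` (standard) or
#'   `"window"` (literal published formulation).
#' @param post_ffn_ln Apply a second residual + layer normalization after
#'   the FFN (default). `FALSE` reproduces the literal formulation in which
#'   the encoder output is the raw FFN output.
#' @param log1p Apply `log1p` to expression values before encoding.
#' @param n_restarts Number of independent initializations trained; the
#'   one with the best validation AUROC is kept (all restarts share the
#'   encoded data, so only optimization is repeated). With no validation
#'   samples the first restart is returned.
#' @param seed Integer seed fixing initialization, shuffling and dropout.
#' @param verbose Print per-epoch losses.
#' @return An object of class `gemgrn`: a list with elements `params`
#'   (weights), `config`, `history` (per-epoch data.frame), `best_epoch`
#'   and `call`. Use [predict.gemgrn()] to score new pairs.
#' @seealso [split_gene_gene()], [make_tf_folds()], [gemgrn_crossval()],
#'   [roc_pr_curves()], [subvector_probabilities()]
#' @export
gemgrn <- function(samples, expr, val_samples = NULL,
                   window = 100, n_heads = 2, d_ff = NULL,
                   head_hidden = NULL, dropout = 0.5, weight_decay = 0,
                   lr = 1e-3, epochs = 50, batch_size = 32,
                   warmup_epochs = 5, ema_decay = 0.99, positional = TRUE,
                   pe_divisor = c("d_model", "window"),
                   attn_scale = c("sqrt_d_head", "window"),
                   post_ffn_ln = TRUE, log1p = TRUE,
                   n_restarts = 1, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(expr, "expression_matrix"))
  pe_divisor <- match.arg(pe_divisor)
  attn_scale <- match.arg(attn_scale)
  k <- ncol(expr$values)
  if (window > k) {
    message(sprintf("window %d exceeds %d cells; clamped to %d", window, k, k))
    window <- k
  }
  cfg <- gemgrn_config(window = window, n_heads = n_heads, d_ff = d_ff,
                       head_hidden = head_hidden, dropout = dropout,
                       weight_decay = weight_decay,
                       lr = lr, epochs = epochs, batch_size = batch_size,
                       warmup_epochs = warmup_epochs, ema_decay = ema_decay,
                       positional = positional, pe_divisor = pe_divisor,
                       attn_scale = attn_scale, post_ffn_ln = post_ffn_ln,
                       log1p = log1p, seed = seed)
  Xtr <- encode_pairs(samples, expr, cfg$window, log1p = cfg$log1p)
  L <- attr(Xtr, "L")
  Xval <- NULL; yval <- NULL
  if (!is.null(val_samples) && nrow(val_samples) > 0) {
    Xval <- encode_pairs(val_samples, expr, cfg$window, log1p = cfg$log1p)
    yval <- val_samples$label
  }
  runs <- lapply(seq_len(max(1, n_restarts)), function(r) {
    with_seed(seed + (r - 1L) * 1009L,
              nn_train(Xtr, samples$label, Xval, yval, cfg, L,
                       verbose = verbose))
  })
  crit <- vapply(runs, function(r) {
    va <- r$history$val_auroc
    if (length(va) == 0 || all(is.na(va))) -Inf else max(va, na.rm = TRUE)
  }, numeric(1))
  res <- if (all(!is.finite(crit))) runs[[1]] else runs[[which.max(crit)]]
  structure(list(params = res$params, config = cfg, L = L, k = k,
                 history = res$history, best_epoch = res$best_epoch,
                 restart = which.max(crit),
                 n_train = nrow(samples), task = samples$task[1] %||% NA,
                 call = match.call()),
            class = "gemgrn")
}

#' Model hyperparameter container
#'
#' Validates and assembles the hyperparameters of the gene-pair
#' transformer. `d_model = 2 * window`, which must be divisible by
#' `n_heads`; exactly one encoder layer is used.
#'
#' @inheritParams gemgrn
#' @return A list of class `gemgrn_config`.
#' @export
gemgrn_config <- function(window = 100, n_heads = 2, d_ff = NULL,
                          head_hidden = NULL, dropout = 0.5,
                          weight_decay = 0, lr = 1e-3,
                          epochs = 50, batch_size = 32, warmup_epochs = 5,
                          ema_decay = 0.99,
                          positional = TRUE, pe_divisor = "d_model",
                          attn_scale = "sqrt_d_head", post_ffn_ln = TRUE,
                          log1p = TRUE, seed = 1L) {
  if (window < 1 || window != floor(window)) stop2("`window` must be a positive integer")
  d_model <- 2L * as.integer(window)
  if (d_model %% n_heads != 0) {
    stop2(sprintf("d_model (%d) not divisible by n_heads (%d)", d_model, n_heads))
  }
  if (dropout < 0 || dropout >= 1) stop2("`dropout` must be in [0, 1)")
  if (epochs < 0) stop2("`epochs` must be >= 0")
  if (batch_size < 1) stop2("`batch_size` must be >= 1")
  structure(list(window = as.integer(window), d_model = d_model,
                 n_heads = as.integer(n_heads),
                 d_head = d_model %/% as.integer(n_heads),
                 d_ff = as.integer(d_ff %||% (2L * d_model)),
                 head_hidden = as.integer(head_hidden %||% window),
                 dropout = dropout, weight_decay = weight_decay, lr = lr,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 warmup_epochs = as.integer(warmup_epochs),
                 ema_decay = ema_decay,
                 n_encoder_layers = 1L,
                 positional = isTRUE(positional),
                 pe_divisor = pe_divisor, attn_scale = attn_scale,
                 post_ffn_ln = isTRUE(post_ffn_ln),
                 log1p = isTRUE(log1p), seed = as.integer(seed)),
            class = "gemgrn_config")
}

#' Predict interaction probabilities for gene pairs
#'
#' @param object A fitted [gemgrn()] model.
#' @param samples `pair_samples` (labels, if present, are ignored).
#' @param expr An [expression_matrix()]; must have at least `window` cells.
#' @param type `"prob"` for sigmoid probabilities, `"link"` for logits,
#'   `"class"` for 0/1 at `threshold`.
#' @param threshold Classification threshold for `type = "class"`.
#' @param ... Unused.
#' @return Numeric (or integer for `"class"`) vector, one value per sample
#'   row.
#' @export
predict.gemgrn <- function(object, samples, expr,
                           type = c("prob", "link", "class"),
                           threshold = 0.5, ...) {
  type <- match.arg(type)
  cfg <- object$config
  if (cfg$window > ncol(expr$values)) {
    stop2(sprintf("model window (%d) exceeds the %d cells of the new matrix",
                  cfg$window, ncol(expr$values)))
  }
  X <- encode_pairs(samples, expr, cfg$window, log1p = cfg$log1p)
  fwd <- nn_forward(object$params, X, cfg, attr(X, "L"),
                    train = FALSE, keep_cache = FALSE)
  switch(type,
         prob = fwd$prob,
         link = fwd$logit,
         class = as.integer(fwd$prob >= threshold))
}

#' Forward trace of a single gene pair
#'
#' Runs one encoded pair through the fitted network in evaluation mode and
#' returns every intermediate activation: the positionally encoded input,
#' the per-head attention weight matrices, the post-attention and
#' post-encoder representations, the pooled vector and the probability.
#'
#' @param object A fitted [gemgrn()] model.
#' @param gem A [encode_pair()] motif whose window matches the model (raw
#'   expression must already be on the model's scale, i.e. `log1p`-ed when
#'   the model was fitted with `log1p = TRUE`).
#' @return A list of class `gemgrn_trace` with elements `x_posi`,
#'   `attn_weights` (list of `n_heads` `L x L` matrices), `x_attention`,
#'   `x_encoder`, `x_average`, `prob`.
#' @export
gemgrn_trace <- function(object, gem) {
  cfg <- object$config
  if (attr(gem, "window") != cfg$window) {
    stop2(sprintf("motif window (%d) does not match model window (%d)",
                  attr(gem, "window"), cfg$window))
  }
  X <- unclass(gem)
  attributes(X) <- list(dim = dim(X))
  L <- nrow(X)
  fwd <- nn_forward(object$params, X, cfg, L, train = FALSE, keep_cache = FALSE)
  structure(list(x_posi = fwd$Xp,
                 attn_weights = fwd$attn,
                 x_attention = fwd$x_att,
                 x_encoder = fwd$x_enc,
                 x_average = drop(fwd$pooled),
                 prob = fwd$prob),
            class = "gemgrn_trace")
}

#' @export
print.gemgrn <- function(x, ...) {
  cfg <- x$config
  cat("gemgrn: gene-pair transformer classifier\n")
  cat(sprintf("  task: %s, trained on %d samples (%d cells, window %d, L = %d)\n",
              x$task, x$n_train, x$k, cfg$window, x$L))
  cat(sprintf("  d_model %d | %d head(s) | d_ff %d | dropout %.2f | lr %g\n",
              cfg$d_model, cfg$n_heads, cfg$d_ff, cfg$dropout, cfg$lr))
  if (nrow(x$history) > 0) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  %d epoch(s); best checkpoint at epoch %d", cfg$epochs, x$best_epoch))
    if (!is.na(last$val_auroc)) {
      cat(sprintf(" (val AUROC %.3f)", max(x$history$val_auroc, na.rm = TRUE)))
    }
    cat("\n")
  } else {
    cat("  untrained (epochs = 0)\n")
  }
  invisible(x)
}

#' @export
summary.gemgrn <- function(object, ...) {
  n_par <- sum(vapply(object$params, length, integer(1)))
  structure(list(model = object, n_parameters = n_par),
            class = "summary.gemgrn")
}

#' @export
print.summary.gemgrn <- function(x, ...) {
  print(x$model)
  cat(sprintf("  %d trainable parameters\n", x$n_parameters))
  h <- x$model$history
  if (nrow(h) > 0) {
    cat("  training history (last 5 epochs):\n")
    print(utils::tail(h, 5), row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.gemgrn <- function(object, ...) object$params

#' Plot training history
#'
#' Training/validation loss per epoch (left axis) and validation AUROC
#' (right axis) of a fitted model.
#'
#' @param x A fitted [gemgrn()] model.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.gemgrn <- function(x, ...) {
  h <- x$history
  if (nrow(h) == 0) stop2("model has no training history")
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "firebrick"),
                    xlab = "epoch", ylab = "binary cross-entropy", ...)
  if (any(!is.na(h$val_auroc))) {
    graphics::par(new = TRUE)
    graphics::plot(h$epoch, h$val_auroc, type = "l", col = "steelblue",
                   axes = FALSE, xlab = "", ylab = "", ylim = c(0, 1))
    graphics::axis(4)
    graphics::mtext("validation AUROC", side = 4, line = 2, col = "steelblue")
  }
  graphics::legend("topright", c("train loss", "val loss", "val AUROC"),
                   col = c("black", "firebrick", "steelblue"), lty = 1,
                   bty = "n", cex = 0.8)
  invisible(x)
}
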