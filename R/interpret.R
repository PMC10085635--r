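#' Per-sub-vector classification probabilities
#'
#' The interpretability probe: the pair is run through the encoder and the
#' trained classification head is applied to each of the `L` position-wise
#' encoder outputs individually, bypassing the average pooling. The
#' resulting per-position probabilities show which window of cells drives
#' the pair's classification; the position with the maximal probability is
#' the pair's most important sub-vector (ties broken toward the earliest
#' position).
#'
#' @param object A fitted [gemgrn()] model (an untrained model yields a
#'   meaningless profile; a warning is raised when `epochs = 0`).
#' @param samples A single-row or multi-row `pair_samples` data.frame.
#' @param expr An [expression_matrix()].
#' @return An `importance_profile` data.frame with one row per
#'   (sample, position): columns `gene_a`, `gene_b`, `position` (1-based),
#'   `prob`, and attribute `argmax` (integer vector, one per sample).
#' @export
subvector_probabilities <- function(object, samples, expr) {
  cfg <- object$config
  if (nrow(object$history) == 0) {
    warn2("model is untrained (epochs = 0); importance profile is meaningless")
  }
  X <- encode_pairs(samples, expr, cfg$window, log1p = cfg$log1p)
  L <- attr(X, "L")
  n <- attr(X, "n")
  fwd <- nn_forward(object$params, X, cfg, L, train = FALSE, keep_cache = FALSE)
  # head applied to every position-wise encoder output row; the argmax is
  # taken over logits (same ordering as probabilities, but immune to
  # sigmoid saturation at probabilities numerically equal to 1)
  p <- object$params
  hh <- pmax(addb(fwd$x_enc %*% p$hd_W1, p$hd_b1), 0)
  logits <- drop(hh %*% p$hd_W2) + p$hd_b2
  probs <- stats::plogis(logits)
  prof <- data.frame(gene_a = rep(samples$gene_a, each = L),
                     gene_b = rep(samples$gene_b, each = L),
                     position = rep(seq_len(L), n),
                     prob = probs,
                     logit = logits,
                     stringsAsFactors = FALSE)
  am <- vapply(seq_len(n), function(i) {
    which.max(logits[((i - 1) * L + 1):(i * L)])  # which.max = earliest tie
  }, integer(1))
  structure(prof, class = c("importance_profile", "data.frame"),
            argmax = am, L = L)
}

#' Most-important-sub-vector tally for one regulator
#'
#' Computes the per-position importance profile of every sample in a
#' regulator's block and tallies which position is most important, as a
#' fraction of samples. On data where the regulator-target synchrony is
#' confined to a known span of cells, the modal position identifies the
#' sub-vector covering that span.
#'
#' @param object A fitted [gemgrn()] model.
#' @param samples `pair_samples` for one `tf_group` (or any sample set of
#'   interest, e.g. its true positives).
#' @param expr An [expression_matrix()].
#' @return data.frame with columns `position` (1..L), `count` and
#'   `fraction` (sums to 1).
#' @export
tf_importance_tally <- function(object, samples, expr) {
  if (nrow(samples) < 1) stop2("need at least one sample")
  prof <- subvector_probabilities(object, samples, expr)
  am <- attr(prof, "argmax")
  L <- attr(prof, "L")
  cnt <- tabulate(am, nbins = L)
  data.frame(position = seq_len(L), count = cnt,
             fraction = cnt / sum(cnt))
}

#' Export an importance profile or tally as TSV
#' @param x An `importance_profile` or tally data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_importance <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
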