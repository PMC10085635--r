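#' Gene-pair training samples
#'
#' All three sample constructors return a `pair_samples` data.frame with
#' columns `gene_a` (regulator slot), `gene_b` (target slot), `label`
#' (0/1), `task` and `tf_group` (the transcription factor whose block of
#' samples this pair belongs to; equals `gene_a` except for the reversed
#' member of a causality pair, which stays grouped under its regulator).
#'
#' @name pair_samples
NULL

new_pair_samples <- function(gene_a, gene_b, label, task, tf_group,
                             n_dropped_edges = 0L) {
  df <- data.frame(gene_a = gene_a, gene_b = gene_b,
                   label = as.integer(label), task = task,
                   tf_group = tf_group, stringsAsFactors = FALSE)
  structure(df, class = c("pair_samples", "data.frame"),
            n_dropped_edges = n_dropped_edges)
}

#' Build unbalanced regulator-anchored gene-gene samples
#'
#' For network reconstruction: positives are all known (TF, target) edges
#' resolvable in the matrix; negatives are every other (TF, gene) pair with
#' the same TFs, excluding self-pairs. The natural class imbalance is kept.
#' Edges whose genes are absent from the matrix (e.g. removed by HVG
#' selection) are dropped; the count is in attribute `n_dropped_edges`.
#'
#' @param net An [edge_list()].
#' @param m An [expression_matrix()].
#' @return A `pair_samples` data.frame, `task = "gene_gene"`.
#' @export
build_gene_gene_samples <- function(net, m) {
  if (nrow(net) == 0) stop2("edge list is empty")
  res <- resolve_edges(net, m)
  if (length(res$regulator) == 0) {
    stop2("no edge of the network resolves in the expression matrix")
  }
  tfs <- sort(unique(res$regulator))
  ids <- gene_ids(m)
  edge_key <- paste(res$regulator, res$target, sep = "\r")
  ga <- gb <- character(0)
  lab <- integer(0)
  for (tf in tfs) {
    cand <- setdiff(ids, tf)
    key <- paste(tf, cand, sep = "\r")
    pos <- key %in% edge_key
    ga <- c(ga, rep(tf, length(cand)))
    gb <- c(gb, cand)
    lab <- c(lab, as.integer(pos))
  }
  new_pair_samples(ga, gb, lab, "gene_gene", ga,
                   n_dropped_edges = res$n_dropped)
}

#' Build balanced interaction samples
#'
#' For each known edge (a, b) (label 1) one negative (a, c) (label 0) is
#' drawn, with c sampled uniformly without replacement per TF from the
#' genes a is not known to regulate. The result is exactly class-balanced
#' per TF; if a TF regulates so many genes that not enough non-targets
#' remain, its unmatched positives are dropped with a warning.
#'
#' @param net An [edge_list()].
#' @param m An [expression_matrix()].
#' @param seed Integer seed making the negative draw reproducible.
#' @return A `pair_samples` data.frame, `task = "interaction"`.
#' @export
build_interaction_samples <- function(net, m, seed = 1L) {
  res <- resolve_edges(net, m)
  if (length(res$regulator) == 0) stop2("no resolvable positive edges")
  ids <- gene_ids(m)
  with_seed(seed, {
    ga <- gb <- character(0)
    lab <- integer(0)
    for (tf in sort(unique(res$regulator))) {
      targets <- res$target[res$regulator == tf]
      pool <- setdiff(ids, c(targets, tf))
      n_pos <- length(targets)
      if (length(pool) < n_pos) {
        warn2(sprintf("TF '%s': only %d non-targets for %d positives; %d positive(s) dropped",
                      tf, length(pool), n_pos, n_pos - length(pool)))
        targets <- targets[seq_len(length(pool))]
        n_pos <- length(targets)
      }
      negs <- sample(pool, n_pos, replace = FALSE)
      ga <- c(ga, rep(tf, 2 * n_pos))
      gb <- c(gb, targets, negs)
      lab <- c(lab, rep(1L, n_pos), rep(0L, n_pos))
    }
    new_pair_samples(ga, gb, lab, "interaction", ga,
                     n_dropped_edges = res$n_dropped)
  })
}

#' Build balanced causality (direction) samples
#'
#' For each known edge (a, b), the ordered pair (a, b) gets label 1 and the
#' reversed pair (b, a) gets label 0; both carry `tf_group = a` so that a
#' regulator's block stays together under TF-held-out cross-validation.
#'
#' @param net An [edge_list()].
#' @param m An [expression_matrix()].
#' @param drop_bidirectional If the network contains a pair present in both
#'   directions the direction label is ambiguous; with this flag both
#'   directions are excluded (and counted in attribute
#'   `n_dropped_bidirectional`), otherwise an error is raised.
#' @return A `pair_samples` data.frame, `task = "causality"`.
#' @export
build_causality_samples <- function(net, m, drop_bidirectional = FALSE) {
  res <- resolve_edges(net, m)
  if (length(res$regulator) == 0) stop2("no resolvable positive edges")
  key <- paste(res$regulator, res$target, sep = "\r")
  rev_key <- paste(res$target, res$regulator, sep = "\r")
  bidir <- key %in% rev_key
  n_bidir <- sum(bidir)
  if (n_bidir > 0) {
    if (!drop_bidirectional) {
      stop2(sprintf("%d edge(s) present in both directions; set drop_bidirectional = TRUE to exclude them",
                    n_bidir))
    }
    res$regulator <- res$regulator[!bidir]
    res$target <- res$target[!bidir]
  }
  a <- res$regulator; b <- res$target
  out <- new_pair_samples(c(a, b), c(b, a),
                          c(rep(1L, length(a)), rep(0L, length(a))),
                          "causality", c(a, a),
                          n_dropped_edges = res$n_dropped)
  attr(out, "n_dropped_bidirectional") <- n_bidir
  out
}

#' Write / read pair samples as TSV
#'
#' @param samples A `pair_samples` data.frame.
#' @param path File path.
#' @return `path` (write) or a `pair_samples` data.frame (read).
#' @export
write_samples <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_samples
#' @export
read_samples <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  new_pair_samples(df$gene_a, df$gene_b, df$label, df$task, df$tf_group)
}
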