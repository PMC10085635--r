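#' Specification for a synthetic single-cell dataset
#'
#' Describes an scRNA-seq-like genes-by-cells matrix with planted
#' regulatory structure: each simulated transcription factor (TF) has a set
#' of target genes whose expression tracks the TF over one or more known
#' contiguous spans of cells (cells are taken as ordered, as along a
#' pseudo-time axis), plus unrelated noise genes. Expression is log-normal
#' (a smoothed latent profile exponentiated), with multiplicative noise and
#' i.i.d. dropout zeros -- the minimal model reproducing the sparse, bursty
#' look of real single-cell data without library-size or batch structure.
#'
#' @param n_tfs Number of planted regulators.
#' @param targets_per_tf Targets per regulator.
#' @param n_noise_genes Unregulated genes.
#' @param k_cells Number of cells (columns, in pseudo-temporal order).
#' @param sync_spans Per-TF list of 0-based half-open `c(start, end)` cell
#'   intervals inside which targets track their TF. Default: one span per
#'   TF of half the cells at a random offset.
#' @param coupling Mixing weight in `[0, 1]`: inside a span a target's
#'   latent log-expression is `coupling * TF + (1 - coupling) *
#'   independent`; outside it is fully independent.
#' @param dropout_rate Probability that any value is zeroed (technical
#'   dropout).
#' @param noise_sd SD of multiplicative log-normal noise.
#' @param base_profile Latent profile family: `"random_walk"` (smoothed),
#'   `"pulse"` (on/off blocks) or `"constant"`.
#' @param tf_scale Multiplicative expression scale of TFs relative to other
#'   genes (> 1 makes regulators distinguishable from targets by level,
#'   which is what makes direction-of-regulation learnable).
#' @param seed Integer seed; the dataset is fully reproducible from the
#'   spec.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_tfs = 5, targets_per_tf = 20,
                            n_noise_genes = 100, k_cells = 500,
                            sync_spans = NULL, coupling = 0.8,
                            dropout_rate = 0.3, noise_sd = 0.2,
                            base_profile = c("random_walk", "pulse", "constant"),
                            tf_scale = 1, seed = 1L) {
  base_profile <- match.arg(base_profile)
  if (coupling < 0 || coupling > 1) stop2("`coupling` must be in [0, 1]")
  if (dropout_rate < 0 || dropout_rate > 1) stop2("`dropout_rate` must be in [0, 1]")
  if (n_tfs < 1 || targets_per_tf < 1 || k_cells < 2) {
    stop2("need at least 1 TF, 1 target per TF and 2 cells")
  }
  if (!is.null(sync_spans)) {
    if (length(sync_spans) != n_tfs) stop2("`sync_spans` needs one entry per TF")
    for (sp in sync_spans) {
      sp <- if (is.list(sp)) sp else list(sp)
      for (iv in sp) {
        if (length(iv) != 2 || iv[1] < 0 || iv[2] > k_cells || iv[1] >= iv[2]) {
          stop2("each span must be a 0-based half-open [start, end) within the cell axis")
        }
      }
    }
  }
  structure(list(n_tfs = n_tfs, targets_per_tf = targets_per_tf,
                 n_noise_genes = n_noise_genes, k_cells = k_cells,
                 sync_spans = sync_spans, coupling = coupling,
                 dropout_rate = dropout_rate, noise_sd = noise_sd,
                 base_profile = base_profile, tf_scale = tf_scale,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

# latent log-scale profile over k cells, mean-centred
latent_profile <- function(kind, k) {
  switch(kind,
         random_walk = {
           # mean-reverting (stationary) walk: independent genes must stay
           # uncorrelated, which a pure random walk violates (spurious
           # correlation between nonstationary series)
           rho <- 0.95; sigma <- 1.2
           eps <- stats::rnorm(k, 0, sigma * sqrt(1 - rho^2))
           z <- numeric(k)
           z[1] <- stats::rnorm(1, 0, sigma)
           for (t in 2:k) z[t] <- rho * z[t - 1] + eps[t]
           zs <- stats::filter(z, rep(1 / 5, 5), sides = 2)
           z[!is.na(zs)] <- zs[!is.na(zs)]
           z - mean(z)
         },
         pulse = {
           n_blocks <- max(2, k %/% 50)
           lev <- sample(c(-0.8, 0.8), n_blocks, replace = TRUE)
           z <- rep(lev, each = ceiling(k / n_blocks))[seq_len(k)]
           z - mean(z)
         },
         constant = numeric(k))
}

#' Simulate a single-cell expression matrix with a planted network
#'
#' Draws every gene's latent log-expression from the spec's base profile;
#' inside each TF's synchrony spans its targets' latents are mixed with the
#' TF's latent at weight `coupling`. Values are exponentiated, jittered
#' with multiplicative log-normal noise, and zeroed i.i.d. at the dropout
#' rate. The planted (TF, target) edges and the span metadata are returned
#' alongside the matrix so downstream tests can check recovery against
#' ground truth.
#'
#' @param spec A [simulation_spec()].
#' @return List with `expr` (an [expression_matrix()], cells flagged as
#'   pseudo-time ordered), `net` (an [edge_list()] of planted edges) and
#'   `spans` (data.frame `tf`, `start`, `end`, 0-based half-open).
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  k <- spec$k_cells
  with_seed(spec$seed, {
    spans <- spec$sync_spans
    if (is.null(spans)) {
      len <- max(1, floor(k / 2))
      spans <- lapply(seq_len(spec$n_tfs), function(i) {
        st <- sample.int(k - len + 1, 1) - 1
        c(st, st + len)
      })
    }
    spans <- lapply(spans, function(sp) if (is.list(sp)) sp else list(sp))

    tf_ids <- sprintf("tf%02d", seq_len(spec$n_tfs))
    tg_ids <- as.vector(t(outer(seq_len(spec$n_tfs), seq_len(spec$targets_per_tf),
                                function(i, j) sprintf("tf%02d_tg%02d", i, j))))
    nz_ids <- if (spec$n_noise_genes > 0) {
      sprintf("noise%03d", seq_len(spec$n_noise_genes))
    } else character(0)

    gene_log <- function(scale = 1) {
      stats::rnorm(1, 1, 0.3) + log(scale) + latent_profile(spec$base_profile, k)
    }

    log_tf <- lapply(seq_len(spec$n_tfs), function(i) gene_log(spec$tf_scale))
    rows <- vector("list", 0)
    reg <- tgt <- character(0)
    for (i in seq_len(spec$n_tfs)) {
      rows[[tf_ids[i]]] <- log_tf[[i]]
    }
    for (i in seq_len(spec$n_tfs)) {
      for (j in seq_len(spec$targets_per_tf)) {
        own <- gene_log(1)
        lg <- own
        for (iv in spans[[i]]) {
          cells <- (iv[1] + 1):iv[2]
          lg[cells] <- spec$coupling * log_tf[[i]][cells] +
            (1 - spec$coupling) * own[cells]
        }
        id <- sprintf("tf%02d_tg%02d", i, j)
        rows[[id]] <- lg
        reg <- c(reg, tf_ids[i]); tgt <- c(tgt, id)
      }
    }
    for (id in nz_ids) rows[[id]] <- gene_log(1)

    lmat <- do.call(rbind, rows)
    vals <- exp(lmat + matrix(stats::rnorm(length(lmat), 0, spec$noise_sd),
                              nrow(lmat)))
    if (spec$dropout_rate > 0) {
      vals[matrix(stats::runif(length(vals)) < spec$dropout_rate,
                  nrow(vals))] <- 0
    }
    rownames(vals) <- names(rows)
    colnames(vals) <- sprintf("cell%04d", seq_len(k))

    span_df <- do.call(rbind, lapply(seq_len(spec$n_tfs), function(i) {
      do.call(rbind, lapply(spans[[i]], function(iv) {
        data.frame(tf = tf_ids[i], start = iv[1], end = iv[2],
                   stringsAsFactors = FALSE)
      }))
    }))

    list(expr = expression_matrix(vals, cell_order_kind = "pseudotime"),
         net = edge_list(reg, tgt),
         spans = span_df)
  })
}

#' Build a ready-to-train synthetic fixture for one task
#'
#' Composes [simulate_dataset()] with the sample constructors and the
#' stratified 3:1:1 split, yielding everything needed to fit and evaluate a
#' model on planted ground truth. For the causality task the TF expression
#' scale is raised to 3 when the spec leaves it at 1, so that regulator and
#' target profiles are distinguishable by level and direction is learnable.
#'
#' @param spec A [simulation_spec()].
#' @param task `"gene_gene"`, `"interaction"` or `"causality"`.
#' @return List with `expr`, `net`, `spans`, `samples`, `split` (a 3:1:1
#'   `split_spec`), and the `spec` actually used.
#' @export
make_task_fixture <- function(spec, task = c("gene_gene", "interaction",
                                             "causality")) {
  task <- match.arg(task)
  if (task == "causality" && spec$tf_scale <= 1) {
    message("raising tf_scale to 3 so regulation direction is learnable")
    spec$tf_scale <- 3
  }
  sim <- simulate_dataset(spec)
  samples <- switch(task,
                    gene_gene = build_gene_gene_samples(sim$net, sim$expr),
                    interaction = build_interaction_samples(sim$net, sim$expr,
                                                            seed = spec$seed),
                    causality = build_causality_samples(sim$net, sim$expr))
  split <- split_gene_gene(samples, seed = spec$seed)
  list(expr = sim$expr, net = sim$net, spans = sim$spans,
       samples = samples, split = split, spec = spec)
}
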