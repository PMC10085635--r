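# small in-code fixtures shared across test files

# 3-gene x 4-cell matrix with known values
tiny_expr <- function() {
  m <- matrix(c(1, 0, 2, 3,
                0, 0, 1, 0,
                5, 4, 3, 2), nrow = 3, byrow = TRUE,
              dimnames = list(c("gA", "gB", "gC"), paste0("c", 1:4)))
  expression_matrix(m)
}

# deterministic random expression matrix with named genes
rand_expr <- function(n_genes, n_cells, seed = 1) {
  gemgrn:::with_seed(seed, {
    m <- matrix(rexp(n_genes * n_cells), n_genes, n_cells,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                sprintf("c%03d", seq_len(n_cells))))
    expression_matrix(m)
  })
}

# tiny model config for fast network-level tests
tiny_cfg <- function(...) {
  gemgrn_config(window = 3, d_ff = 8, head_hidden = 4, dropout = 0,
                epochs = 2, batch_size = 4, warmup_epochs = 0, ...)
}

# a fitted model on a tiny separable problem, memoised
.test_cache <- new.env(parent = emptyenv())
cache_get <- function(key, build) {
  if (is.null(.test_cache[[key]])) .test_cache[[key]] <- build()
  .test_cache[[key]]
}
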