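#' Split an expression vector into contiguous windows
#'
#' Cuts a length-`k` expression vector into `L = ceiling(k / s)` contiguous
#' sub-vectors of `s` cells each. When `s` does not divide `k` the final
#' sub-vector is zero-padded so that no cell is discarded.
#'
#' @param x Numeric expression vector over cells, in temporal/column order.
#' @param s Window size (cells per sub-vector), `s >= 1`.
#' @return An `L x s` numeric matrix; row `m` holds cells
#'   `[(m-1)*s + 1, m*s]` of `x`, zero-padded past `k`.
#' @export
split_subvectors <- function(x, s) {
  if (!is.numeric(s) || length(s) != 1 || s < 1 || s != floor(s)) {
    stop2("window size `s` must be a positive integer")
  }
  k <- length(x)
  if (k < 1) stop2("expression vector is empty")
  L <- ceiling(k / s)
  xp <- c(as.numeric(x), numeric(L * s - k))
  matrix(xp, nrow = L, ncol = s, byrow = TRUE)
}

#' Encode one gene pair as a gene expression motif
#'
#' The gene expression motif (GEM) for an ordered pair (a, b) is the
#' sequence of `L = ceiling(k / s)` sub-vectors of length `2s`, where
#' sub-vector `m` is the concatenation of gene a's and gene b's cells
#' `[(m-1)*s + 1, m*s]`. The ordering of the two halves makes the encoding
#' asymmetric in (a, b), which is what lets a classifier learn regulation
#' direction.
#'
#' @param xa,xb Numeric expression vectors of equal length (same cells in
#'   the same order).
#' @param s Window size.
#' @param pair Optional character vector of the two gene identifiers, kept
#'   as an attribute.
#' @return An object of class `gem`: an `L x 2s` matrix with attributes
#'   `window` and `pair`.
#' @export
encode_pair <- function(xa, xb, s, pair = NULL) {
  if (length(xa) != length(xb)) {
    stop2(sprintf("expression vectors differ in length (%s: %d, %s: %d)",
                  (pair %||% c("gene_a", "gene_b"))[1], length(xa),
                  (pair %||% c("gene_a", "gene_b"))[2], length(xb)))
  }
  seq <- cbind(split_subvectors(xa, s), split_subvectors(xb, s))
  structure(seq, class = c("gem", "matrix"), window = s,
            pair = pair %||% c("gene_a", "gene_b"))
}

# Encode a batch of pair samples into one (n * L) x (2s) matrix with rows
# sample-major: rows (i-1)*L + 1:L hold sample i's motif. Values are
# log1p-transformed first when `log1p = TRUE` (the default used by the
# fitted model).
encode_pairs <- function(samples, m, s, log1p = TRUE) {
  stopifnot(inherits(m, "expression_matrix"))
  vals <- m$values
  if (log1p) vals <- log1p(vals)
  k <- ncol(vals)
  if (s > k) stop2(sprintf("window (%d) exceeds the number of cells (%d)", s, k))
  miss <- setdiff(unique(c(samples$gene_a, samples$gene_b)), rownames(vals))
  if (length(miss) > 0) {
    stop2("sample genes absent from expression matrix: ",
          paste(utils::head(miss, 5), collapse = ", "))
  }
  L <- ceiling(k / s)
  pad <- L * s - k
  A <- vals[samples$gene_a, , drop = FALSE]
  B <- vals[samples$gene_b, , drop = FALSE]
  n <- nrow(samples)
  if (pad > 0) {
    A <- cbind(A, matrix(0, n, pad))
    B <- cbind(B, matrix(0, n, pad))
  }
  # reshape n x (L*s) into (n*L) x s, sample-major rows
  reshape_lr <- function(M) t(matrix(t(M), nrow = s))
  X <- cbind(reshape_lr(A), reshape_lr(B))
  structure(X, L = L, n = n, window = s)
}

#' Sinusoidal positional encoding matrix
#'
#' Position `m` (0-based) and channel `c` (0-based) get
#' `sin(m / 10000^(c / d_pe))` for even `c` and `cos(m / 10000^(c / d_pe))`
#' for odd `c`. The default exponent divisor `d_pe = d` is the standard
#' transformer convention; `d_pe = s` (the window size) reproduces the
#' literal formulation in which the divisor is the window rather than the
#' embedding width.
#'
#' @param L Sequence length (number of sub-vectors), `>= 1`.
#' @param d Embedding width (`2s`), even and `>= 2`.
#' @param d_pe Exponent divisor; defaults to `d`.
#' @return An `L x d` matrix with entries in `[-1, 1]`.
#' @export
positional_encoding <- function(L, d, d_pe = d) {
  if (L < 1) stop2("`L` must be >= 1")
  if (d < 2 || d %% 2 != 0) stop2("`d` must be even and >= 2")
  pos <- seq_len(L) - 1
  chan <- seq_len(d) - 1
  ang <- outer(pos, 10000^(-chan / d_pe))
  even <- chan %% 2 == 0
  ang[, even] <- sin(ang[, even])
  ang[, !even] <- cos(ang[, !even])
  ang
}
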