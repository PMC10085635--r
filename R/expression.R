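#' Construct an expression matrix object
#'
#' A light container for a genes-by-cells matrix of non-negative expression
#' values (counts or normalized values). Row names are gene identifiers,
#' column names are cell identifiers. When cells carry a temporal or
#' pseudo-temporal ordering, `cell_order_kind` records it and the column
#' order is taken to be that ordering.
#'
#' @param values Numeric matrix, genes in rows, cells in columns. Must be
#'   non-negative with unique (case-insensitively) non-empty row names.
#' @param cell_order_kind One of `"unordered"`, `"pseudotime"`,
#'   `"timecourse"`. For the latter two the column order is meaningful and
#'   is consumed as-is by the motif encoder.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values` (the matrix) and `cell_order_kind`.
#' @examples
#' m <- matrix(rpois(12, 5), 3, 4,
#'             dimnames = list(c("g1", "g2", "g3"), paste0("c", 1:4)))
#' em <- expression_matrix(m)
#' dim(em)
#' @export
expression_matrix <- function(values,
                              cell_order_kind = c("unordered", "pseudotime",
                                                  "timecourse")) {
  cell_order_kind <- match.arg(cell_order_kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop2("`values` must be a numeric matrix (genes x cells)")
  }
  if (is.null(rownames(values)) || anyNA(rownames(values)) ||
      any(!nzchar(rownames(values)))) {
    stop2("`values` must have non-empty row names (gene identifiers)")
  }
  if (anyNA(values)) stop2("expression values contain NA")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop2(sprintf("negative expression value at gene '%s', cell %d",
                  rownames(values)[bad[1]], bad[2]))
  }
  ids <- norm_id(rownames(values))
  if (anyDuplicated(ids)) {
    dup <- unique(rownames(values)[ids %in% ids[duplicated(ids)]])
    stop2("duplicated gene identifiers after case normalization: ",
          paste(dup, collapse = ", "))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("cell", seq_len(ncol(values)))
  }
  structure(list(values = values, cell_order_kind = cell_order_kind),
            class = "expression_matrix")
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d cells (%s cell order)\n",
              nrow(x$values), ncol(x$values), x$cell_order_kind))
  invisible(x)
}

#' Gene identifiers of an expression matrix
#' @param m An `expression_matrix`.
#' @return Character vector of gene identifiers in row order.
#' @export
gene_ids <- function(m) rownames(m$values)

#' Read a delimited expression matrix
#'
#' Reads a genes-by-cells (or cells-by-genes) delimited text file. The first
#' column (row, if `genes_in_rows = FALSE`) holds gene identifiers and the
#' header row (column) holds cell identifiers. Cell order in the file is
#' preserved exactly.
#'
#' @param path Path to a delimited text file.
#' @param delimiter Field separator, default `","`.
#' @param genes_in_rows Logical; if `FALSE` the file is transposed on read.
#' @param cell_order_kind Passed to [expression_matrix()].
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, delimiter = ",",
                                   genes_in_rows = TRUE,
                                   cell_order_kind = "unordered") {
  if (!file.exists(path)) stop2("file not found: ", path)
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          row.names = 1, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  vals <- as.matrix(df)
  if (!is.numeric(vals)) {
    bad <- which(is.na(suppressWarnings(array(as.numeric(vals), dim(vals)))) &
                   !is.na(vals), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop2(sprintf("non-numeric value at row '%s', column '%s'",
                    rownames(vals)[bad[1, 1]], colnames(vals)[bad[1, 2]]))
    }
    storage.mode(vals) <- "numeric"
  }
  storage.mode(vals) <- "double"
  if (!genes_in_rows) vals <- t(vals)
  expression_matrix(vals, cell_order_kind = cell_order_kind)
}

#' Write an expression matrix to delimited text
#'
#' Inverse of [read_expression_matrix()]: values survive a write/read round
#' trip exactly.
#'
#' @param m An `expression_matrix`.
#' @param path Output path.
#' @param delimiter Field separator.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path, delimiter = ",") {
  stopifnot(inherits(m, "expression_matrix"))
  # 17 significant digits so doubles survive the text round trip bitwise
  txt <- matrix(formatC(m$values, digits = 17, format = "g"),
                nrow(m$values), dimnames = dimnames(m$values))
  df <- data.frame(gene = rownames(m$values), txt,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Remove genes expressed in too few cells
#'
#' Drops genes with nonzero expression in fewer than
#' `ceiling(min_cell_fraction * n_cells)` cells; a gene expressed in exactly
#' that many cells is retained ("fewer than" is strict).
#'
#' @param m An `expression_matrix`.
#' @param min_cell_fraction Minimum fraction of cells (default 0.1) in which
#'   a gene must be detected.
#' @return A filtered `expression_matrix` with the same cells.
#' @export
filter_genes <- function(m, min_cell_fraction = 0.1) {
  stopifnot(inherits(m, "expression_matrix"))
  if (min_cell_fraction < 0 || min_cell_fraction > 1) {
    stop2("`min_cell_fraction` must be in [0, 1]")
  }
  need <- ceiling(min_cell_fraction * ncol(m$values))
  n_nonzero <- rowSums(m$values > 0)
  keep <- n_nonzero >= need
  if (!any(keep)) stop2("filter removed all genes")
  expression_matrix(m$values[keep, , drop = FALSE],
                    cell_order_kind = m$cell_order_kind)
}

# per-gene dispersion score used for HVG ranking: variance of log1p values
hvg_score <- function(values) apply(log1p(values), 1, stats::var)

#' Select highly variable genes
#'
#' Ranks genes by the variance of their `log1p`-transformed expression and
#' keeps the `n_top` highest-scoring ones. Ties are broken by lexicographic
#' gene identifier so the selection is deterministic. Regulators listed in
#' `force_keep` are retained regardless of rank.
#'
#' @param m An `expression_matrix`.
#' @param n_top Number of genes to keep (e.g. 500 or 1000).
#' @param force_keep Optional character vector of gene identifiers
#'   (case-insensitive) always retained, e.g. known transcription factors.
#' @return An `expression_matrix` restricted to the selected genes, in
#'   original row order.
#' @export
select_hvg <- function(m, n_top, force_keep = NULL) {
  stopifnot(inherits(m, "expression_matrix"))
  if (n_top < 1) stop2("`n_top` must be >= 1")
  ng <- nrow(m$values)
  if (n_top >= ng) {
    if (n_top > ng) warn2(sprintf("n_top (%d) exceeds gene count (%d); returning all genes",
                                  n_top, ng))
    return(m)
  }
  score <- hvg_score(m$values)
  ord <- order(-score, rownames(m$values), method = "radix")
  keep_idx <- ord[seq_len(n_top)]
  if (!is.null(force_keep)) {
    extra <- which(norm_id(rownames(m$values)) %in% norm_id(force_keep))
    keep_idx <- union(keep_idx, extra)
  }
  keep_idx <- sort(keep_idx)
  expression_matrix(m$values[keep_idx, , drop = FALSE],
                    cell_order_kind = m$cell_order_kind)
}
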