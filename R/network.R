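#' Construct a directed edge list
#'
#' Ground-truth regulatory networks are directed (regulator, target) pairs.
#' Duplicated edges are removed (a count is kept in the `n_duplicates`
#' attribute); opposite directions are distinct edges.
#'
#' @param regulator,target Character vectors of equal length.
#' @param allow_self_loops Keep regulator == target edges (default drops
#'   them with an error, since self-pairs are never used as samples).
#' @return An object of class `edge_list`: a data.frame with columns
#'   `regulator` and `target`, attribute `tf_ids` (unique regulators) and
#'   `n_duplicates`.
#' @export
edge_list <- function(regulator, target, allow_self_loops = FALSE) {
  regulator <- as.character(regulator)
  target <- as.character(target)
  stopifnot(length(regulator) == length(target))
  if (!allow_self_loops && any(norm_id(regulator) == norm_id(target))) {
    bad <- regulator[norm_id(regulator) == norm_id(target)]
    stop2("self-loop edges not allowed: ", paste(unique(bad), collapse = ", "))
  }
  key <- paste(norm_id(regulator), norm_id(target), sep = "\r")
  dup <- duplicated(key)
  df <- data.frame(regulator = regulator[!dup], target = target[!dup],
                   stringsAsFactors = FALSE)
  structure(df, class = c("edge_list", "data.frame"),
            tf_ids = unique(df$regulator), n_duplicates = sum(dup))
}

#' Read a two-column edge list
#'
#' Reads a delimited file whose first two columns are (regulator, target);
#' any further columns (e.g. a label) are ignored. Duplicate edges are
#' dropped and reported via a message.
#'
#' @param path Path to the file.
#' @param delimiter Field separator, default `","`.
#' @param header Logical; whether the first line is a header.
#' @return An [edge_list()].
#' @export
read_edge_list <- function(path, delimiter = ",", header = FALSE) {
  if (!file.exists(path)) stop2("file not found: ", path)
  info <- file.info(path)
  if (info$size == 0 || length(readLines(path, n = 1)) == 0) {
    warn2("empty edge list file: ", path)
    return(edge_list(character(0), character(0)))
  }
  df <- utils::read.table(path, sep = delimiter, header = header,
                          stringsAsFactors = FALSE, comment.char = "")
  if (ncol(df) < 2) stop2("edge list needs at least two columns")
  el <- edge_list(df[[1]], df[[2]])
  nd <- attr(el, "n_duplicates")
  if (nd > 0) message(nd, " duplicate edge(s) dropped")
  el
}

#' Write an edge list to delimited text
#' @param net An `edge_list`.
#' @param path Output path.
#' @param delimiter Field separator.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path, delimiter = ",") {
  utils::write.table(net, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Resolve an edge list against an expression matrix, case-insensitively.
# Returns edges rewritten to the matrix's identifiers plus a count of
# dropped (unresolvable) edges.
resolve_edges <- function(net, m) {
  ids <- gene_ids(m)
  lut <- stats::setNames(ids, norm_id(ids))
  reg <- lut[norm_id(net$regulator)]
  tgt <- lut[norm_id(net$target)]
  ok <- !is.na(reg) & !is.na(tgt)
  list(regulator = unname(reg[ok]), target = unname(tgt[ok]),
       n_dropped = sum(!ok))
}
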