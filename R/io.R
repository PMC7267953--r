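#' Read and write the delimited-text formats used throughout the pipeline
#'
#' All on-disk tables are plain TSV. Node identifiers on disk are 0-based
#' ordinal indices (matching the coordinate-table convention); in memory
#' everything is a 1-based R matrix/vector.
#'
#' @param M symmetric numeric matrix
#' @param path file path
#' @name navopt-io
NULL

#' @describeIn navopt-io Write a symmetric matrix with a header row of
#'   0-based node ids.
#' @export
write_matrix_tsv <- function(M, path) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  df <- as.data.frame(M)
  names(df) <- as.character(seq_len(ncol(M)) - 1L)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @describeIn navopt-io Read a symmetric matrix written by
#'   \code{write_matrix_tsv}.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  M <- as.matrix(df)
  dimnames(M) <- NULL
  M
}

#' @describeIn navopt-io Write a coordinate table (node_id, x, y, z).
#' @param coords n x 3 numeric matrix of node positions
#' @export
write_coords_tsv <- function(coords, path) {
  stopifnot(is.matrix(coords), ncol(coords) == 3)
  df <- data.frame(node_id = seq_len(nrow(coords)) - 1L,
                   x = coords[, 1], y = coords[, 2], z = coords[, 3])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @describeIn navopt-io Read a coordinate table; returns an n x 3 matrix
#'   ordered by node_id.
#' @export
read_coords_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  df <- df[order(df$node_id), ]
  as.matrix(df[, c("x", "y", "z")])
}

#' @describeIn navopt-io Write a node-to-network partition table
#'   (node_id, label).
#' @param partition vector of labels, one per node
#' @export
write_partition_tsv <- function(partition, path) {
  df <- data.frame(node_id = seq_along(partition) - 1L,
                   label = as.character(partition))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @describeIn navopt-io Read a partition table; returns a character vector
#'   ordered by node_id.
#' @export
read_partition_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("integer", "character"))
  df$label[order(df$node_id)]
}

#' @describeIn navopt-io Write a ROI x gene expression matrix (rows are
#'   node ids, columns gene ids).
#' @param X numeric matrix, rows = nodes, columns = genes
#' @export
write_expression_tsv <- function(X, path) {
  df <- data.frame(node_id = seq_len(nrow(X)) - 1L, X, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @describeIn navopt-io Read an expression matrix written by
#'   \code{write_expression_tsv}.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  df <- df[order(df$node_id), ]
  X <- as.matrix(df[, setdiff(names(df), "node_id"), drop = FALSE])
  rownames(X) <- NULL
  X
}

#' @describeIn navopt-io Write an edge-classification table
#'   (node_i, node_j, class), one row per undirected edge.
#' @param cls an \code{edge_classification} object
#' @export
write_classification_tsv <- function(cls, path) {
  stopifnot(inherits(cls, "edge_classification"))
  one <- function(edges, label) {
    if (nrow(edges) == 0)
      return(data.frame(node_i = integer(0), node_j = integer(0),
                        class = character(0)))
    data.frame(node_i = edges[, 1] - 1L, node_j = edges[, 2] - 1L,
               class = label)
  }
  df <- rbind(one(cls$optimal_edges, "optimal"),
              one(cls$nonoptimal_edges, "nonoptimal"),
              one(cls$false_positive_edges, "false_positive"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
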