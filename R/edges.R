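#' Canonical edge ordering for an N-node connectome
#'
#' Edges are the off-diagonal node pairs (i, j) with i < j, enumerated in
#' row-major upper-triangle order: i ascending, and j ascending within i.
#' All edge vectors in the package (selection masks, planted-effect indices,
#' lesion masks, cohort edge tables) use this ordering.
#'
#' @param n_nodes Number of nodes N (>= 2).
#' @return A data.frame with integer columns `i` and `j` (1-based node
#'   indices, `i < j`) and `n_nodes * (n_nodes - 1) / 2` rows.
#' @examples
#' edge_pairs(4)
#' @export
edge_pairs <- function(n_nodes) {
  n_nodes <- as.integer(n_nodes)
  if (is.na(n_nodes) || n_nodes < 2L) {
    stop("`n_nodes` must be an integer >= 2", call. = FALSE)
  }
  i <- rep.int(seq_len(n_nodes - 1L), times = (n_nodes - 1L):1L)
  j <- sequence((n_nodes - 1L):1L, from = 2:n_nodes)
  data.frame(i = i, j = j)
}

#' Number of edges for an N-node connectome
#' @param n_nodes Number of nodes.
#' @return Integer N(N-1)/2.
#' @export
n_edges <- function(n_nodes) {
  as.integer(n_nodes * (n_nodes - 1) / 2)
}

#' Vectorize a connectome to its canonical edge vector
#'
#' Extracts the strict upper triangle of a symmetric matrix in the canonical
#' edge order (see [edge_pairs()]). `devectorize_edges()` is the inverse on
#' the off-diagonal; the diagonal is restored as 0.
#'
#' @param x A `connectome` object or a symmetric numeric matrix.
#' @return Numeric vector of length N(N-1)/2.
#' @seealso [edge_pairs()], [devectorize_edges()]
#' @export
vectorize_connectome <- function(x) {
  z <- if (inherits(x, "connectome")) x$z else x
  if (!is.matrix(z) || nrow(z) != ncol(z)) {
    stop("`x` must be a square matrix or connectome", call. = FALSE)
  }
  # row-major upper triangle == column-major lower triangle of the transpose
  t(z)[lower.tri(z)]
}

#' Rebuild a symmetric zero-diagonal matrix from an edge vector
#'
#' @param values Numeric vector of length N(N-1)/2 in canonical edge order.
#' @param n_nodes Number of nodes N.
#' @return An N x N symmetric numeric matrix with zero diagonal.
#' @export
devectorize_edges <- function(values, n_nodes) {
  e <- n_edges(n_nodes)
  if (length(values) != e) {
    stop(sprintf("edge vector has length %d; expected %d for %d nodes",
                 length(values), e, n_nodes), call. = FALSE)
  }
  m <- matrix(0, n_nodes, n_nodes)
  m[lower.tri(m)] <- values
  m <- t(m)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}
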