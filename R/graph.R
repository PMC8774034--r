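#' Symmetric normalization of a similarity graph
#'
#' Builds the graph-convolution operator `A = D^{-1/2} S D^{-1/2}` where
#' `D(i,i) = sum_j S(i,j)` is the degree of node `i` in the similarity
#' graph.  With nonnegative `S` and positive degrees the spectral radius of
#' `A` is at most 1.  No self-loop is added: the similarity matrix already
#' carries a unit diagonal.
#'
#' @param S a [similarity_matrix()] (or any nonnegative symmetric matrix
#'   with positive row sums).
#' @return object of class `normalized_graph`: list with `adjacency`,
#'   `degree`, `ids`.
#' @export
normalize_adjacency <- function(S) {
  M <- as.matrix(unclass(S))
  if (nrow(M) != ncol(M)) stop_data("similarity matrix must be square")
  if (max(abs(M - t(M))) > 1e-9) stop_data("similarity matrix must be symmetric")
  deg <- rowSums(M)
  if (any(deg <= 0)) stop_data("zero row sum: cannot normalize adjacency")
  inv_sqrt <- 1 / sqrt(deg)
  A <- M * tcrossprod(inv_sqrt)  # A_ij = S_ij / sqrt(d_i d_j)
  dimnames(A) <- dimnames(M)
  structure(list(adjacency = A, degree = deg, ids = rownames(M)),
            class = "normalized_graph")
}

#' @export
print.normalized_graph <- function(x, ...) {
  cat(sprintf("normalized_graph: %d nodes, degree range [%.3g, %.3g]\n",
              length(x$degree), min(x$degree), max(x$degree)))
  invisible(x)
}
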