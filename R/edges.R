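#' Edge enumeration for a parcellation
#'
#' All edge-indexed quantities in the package use one fixed ordering of the
#' strict upper triangle: row-major, i < j, i.e. (1,2), (1,3), ..., (1,N),
#' (2,3), ... in 1-based node indices ((0,1), (0,2), ... 0-based in files).
#'
#' @param n Number of nodes.
#' @return `edge_pairs`: integer matrix with columns `i`, `j` (1-based,
#'   i < j), one row per edge, in canonical order.
#' @examples
#' edge_pairs(4)
#' @export
edge_pairs <- function(n) {
  n <- as.integer(n)
  stopifnot(n >= 2L)
  # row-major: for i = 1..n-1, j = i+1..n
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(a) (a + 1L):n), use.names = FALSE)
  cbind(i = i, j = j)
}

#' @rdname edge_pairs
#' @param i,j Node indices (1-based, any order, vectorised).
#' @return `edge_index`: the position of edge (i, j) in the canonical
#'   ordering.
#' @export
edge_index <- function(i, j, n) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  if (any(lo == hi)) stop("self-loops have no edge index")
  if (any(hi > n) || any(lo < 1)) stop("node index out of range")
  # edges before row lo: (lo-1) rows of lengths n-1, n-2, ...
  (lo - 1L) * n - (lo * (lo - 1L)) %/% 2L + (hi - lo)
}

#' Vectorise a connectivity matrix / rebuild it from an edge vector
#'
#' `vectorize_edges` extracts the strict upper triangle of a symmetric
#' matrix in the canonical edge order; `devectorize_edges` is its inverse,
#' returning a symmetric matrix with zero diagonal.
#'
#' @param m Symmetric numeric matrix.
#' @return `vectorize_edges`: numeric vector of length N(N-1)/2.
#' @export
vectorize_edges <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  ep <- edge_pairs(nrow(m))
  m[ep]
}

#' @rdname vectorize_edges
#' @param v Edge vector in canonical order.
#' @param n Node count; inferred from `length(v)` if omitted.
#' @export
devectorize_edges <- function(v, n = NULL) {
  if (is.null(n)) {
    n <- (1 + sqrt(1 + 8 * length(v))) / 2
    if (n != round(n)) stop("length is not a triangular number; supply n")
    n <- as.integer(n)
  }
  if (length(v) != (n * (n - 1L)) %/% 2L)
    stop("edge vector length ", length(v), " does not match ", n, " nodes")
  m <- matrix(0, n, n)
  ep <- edge_pairs(n)
  m[ep] <- v
  m[ep[, c(2L, 1L)]] <- v
  m
}
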