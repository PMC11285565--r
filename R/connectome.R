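#' Build a functional connectivity matrix from node time series
#'
#' Computes all pairwise Pearson correlations between node time series,
#' applies the Fisher z-transform (atanh) and zeroes the diagonal.
#' Correlations are clipped to |r| <= 1 - `clip_eps` before the transform
#' so that degenerate (perfectly correlated or anti-correlated) series
#' yield large finite weights instead of infinities; realistic values are
#' perturbed negligibly.
#'
#' @param series Numeric matrix, nodes x frames.
#' @param atlas Optional `cpm_atlas`; if given, its node count must match.
#' @param clip_eps Clipping margin for |r| (default 1e-7).
#' @return Symmetric N x N matrix of Fisher-z connectivity, zero diagonal,
#'   with attribute `atlas` when one was supplied.
#' @export
build_connectome <- function(series, atlas = NULL, clip_eps = 1e-7) {
  stopifnot(is.matrix(series))
  n <- nrow(series)
  if (ncol(series) < 3L) stop("need at least 3 frames")
  if (!all(is.finite(series))) stop("time series contain non-finite values")
  if (!is.null(atlas) && n != n_nodes(atlas))
    stop("series has ", n, " nodes but atlas has ", n_nodes(atlas))
  v <- apply(series, 1L, stats::var)
  if (any(v == 0))
    stop("zero-variance node(s): ", paste(which(v == 0), collapse = ", "))
  r <- stats::cor(t(series))
  r <- pmin(pmax(r, -1 + clip_eps), 1 - clip_eps)
  z <- atanh(r)
  diag(z) <- 0
  z <- (z + t(z)) / 2
  if (!is.null(atlas)) attr(z, "atlas") <- atlas
  z
}

#' Validate a precomputed connectivity matrix
#'
#' Entry point for user-supplied matrices that bypass [build_connectome]:
#' checks squareness, finiteness and symmetry (to `tol`), then returns the
#' matrix symmetrised with an exactly zero diagonal.
#'
#' @param m Numeric square matrix.
#' @param atlas Optional `cpm_atlas` to check the dimension against.
#' @param tol Symmetry tolerance (default 1e-8).
#' @return The validated matrix.
#' @export
validate_connectome <- function(m, atlas = NULL, tol = 1e-8) {
  stopifnot(is.matrix(m))
  if (nrow(m) != ncol(m)) stop("connectome must be square")
  if (!all(is.finite(m))) stop("connectome contains non-finite values")
  if (max(abs(m - t(m))) > tol)
    stop("connectome is not symmetric within tolerance ", tol)
  if (!is.null(atlas) && nrow(m) != n_nodes(atlas))
    stop("connectome dimension does not match atlas node count")
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

#' Read / write a connectivity matrix as delimited text
#'
#' Matrices are stored as plain whitespace-delimited N x N text with no
#' header, the interchange format used for all connectome files in the
#' package.
#'
#' @param path File path.
#' @param atlas Optional atlas for validation on read.
#' @return `read_connectome` returns a validated matrix.
#' @export
read_connectome <- function(path, atlas = NULL) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  validate_connectome(m, atlas = atlas)
}

#' @rdname read_connectome
#' @param m Matrix to write.
#' @export
write_connectome <- function(m, path) {
  utils::write.table(format(m, digits = 10, trim = TRUE), path,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
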