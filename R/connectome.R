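#' Fisher z-transform of a correlation coefficient
#'
#' The variance-stabilizing scale on which functional connectivity edges are
#' stored: `z = atanh(r)`.
#'
#' @param r correlation coefficient(s), strictly inside (-1, 1).
#' @return `atanh(r)`.
#' @examples
#' fisher_z(0.5)
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1))
    stop("fisher_z requires |r| < 1 (degenerate time series upstream?)")
  atanh(r)
}

#' Normalize streamline counts by node volume
#'
#' Structural connectome edge weights are raw streamline counts corrected for
#' parcel size. The default rule divides the count between nodes i and j by
#' the summed volumes `vol_i + vol_j` (contact-surface rationale); geometric
#' mean (`sqrt(vol_i * vol_j)`) and global mean-volume alternatives are
#' selectable. The rule used is recorded in the `normalization` attribute.
#'
#' @param counts square symmetric matrix of non-negative streamline counts.
#' @param volumes strictly positive per-node volumes (mm^3).
#' @param rule one of `"sum"` (default, count/(vol_i+vol_j)),
#'   `"geometric"` (count/sqrt(vol_i*vol_j)), `"mean"` (count/mean(vol)).
#' @return Normalized matrix with zeroed diagonal and a `normalization`
#'   attribute naming the rule.
#' @export
volume_normalize <- function(counts, volumes,
                             rule = c("sum", "geometric", "mean")) {
  rule <- match.arg(rule)
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("counts must be square")
  if (any(counts < 0, na.rm = TRUE)) stop("streamline counts must be non-negative")
  volumes <- as.numeric(volumes)
  if (length(volumes) != nrow(counts))
    stop("one volume per node required")
  if (any(!is.finite(volumes)) || any(volumes <= 0))
    stop("node volumes must be finite and strictly positive")
  denom <- switch(rule,
    sum = outer(volumes, volumes, `+`),
    geometric = sqrt(outer(volumes, volumes)),
    mean = matrix(mean(volumes), nrow(counts), ncol(counts)))
  out <- counts / denom
  diag(out) <- 0
  attr(out, "normalization") <- paste0("volume_", rule)
  out
}

#' Upper-triangle edge index
#'
#' The canonical bijection between node pairs (i < j, 1-based) and linear
#' edge positions. Order is R's column-major upper triangle: edges sorted by
#' j ascending, then i ascending within j — for n = 3 that is (1,2), (1,3),
#' (2,3). Linear positions are 0-based internal plumbing; the `i`, `j`
#' columns are what reports use.
#'
#' @param n_nodes number of nodes.
#' @return Data frame with columns `i`, `j` (1-based node indices) and
#'   `pos` (0-based linear position); `n*(n-1)/2` rows.
#' @export
edge_index <- function(n_nodes) {
  ut <- upper.tri(matrix(0, n_nodes, n_nodes))
  data.frame(i = row(ut)[ut], j = col(ut)[ut],
             pos = seq_len(n_nodes * (n_nodes - 1L) / 2L) - 1L)
}

#' Vectorize a connectome matrix
#'
#' Extracts the upper triangle in the canonical order of [edge_index()].
#'
#' @param m square symmetric matrix.
#' @return Numeric vector of length `n*(n-1)/2`.
#' @seealso [edges_to_matrix()] for the inverse.
#' @export
matrix_to_edges <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("connectome matrix must be square")
  m[upper.tri(m)]
}

#' Reconstruct a symmetric matrix from an edge vector
#'
#' Inverse of [matrix_to_edges()]; the diagonal is zero.
#'
#' @param edges edge-weight vector in canonical order.
#' @param n_nodes number of nodes.
#' @return Symmetric `n_nodes` x `n_nodes` matrix with zero diagonal.
#' @export
edges_to_matrix <- function(edges, n_nodes) {
  if (length(edges) != n_nodes * (n_nodes - 1L) / 2L)
    stop("edge vector length does not match n_nodes*(n_nodes-1)/2")
  m <- matrix(0, n_nodes, n_nodes)
  m[upper.tri(m)] <- edges
  m + t(m)
}

#' Ingest a raw connectome matrix
#'
#' Validates and canonicalizes one subject/modality matrix: square, finite
#' off-diagonal, symmetric within tolerance. Symmetrization `(M + t(M))/2`
#' is applied when the maximum asymmetry is at most `tol` relative to the
#' largest absolute weight; larger asymmetry is an error, not a silent fix.
#' The diagonal is forced to zero (self-connections are meaningless).
#'
#' @param m square numeric matrix.
#' @param tol relative asymmetry tolerance (default 1e-6).
#' @param nonnegative require non-negative weights (structural connectomes).
#' @return Canonical symmetric matrix with zero diagonal.
#' @export
ingest_connectome <- function(m, tol = 1e-6, nonnegative = FALSE) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("connectome matrix must be square")
  diag(m) <- 0
  if (any(!is.finite(m))) {
    bad <- sort(which(!is.finite(m), arr.ind = TRUE)[1L, ])
    stop(sprintf("non-finite edge weight at (%d, %d)", bad[1L], bad[2L]))
  }
  scale <- max(abs(m), 1e-300)
  asym <- max(abs(m - t(m))) / scale
  if (asym > tol)
    stop(sprintf("matrix asymmetry %.3g exceeds tolerance %.3g", asym, tol))
  m <- (m + t(m)) / 2
  if (nonnegative && any(m < 0))
    stop("structural edge weights must be non-negative")
  m
}

#' Read a connectome matrix file
#'
#' Square numeric delimited text (comma or whitespace, autodetected), no
#' header, row k = node k.
#'
#' @param path file path.
#' @param n_nodes expected node count (e.g. from the atlas); checked.
#' @param ... passed to [ingest_connectome()].
#' @return Canonical symmetric matrix.
#' @export
read_connectome <- function(path, n_nodes = NULL, ...) {
  m <- as.matrix(utils::read.table(path, header = FALSE,
                                   sep = detect_sep(path)))
  dimnames(m) <- NULL
  if (!is.null(n_nodes) && nrow(m) != n_nodes)
    stop(sprintf("matrix in %s is %dx%d but atlas has %d nodes",
                 path, nrow(m), ncol(m), n_nodes))
  ingest_connectome(m, ...)
}
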