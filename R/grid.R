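#' Hexagonal SOM grid specification
#'
#' Nodes are laid out on a hexagonal lattice in "offset columns" convention:
#' columns are spaced `sqrt(3)/2` apart, nodes within a column are spaced 1
#' apart, and odd columns (0-based) are shifted down by 0.5.  Every pair of
#' adjacent hexagons is at planar distance exactly 1.  Node ids run
#' column-major: node `i` sits at column `(i-1) %/% ydim + 1`, row
#' `(i-1) %% ydim + 1`.
#'
#' @param xdim number of columns.
#' @param ydim number of rows.
#' @return An object of class `som_grid` with `xdim`, `ydim`, `n_nodes`,
#'   `topology = "hexagonal"`, and `coords` (n_nodes x 2 planar coordinates).
#' @export
som_grid <- function(xdim, ydim) {
  xdim <- as.integer(xdim); ydim <- as.integer(ydim)
  if (xdim < 1L || ydim < 1L) stop("grid dimensions must be >= 1")
  col <- rep(seq_len(xdim) - 1L, each = ydim)
  row <- rep(seq_len(ydim) - 1L, times = xdim)
  coords <- cbind(x = col * sqrt(3) / 2,
                  y = row + 0.5 * (col %% 2L))
  structure(list(xdim = xdim, ydim = ydim, n_nodes = xdim * ydim,
                 topology = "hexagonal", coords = coords),
            class = "som_grid")
}

#' @export
print.som_grid <- function(x, ...) {
  cat("<som_grid> hexagonal ", x$xdim, " x ", x$ydim, " (",
      x$n_nodes, " nodes)\n", sep = "")
  invisible(x)
}

#' Squared planar distances between all grid nodes
#' @param grid a [som_grid].
#' @return n_nodes x n_nodes matrix of squared planar distances.
#' @export
grid_distances2 <- function(grid) {
  cx <- grid$coords[, 1L]; cy <- grid$coords[, 2L]
  outer(cx, cx, "-")^2 + outer(cy, cy, "-")^2
}

#' Hexagonal adjacency of grid nodes
#'
#' Two nodes are neighbours iff their planar distance is 1 (up to rounding);
#' interior nodes have six neighbours, border nodes fewer.
#'
#' @param grid a [som_grid].
#' @return Logical n_nodes x n_nodes symmetric matrix, diagonal `FALSE`.
#' @export
grid_adjacency <- function(grid) {
  d2 <- grid_distances2(grid)
  adj <- abs(d2 - 1) < 1e-9
  diag(adj) <- FALSE
  adj
}

#' Map size from the number of samples and the data shape
#'
#' Classic heuristic sizing: the number of map units is `5 * sqrt(N)` and the
#' side ratio follows the square root of the ratio of the two largest data
#' covariance eigenvalues.  Rounding convention:
#' `xdim = round(sqrt(munits * sqrt(eig_ratio)))`, `ydim = round(munits / xdim)`.
#'
#' @param n_samples number of training samples (>= 4).
#' @param eig_ratio ratio of the two largest covariance eigenvalues of the
#'   (scaled) training data, >= 1.
#' @return A [som_grid] of the heuristic size.
#' @export
heuristic_map_size <- function(n_samples, eig_ratio) {
  if (n_samples < 4) stop("need at least 4 samples to size a map")
  if (eig_ratio < 1) stop("eig_ratio must be >= 1 (largest eigenvalue first)")
  munits <- 5 * sqrt(n_samples)
  xdim <- max(1L, as.integer(round(sqrt(munits * sqrt(eig_ratio)))))
  ydim <- max(1L, as.integer(round(munits / xdim)))
  som_grid(xdim, ydim)
}

#' Leading covariance eigenvalue ratio of a data matrix
#'
#' Convenience input to [heuristic_map_size()].
#' @param X numeric matrix (no missing values).
#' @return `lambda1 / lambda2` of `cov(X)`.
#' @export
eigen_ratio <- function(X) {
  ev <- eigen(stats::cov(X), symmetric = TRUE, only.values = TRUE)$values
  if (length(ev) < 2L || ev[2L] <= .Machine$double.eps)
    stop("data covariance is rank-deficient; eigenvalue ratio undefined")
  ev[1L] / ev[2L]
}
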