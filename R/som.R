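#' Linear (PCA-plane) initialization of a codebook
#'
#' Initializes node vectors on the plane of the first two principal
#' components of the training data, linear in the grid coordinates: the long
#' grid axis spans +/- one standard deviation along PC1, the short axis along
#' PC2.  Deterministic; `seed` is only consulted for the degenerate fallback
#' when the data have rank 1 (a seeded random direction replaces PC2 at
#' negligible amplitude).
#'
#' @param X scaled data matrix with at least two distinct rows.
#' @param grid a [som_grid].
#' @param seed integer, degenerate-fallback seed.
#' @return Codebook matrix (n_nodes x n_variables).
#' @export
linear_init <- function(X, grid, seed = 1L) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("X contains missing values")
  ctr <- colMeans(X)
  Z <- sweep(X, 2L, ctr)
  sv <- svd(Z, nu = 0L, nv = min(2L, ncol(X)))
  ev <- sv$d^2 / max(1L, nrow(X) - 1L)
  if (ev[1L] <= .Machine$double.eps)
    stop("data have rank 0 (all rows identical); cannot initialize")
  v1 <- sv$v[, 1L]
  s1 <- sqrt(ev[1L])
  if (length(ev) >= 2L && ev[2L] > 1e-12 * ev[1L]) {
    v2 <- sv$v[, 2L]
    s2 <- sqrt(ev[2L])
  } else {
    # rank-1 data: seeded random direction orthogonal to v1, tiny amplitude
    rng <- local({set.seed(seed); stats::rnorm(ncol(X))})
    v2 <- rng - sum(rng * v1) * v1
    v2 <- v2 / sqrt(sum(v2^2))
    s2 <- 1e-8 * s1
  }
  # linear ramps over the integer grid indices (not the hex planar
  # coordinates, whose half-row shift would zigzag degenerate grids)
  ids <- seq_len(grid$n_nodes) - 1L
  col_idx <- ids %/% grid$ydim
  row_idx <- ids %% grid$ydim
  ax <- function(v) if (diff(range(v)) > 0) 2 * (v - min(v)) / diff(range(v)) - 1 else rep(0, length(v))
  a1 <- ax(if (grid$xdim >= grid$ydim) col_idx else row_idx)
  a2 <- ax(if (grid$xdim >= grid$ydim) row_idx else col_idx)
  M <- matrix(ctr, nrow = grid$n_nodes, ncol = ncol(X), byrow = TRUE) +
    outer(a1 * s1, v1) + outer(a2 * s2, v2)
  colnames(M) <- colnames(X)
  M
}

# chunked nearest/second-nearest node search; returns bmu, second, qe
.bmu_scan <- function(M, X, chunk = 4096L) {
  n <- nrow(X); m <- nrow(M)
  bmu <- integer(n); second <- integer(n); qe <- numeric(n)
  m2 <- rowSums(M^2)
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    Xi <- X[lo:hi, , drop = FALSE]
    D2 <- outer(rowSums(Xi^2), m2, "+") - 2 * tcrossprod(Xi, M)
    b1 <- max.col(-D2, ties.method = "first")
    ii <- seq_len(hi - lo + 1L)
    qe[lo:hi] <- sqrt(pmax(D2[cbind(ii, b1)], 0))
    if (m >= 2L) {
      D2[cbind(ii, b1)] <- Inf
      second[lo:hi] <- max.col(-D2, ties.method = "first")
    } else second[lo:hi] <- b1
    bmu[lo:hi] <- b1
  }
  list(bmu = bmu, second = second, qe = qe)
}

#' Best-matching-unit assignment
#'
#' For every sample, the node whose codebook vector is nearest in Euclidean
#' distance (ties broken by lowest node index), the runner-up node under the
#' same rule, and the per-sample quantization error (distance to the BMU).
#'
#' @param codebook codebook matrix (n_nodes x n_variables), same scale as `X`.
#' @param X data matrix.
#' @return An object of class `bmu_assignment`: list with integer vectors
#'   `bmu`, `second` and numeric `qe`, aligned with the rows of `X`.
#' @export
assign_bmu <- function(codebook, X) {
  X <- as.matrix(X); codebook <- as.matrix(codebook)
  if (ncol(X) != ncol(codebook))
    stop("X and codebook disagree on the number of variables")
  if (anyNA(X)) stop("X contains missing values; impute before assignment")
  res <- .bmu_scan(codebook, X)
  structure(list(bmu = res$bmu, second = res$second, qe = res$qe),
            class = "bmu_assignment")
}

#' @export
print.bmu_assignment <- function(x, ...) {
  cat("<bmu_assignment> ", length(x$bmu), " samples, mean QE ",
      signif(mean(x$qe), 4), "\n", sep = "")
  invisible(x)
}

# two-sample Kolmogorov-Smirnov distance (sup norm of ECDF difference)
.ks_distance <- function(a, b) {
  v <- sort(unique(c(a, b)))
  max(abs(stats::ecdf(a)(v) - stats::ecdf(b)(v)))
}

#' SOM quality metrics
#'
#' * `qe` — overall quantization error, the mean distance of each sample to
#'   its BMU;
#' * `te` — topographic error, the fraction of samples whose first and second
#'   BMUs are not hex-adjacent on the grid;
#' * `dme` — distribution-matching error, the mean over variables of the
#'   Kolmogorov-Smirnov distance between the sample values and the
#'   BMU-mapped codebook values (i.e. each sample represented by its BMU's
#'   value).  This KS surrogate stands in for the metric's original
#'   definition, which is not fully standardised in the literature.
#'
#' @param model a [train_batch_som()] model (or a list with `codebook` and
#'   `grid`).
#' @param X data matrix on the codebook scale.
#' @param assignment optional precomputed [assign_bmu()] result.
#' @return List with numeric scalars `qe`, `te`, `dme`.
#' @export
quality_metrics <- function(model, X, assignment = NULL) {
  if (is.null(assignment)) assignment <- assign_bmu(model$codebook, X)
  adj <- grid_adjacency(model$grid)
  not_adj <- !adj[cbind(assignment$bmu, assignment$second)] &
    assignment$bmu != assignment$second
  # a sample whose two best nodes coincide (single-node map) is not an error
  te <- mean(not_adj)
  mapped <- model$codebook[assignment$bmu, , drop = FALSE]
  dme <- mean(vapply(seq_len(ncol(X)), function(j)
    .ks_distance(X[, j], mapped[, j]), numeric(1)))
  list(qe = mean(assignment$qe), te = te, dme = dme)
}

#' Train a batch self-organizing map
#'
#' Batch Kohonen training with a Gaussian neighbourhood: each epoch assigns
#' every sample to its BMU, then replaces each node vector by the
#' neighbourhood-weighted mean of the samples,
#' `m_i <- sum_j h(c_j, i) x_j / sum_j h(c_j, i)` with
#' `h(c, i) = exp(-d2(c, i) / (2 sigma^2))` on the grid.  The radius `sigma`
#' shrinks linearly from `radius_init` to 1 over the rough phase (the first
#' `ceiling(epochs/2)` epochs) and stays at 1 for the fine phase.  With the
#' default PCA initialization the procedure is fully deterministic.
#'
#' @param X scaled, complete data matrix.
#' @param grid a [som_grid].
#' @param epochs total number of batch epochs (default 100).
#' @param radius_init initial neighbourhood radius; default
#'   `max(xdim, ydim) / 4`.
#' @param radius_final final radius, default 1 (must be >= 1 and <=
#'   `radius_init`).
#' @param seed integer; stored with the model and used only for the
#'   degenerate initialization fallback.
#' @param init optional codebook matrix to start from instead of
#'   [linear_init()].
#' @return An object of class `som_model`: list with `grid`, `codebook`,
#'   `scale = "autoscaled"`, `params`, `trace` (mean QE per epoch) and
#'   `quality` ([quality_metrics()] on the training data).
#' @export
train_batch_som <- function(X, grid, epochs = 100L, radius_init = NULL,
                            radius_final = 1, seed = 1L, init = NULL) {
  X <- as.matrix(X)
  if (anyNA(X) || any(!is.finite(X))) stop("X must be finite and complete")
  if (is.null(radius_init)) radius_init <- max(grid$xdim, grid$ydim) / 4
  radius_init <- max(radius_init, radius_final)
  if (radius_final < 1) stop("radius_final must be >= 1")
  if (epochs < 1L) stop("epochs must be >= 1")
  M <- if (is.null(init)) {
    tryCatch(linear_init(X, grid, seed), error = function(e) {
      if (!grepl("rank 0", conditionMessage(e))) stop(e)
      # degenerate data (all rows identical): every node starts at the mean
      matrix(colMeans(X), grid$n_nodes, ncol(X), byrow = TRUE,
             dimnames = list(NULL, colnames(X)))
    })
  } else as.matrix(init)
  if (nrow(M) != grid$n_nodes) stop("init codebook does not match grid size")
  D2g <- grid_distances2(grid)
  rough <- ceiling(epochs / 2)
  sigmas <- c(if (rough > 1) seq(radius_init, radius_final, length.out = rough)
              else radius_final,
              rep(radius_final, epochs - rough))
  trace <- numeric(epochs)
  n_empty <- 0L
  m <- grid$n_nodes
  for (e in seq_len(epochs)) {
    a <- .bmu_scan(M, X)
    trace[e] <- mean(a$qe)
    counts <- tabulate(a$bmu, nbins = m)
    S <- matrix(0, m, ncol(X))
    rs <- rowsum(X, group = a$bmu)
    S[as.integer(rownames(rs)), ] <- rs
    K <- exp(-D2g / (2 * sigmas[e]^2))
    num <- K %*% S
    den <- as.vector(K %*% counts)
    upd <- den > .Machine$double.eps
    if (!all(upd)) n_empty <- n_empty + sum(!upd)
    M[upd, ] <- num[upd, , drop = FALSE] / den[upd]
  }
  if (n_empty > 0L)
    warning(n_empty, " node update(s) had an empty neighbourhood; ",
            "previous values kept")
  model <- structure(
    list(grid = grid, codebook = M, scale = "autoscaled",
         params = list(epochs = as.integer(epochs), radius_init = radius_init,
                       radius_final = radius_final, seed = as.integer(seed)),
         trace = trace, quality = NULL),
    class = "som_model")
  model$quality <- quality_metrics(model, X)
  model
}

#' @export
print.som_model <- function(x, ...) {
  cat("<som_model> ", x$grid$xdim, " x ", x$grid$ydim, " hexagonal, ",
      x$grid$n_nodes, " nodes, scale=", x$scale, "\n", sep = "")
  if (!is.null(x$quality))
    cat(sprintf("  qe=%.4f  te=%.4f  dme=%.4f\n",
                x$quality$qe, x$quality$te, x$quality$dme))
  invisible(x)
}

#' Train candidate maps and pick the best by (qe, te, dme)
#'
#' Reproducible model-selection rule: among candidate grids, keep those whose
#' quantization error is within 5% of the minimum, then choose the lowest
#' topographic error, breaking remaining ties by lowest distribution-matching
#' error, then by fewest nodes.
#'
#' @param X scaled data matrix.
#' @param grids list of [som_grid] candidates.
#' @param ... passed to [train_batch_som()].
#' @return List with `model` (the selected [train_batch_som()] fit) and
#'   `table` (data.frame of per-candidate metrics).
#' @export
select_som <- function(X, grids, ...) {
  fits <- lapply(grids, function(g) train_batch_som(X, g, ...))
  tab <- do.call(rbind, lapply(fits, function(f)
    data.frame(xdim = f$grid$xdim, ydim = f$grid$ydim,
               n_nodes = f$grid$n_nodes, qe = f$quality$qe,
               te = f$quality$te, dme = f$quality$dme)))
  ok <- tab$qe <= min(tab$qe) * 1.05
  cand <- which(ok)
  cand <- cand[order(tab$te[cand], tab$dme[cand], tab$n_nodes[cand])]
  pick <- cand[1L]
  tab$selected <- seq_len(nrow(tab)) == pick
  list(model = fits[[pick]], table = tab)
}

#' Neighbour-distance (U-matrix) values
#'
#' For each node, the mean Euclidean distance between its codebook vector and
#' those of its hex neighbours (4-6 depending on grid position).
#' Discontinuities in this map reveal cluster borders.
#'
#' @param model a [train_batch_som()] model.
#' @return Numeric vector of length n_nodes.
#' @export
u_matrix <- function(model) {
  adj <- grid_adjacency(model$grid)
  M <- model$codebook
  vapply(seq_len(nrow(M)), function(i) {
    nb <- which(adj[i, ])
    mean(sqrt(rowSums((M[nb, , drop = FALSE] -
                         matrix(M[i, ], length(nb), ncol(M), byrow = TRUE))^2)))
  }, numeric(1))
}

#' Flag high-quantization-error samples as possible outliers
#'
#' A sample far from every recurrent profile in the codebook is a candidate
#' outlier event.  The rule is the Tukey fence on the per-sample quantization
#' errors: flag `qe > Q3 + k * IQR` (default `k = 1.5`).  The rule is
#' invariant under any common positive rescaling of the QEs.
#'
#' @param assignment a [assign_bmu()] result (>= 4 samples).
#' @param k fence multiplier.
#' @return Logical vector aligned with the samples.
#' @export
detect_qe_outliers <- function(assignment, k = 1.5) {
  qe <- assignment$qe
  if (length(qe) < 4L) stop("need at least 4 samples to form quartiles")
  q <- stats::quantile(qe, c(0.25, 0.75), names = FALSE, type = 7)
  qe > q[2L] + k * (q[2L] - q[1L])
}
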