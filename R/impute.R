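#' Iterative-PCA imputation of missing concentrations
#'
#' Fills missing cells by alternating between a principal component fit on the
#' completed matrix and reconstruction of the missing cells, the classic
#' EM-style scheme behind multivariate missing-value replacement in
#' chemometrics.  Columns are standardised internally before each fit so the
#' components are not dominated by the largest-scale pollutant; observed cells
#' are never touched and are returned bit-for-bit identical.
#'
#' @param X numeric matrix with `NA` missing marks.
#' @param n_components number of principal components of the reconstruction;
#'   must satisfy `1 <= n_components < ncol(X)`.
#' @param tol convergence threshold on the relative change of the imputed
#'   cells between iterations.
#' @param max_iter iteration cap; hitting it sets the `converged` attribute to
#'   `FALSE` (with a warning) rather than failing.
#' @param nonneg clamp imputed cells at zero (default `TRUE`: concentrations
#'   cannot be negative).  Observed cells are never touched.
#' @return The completed matrix with attribute `converged` (logical) and
#'   `iterations` (count).  If `X` has no missing cells it is returned as is
#'   (with `converged = TRUE`).
#' @export
impute_iterative_pca <- function(X, n_components = 2L, tol = 1e-6,
                                 max_iter = 100L, nonneg = TRUE) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (n_components < 1L || n_components >= p)
    stop("n_components must be in [1, ncol(X) - 1]")
  miss <- is.na(X)
  if (!any(miss)) {
    attr(X, "converged") <- TRUE
    attr(X, "iterations") <- 0L
    return(X)
  }
  n_obs <- colSums(!miss)
  if (any(n_obs == 0L))
    stop("column(s) entirely missing: ",
         paste(colnames(X)[n_obs == 0L], collapse = ", "))
  if (any(n_obs < n_components + 1L))
    stop("each column needs at least n_components + 1 observed values")

  filled <- X
  mu0 <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(p)) filled[miss[, j], j] <- mu0[j]

  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    mu <- colMeans(filled)
    sdv <- apply(filled, 2L, stats::sd)
    sdv[sdv < .Machine$double.eps] <- 1
    Z <- sweep(sweep(filled, 2L, mu), 2L, sdv, "/")
    V <- svd(Z, nu = 0L, nv = n_components)$v
    # project each incomplete row onto the component space using its
    # observed cells only, then reconstruct the missing ones
    Zhat <- Z
    for (i in which(rowSums(miss) > 0L)) {
      o <- which(!miss[i, ])
      Vo <- V[o, , drop = FALSE]
      scores <- qr.coef(qr(Vo), Z[i, o])
      scores[is.na(scores)] <- 0
      Zhat[i, miss[i, ]] <- V[miss[i, ], , drop = FALSE] %*% scores
    }
    recon <- sweep(sweep(Zhat, 2L, sdv, "*"), 2L, mu, "+")
    old <- filled[miss]
    filled[miss] <- recon[miss]
    delta <- sqrt(sum((filled[miss] - old)^2) /
                    max(sum(old^2), .Machine$double.eps))
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("imputation did not converge in ", max_iter, " iterations")
  out <- X
  out[miss] <- if (nonneg) pmax(filled[miss], 0) else filled[miss]
  attr(out, "converged") <- converged
  attr(out, "iterations") <- it
  out
}
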