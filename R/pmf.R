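#' Build the PMF uncertainty matrix
#'
#' Element-wise `u_ij = max(rel_j * x_ij, floor_j)`: a per-variable relative
#' uncertainty with an absolute floor that keeps weights finite where a
#' concentration is zero.  Typical relative uncertainties for this panel are
#' 6.2% for NO and NO2, 10.9% for benzene and toluene, and 10% for PM10.
#'
#' @param X nonnegative concentration-scale matrix (inverse-autoscale a
#'   codebook first).
#' @param rel per-variable relative uncertainties (fractions, > 0), length
#'   `ncol(X)` or scalar.
#' @param floor per-variable absolute floors (>= 0); default 10% of each
#'   variable's 5th percentile (a small strictly positive guard when the
#'   percentile is 0).
#' @return Strictly positive uncertainty matrix, same shape as `X`.
#' @export
build_uncertainties <- function(X, rel, floor = NULL) {
  X <- as.matrix(X)
  if (any(X < 0))
    stop("X has negative entries; PMF needs concentration-scale data ",
         "(use inverse_autoscale on an autoscaled codebook)")
  rel <- rep_len(rel, ncol(X))
  if (any(rel <= 0)) stop("relative uncertainties must be > 0")
  if (is.null(floor)) {
    floor <- 0.1 * apply(X, 2L, stats::quantile, probs = 0.05, names = FALSE)
    floor[floor <= 0] <- 0.1 * rel[floor <= 0] * pmax(colMeans(X)[floor <= 0],
                                                      .Machine$double.eps)
  }
  floor <- rep_len(floor, ncol(X))
  if (any(floor < 0)) stop("floors must be >= 0")
  U <- pmax(sweep(X, 2L, rel, "*"), rep(floor, each = nrow(X)))
  if (any(U <= 0))
    stop("zero uncertainty produced; supply a positive floor for variables ",
         "with zero concentrations")
  U
}

# uncertainty-weighted squared-residual objective
.pmf_q <- function(X, U, G, F) sum(((X - G %*% F) / U)^2)

# one run of weighted multiplicative updates from a given (G, F).
# q_floor: an exact factorization always exists once k reaches ncol(X)
# (identity profiles), so Q below numerical noise counts as converged --
# without this the iteration drifts along the degenerate zero-Q manifold.
.pmf_run <- function(X, U, G, F, tol, max_iter) {
  W <- 1 / U^2
  eps <- .Machine$double.eps
  q_floor <- 1e-9 * length(X)  # mean squared scaled residual < 1e-9: exact
  q_trace <- numeric(0)
  q_prev <- q <- .pmf_q(X, U, G, F)
  converged <- FALSE
  if (q_prev < q_floor) converged <- TRUE
  for (it in seq_len(max_iter)) {
    if (converged) break
    WX <- W * X
    G <- G * ((WX %*% t(F)) / ((W * (G %*% F)) %*% t(F) + eps))
    F <- F * ((t(G) %*% WX) / (t(G) %*% (W * (G %*% F)) + eps))
    q <- .pmf_q(X, U, G, F)
    q_trace <- c(q_trace, q)
    if (q < q_floor || q_prev - q < tol * max(q_prev, eps)) converged <- TRUE
    q_prev <- q
  }
  list(G = G, F = F, Q = q, q_trace = q_trace, converged = converged)
}

# successive-projection pick of k extreme, mutually dissimilar rows of X;
# used as a deterministic data-anchored initialization of the profiles
.spa_rows <- function(X, k) {
  Xn <- X / sqrt(rowSums(X^2) + .Machine$double.eps)
  R <- Xn
  picks <- integer(k)
  for (j in seq_len(k)) {
    picks[j] <- which.max(rowSums(R^2))
    v <- R[picks[j], ]
    nv <- sum(v^2)
    if (nv <= .Machine$double.eps) { picks[j:k] <- picks[j]; break }
    R <- R - (R %*% v / nv) %*% t(v)
  }
  picks
}

# scale F rows to unit sum, G columns inversely; GF unchanged
.pmf_normalize <- function(G, F) {
  s <- rowSums(F)
  s[s <= 0] <- 1
  list(G = sweep(G, 2L, s, "*"), F = sweep(F, 1L, s, "/"))
}

#' Expected value of the PMF objective
#'
#' Degrees-of-freedom reference `Q_exp = n*m - k*(n + m)` for an `n x m` data
#' matrix factorized with `k` factors; `Q/Q_exp` near 1 indicates a
#' well-specified model.  Note that with `m` variables the formula is always
#' negative at `k = m`, so it cannot arbitrate a factor count equal to the
#' number of species.
#'
#' @param n_rows,n_variables data dimensions.
#' @param k factor count.
#' @return The expected Q (positive), or an error when the model is
#'   overparameterized (`Q_exp <= 0`).
#' @export
q_expected <- function(n_rows, n_variables, k) {
  q <- n_rows * n_variables - k * (n_rows + n_variables)
  if (q <= 0)
    stop("Q_expected is nonpositive (", q, "): model overparameterized")
  q
}

#' Fit positive matrix factorization by weighted multiplicative updates
#'
#' Minimizes the receptor-model objective
#' `Q = sum_ij ((x_ij - (GF)_ij) / u_ij)^2` over elementwise-nonnegative `G`
#' (contributions) and `F` (profiles) with the weighted Lee-Seung
#' multiplicative updates, which keep `Q` non-increasing.  The best of
#' `n_starts` random nonnegative initializations is returned; profiles are
#' normalized to unit row sum with `G` rescaled inversely, so `GF` is
#' unchanged.
#'
#' @param X nonnegative matrix (rows = codebook nodes or samples).
#' @param U strictly positive uncertainty matrix, same shape.
#' @param k number of factors (`1 <= k < nrow(X)`; more factors than
#'   variables triggers a warning, not an error, so that over-specified
#'   counts can still be scanned and rejected on stability).
#' @param n_starts random restarts (default 20).
#' @param seed integer RNG seed for the restarts.
#' @param tol stop when the relative Q decrease falls below this (default 1e-8).
#' @param max_iter per-start iteration cap (default 5000).
#' @param init optional warm start, a list with nonnegative `G` (n x k) and
#'   `F` (k x m); when given it replaces the random restarts.
#' @return An object of class `pmf_solution`: `G`, `F`, `k`, `Q`,
#'   `Q_expected` (NA when the formula is nonpositive), `scaled_residuals`,
#'   `q_trace` of the winning run, `n_starts`, `seed`, `converged`.
#' @export
fit_pmf <- function(X, U, k, n_starts = 20L, seed = 1L, tol = 1e-8,
                    max_iter = 5000L, init = NULL) {
  X <- as.matrix(X); U <- as.matrix(U)
  if (any(X < 0)) stop("X must be nonnegative (inverse_autoscale first)")
  if (any(U <= 0)) stop("U must be strictly positive")
  if (!all(dim(X) == dim(U))) stop("X and U dimensions differ")
  n <- nrow(X); m <- ncol(X)
  if (k < 1L || k >= n) stop("k must satisfy 1 <= k < nrow(X)")
  if (k > m)
    warning("k = ", k, " exceeds the number of variables (", m,
            "); the model is overparameterized")
  scale0 <- sqrt(mean(X) / max(k, 1L))
  runs <- if (!is.null(init)) {
    list(.pmf_run(X, U, as.matrix(init$G), as.matrix(init$F), tol, max_iter))
  } else {
    with_seed(seed, {
      rr <- lapply(seq_len(n_starts), function(s) {
        G0 <- matrix(stats::runif(n * k, 0.1, 1) * scale0, n, k)
        F0 <- matrix(stats::runif(k * m, 0.1, 1) * scale0, k, m)
        .pmf_run(X, U, G0, F0, tol, max_iter)
      })
      # one extra deterministic start anchored on extreme data rows, so at
      # least one run begins near the data's own conical hull
      F0 <- X[.spa_rows(X, k), , drop = FALSE] + scale0 * 1e-3
      G0 <- matrix(stats::runif(n * k, 0.1, 1) * scale0, n, k)
      c(rr, list(.pmf_run(X, U, G0, F0, tol, max_iter)))
    })
  }
  qs <- vapply(runs, `[[`, numeric(1), "Q")
  # ties on Q are real once k reaches the number of variables (a continuum of
  # exact factorizations exists); among near-tied runs prefer the
  # minimum-volume profile simplex -- the standard identifiability criterion
  # that anchors factors on the data's own extreme profiles
  cand <- which(qs <= min(qs) + max(min(qs) * 1e-3, 1e-9 * length(X)))
  if (length(cand) > 1L) {
    vol <- vapply(cand, function(i) {
      Fn <- runs[[i]]$F / sqrt(rowSums(runs[[i]]$F^2) + .Machine$double.eps)
      determinant(tcrossprod(Fn), logarithm = TRUE)$modulus
    }, numeric(1))
    best <- runs[[cand[which.min(vol)]]]
  } else best <- runs[[cand]]
  nb <- .pmf_normalize(best$G, best$F)
  qe_ref <- tryCatch(q_expected(n, m, k), error = function(e) NA_real_)
  F <- nb$F
  colnames(F) <- colnames(X)
  structure(
    list(G = nb$G, F = F, k = as.integer(k), Q = best$Q, Q_expected = qe_ref,
         scaled_residuals = (X - nb$G %*% nb$F) / U,
         q_trace = best$q_trace, n_starts = length(runs),
         seed = as.integer(seed), converged = best$converged),
    class = "pmf_solution")
}

#' @export
print.pmf_solution <- function(x, ...) {
  cat("<pmf_solution> k=", x$k, ", Q=", signif(x$Q, 6), sep = "")
  if (is.finite(x$Q_expected))
    cat(", Q/Qexp=", signif(x$Q / x$Q_expected, 4), sep = "")
  cat(if (x$converged) ", converged" else ", NOT converged", "\n", sep = "")
  invisible(x)
}

#' Bootstrap validation of a PMF solution
#'
#' Resamples the rows of `X` (and `U`) with replacement, refits from the base
#' solution as warm start, and maps each bootstrap factor to the base factor
#' whose contribution values (over the resampled rows) it correlates with
#' most, provided the Pearson correlation reaches `r_threshold`; otherwise
#' the factor counts as unmapped.  Also reports, per base factor, the
#' fraction of species whose base profile value falls inside the bootstrap
#' interquartile range.
#'
#' @param X,U the data and uncertainties the base model was fitted on.
#' @param base a [fit_pmf()] solution.
#' @param n_boot number of replicates (>= 2).
#' @param r_threshold mapping correlation threshold in (0, 1), default 0.6.
#' @param seed integer RNG seed.
#' @param tol,max_iter refit controls.  The refits are perturbation analyses
#'   from the base optimum, so they use a looser tolerance than the base
#'   fit; pushing them to high precision only makes them wander along the
#'   near-degenerate Q surface.
#' @return An object of class `pmf_bootstrap`: `n_boot`, `n_effective`
#'   (replicates not skipped), `skipped`, `mapping_counts` (bootstrap factors
#'   mapped to each base factor), `unmapped`, `factor_mapping_rate` (fraction
#'   of replicates in which each base factor received at least one mapped
#'   factor), `iqr_coverage` (per-factor species coverage).
#' @export
bootstrap_pmf <- function(X, U, base, n_boot = 100L, r_threshold = 0.6,
                          seed = 1L, tol = 1e-5, max_iter = 500L) {
  X <- as.matrix(X); U <- as.matrix(U)
  if (n_boot < 2L) stop("n_boot must be >= 2")
  if (r_threshold <= 0 || r_threshold >= 1) stop("r_threshold must be in (0,1)")
  k <- base$k
  n <- nrow(X)
  mapping_counts <- integer(k)
  runs_mapped <- integer(k)
  unmapped <- 0L
  skipped <- 0L
  boot_F <- vector("list", k)  # rows of mapped bootstrap profiles per factor
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      Xb <- X[idx, , drop = FALSE]
      if (any(apply(Xb, 2L, function(v) diff(range(v)) == 0))) {
        skipped <- skipped + 1L
        next
      }
      fit <- fit_pmf(Xb, U[idx, , drop = FALSE], k,
                     init = list(G = base$G[idx, , drop = FALSE], F = base$F),
                     tol = tol, max_iter = max_iter)
      hit <- logical(k)
      for (f in seq_len(k)) {
        r <- suppressWarnings(vapply(seq_len(k), function(g)
          stats::cor(fit$G[, f], base$G[idx, g]), numeric(1)))
        r[is.na(r)] <- -Inf
        gbest <- which.max(r)
        if (r[gbest] >= r_threshold) {
          mapping_counts[gbest] <- mapping_counts[gbest] + 1L
          hit[gbest] <- TRUE
          boot_F[[gbest]] <- rbind(boot_F[[gbest]], fit$F[f, ])
        } else unmapped <- unmapped + 1L
      }
      runs_mapped <- runs_mapped + hit
    }
  })
  n_eff <- n_boot - skipped
  # when the fit is numerically exact the bootstrap IQR collapses to zero
  # width; a tiny absolute guard (1e-6 of unit profile mass, orders below
  # any measurement uncertainty) keeps the coverage comparison meaningful
  iqr_tol <- 1e-6
  iqr_coverage <- vapply(seq_len(k), function(g) {
    Fb <- boot_F[[g]]
    if (is.null(Fb) || nrow(Fb) < 2L) return(NA_real_)
    qs <- apply(Fb, 2L, stats::quantile, probs = c(0.25, 0.75), names = FALSE)
    mean(base$F[g, ] >= qs[1L, ] - iqr_tol & base$F[g, ] <= qs[2L, ] + iqr_tol)
  }, numeric(1))
  structure(
    list(n_boot = as.integer(n_boot), n_effective = as.integer(n_eff),
         skipped = as.integer(skipped), mapping_counts = mapping_counts,
         unmapped = as.integer(unmapped),
         factor_mapping_rate = if (n_eff > 0) runs_mapped / n_eff
                               else rep(NA_real_, k),
         iqr_coverage = iqr_coverage, r_threshold = r_threshold),
    class = "pmf_bootstrap")
}

#' @export
print.pmf_bootstrap <- function(x, ...) {
  cat("<pmf_bootstrap> ", x$n_effective, "/", x$n_boot,
      " replicates (", x$skipped, " skipped), unmapped factors: ",
      x$unmapped, "\n", sep = "")
  print(data.frame(factor = seq_along(x$mapping_counts),
                   mapped = x$mapping_counts,
                   mapping_rate = round(x$factor_mapping_rate, 3),
                   iqr_coverage = round(x$iqr_coverage, 3)),
        row.names = FALSE)
  invisible(x)
}

#' Scan factor counts and select by replication stability
#'
#' Fits PMF for each `k` in `[kmin, kmax]` and assesses each fit two ways:
#'
#' 1. *Bootstrap mapping* ([bootstrap_pmf()], warm-started as usual): each
#'    factor should be recovered in at least `stability` (default 80%) of
#'    the resampled replicates.
#' 2. *Cold replication*: the model is refitted `n_replicates` times from
#'    fresh random starts and every base factor must be matched (contribution
#'    correlation `>= r_threshold`) by some factor of each replicate in at
#'    least `stability` of the runs.
#'
#' 3. *Distinctness*: no two factor profiles may be near-duplicates (cosine
#'    similarity above `distinct_cos`, default 0.875, set from the measured
#'    gap between genuine factor pairs and split-factor pairs); a split
#'    source shows up as a duplicated profile pair, the classic symptom of
#'    one factor too many.
#'
#' A count is *stable* when every factor passes all three.  The chosen `k`
#' is the largest stable one: splitting a real source produces an extra
#' factor that fresh starts do not reproduce (or that duplicates another),
#' while merging sources stays stable.  The
#' scan leans on replication rather than `Q/Q_expected` because the
#' degrees-of-freedom reference is undefined once `k` reaches the number of
#' variables (and with `k = m` an exact zero-Q factorization always exists),
#' so the fit statistic alone cannot arbitrate the factor count; the full
#' diagnostics table is returned for audit.  If no count is stable, the `k`
#' with the best worst-factor rate is returned.
#'
#' @param X,U data and uncertainties (see [fit_pmf()]).
#' @param kmin,kmax factor-count range (default 4..6).
#' @param n_starts,seed,tol,max_iter passed to [fit_pmf()].
#' @param n_boot,r_threshold passed to [bootstrap_pmf()].
#' @param n_replicates cold-replication refits per candidate count.
#' @param stability per-factor rate threshold (default 0.8).
#' @param distinct_cos maximum allowed cosine similarity between two factor
#'   profiles (default 0.875).
#' @return List with `k` (chosen), `table` (per-k data.frame: `k`, `Q`,
#'   `Q_expected`, `q_ratio`, `min_boot_rate`, `min_cold_rate`,
#'   `max_profile_cos`, `stable`), `fits` (list of [fit_pmf()] solutions)
#'   and `bootstraps`.
#' @export
select_factor_count <- function(X, U, kmin = 4L, kmax = 6L, n_starts = 20L,
                                seed = 1L, n_boot = 50L, r_threshold = 0.6,
                                n_replicates = 5L, stability = 0.8,
                                distinct_cos = 0.875,
                                tol = 1e-8, max_iter = 5000L) {
  if (kmin > kmax) stop("kmin must be <= kmax")
  ks <- seq.int(kmin, kmax)
  fits <- list(); boots <- list()
  rows <- lapply(seq_along(ks), function(i) {
    k <- ks[i]
    fit <- fit_pmf(X, U, k, n_starts = n_starts, seed = seed + i,
                   tol = tol, max_iter = max_iter)
    bt <- bootstrap_pmf(X, U, fit, n_boot = n_boot,
                        r_threshold = r_threshold, seed = seed + 1000L + i)
    hits <- integer(k)
    for (r in seq_len(n_replicates)) {
      refit <- fit_pmf(X, U, k, n_starts = max(2L, n_starts %/% 4L),
                       seed = seed + 2000L + i * 100L + r,
                       tol = tol, max_iter = max_iter)
      for (g in seq_len(k)) {
        rr <- suppressWarnings(vapply(seq_len(k), function(f)
          stats::cor(refit$G[, f], fit$G[, g]), numeric(1)))
        if (max(rr, na.rm = TRUE) >= r_threshold) hits[g] <- hits[g] + 1L
      }
    }
    cold_rate <- hits / n_replicates
    fits[[i]] <<- fit; boots[[i]] <<- bt
    mbr <- min(bt$factor_mapping_rate)
    mcr <- min(cold_rate)
    Fn <- fit$F / sqrt(rowSums(fit$F^2))
    cosF <- tcrossprod(Fn)
    mpc <- if (k > 1L) max(cosF[upper.tri(cosF)]) else 0
    data.frame(k = k, Q = fit$Q, Q_expected = fit$Q_expected,
               q_ratio = fit$Q / fit$Q_expected,
               min_boot_rate = mbr, min_cold_rate = mcr,
               max_profile_cos = mpc,
               stable = is.finite(mbr) && mbr >= stability &&
                 mcr >= stability && mpc <= distinct_cos)
  })
  tab <- do.call(rbind, rows)
  worst <- pmin(tab$min_boot_rate, tab$min_cold_rate,
                1 - pmax(tab$max_profile_cos - 0.85, 0))
  chosen <- if (any(tab$stable)) max(tab$k[tab$stable])
            else tab$k[which.max(worst)]
  list(k = chosen, table = tab, fits = stats::setNames(fits, ks),
       bootstraps = stats::setNames(boots, ks))
}

#' Percent contribution of each species to each factor
#'
#' The mass of variable `j` attributed to factor `g` is
#' `colSums(G)[g] * F[g, j]`; percentages normalize each variable's column so
#' factors sum to 100 per species (`sum of factors = 100%`).
#'
#' @param solution a [fit_pmf()] result.
#' @return `k x n_variables` matrix of percentages; a variable with zero
#'   attributed mass yields `NA` in its column.
#' @export
species_percent_profile <- function(solution) {
  mass <- solution$F * colSums(solution$G)  # recycles columnwise: k x m
  tot <- colSums(mass)
  out <- sweep(mass, 2L, tot, "/") * 100
  out[, tot <= 0] <- NA_real_
  dimnames(out) <- list(paste0("factor", seq_len(nrow(out))),
                        colnames(solution$F))
  out
}

#' Nodes contributing most to each factor
#'
#' Normalizes each node's contributions to sum 1 and, per factor, returns the
#' nodes whose normalized contribution exceeds the factor's `q`-quantile.
#'
#' @param solution a [fit_pmf()] result.
#' @param q quantile in (0, 1), default 0.9.
#' @return List (length k) of integer node-index vectors.
#' @export
top_nodes_per_factor <- function(solution, q = 0.9) {
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  rs <- rowSums(solution$G)
  rs[rs <= 0] <- Inf  # nodes with no mass can top nothing
  R <- solution$G / rs
  lapply(seq_len(solution$k), function(g) {
    thr <- stats::quantile(R[, g], q, names = FALSE)
    which(R[, g] > thr)
  })
}

#' Cross-tabulate factor top nodes against codebook clusters
#'
#' Shows where each factor's top-contributing nodes sit in the air-type
#' clustering, the link used to interpret factors as sources.
#'
#' @param solution a [fit_pmf()] result.
#' @param labels per-node cluster ids aligned with the rows of `G`.
#' @param q top-node quantile (see [top_nodes_per_factor()]).
#' @return List with `counts` (k x n_clusters) and `percent` (row
#'   percentages).
#' @export
factor_cluster_crosstab <- function(solution, labels, q = 0.9) {
  if (length(labels) != nrow(solution$G))
    stop("labels length (", length(labels), ") does not match node count (",
         nrow(solution$G), ")")
  tops <- top_nodes_per_factor(solution, q)
  ids <- sort(unique(labels))
  counts <- matrix(0L, solution$k, length(ids),
                   dimnames = list(paste0("factor", seq_len(solution$k)),
                                   paste0("cluster", ids)))
  for (g in seq_len(solution$k))
    for (ci in seq_along(ids))
      counts[g, ci] <- sum(labels[tops[[g]]] == ids[ci])
  rs <- rowSums(counts)
  percent <- counts / ifelse(rs == 0, 1, rs) * 100
  list(counts = counts, percent = percent)
}
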