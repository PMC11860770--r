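#' Ward hierarchical clustering of a codebook
#'
#' Agglomerative clustering of the node vectors with Euclidean distances and
#' Ward's minimum-variance criterion (the `ward.D2` convention: merge heights
#' live on the distance scale, so two singletons merge at their Euclidean
#' distance).  Heights are non-decreasing along the merge sequence.
#'
#' @param codebook codebook matrix (n_nodes x n_variables) or a `som_model`.
#' @return An object of class `aq_linkage` wrapping the `stats::hclust` tree
#'   (`merge`, `height`, `order`).
#' @export
ward_linkage <- function(codebook) {
  if (inherits(codebook, "som_model")) codebook <- codebook$codebook
  M <- as.matrix(codebook)
  if (nrow(M) < 2L) stop("need at least 2 nodes to cluster")
  if (anyNA(M) || any(!is.finite(M))) stop("codebook contains non-finite values")
  hc <- stats::hclust(stats::dist(M), method = "ward.D2")
  structure(list(hclust = hc, n_nodes = nrow(M)), class = "aq_linkage")
}

#' @export
print.aq_linkage <- function(x, ...) {
  cat("<aq_linkage> Ward (D2) tree over ", x$n_nodes, " nodes, max height ",
      signif(max(x$hclust$height), 4), "\n", sep = "")
  invisible(x)
}

#' Cut a linkage tree into k clusters
#'
#' Labels are renumbered for reproducible reporting: cluster 1 is the largest,
#' ties broken by the smallest member node index.
#'
#' @param tree an [ward_linkage()] result.
#' @param k number of clusters, `1 <= k <= n_nodes`.
#' @return Integer vector of labels in `1..k`, one per node.
#' @export
cut_clusters <- function(tree, k) {
  if (k < 1L || k > tree$n_nodes) stop("k must be between 1 and n_nodes")
  raw <- stats::cutree(tree$hclust, k = k)
  sizes <- tabulate(raw, nbins = k)
  first <- vapply(seq_len(k), function(g) min(which(raw == g)), integer(1))
  new_id <- integer(k)
  new_id[order(-sizes, first)] <- seq_len(k)
  new_id[raw]
}

#' Davies-Bouldin cluster validity index
#'
#' `DB = (1/k) * sum_i max_{j != i} (S_i + S_j) / M_ij` with `S_i` the mean
#' Euclidean distance of cluster members to their centroid and `M_ij` the
#' distance between centroids; lower is better.  Coincident centroids yield
#' `Inf`.
#'
#' @param M data matrix (rows are observations).
#' @param labels integer cluster ids, >= 2 non-empty clusters.
#' @return The index (numeric scalar).
#' @export
davies_bouldin <- function(M, labels) {
  M <- as.matrix(M)
  ids <- sort(unique(labels))
  k <- length(ids)
  if (k < 2L) stop("need at least 2 clusters")
  cent <- do.call(rbind, lapply(ids, function(g)
    colMeans(M[labels == g, , drop = FALSE])))
  S <- vapply(seq_len(k), function(i) {
    mm <- M[labels == ids[i], , drop = FALSE]
    mean(sqrt(rowSums((mm - matrix(cent[i, ], nrow(mm), ncol(M),
                                   byrow = TRUE))^2)))
  }, numeric(1))
  Mc <- as.matrix(stats::dist(cent))
  R <- outer(S, S, "+") / Mc
  diag(R) <- -Inf
  worst <- apply(R, 1L, max)
  if (any(!is.finite(worst))) return(Inf)
  mean(worst)
}

#' Scan cluster counts and select by the Davies-Bouldin index
#'
#' Builds one Ward tree, cuts it at every `k` in `[kmin, kmax]`, scores each
#' partition with [davies_bouldin()], and keeps the `k` with the lowest index
#' (ties broken by the smallest `k`).
#'
#' @param codebook codebook matrix or `som_model`.
#' @param kmin,kmax candidate range, `2 <= kmin <= kmax <= n_nodes`.
#' @return An object of class `cluster_solution`: list with `k`, `labels`,
#'   `centroids` (k x n_variables, exact member means), `db_table`
#'   (data.frame `k`, `db`) and `tree`.
#' @export
select_k <- function(codebook, kmin = 2L, kmax = 10L) {
  if (inherits(codebook, "som_model")) codebook <- codebook$codebook
  M <- as.matrix(codebook)
  if (kmin < 2L || kmin > kmax || kmax > nrow(M))
    stop("need 2 <= kmin <= kmax <= n_nodes")
  tree <- ward_linkage(M)
  ks <- seq.int(kmin, kmax)
  cuts <- lapply(ks, function(k) cut_clusters(tree, k))
  db <- vapply(cuts, function(l) davies_bouldin(M, l), numeric(1))
  best <- which.min(db)  # ties -> smallest k (first index)
  labels <- cuts[[best]]
  centroids <- do.call(rbind, lapply(seq_len(ks[best]), function(g)
    colMeans(M[labels == g, , drop = FALSE])))
  colnames(centroids) <- colnames(M)
  structure(
    list(k = ks[best], labels = labels, centroids = centroids,
         db_table = data.frame(k = ks, db = db), tree = tree),
    class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat("<cluster_solution> k=", x$k, " (Davies-Bouldin ",
      signif(x$db_table$db[x$db_table$k == x$k], 4), ")\n", sep = "")
  cat("  sizes:", paste(tabulate(x$labels, x$k), collapse = ", "), "\n")
  invisible(x)
}

#' Nonparametric tests of cluster differences
#'
#' Per variable: a Kruskal-Wallis test across all clusters (tie-corrected H,
#' chi-square approximation) and all pairwise two-sided Wilcoxon rank-sum
#' tests with Bonferroni correction over the `k*(k-1)/2` comparisons (exact
#' distribution when both groups have <= 20 members and no ties interfere,
#' normal approximation otherwise).  Pairs involving a cluster with fewer
#' than 2 members are reported as `NA` rather than failing.
#'
#' @param M observation matrix (typically the codebook).
#' @param labels integer cluster ids aligned to the rows of `M`.
#' @return An object of class `cluster_tests`: list with `kw_p` (named
#'   per-variable vector), `pairwise` (per-variable list of k x k matrices of
#'   Bonferroni-corrected p-values) and `table` (tidy data.frame).
#' @export
cluster_tests <- function(M, labels) {
  M <- as.matrix(M)
  ids <- sort(unique(labels))
  k <- length(ids)
  if (k < 2L) stop("need at least 2 clusters")
  vars <- colnames(M)
  if (is.null(vars)) vars <- paste0("V", seq_len(ncol(M)))
  m_comp <- k * (k - 1L) / 2L
  kw_p <- vapply(seq_len(ncol(M)), function(j)
    stats::kruskal.test(M[, j], factor(labels))$p.value, numeric(1))
  names(kw_p) <- vars
  pairwise <- vector("list", ncol(M))
  names(pairwise) <- vars
  rows <- list()
  for (j in seq_len(ncol(M))) {
    P <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
    for (a in seq_len(k - 1L)) for (b in seq.int(a + 1L, k)) {
      xa <- M[labels == ids[a], j]
      xb <- M[labels == ids[b], j]
      if (length(xa) < 2L || length(xb) < 2L) { praw <- NA_real_ } else {
        use_exact <- length(xa) <= 20L && length(xb) <= 20L
        praw <- suppressWarnings(
          stats::wilcox.test(xa, xb, exact = use_exact,
                             correct = !use_exact)$p.value)
      }
      pc <- if (is.na(praw)) NA_real_ else min(1, praw * m_comp)
      P[a, b] <- P[b, a] <- pc
      rows[[length(rows) + 1L]] <-
        data.frame(variable = vars[j], cluster_a = ids[a], cluster_b = ids[b],
                   p_raw = praw, p_bonferroni = pc)
    }
    pairwise[[j]] <- P
  }
  structure(list(kw_p = kw_p, pairwise = pairwise,
                 table = do.call(rbind, rows)),
            class = "cluster_tests")
}

#' @export
print.cluster_tests <- function(x, ...) {
  cat("<cluster_tests> Kruskal-Wallis p-values:\n")
  print(signif(x$kw_p, 3))
  sig <- sum(x$table$p_bonferroni < 0.05, na.rm = TRUE)
  cat("  significant pairwise comparisons (Bonferroni < 0.05): ", sig, "/",
      nrow(x$table), "\n", sep = "")
  invisible(x)
}
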