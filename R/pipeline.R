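#' Default per-variable relative PMF uncertainties
#'
#' 10.9% for benzene and toluene, 10% for PM10, 6.2% for NO and NO2 —
#' typical analyser uncertainties for this pollutant panel.
#'
#' @return Named numeric vector over [AQ_VARIABLES].
#' @export
default_uncertainties <- function() {
  c(Ben = 0.109, Tol = 0.109, PM10 = 0.10, NO = 0.062, NO2 = 0.062)
}

#' Run the full SOM / clustering / PMF pipeline on a panel
#'
#' One call chaining the whole elaboration: timestamp intersection and
#' row-completeness filtering, iterative-PCA imputation of the surviving
#' gaps, autoscaling, batch-SOM training, Ward + Davies-Bouldin clustering of
#' the codebook, QE outlier flagging, calendar reports, and
#' uncertainty-weighted PMF (with factor-count scan and bootstrap) on the
#' inverse-autoscaled codebook.  Residual negative concentrations after
#' inverse autoscaling (possible at map borders) are clipped to zero with a
#' recorded count.
#'
#' @param panel an [aq_panel] of raw hourly data.
#' @param grid a [som_grid]; `NULL` sizes the map with
#'   [heuristic_map_size()].
#' @param max_na_per_row row-completeness threshold
#'   (see [intersect_complete_timestamps()]).
#' @param n_components,imp_tol,imp_max_iter imputation controls.
#' @param epochs SOM epochs.
#' @param kmin,kmax cluster-count scan range.
#' @param factors integer vector of PMF factor counts to scan.
#' @param rel_uncertainty per-variable relative uncertainties.
#' @param n_starts,n_boot PMF restarts and bootstrap replicates.
#' @param outlier_k Tukey fence multiplier for QE outliers.
#' @param seed master seed for SOM degenerate fallback, PMF restarts and
#'   bootstrap.
#' @return List with `panel` (cleaned), `scaling`, `som`, `assignment`,
#'   `clusters`, `outlier_flags`, `daily_clusters`, `outliers`,
#'   `codebook_conc` (concentration-scale codebook; attribute
#'   `n_clipped` counts clipped negatives), `uncertainties`, `pmf_scan`,
#'   `pmf` (fit at the chosen factor count), `bootstrap`, `fingerprint`
#'   (species percent profile), `crosstab` (factor x cluster).
#' @export
run_pipeline <- function(panel, grid = NULL, max_na_per_row = 1L,
                         n_components = 2L, imp_tol = 1e-6,
                         imp_max_iter = 100L, epochs = 50L,
                         kmin = 2L, kmax = 10L, factors = 4:6,
                         rel_uncertainty = default_uncertainties(),
                         n_starts = 20L, n_boot = 50L, outlier_k = 1.5,
                         seed = 1L) {
  clean <- intersect_complete_timestamps(panel, max_na_per_row)
  X <- impute_iterative_pca(clean$X, n_components = n_components,
                            tol = imp_tol, max_iter = imp_max_iter)
  sc <- autoscale(X)
  if (is.null(grid))
    grid <- heuristic_map_size(nrow(sc$X), eigen_ratio(sc$X))
  som <- train_batch_som(sc$X, grid, epochs = epochs, seed = seed)
  assignment <- assign_bmu(som$codebook, sc$X)
  clusters <- select_k(som$codebook, kmin = kmin, kmax = kmax)
  flags <- detect_qe_outliers(assignment, k = outlier_k)
  daily <- daily_cluster_fractions(clean, assignment, clusters$labels)
  outliers <- outlier_timeline(clean, assignment, clusters$labels, flags)

  cb <- inverse_autoscale(som$codebook, sc$scaling)
  n_clipped <- sum(cb < 0)
  cb[cb < 0] <- 0
  attr(cb, "n_clipped") <- n_clipped
  U <- build_uncertainties(cb, rel_uncertainty[colnames(cb)])
  scan <- select_factor_count(cb, U, kmin = min(factors), kmax = max(factors),
                              n_starts = n_starts, seed = seed,
                              n_boot = n_boot)
  fit <- scan$fits[[as.character(scan$k)]]
  boot <- scan$bootstraps[[as.character(scan$k)]]
  list(panel = clean, scaling = sc$scaling, som = som,
       assignment = assignment, clusters = clusters, outlier_flags = flags,
       daily_clusters = daily, outliers = outliers, codebook_conc = cb,
       uncertainties = U, pmf_scan = scan, pmf = fit, bootstrap = boot,
       fingerprint = species_percent_profile(fit),
       crosstab = factor_cluster_crosstab(fit, clusters$labels))
}
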