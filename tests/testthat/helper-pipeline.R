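# Shared, memoised end-to-end pipeline runs for the acceptance tests.
# Scaled down relative to the full study (12x8 map instead of 30x20,
# 40 epochs, 10 PMF starts, 30 bootstrap replicates, 5 seeds) to fit the
# test-time budget; all acceptance thresholds are unchanged.

.acc_cache <- new.env(parent = emptyenv())

acceptance_seeds <- function() 1:5

acceptance_run <- function(seed) {
  key <- as.character(seed)
  if (!is.null(.acc_cache[[key]])) return(.acc_cache[[key]])
  sim <- simulate_panel(sim_config(), seed = seed)
  res <- suppressWarnings(
    run_pipeline(sim$panel, grid = som_grid(12, 8), epochs = 40L,
                 n_starts = 10L, n_boot = 30L, seed = seed))
  key_truth <- paste(sim$truth$outlier_hours$site,
                     sim$truth$outlier_hours$timestamp)
  planted <- paste(res$panel$site, res$panel$timestamp) %in% key_truth
  out <- list(sim = sim, res = res, planted = planted)
  .acc_cache[[key]] <- out
  out
}
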