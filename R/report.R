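#' Daily cluster prevalence per site
#'
#' Projects the node clustering back onto calendar time: every sample is
#' labelled with its BMU's cluster, samples are grouped by (site, calendar
#' date), and each cluster's share of the day's retained hours is reported.
#' Days with zero retained hours are absent, not zero-filled, and per-day
#' percentages sum to 100.
#'
#' @param panel the [aq_panel] the assignment was computed on (row order is
#'   the alignment contract).
#' @param assignment a [assign_bmu()] result aligned to `panel` rows.
#' @param labels per-node cluster ids aligned to codebook node order.
#' @return data.frame with columns `site`, `date`, `cluster`, `n_hours`,
#'   `percent`.
#' @export
daily_cluster_fractions <- function(panel, assignment, labels) {
  if (length(assignment$bmu) != n_samples(panel))
    stop("assignment is not aligned with the panel rows")
  if (max(assignment$bmu) > length(labels))
    stop("labels do not cover all nodes referenced by the assignment")
  cl <- labels[assignment$bmu]
  date <- substr(panel$timestamp, 1L, 10L)
  agg <- as.data.frame(table(site = panel$site, date = date, cluster = cl),
                       stringsAsFactors = FALSE)
  agg <- agg[agg$Freq > 0L, ]
  names(agg)[4L] <- "n_hours"
  day_tot <- stats::aggregate(n_hours ~ site + date, agg, sum)
  names(day_tot)[3L] <- "day_hours"
  out <- merge(agg, day_tot, by = c("site", "date"))
  out$percent <- 100 * out$n_hours / out$day_hours
  out$cluster <- as.integer(out$cluster)
  out <- out[order(out$site, out$date, out$cluster),
             c("site", "date", "cluster", "n_hours", "percent")]
  rownames(out) <- NULL
  out
}

#' Timeline of flagged outlier samples
#'
#' Lists every sample flagged by [detect_qe_outliers()] with its site,
#' timestamp, quantization error and the air-type cluster of its BMU, ready
#' to be split by site and year.
#'
#' @param panel the [aq_panel] (alignment reference).
#' @param assignment a [assign_bmu()] result aligned to `panel` rows.
#' @param labels per-node cluster ids.
#' @param flags logical vector from [detect_qe_outliers()], aligned to
#'   `panel` rows.
#' @return data.frame with columns `site`, `timestamp`, `qe`, `cluster`,
#'   one row per flagged sample (possibly zero rows).
#' @export
outlier_timeline <- function(panel, assignment, labels, flags) {
  n <- n_samples(panel)
  if (length(assignment$bmu) != n || length(flags) != n)
    stop("assignment/flags are not aligned with the panel rows")
  if (max(assignment$bmu) > length(labels))
    stop("labels do not cover all nodes referenced by the assignment")
  idx <- which(flags)
  out <- data.frame(site = panel$site[idx], timestamp = panel$timestamp[idx],
                    qe = assignment$qe[idx],
                    cluster = labels[assignment$bmu[idx]])
  rownames(out) <- NULL
  out
}
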