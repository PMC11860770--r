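#' Specify a synthetic emission source
#'
#' @param name source name.
#' @param profile nonnegative vector over the five pollutants
#'   ([AQ_VARIABLES] order); normalized internally to unit sum.
#' @param base_level mean contribution (native concentration units).
#' @param diurnal_amplitude relative amplitude of the daily cycle in `[0, 1)`.
#' @param diurnal_peak hour of day (0-23) at which the cycle peaks.
#' @param site_weights named nonnegative multipliers, one per site.
#' @param year_weights named nonnegative multipliers, one per simulated year.
#' @return An object of class `source_spec`.
#' @export
source_spec <- function(name, profile, base_level, diurnal_amplitude = 0,
                        diurnal_peak = 12, site_weights = NULL,
                        year_weights = NULL) {
  profile <- as.numeric(profile)
  if (length(profile) != length(AQ_VARIABLES) || any(profile < 0) ||
      sum(profile) <= 0)
    stop("profile must be a nonnegative vector over the 5 pollutants")
  if (base_level < 0) stop("base_level must be >= 0")
  if (diurnal_amplitude < 0 || diurnal_amplitude >= 1)
    stop("diurnal_amplitude must be in [0, 1)")
  if (!is.null(site_weights) && any(site_weights < 0))
    stop("site_weights must be >= 0")
  if (!is.null(year_weights) && any(year_weights < 0))
    stop("year_weights must be >= 0")
  structure(list(name = name, profile = profile / sum(profile),
                 base_level = base_level,
                 diurnal_amplitude = diurnal_amplitude,
                 diurnal_peak = diurnal_peak,
                 site_weights = site_weights, year_weights = year_weights),
            class = "source_spec")
}

#' Default planted source set
#'
#' Five sources chosen to emulate the taxonomy recovered from urban panels of
#' this kind: road traffic (NO-dominant with NO2), an industrial hydrocarbon
#' source active at one site only (benzene/toluene), a near-pure PM10 dust
#' source, aged combustion (NO2 + PM10), and a mixed PM10/hydrocarbon
#' source.  One simulated year applies a 0.2 multiplier to the traffic
#' source, the mobility-restriction (lockdown) analogue.
#'
#' @param sites site names (first letter `A` = traffic, `B` = background).
#' @param years simulated years.
#' @param lockdown_year the year receiving the traffic multiplier.
#' @return List of [source_spec] objects.
#' @export
default_sources <- function(sites = c("A1", "A2", "B1", "B2"),
                            years = 2018:2023, lockdown_year = 2020) {
  w <- function(vals) stats::setNames(vals, sites)
  traffic_site <- startsWith(sites, "A")
  yw <- stats::setNames(rep(1, length(years)), years)
  yw_traffic <- yw
  if (as.character(lockdown_year) %in% names(yw_traffic))
    yw_traffic[as.character(lockdown_year)] <- 0.2
  list(
    source_spec("traffic", c(0.02, 0.03, 0.10, 0.55, 0.30),
                base_level = 25, diurnal_amplitude = 0.2, diurnal_peak = 8,
                site_weights = w(ifelse(traffic_site, 1, 0.7)),
                year_weights = yw_traffic),
    source_spec("industrial_hc", c(0.40, 0.45, 0.05, 0.02, 0.08),
                base_level = 12, diurnal_amplitude = 0.15, diurnal_peak = 12,
                site_weights = w(ifelse(sites == sites[1L], 1, 0.15)),
                year_weights = yw),
    source_spec("dust", c(0.005, 0.005, 0.965, 0.005, 0.02),
                base_level = 15, diurnal_amplitude = 0.05, diurnal_peak = 12,
                site_weights = w(rep(1, length(sites))), year_weights = yw),
    source_spec("aged", c(0.02, 0.05, 0.15, 0.03, 0.75),
                base_level = 16, diurnal_amplitude = 0.1, diurnal_peak = 3,
                site_weights = w(ifelse(traffic_site, 0.9, 1.2)),
                year_weights = yw),
    # toluene-rich solvent-type hydrocarbons with PM10: keeps the source
    # outside the convex hull of the other four profiles
    source_spec("mixed", c(0.08, 0.38, 0.38, 0.03, 0.13),
                base_level = 10, diurnal_amplitude = 0.1, diurnal_peak = 12,
                site_weights = w(rep(1, length(sites))), year_weights = yw))
}

#' Default activity regimes of the synthetic world
#'
#' Regime activity multipliers (regimes x sources) and per-site-type
#' occurrence probabilities.  The six regimes are the planted "air types":
#' background, traffic peak, industrial episode, elevated dust, stagnant
#' aged air, and a mixed-source episode.
#'
#' @return List with `activity` (6 x 5 multiplier matrix) and `probs`
#'   (regime probabilities for traffic and background sites).
#' @export
default_regimes <- function() {
  act <- rbind(
    background    = c(0.25, 0.20, 0.30, 0.35, 0.30),
    traffic_peak  = c(6.00, 0.20, 0.20, 0.20, 0.20),
    industrial    = c(0.20, 5.00, 0.20, 0.20, 0.20),
    dust_high     = c(0.20, 0.20, 2.80, 0.20, 0.20),
    aged_stagnant = c(0.20, 0.20, 0.20, 5.00, 0.20),
    mixed_episode = c(0.20, 0.20, 0.20, 0.20, 8.00))
  colnames(act) <- c("traffic", "industrial_hc", "dust", "aged", "mixed")
  probs <- list(
    traffic    = c(0.30, 0.24, 0.10, 0.12, 0.12, 0.12),
    background = c(0.40, 0.12, 0.06, 0.14, 0.14, 0.14))
  list(activity = act, probs = probs)
}

#' Generator settings for the synthetic multisite panel
#'
#' The defaults state the emulated world: 4 sites (2 "traffic", 2
#' "background"), six simulated 8-week spring windows (2018-2023, starting
#' 9 March), hourly sampling, 5 planted sources driven by 6 discrete
#' activity regimes, multiplicative lognormal noise (sigma = 0.15), 2%
#' missing cells completely at random, about 15 dust episodes of 6-24 h with
#' PM10 contributions 5-15x the dust base level, and a 0.2 traffic
#' multiplier in 2020.
#'
#' @param sites site identifiers; first letter `A` marks a traffic site,
#'   `B` a background site.
#' @param years simulated years (labels only; each contributes one window).
#' @param weeks_per_year length of each yearly window in weeks.
#' @param start_month_day `"MM-DD"` start of each window.
#' @param sources list of [source_spec]; default [default_sources()].
#' @param regimes list with `activity` (regime x source multipliers) and
#'   `probs` (per site type); default [default_regimes()].
#' @param noise_sd lognormal noise sigma.
#' @param within_regime_sd lognormal spread of source activity within a
#'   regime.
#' @param missing_rate MCAR missing-cell probability.
#' @param n_dust_events number of injected dust episodes.
#' @param dust_event_hours min/max episode duration (hours).
#' @param dust_event_scale min/max PM10 contribution multiple of the dust
#'   base level.
#' @param lockdown_year year whose traffic source is damped (bookkeeping;
#'   the damping itself lives in the traffic source's `year_weights`).
#' @return A list of validated settings (class `sim_config`).
#' @export
sim_config <- function(sites = c("A1", "A2", "B1", "B2"),
                       years = 2018:2023,
                       weeks_per_year = 8L,
                       start_month_day = "03-09",
                       sources = NULL,
                       regimes = default_regimes(),
                       noise_sd = 0.15,
                       within_regime_sd = 0.10,
                       missing_rate = 0.02,
                       n_dust_events = 15L,
                       dust_event_hours = c(6L, 24L),
                       dust_event_scale = c(5, 15),
                       lockdown_year = 2020) {
  if (length(sites) < 1L || anyDuplicated(sites)) stop("invalid site list")
  if (!all(startsWith(sites, "A") | startsWith(sites, "B")))
    stop("unknown site type: site names must start with 'A' (traffic) ",
         "or 'B' (background)")
  if (is.null(sources)) sources <- default_sources(sites, years, lockdown_year)
  for (s in sources) {
    if (!all(sites %in% names(s$site_weights)))
      stop("source '", s$name, "' lacks site_weights for some sites")
    if (!all(as.character(years) %in% names(s$year_weights)))
      stop("source '", s$name, "' lacks year_weights for some years")
  }
  if (noise_sd < 0 || missing_rate < 0 || missing_rate >= 1)
    stop("invalid noise_sd or missing_rate")
  if (ncol(regimes$activity) != length(sources))
    stop("regime activity matrix must have one column per source")
  if (any(abs(vapply(regimes$probs, sum, numeric(1)) - 1) > 1e-8))
    stop("regime probabilities must sum to 1")
  structure(list(sites = sites, years = years,
                 weeks_per_year = as.integer(weeks_per_year),
                 start_month_day = start_month_day, sources = sources,
                 regimes = regimes, noise_sd = noise_sd,
                 within_regime_sd = within_regime_sd,
                 missing_rate = missing_rate,
                 n_dust_events = as.integer(n_dust_events),
                 dust_event_hours = as.integer(dust_event_hours),
                 dust_event_scale = dust_event_scale,
                 lockdown_year = lockdown_year),
            class = "sim_config")
}

#' Simulate a multisite hourly pollutant panel with known structure
#'
#' Generates `X = (G_true %*% profiles) * exp(eps)` with
#' `eps ~ N(0, noise_sd)` i.i.d.: each site-hour draws a discrete activity
#' regime (site-type dependent probabilities), the regime multiplies the
#' sources' base contributions, and sources are further modulated by site,
#' year and hour-of-day.  Dust episodes overwrite the dust-source
#' contribution for 6-24 consecutive hours at 5-15x its base level; their
#' positions are recorded as the planted outliers.  Missing cells are then
#' injected completely at random.  Fully deterministic given `seed`.
#'
#' @param config a [sim_config()].
#' @param seed integer RNG seed.
#' @return List with `panel` (an [aq_panel]) and `truth` (class `aq_truth`):
#'   `profiles` (source x pollutant), `G_true` (row-aligned with the panel,
#'   dust episodes included), `regime` (per-row regime id), `n_regimes`,
#'   `outlier_hours` (data.frame site/timestamp), `missing_mask`, `sources`,
#'   `config`.
#' @export
simulate_panel <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  sites <- sort(config$sites)  # aq_panel keeps (site, timestamp) order
  years <- config$years
  n_days <- config$weeks_per_year * 7L
  dates <- unlist(lapply(years, function(y)
    format(as.Date(paste0(y, "-", config$start_month_day)) +
             seq_len(n_days) - 1L)))
  ts_year <- rep(rep(substr(dates, 1L, 4L), each = 24L), times = 1L)
  stamps <- paste0(rep(dates, each = 24L),
                   sprintf("T%02d:00", rep(0:23, times = length(dates))))
  hours <- rep(0:23, times = length(dates))
  n_t <- length(stamps)
  n_site <- length(sites)
  n_src <- length(config$sources)
  src_names <- vapply(config$sources, `[[`, character(1), "name")
  profiles <- t(vapply(config$sources, `[[`, numeric(length(AQ_VARIABLES)),
                       "profile"))
  dimnames(profiles) <- list(src_names, AQ_VARIABLES)

  with_seed(seed, {
    site_v <- rep(sites, each = n_t)
    ts_v <- rep(stamps, times = n_site)
    hour_v <- rep(hours, times = n_site)
    year_v <- rep(ts_year, times = n_site)
    n <- n_t * n_site
    type_v <- ifelse(startsWith(site_v, "A"), "traffic", "background")
    n_reg <- nrow(config$regimes$activity)
    regime <- integer(n)
    for (tp in unique(type_v)) {
      sel <- type_v == tp
      regime[sel] <- sample.int(n_reg, sum(sel), replace = TRUE,
                                prob = config$regimes$probs[[tp]])
    }
    G <- matrix(0, n, n_src, dimnames = list(NULL, src_names))
    for (s in seq_len(n_src)) {
      sp <- config$sources[[s]]
      diurnal <- 1 + sp$diurnal_amplitude *
        cos(2 * pi * (hour_v - sp$diurnal_peak) / 24)
      G[, s] <- sp$base_level * sp$site_weights[site_v] *
        sp$year_weights[year_v] * diurnal *
        config$regimes$activity[regime, s] *
        exp(stats::rnorm(n, 0, config$within_regime_sd))
    }
    # dust episodes: contiguous hours with the dust source forced high
    dust_col <- which(src_names == "dust")
    outlier_rows <- integer(0)
    if (config$n_dust_events > 0L && length(dust_col) == 1L) {
      dur <- sample(seq(config$dust_event_hours[1L],
                        config$dust_event_hours[2L]),
                    config$n_dust_events, replace = TRUE)
      ev_site <- sample(sites, config$n_dust_events, replace = TRUE)
      ev_start <- sample.int(n_t, config$n_dust_events, replace = TRUE)
      ev_scale <- stats::runif(config$n_dust_events,
                               config$dust_event_scale[1L],
                               config$dust_event_scale[2L])
      base_dust <- config$sources[[dust_col]]$base_level
      for (e in seq_len(config$n_dust_events)) {
        t_idx <- ev_start[e]:min(ev_start[e] + dur[e] - 1L, n_t)
        rows <- (match(ev_site[e], sites) - 1L) * n_t + t_idx
        G[rows, dust_col] <- ev_scale[e] * base_dust *
          exp(stats::rnorm(length(rows), 0, 0.1))
        outlier_rows <- c(outlier_rows, rows)
      }
      outlier_rows <- sort(unique(outlier_rows))
    }
    X_clean <- G %*% profiles
    X <- X_clean * exp(matrix(stats::rnorm(n * ncol(profiles), 0,
                                           config$noise_sd),
                              n, ncol(profiles)))
    mask <- matrix(stats::runif(length(X)) < config$missing_rate,
                   n, ncol(X))
    X[mask] <- NA_real_
  })

  panel <- aq_panel(ts_v, site_v, X)
  # rows were generated in (site, timestamp) order already; verify alignment
  stopifnot(identical(panel$site, site_v), identical(panel$timestamp, ts_v))
  truth <- structure(
    list(profiles = profiles, G_true = G, regime = regime,
         n_regimes = nrow(config$regimes$activity),
         regime_names = rownames(config$regimes$activity),
         outlier_hours = data.frame(site = site_v[outlier_rows],
                                    timestamp = ts_v[outlier_rows]),
         outlier_rows = outlier_rows,
         missing_mask = mask, sources = config$sources,
         lockdown_year = config$lockdown_year, config = config),
    class = "aq_truth")
  list(panel = panel, truth = truth)
}

#' @export
print.aq_truth <- function(x, ...) {
  cat("<aq_truth> ", nrow(x$G_true), " site-hours, ",
      nrow(x$profiles), " planted sources, ", x$n_regimes,
      " regimes, ", nrow(x$outlier_hours), " outlier hours\n", sep = "")
  invisible(x)
}
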