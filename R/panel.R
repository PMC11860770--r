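#' Canonical pollutant variable order
#'
#' Every matrix in the pipeline keeps its five columns in this fixed order:
#' benzene, toluene, PM10, nitrogen monoxide, nitrogen dioxide.
#'
#' @format Character vector of length 5.
#' @export
AQ_VARIABLES <- c("Ben", "Tol", "PM10", "NO", "NO2")

default_variable_map <- function() {
  c(datetime = "datetime", site = "site",
    Ben = "ben", Tol = "tol", PM10 = "pm10", NO = "no", NO2 = "no2")
}

#' Construct an hourly multisite pollutant panel
#'
#' An `aq_panel` holds one row per (site, hour) with the five pollutant
#' concentrations in native units.  Rows are kept sorted by (site, timestamp)
#' and this order is the reference for every downstream per-sample artifact
#' (BMU assignments, quantization errors, outlier flags).
#'
#' @param timestamp character vector of ISO-8601 hours (`YYYY-MM-DDTHH:MM`),
#'   treated as naive local time.
#' @param site character vector of site identifiers (e.g. `"A1"`).
#' @param X numeric matrix, rows aligned with `timestamp`/`site`, columns the
#'   five pollutants in [AQ_VARIABLES] order.  `NA` marks a missing value;
#'   observed values must be nonnegative.
#' @return An object of class `aq_panel`: a list with elements `timestamp`,
#'   `site`, `X` and `variable_names`.
#' @export
aq_panel <- function(timestamp, site, X) {
  timestamp <- as.character(timestamp)
  site <- as.character(site)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (length(timestamp) != nrow(X) || length(site) != nrow(X))
    stop("timestamp, site and X must have the same number of rows")
  if (ncol(X) != length(AQ_VARIABLES))
    stop("X must have ", length(AQ_VARIABLES), " columns (",
         paste(AQ_VARIABLES, collapse = ", "), ")")
  colnames(X) <- AQ_VARIABLES
  key <- paste(site, timestamp, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicated (site, timestamp) pair: ",
         sub("\r", " @ ", key[duplicated(key)][1L]))
  if (any(X < 0, na.rm = TRUE))
    stop("negative concentrations are not allowed; mark them missing instead")
  ord <- order(site, timestamp)
  structure(
    list(timestamp = timestamp[ord], site = site[ord],
         X = X[ord, , drop = FALSE], variable_names = AQ_VARIABLES),
    class = "aq_panel")
}

#' @export
print.aq_panel <- function(x, ...) {
  cat("<aq_panel> ", nrow(x$X), " site-hours, ",
      length(unique(x$site)), " sites (",
      paste(sort(unique(x$site)), collapse = ", "), ")\n", sep = "")
  cat("  variables: ", paste(x$variable_names, collapse = ", "), "\n", sep = "")
  cat("  span: ", min(x$timestamp), " .. ", max(x$timestamp), "\n", sep = "")
  cat("  missing cells: ", sum(is.na(x$X)), "\n", sep = "")
  invisible(x)
}

#' Number of rows (site-hours) in a panel
#' @param x an `aq_panel`.
#' @export
n_samples <- function(x) nrow(x$X)

#' Read an hourly pollutant panel from CSV
#'
#' Expects a header row and (by default) columns
#' `datetime,site,ben,tol,pm10,no,no2`, comma separated, decimal point.
#' Empty cells, `NA`, and any unparseable numeric cell become missing values.
#' Negative readings (instrument error codes) are converted to missing with a
#' warning.
#'
#' @param path path to the CSV file.
#' @param variable_map named character vector mapping the internal names
#'   (`datetime`, `site`, `Ben`, `Tol`, `PM10`, `NO`, `NO2`) to the column
#'   names used in the file.  Defaults to the lower-case convention above.
#' @return An [aq_panel].
#' @export
read_hourly_panel <- function(path, variable_map = default_variable_map()) {
  dm <- default_variable_map()
  dm[names(variable_map)] <- variable_map
  variable_map <- dm
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  if (nrow(raw) == 0L) stop("empty input: no data rows in ", path)
  missing_cols <- setdiff(unname(variable_map), names(raw))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  num <- function(v) {
    v[v %in% c("", "NA", "NaN", "n/a", "N/A")] <- NA_character_
    suppressWarnings(as.numeric(v))
  }
  X <- sapply(AQ_VARIABLES, function(nm) num(raw[[variable_map[[nm]]]]))
  X <- matrix(X, nrow = nrow(raw), dimnames = list(NULL, AQ_VARIABLES))
  if (any(X < 0, na.rm = TRUE)) {
    warning(sum(X < 0, na.rm = TRUE),
            " negative concentration value(s) set to missing")
    X[!is.na(X) & X < 0] <- NA_real_
  }
  ts <- raw[[variable_map[["datetime"]]]]
  if (any(is.na(ts)) || any(!grepl("^\\d{4}-\\d{2}-\\d{2}[T ]\\d{2}:\\d{2}", ts)))
    stop("unparseable datetime values; expected ISO-8601 'YYYY-MM-DDTHH:MM'")
  ts <- sub(" ", "T", ts)
  site <- raw[[variable_map[["site"]]]]
  key <- paste(site, ts, sep = "\r")
  if (anyDuplicated(key)) {
    # keep the first occurrence of DST-style duplicates
    dup <- duplicated(key)
    if (sum(dup) > 0.01 * length(key))
      stop("duplicated (site, timestamp) pair: ",
           sub("\r", " @ ", key[dup][1L]))
    ts <- ts[!dup]; site <- site[!dup]; X <- X[!dup, , drop = FALSE]
  }
  aq_panel(ts, site, X)
}

#' Write a panel back to the canonical CSV dialect
#'
#' @param panel an [aq_panel].
#' @param path output path.
#' @param digits significant digits for concentrations.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, digits = 6L) {
  df <- data.frame(datetime = panel$timestamp, site = panel$site,
                   signif(panel$X, digits), check.names = FALSE)
  names(df) <- c("datetime", "site", tolower(AQ_VARIABLES))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Keep only timestamps complete at every site
#'
#' Retains exactly the date-time combinations for which each site has a row
#' passing the row-completeness rule (at most `max_na_per_row` missing
#' values).  With `max_na_per_row = 0` this is the strict reading "drop every
#' row containing an unavailable value, then intersect timestamps"; the
#' default 1 lets single-pollutant gaps survive so they can be imputed.
#'
#' @param panel an [aq_panel] with at least one site.
#' @param max_na_per_row maximum number of missing values a row may carry and
#'   still count as present.
#' @return The filtered [aq_panel]; after the call every site has the same
#'   number of rows and `nrow = n_sites * n_common_timestamps`.
#' @export
intersect_complete_timestamps <- function(panel, max_na_per_row = 1L) {
  sites <- unique(panel$site)
  if (length(sites) < 1L) stop("panel has no sites")
  ok_row <- rowSums(is.na(panel$X)) <= max_na_per_row
  # a timestamp survives iff every site has a passing row for it
  keep_ts <- Reduce(intersect, lapply(sites, function(s) {
    panel$timestamp[panel$site == s & ok_row]
  }))
  if (length(keep_ts) == 0L)
    stop("no timestamp is complete at all ", length(sites),
         " sites; consider relaxing max_na_per_row")
  keep <- ok_row & panel$timestamp %in% keep_ts
  aq_panel(panel$timestamp[keep], panel$site[keep],
           panel$X[keep, , drop = FALSE])
}
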