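#' Canonical registry of annual fire-weather metrics
#'
#' One row per metric: index, annual summary, and the canonical metric name.
#' The 7-, 15- and 31-day running-mean maxima are computed for all indices
#' except DC (seasonal mean) and DSR (seasonal sum, "cDSR"); p95 summaries
#' are kept for FWI and VPD, plus the season length and start date. Registry
#' order is the deterministic tie-break order for predictor selection.
#'
#' @return A data.frame with columns `metric`, `index`, `summary`.
#' @export
metric_registry <- function() {
  idx <- c("ffmc", "dmc", "isi", "bui", "fwi", "vpd")
  rbind(
    data.frame(metric = paste0(toupper(rep(idx, each = 3)), "_",
                               rep(c("7X", "15X", "31X"), times = length(idx))),
               index = rep(idx, each = 3),
               summary = rep(c("7X", "15X", "31X"), times = length(idx))),
    data.frame(metric = c("DC_season", "cDSR_season", "FWI_p95", "VPD_p95",
                          "season_length", "season_start"),
               index = c("dc", "dsr", "fwi", "vpd", "season", "season"),
               summary = c("mean", "sum", "p95", "p95", "length", "start"))
  )
}

#' Fire-season maximum of running means
#'
#' Maximum over all windows fully contained in the season of the window
#' arithmetic mean. A season shorter than the window falls back to the mean
#' of the whole season.
#'
#' @param x In-season daily values.
#' @param window Window length in days (7, 15 or 31 in the registry; any
#'   >= 1 accepted).
#' @return The running-mean maximum, or `NA` for an empty season.
#' @export
running_mean_max <- function(x, window) {
  stopifnot(window >= 1)
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) return(NA_real_)
  if (n < window) return(mean(x))
  rm <- stats::filter(x, rep(1 / window, window), sides = 1)
  max(rm[window:n])
}

#' Seasonal aggregate (mean or sum) of in-season daily values
#'
#' @param x In-season daily values.
#' @param mode `"mean"` or `"sum"`.
#' @return The aggregate, or `NA` for an empty season.
#' @export
season_aggregate <- function(x, mode = c("mean", "sum")) {
  mode <- match.arg(mode)
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  if (mode == "mean") mean(x) else sum(x)
}

#' Percentile of in-season daily values
#'
#' Uses the package-wide linear-interpolation convention ([percentile()]).
#'
#' @param x In-season daily values.
#' @param p Percentile in (0, 100).
#' @return The percentile, or `NA` for an empty season.
#' @export
percentile_metric <- function(x, p = 95) percentile(x, p)

#' Area-weighted regional mean over forested cells
#'
#' @param values Per-cell values.
#' @param cell_area Per-cell areas (km^2), proportional to cos(latitude).
#' @param forest_mask Logical per-cell forest mask.
#' @param region_labels Integer region label per cell.
#' @param region The region to average over.
#' @return `sum(area_i * v_i) / sum(area_i)` over the region's forested
#'   cells. `NA` values are excluded with their weights; all-`NA` gives `NA`.
#' @export
regional_mean <- function(values, cell_area, forest_mask, region_labels, region) {
  sel <- forest_mask & region_labels == region
  if (!any(sel)) {
    stop(sprintf("region %s has no forested cells", region), call. = FALSE)
  }
  v <- values[sel]
  w <- cell_area[sel]
  ok <- !is.na(v)
  if (!any(ok)) return(NA_real_)
  sum(w[ok] * v[ok]) / sum(w[ok])
}

#' Annual metrics for one region-year of daily index series
#'
#' @param daily A data.frame of daily regional-mean index values with
#'   columns `ffmc`, `dmc`, `dc`, `isi`, `bui`, `fwi`, `dsr`, `vpd`
#'   (`NA` outside the season).
#' @param season The region's [fire_season_window()].
#' @return A named numeric vector over [metric_registry()] rows.
#' @export
annual_metrics_one <- function(daily, season) {
  reg <- metric_registry()
  out <- stats::setNames(rep(NA_real_, nrow(reg)), reg$metric)
  out["season_length"] <- season$length
  out["season_start"] <- if (is.null(season$start_day)) NA_real_ else season$start_day
  if (season$length == 0L) return(out)
  days <- seq(season$start_day, min(season$end_day, nrow(daily)))
  for (i in seq_len(nrow(reg))) {
    if (reg$index[i] == "season") next
    x <- daily[[reg$index[i]]][days]
    out[reg$metric[i]] <- switch(
      reg$summary[i],
      "7X" = running_mean_max(x, 7L),
      "15X" = running_mean_max(x, 15L),
      "31X" = running_mean_max(x, 31L),
      mean = season_aggregate(x, "mean"),
      sum = season_aggregate(x, "sum"),
      p95 = percentile_metric(x, 95)
    )
  }
  out
}

#' Base-period anomalies for an annual metric table
#'
#' Adds an `anomaly` column: the value minus the base-period mean of the
#' designated baseline series, computed per (region, metric) across all
#' realizations. With `baseline = NULL` the table is its own baseline; a
#' paired baseline (e.g. the historical-forcing table for a natural-forcing
#' table) preserves the factual-counterfactual offset.
#'
#' @param table A data.frame with columns `region`, `year`, `metric`,
#'   `value` (and optionally `realization`).
#' @param base_years Integer vector of base-period years (all must be
#'   present in the baseline).
#' @param baseline Optional paired baseline table with the same columns.
#' @return `table` with an `anomaly` column added.
#' @export
compute_anomalies <- function(table, base_years, baseline = NULL) {
  src <- if (is.null(baseline)) table else baseline
  if (!all(base_years %in% src$year)) {
    stop("base years missing from the baseline table", call. = FALSE)
  }
  base <- src[src$year %in% base_years, ]
  bm <- stats::aggregate(value ~ region + metric, data = base, FUN = mean,
                         na.action = stats::na.omit)
  names(bm)[names(bm) == "value"] <- "base_mean"
  merged <- merge(table, bm, by = c("region", "metric"), all.x = TRUE, sort = FALSE)
  merged$anomaly <- merged$value - merged$base_mean
  merged$base_mean <- NULL
  merged
}
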