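#' Local base-period FWI thresholds per cell
#'
#' The p-th percentile of in-season daily FWI over the base-period years,
#' computed per cell with the package-wide linear-interpolation percentile
#' convention. Off-season days must already be `NA` in `daily_fwi`. Cells
#' with no in-season base-period days get an `NA` threshold and are excluded
#' downstream.
#'
#' @param daily_fwi Matrix of daily FWI, time x cell, `NA` outside the fire
#'   season.
#' @param years Year of each row of `daily_fwi`.
#' @param base_years Base-period years (e.g. the first common 30 years).
#' @param p Percentile (default 95).
#' @return Numeric vector of per-cell thresholds (possibly `NA`).
#' @export
local_threshold <- function(daily_fwi, years, base_years, p = 95) {
  stopifnot(nrow(daily_fwi) == length(years))
  rows <- years %in% base_years
  if (!any(rows)) stop("no base-period rows in daily_fwi", call. = FALSE)
  apply(daily_fwi[rows, , drop = FALSE], 2L, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) NA_real_ else percentile(x, p)
  })
}

#' Cumulative high fire-risk area for one year
#'
#' Sums, over every in-season day of the year, the area of forested cells
#' whose daily FWI strictly exceeds their local base-period threshold. The
#' result is in km^2 x days: the seasonal accumulation of synchronous
#' extreme fire weather. Cells with `NA` thresholds are excluded.
#'
#' @param daily_fwi Matrix of daily FWI for one year, day x cell, `NA`
#'   outside each cell's fire season.
#' @param thresholds Per-cell thresholds from [local_threshold()].
#' @param cell_area Per-cell areas (km^2).
#' @param forest_mask Logical per-cell forest mask.
#' @return The cumulative high-risk area (>= 0; 0 when no cell exceeds or
#'   all seasons are empty).
#' @export
cumulative_high_risk_area <- function(daily_fwi, thresholds, cell_area, forest_mask) {
  stopifnot(ncol(daily_fwi) == length(thresholds),
            length(cell_area) == length(thresholds),
            length(forest_mask) == length(thresholds))
  use <- forest_mask & !is.na(thresholds)
  if (!any(use)) return(0)
  f <- daily_fwi[, use, drop = FALSE]
  exceed <- sweep(f, 2L, thresholds[use], FUN = ">")
  exceed[is.na(exceed)] <- FALSE
  sum(as.numeric(exceed %*% cell_area[use]))
}
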