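#' Fire-season window
#'
#' @param start_day,end_day Day-of-year indices, or `NULL` for no season.
#' @param n_days Length of the year series (defaults 365).
#' @return A list of class `fire_season_window` with `start_day`, `end_day`
#'   and `length` (`end_day - start_day`, 0 for an empty season).
#' @export
fire_season_window <- function(start_day = NULL, end_day = NULL, n_days = 365L) {
  if (is.null(start_day)) {
    out <- list(start_day = NULL, end_day = NULL, length = 0L)
  } else {
    if (is.null(end_day)) end_day <- n_days
    stopifnot(start_day <= end_day)
    out <- list(start_day = as.integer(start_day), end_day = as.integer(end_day),
                length = as.integer(end_day - start_day))
  }
  class(out) <- "fire_season_window"
  out
}

#' Detect the fire season from a year of daily maximum temperature
#'
#' The season starts on the day immediately following three consecutive days
#' with tmax strictly above 12 deg C, and ends on the day immediately
#' following three consecutive days strictly below 5 deg C occurring after
#' the start. Ties do not qualify. With no qualifying start the season is
#' empty; with no qualifying end it runs to the end of the year. A single
#' window per year is returned (no restart after the ending cold spell).
#'
#' @param tmax Daily maximum temperature for one year (numeric, length >= 3).
#' @param start_temp,end_temp Temperature thresholds (deg C).
#' @param run_length Number of consecutive qualifying days (default 3).
#' @return A [fire_season_window()].
#' @export
detect_fire_season <- function(tmax, start_temp = 12, end_temp = 5,
                               run_length = 3L) {
  if (length(tmax) < run_length) {
    stop("tmax series shorter than the qualifying run length", call. = FALSE)
  }
  n <- length(tmax)
  # last day of the first run of `run_length` consecutive TRUEs, or NA
  third_day <- function(cond, from = 1L) {
    run <- 0L
    for (d in seq(from, n)) {
      run <- if (isTRUE(cond[d])) run + 1L else 0L
      if (run >= run_length) return(d)
    }
    NA_integer_
  }
  warm3 <- third_day(tmax > start_temp)
  if (is.na(warm3) || warm3 >= n) return(fire_season_window(NULL))
  start <- warm3 + 1L
  cold3 <- third_day(tmax < end_temp, from = start)
  end <- if (is.na(cold3)) n else min(cold3 + 1L, n)
  fire_season_window(start, end, n_days = n)
}

#' Overwintered DMC start-up value
#'
#' The default start-up value of 6 plus 1.2 per day since the last rainfall
#' event exceeding 1.5 mm before season start.
#'
#' @param days_since_rain Number of days since the last precipitation event
#'   greater than 1.5 mm (>= 0).
#' @return The DMC start-up value, `6 + 1.2 * days_since_rain`.
#' @export
overwinter_dmc_startup <- function(days_since_rain) {
  if (any(days_since_rain < 0)) {
    stop("days_since_rain must be >= 0", call. = FALSE)
  }
  6 + 1.2 * days_since_rain
}

#' Overwintered DC start-up value
#'
#' Lawson & Armitage (2008) overwintering: fall moisture equivalent
#' `Qf = 800 exp(-DC_f / 400)`, spring moisture equivalent
#' `Qs = a Qf + b (3.94 r_w)` with carry-over fraction `a` and wetting
#' efficiency fraction `b` both 0.75, and
#' `DC_start = max(0, 400 ln(800 / Qs))` with `Qs` capped at 800.
#'
#' @param final_fall_dc DC value at the end of the previous fire season.
#' @param overwinter_precip Total off-season precipitation `r_w` (mm).
#' @param carryover,wetting_efficiency Fractions `a` and `b` (default 0.75).
#' @return The DC start-up value (>= 0).
#' @export
overwinter_dc_startup <- function(final_fall_dc, overwinter_precip,
                                  carryover = 0.75, wetting_efficiency = 0.75) {
  if (any(final_fall_dc < 0) || any(overwinter_precip < 0)) {
    stop("final_fall_dc and overwinter_precip must be >= 0", call. = FALSE)
  }
  qf <- 800 * exp(-final_fall_dc / 400)
  qs <- pmin(carryover * qf + wetting_efficiency * 3.94 * overwinter_precip, 800)
  pmax(400 * log(800 / qs), 0)
}

#' Days since the last qualifying rainfall before season start
#'
#' Counts backward from the day before `start_day` to the most recent day
#' with precipitation above `rain_threshold`, searching through `precip_prior`
#' (the concatenated series ending the day before season start, e.g. the
#' previous off-season). If no qualifying event is found the count is capped.
#'
#' @param precip_prior Daily precipitation series ending the day before the
#'   season start (mm).
#' @param rain_threshold Qualifying event threshold (default 1.5 mm).
#' @param max_days Cap when no event is found (default 90).
#' @return Integer count of days since the last qualifying rainfall.
#' @export
days_since_rain <- function(precip_prior, rain_threshold = 1.5, max_days = 90L) {
  idx <- which(precip_prior > rain_threshold)
  if (length(idx) == 0L) return(as.integer(min(length(precip_prior), max_days)))
  min(length(precip_prior) - max(idx), max_days)
}
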