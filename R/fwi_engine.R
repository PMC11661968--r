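#' Canadian Fire Weather Index System engine
#'
#' Standard CFFDRS update equations (Van Wagner & Pickett 1985, For. Tech.
#' Rep. 33) driven by daily maximum temperature and daily minimum relative
#' humidity as noon surrogates (the minimum RH is assumed to occur with the
#' maximum temperature), i.e. no hourly local-noon correction is applied.
#' All update functions are vectorized over grid cells.
#'
#' @name fwi_engine
NULL

# monthly day-length factors, Northern Hemisphere standard tables
.dmc_day_length <- c(6.5, 7.5, 9.0, 12.8, 13.9, 13.9, 12.4, 10.9, 9.4, 8.0, 7.0, 6.0)
.dc_day_length <- c(-1.6, -1.6, -1.6, 0.9, 3.8, 5.8, 6.4, 5.0, 2.4, 0.4, -1.6, -1.6)

.check_weather <- function(tmax, rhmin, wind, precip) {
  if (any(!is.finite(rhmin)) || any(rhmin < 0) || any(rhmin > 100)) {
    stop("rhmin must be within [0, 100]", call. = FALSE)
  }
  if (any(!is.finite(precip)) || any(precip < 0)) {
    stop("precip must be >= 0", call. = FALSE)
  }
  if (!missing(wind) && (any(!is.finite(wind)) || any(wind < 0))) {
    stop("wind must be >= 0", call. = FALSE)
  }
  invisible(NULL)
}

#' Update the Fine Fuel Moisture Code by one day
#'
#' @param ffmc_prev Previous day's FFMC in `[0, 101]`.
#' @param tmax Daily maximum temperature (deg C).
#' @param rhmin Daily minimum relative humidity (%).
#' @param wind Wind speed (km/h).
#' @param precip 24-h precipitation (mm).
#' @return Updated FFMC in `[0, 101]`. Vectorized.
#' @export
update_ffmc <- function(ffmc_prev, tmax, rhmin, wind, precip) {
  .check_weather(tmax, rhmin, wind, precip)
  if (any(ffmc_prev < 0 | ffmc_prev > 101)) {
    stop("ffmc_prev must be within [0, 101]", call. = FALSE)
  }
  # fine-fuel moisture content (%) from yesterday's code
  wmo <- 147.2 * (101 - ffmc_prev) / (59.5 + ffmc_prev)

  # rainfall phase: effective rain above the 0.5 mm canopy threshold
  ra <- pmax(precip - 0.5, 0)
  wet <- precip > 0.5
  if (any(wet)) {
    add <- 42.5 * ra * exp(-100 / (251 - wmo)) * (1 - exp(-6.93 / ra))
    extra <- ifelse(wmo > 150, 0.0015 * (wmo - 150)^2 * sqrt(ra), 0)
    wmo <- ifelse(wet, pmin(wmo + add + extra, 250), wmo)
  }

  ed <- 0.942 * rhmin^0.679 + 11 * exp((rhmin - 100) / 10) +
    0.18 * (21.1 - tmax) * (1 - exp(-0.115 * rhmin))
  ew <- 0.618 * rhmin^0.753 + 10 * exp((rhmin - 100) / 10) +
    0.18 * (21.1 - tmax) * (1 - exp(-0.115 * rhmin))

  # drying toward ed
  z_dry <- 0.424 * (1 - (rhmin / 100)^1.7) +
    0.0694 * sqrt(wind) * (1 - (rhmin / 100)^8)
  x_dry <- z_dry * 0.581 * exp(0.0365 * tmax)
  wm_dry <- ed + (wmo - ed) / 10^x_dry
  # wetting toward ew
  z_wet <- 0.424 * (1 - ((100 - rhmin) / 100)^1.7) +
    0.0694 * sqrt(wind) * (1 - ((100 - rhmin) / 100)^8)
  x_wet <- z_wet * 0.581 * exp(0.0365 * tmax)
  wm_wet <- ew - (ew - wmo) / 10^x_wet

  wm <- ifelse(wmo < ed & wmo < ew, wm_wet, ifelse(wmo > ed, wm_dry, wmo))
  ffmc <- 59.5 * (250 - wm) / (147.2 + wm)
  pmin(pmax(ffmc, 0), 101)
}

#' Update the Duff Moisture Code by one day
#'
#' @inheritParams update_ffmc
#' @param dmc_prev Previous day's DMC (>= 0).
#' @param month Calendar month 1..12 (selects the day-length factor).
#' @return Updated DMC (>= 0). Vectorized over cells; `month` is scalar.
#' @export
update_dmc <- function(dmc_prev, tmax, rhmin, precip, month) {
  .check_weather(tmax, rhmin, precip = precip)
  if (any(dmc_prev < 0)) stop("dmc_prev must be >= 0", call. = FALSE)
  if (length(month) != 1L || !month %in% 1:12) {
    stop("month must be a single integer in 1..12", call. = FALSE)
  }
  # log drying rate; no drying below the -1.1 C activation temperature
  rk <- ifelse(tmax > -1.1,
               1.894 * (tmax + 1.1) * (100 - rhmin) * .dmc_day_length[month] * 1e-4,
               0)
  # rainfall phase above 1.5 mm
  rw <- 0.92 * precip - 1.27
  wmi <- 20 + 280 / exp(0.023 * dmc_prev)
  b <- ifelse(dmc_prev <= 33, 100 / (0.5 + 0.3 * dmc_prev),
              ifelse(dmc_prev <= 65, 14 - 1.3 * log(dmc_prev),
                     6.2 * log(dmc_prev) - 17.2))
  wmr <- wmi + 1000 * rw / (48.77 + b * rw)
  # pmax guard: the log is only used on the precip > 1.5 branch where wmr > 20
  pr <- ifelse(precip > 1.5, 43.43 * (5.6348 - log(pmax(wmr - 20, 1e-8))), dmc_prev)
  pmax(pr, 0) + rk
}

#' Update the Drought Code by one day
#'
#' @inheritParams update_dmc
#' @param dc_prev Previous day's DC (>= 0).
#' @return Updated DC (>= 0). Vectorized over cells; `month` is scalar.
#' @export
update_dc <- function(dc_prev, tmax, precip, month) {
  if (any(precip < 0) || any(!is.finite(precip))) {
    stop("precip must be >= 0", call. = FALSE)
  }
  if (any(dc_prev < 0)) stop("dc_prev must be >= 0", call. = FALSE)
  if (length(month) != 1L || !month %in% 1:12) {
    stop("month must be a single integer in 1..12", call. = FALSE)
  }
  # potential evapotranspiration; temperature clamped at -2.8, floor at 0
  # (the day-length factor is negative in winter months)
  pe <- pmax((0.36 * (pmax(tmax, -2.8) + 2.8) + .dc_day_length[month]) / 2, 0)
  # rainfall phase above 2.8 mm
  rw <- 0.83 * precip - 1.27
  smi <- 800 * exp(-dc_prev / 400)
  # pmax guard: the log argument is only used where precip > 2.8 (rw > 0)
  dr <- pmax(dc_prev - 400 * log(pmax(1 + 3.937 * rw / smi, 1e-8)), 0)
  ifelse(precip > 2.8, dr + pe, dc_prev + pe)
}

#' Initial Spread Index from FFMC and wind
#' @inheritParams update_ffmc
#' @param ffmc Today's FFMC.
#' @return ISI (>= 0). Vectorized.
#' @export
fwi_isi <- function(ffmc, wind) {
  fm <- 147.2 * (101 - ffmc) / (59.5 + ffmc)
  fw <- exp(0.05039 * wind)
  ff <- 91.9 * exp(-0.1386 * fm) * (1 + fm^5.31 / 4.93e7)
  0.208 * fw * ff
}

#' Buildup Index from DMC and DC
#' @param dmc,dc Today's DMC and DC.
#' @return BUI (>= 0). Vectorized.
#' @export
fwi_bui <- function(dmc, dc) {
  low <- 0.8 * dc * dmc / (dmc + 0.4 * dc)
  low[dmc == 0 & dc == 0] <- 0
  high <- dmc - (1 - 0.8 * dc / (dmc + 0.4 * dc)) * (0.92 + (0.0114 * dmc)^1.7)
  high[dmc == 0 & dc == 0] <- 0
  bui <- ifelse(dmc <= 0.4 * dc, low, high)
  pmax(bui, 0)
}

#' Fire Weather Index from ISI and BUI
#' @param isi,bui Today's ISI and BUI.
#' @return FWI (>= 0). Vectorized.
#' @export
fwi_fwi <- function(isi, bui) {
  fd <- ifelse(bui <= 80,
               0.626 * bui^0.809 + 2,
               1000 / (25 + 108.64 * exp(-0.023 * bui)))
  bb <- 0.1 * isi * fd
  # pmax guard keeps the unused branch's log argument >= 1
  ifelse(bb <= 1, bb, exp(2.72 * (0.434 * log(pmax(bb, 1)))^0.647))
}

#' Daily Severity Rating from FWI
#' @param fwi Today's FWI.
#' @return DSR (>= 0). Vectorized.
#' @export
fwi_dsr <- function(fwi) 0.0272 * fwi^1.77

#' Behavior indices derived from the moisture codes and today's weather
#'
#' @param state A list with elements `ffmc`, `dmc`, `dc` (today's codes).
#' @inheritParams update_ffmc
#' @return A list with `isi`, `bui`, `fwi`, `dsr`, `vpd`, all >= 0.
#' @export
compute_derived <- function(state, tmax, rhmin, wind) {
  stopifnot(all(c("ffmc", "dmc", "dc") %in% names(state)))
  isi <- fwi_isi(state$ffmc, wind)
  bui <- fwi_bui(state$dmc, state$dc)
  fwi <- fwi_fwi(isi, bui)
  list(isi = isi, bui = bui, fwi = fwi, dsr = fwi_dsr(fwi),
       vpd = compute_vpd(tmax, rhmin))
}

#' Vapour pressure deficit
#'
#' `vpd = es(tmax) * (1 - rhmin/100)` with the Tetens saturation vapour
#' pressure over water, `es(T) = 0.6108 * exp(17.27 T / (T + 237.3))` kPa.
#'
#' @inheritParams update_ffmc
#' @return VPD in kPa (>= 0). Vectorized.
#' @export
compute_vpd <- function(tmax, rhmin) {
  if (any(rhmin < 0 | rhmin > 100)) {
    stop("rhmin must be within [0, 100]", call. = FALSE)
  }
  es <- 0.6108 * exp(17.27 * tmax / (tmax + 237.3))
  es * (1 - rhmin / 100)
}

#' Run the FWI System over one cell-year of daily weather
#'
#' Indices are defined only on in-season days; the first in-season day
#' advances the start-up codes one step. Outside the season all values are
#' `NA`. Missing weather inside the season is an input-integrity error.
#'
#' @param wx A data.frame with columns `tmax`, `rhmin`, `wind`, `precip`,
#'   `month`, one row per day of the year.
#' @param season A [fire_season_window()] (or the list returned by
#'   [detect_fire_season()]).
#' @param startup A list with the start-up codes `ffmc`, `dmc`, `dc`
#'   (e.g. defaults 85, 6, 15 or overwintered values).
#' @return A data.frame with one row per day and columns `ffmc`, `dmc`,
#'   `dc`, `isi`, `bui`, `fwi`, `dsr`, `vpd` (`NA` outside the season).
#' @export
run_fwi_series <- function(wx, season, startup = list(ffmc = 85, dmc = 6, dc = 15)) {
  stopifnot(is.data.frame(wx),
            all(c("tmax", "rhmin", "wind", "precip", "month") %in% names(wx)))
  n <- nrow(wx)
  out <- data.frame(ffmc = rep(NA_real_, n), dmc = NA_real_, dc = NA_real_,
                    isi = NA_real_, bui = NA_real_, fwi = NA_real_,
                    dsr = NA_real_, vpd = NA_real_)
  if (is.null(season$start_day)) return(out)
  days <- seq(season$start_day, season$end_day)
  days <- days[days >= 1 & days <= n]
  if (any(!stats::complete.cases(wx[days, c("tmax", "rhmin", "wind", "precip")]))) {
    stop("missing weather inside the fire season", call. = FALSE)
  }
  ffmc <- startup$ffmc; dmc <- startup$dmc; dc <- startup$dc
  for (d in days) {
    ffmc <- update_ffmc(ffmc, wx$tmax[d], wx$rhmin[d], wx$wind[d], wx$precip[d])
    dmc <- update_dmc(dmc, wx$tmax[d], wx$rhmin[d], wx$precip[d], wx$month[d])
    dc <- update_dc(dc, wx$tmax[d], wx$precip[d], wx$month[d])
    der <- compute_derived(list(ffmc = ffmc, dmc = dmc, dc = dc),
                           wx$tmax[d], wx$rhmin[d], wx$wind[d])
    out[d, ] <- c(ffmc, dmc, dc, der$isi, der$bui, der$fwi, der$dsr, der$vpd)
  }
  out
}
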