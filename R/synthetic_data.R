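#' Configuration for a synthetic gridded climate scenario
#'
#' Describes a multi-realization ensemble of gridded daily weather
#' (tmax, rhmin, wind, precip) on a regular lat/lon grid with a 365-day
#' calendar. Each variable follows a sinusoidal seasonal cycle plus
#' independent daily Gaussian noise; precipitation is Bernoulli wet-day
#' occurrence times exponential intensity; a linear warming trend can be
#' imposed on daily maximum temperature and a fractional trend on the
#' wet-day rate. An optional negative tmax--rhmin coupling makes warm
#' anomalies dry, the dominant covariance that fire-weather indices react to.
#'
#' @param n_realizations Number of ensemble members (initial-condition
#'   realizations).
#' @param years Integer vector of consecutive simulation years.
#' @param n_lat,n_lon Grid size.
#' @param lat_range,lon_range Coordinate ranges in degrees.
#' @param tmax_mean,tmax_amp Annual mean and seasonal semi-amplitude of daily
#'   maximum temperature (deg C). The cycle peaks at `tmax_peak_doy`.
#' @param tmax_peak_doy Day of year at which tmax peaks (default mid July).
#' @param tmax_sd Daily tmax noise s.d. (deg C).
#' @param lat_gradient Mean tmax change per degree latitude (deg C/deg,
#'   negative = colder northward).
#' @param rh_mean,rh_amp,rh_sd Seasonal mean, semi-amplitude and noise s.d.
#'   of daily minimum relative humidity (%). The cycle peaks half a year
#'   after `tmax_peak_doy`, so summers are dry.
#' @param tmax_rh_coupling Percent RH change per deg C of tmax noise
#'   anomaly (default negative: warm days are dry days).
#' @param wind_mean,wind_amp,wind_sd Wind speed cycle (km/h).
#' @param wet_day_prob Probability a day is wet (precip > 0).
#' @param precip_mean_intensity Mean of the exponential wet-day precipitation
#'   amount (mm).
#' @param warming_trend Imposed linear tmax trend, deg C per decade.
#' @param precip_trend Fractional change in wet-day probability per decade.
#' @param trend_jitter_sd Optional per-realization jitter s.d. on the warming
#'   trend (deg C per decade), a stand-in for differing model climate
#'   sensitivities; 0 disables it.
#' @param seed Integer base seed; every realization derives its own stream
#'   from it, so subsets of realizations are reproducible independently.
#'
#' @return A list of class `climate_config`.
#' @export
climate_config <- function(n_realizations = 8L,
                           years = 1951:2030,
                           n_lat = 6L, n_lon = 6L,
                           lat_range = c(48, 60), lon_range = c(-120, -70),
                           tmax_mean = 6, tmax_amp = 19, tmax_peak_doy = 198L,
                           tmax_sd = 3.5, lat_gradient = -0.4,
                           rh_mean = 55, rh_amp = 15, rh_sd = 10,
                           tmax_rh_coupling = -1.5,
                           wind_mean = 14, wind_amp = 3, wind_sd = 5,
                           wet_day_prob = 0.35, precip_mean_intensity = 4,
                           warming_trend = 0, precip_trend = 0,
                           trend_jitter_sd = 0,
                           seed = 1L) {
  .check_scalar(n_realizations, "n_realizations", lower = 1)
  stopifnot(length(years) >= 1L, all(diff(years) == 1L))
  .check_scalar(n_lat, "n_lat", lower = 1)
  .check_scalar(n_lon, "n_lon", lower = 1)
  .check_scalar(tmax_sd, "tmax_sd", lower = 0)
  .check_scalar(rh_sd, "rh_sd", lower = 0)
  .check_scalar(wind_sd, "wind_sd", lower = 0)
  .check_scalar(wet_day_prob, "wet_day_prob", lower = 0, upper = 1)
  .check_scalar(precip_mean_intensity, "precip_mean_intensity", lower = 0)
  .check_scalar(trend_jitter_sd, "trend_jitter_sd", lower = 0)
  .check_scalar(rh_mean, "rh_mean", lower = 0, upper = 100)
  cfg <- list(
    n_realizations = as.integer(n_realizations), years = as.integer(years),
    n_lat = as.integer(n_lat), n_lon = as.integer(n_lon),
    lat_range = lat_range, lon_range = lon_range,
    tmax_mean = tmax_mean, tmax_amp = tmax_amp,
    tmax_peak_doy = as.integer(tmax_peak_doy),
    tmax_sd = tmax_sd, lat_gradient = lat_gradient,
    rh_mean = rh_mean, rh_amp = rh_amp, rh_sd = rh_sd,
    tmax_rh_coupling = tmax_rh_coupling,
    wind_mean = wind_mean, wind_amp = wind_amp, wind_sd = wind_sd,
    wet_day_prob = wet_day_prob, precip_mean_intensity = precip_mean_intensity,
    warming_trend = warming_trend, precip_trend = precip_trend,
    trend_jitter_sd = trend_jitter_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "climate_config"
  cfg
}

#' Grid geometry for a climate configuration
#'
#' Cell areas are proportional to cos(latitude), the area of a fixed
#' angular-size cell on the sphere.
#'
#' @param config A [climate_config()].
#' @return A data.frame with columns `cell`, `lat`, `lon`, `area_km2`.
#' @export
grid_geometry <- function(config) {
  lats <- seq(config$lat_range[1], config$lat_range[2], length.out = config$n_lat)
  lons <- seq(config$lon_range[1], config$lon_range[2], length.out = config$n_lon)
  g <- expand.grid(lat = lats, lon = lons, KEEP.OUT.ATTRS = FALSE)
  dlat <- if (config$n_lat > 1) diff(lats[1:2]) else 1
  dlon <- if (config$n_lon > 1) diff(lons[1:2]) else 1
  # R_earth = 6371 km; area of a dlat x dlon cell at latitude phi
  g$area_km2 <- (pi * 6371 / 180)^2 * dlat * dlon * cos(g$lat * pi / 180)
  data.frame(cell = seq_len(nrow(g)), g)
}

# seasonal sinusoid: mean + amp * cos(2*pi*(doy - peak)/365)
.seasonal <- function(doy, mean, amp, peak_doy) {
  mean + amp * cos(2 * pi * (doy - peak_doy) / 365)
}

#' Generate one realization of gridded daily weather
#'
#' @param config A [climate_config()].
#' @param realization Integer realization id (its random stream is derived
#'   from `config$seed`, so each id is reproducible in isolation; id 0 is
#'   conventionally the pseudo-observation member).
#' @return A list of class `weather_realization` with matrices `tmax`,
#'   `rhmin`, `wind`, `precip` of dimension time x cell, a `time` data.frame
#'   (`year`, `doy`, `month`), the grid geometry, and an attribute
#'   `clipped` counting values clipped into their physical ranges.
#' @export
generate_weather_realization <- function(config, realization) {
  stopifnot(inherits(config, "climate_config"))
  grid <- grid_geometry(config)
  n_cell <- nrow(grid)
  years <- config$years
  time <- data.frame(
    year = rep(years, each = 365L),
    doy = rep(1:365, times = length(years))
  )
  time$month <- month_of_doy(time$doy)
  n_t <- nrow(time)

  set.seed(.stream_seed(config$seed, realization))
  trend <- config$warming_trend
  if (config$trend_jitter_sd > 0) {
    trend <- trend + stats::rnorm(1L, 0, config$trend_jitter_sd)
  }
  elapsed <- (time$year - years[1L]) / 10  # decades since start

  seas_t <- .seasonal(time$doy, config$tmax_mean, config$tmax_amp, config$tmax_peak_doy)
  seas_rh <- .seasonal(time$doy, config$rh_mean, config$rh_amp,
                       (config$tmax_peak_doy + 182L - 1L) %% 365L + 1L)
  seas_w <- .seasonal(time$doy, config$wind_mean, config$wind_amp, 90L)

  lat_off <- config$lat_gradient * (grid$lat - mean(grid$lat))

  eps_t <- matrix(stats::rnorm(n_t * n_cell, 0, config$tmax_sd), n_t, n_cell)
  tmax <- outer(seas_t + trend * elapsed, rep(1, n_cell)) +
    outer(rep(1, n_t), lat_off) + eps_t

  rhmin <- outer(seas_rh, rep(1, n_cell)) +
    config$tmax_rh_coupling * eps_t +
    matrix(stats::rnorm(n_t * n_cell, 0, config$rh_sd), n_t, n_cell)

  wind <- outer(seas_w, rep(1, n_cell)) +
    matrix(stats::rnorm(n_t * n_cell, 0, config$wind_sd), n_t, n_cell)

  p_wet <- pmin(1, pmax(0, config$wet_day_prob * (1 + config$precip_trend * elapsed)))
  wet <- matrix(stats::rbinom(n_t * n_cell, 1L, rep(p_wet, n_cell)), n_t, n_cell)
  amount <- matrix(stats::rexp(n_t * n_cell, rate = 1 / config$precip_mean_intensity),
                   n_t, n_cell)
  precip <- wet * amount

  clipped <- c(
    rh_low = sum(rhmin < 0), rh_high = sum(rhmin > 100),
    wind_low = sum(wind < 0)
  )
  rhmin <- pmax(pmin(rhmin, 100), 0)  # argument order keeps the dim attribute
  wind <- pmax(wind, 0)

  out <- list(tmax = tmax, rhmin = rhmin, wind = wind, precip = precip,
              time = time, grid = grid, realization = realization)
  attr(out, "clipped") <- clipped
  class(out) <- "weather_realization"
  out
}

#' Generate a full synthetic weather ensemble
#'
#' Calls [generate_weather_realization()] for realization ids 1..n; identical
#' config and seed give bit-identical output.
#'
#' @param config A [climate_config()].
#' @return A list of class `weather_ensemble`: grid geometry, time table and
#'   a list `realizations` of [generate_weather_realization()] outputs.
#' @export
generate_weather_grid <- function(config) {
  stopifnot(inherits(config, "climate_config"))
  reals <- lapply(seq_len(config$n_realizations), function(r) {
    generate_weather_realization(config, r)
  })
  out <- list(grid = grid_geometry(config), time = reals[[1L]]$time,
              realizations = reals, config = config)
  class(out) <- "weather_ensemble"
  out
}

#' Generate forest mask and region labels
#'
#' Partitions the grid into `n_regions` spatially coherent regions (k-means
#' on cell coordinates) standing in for ecozones, and samples a forest mask
#' with the requested forest fraction. Every region is guaranteed at least
#' one forested cell.
#'
#' @param grid A grid geometry data.frame from [grid_geometry()].
#' @param n_regions Number of regions (must not exceed the cell count).
#' @param forest_fraction Fraction of cells that are forested, in (0, 1].
#' @param seed Integer seed.
#' @return A list with `region` (integer label per cell, 1..n_regions) and
#'   `forest` (logical per cell).
#' @export
generate_region_masks <- function(grid, n_regions, forest_fraction = 0.8, seed = 1L) {
  n_cell <- nrow(grid)
  if (n_regions > n_cell) {
    stop("n_regions exceeds the number of grid cells", call. = FALSE)
  }
  .check_scalar(forest_fraction, "forest_fraction", lower = 1e-12, upper = 1)
  set.seed(.stream_seed(seed, 2L))
  if (n_regions == 1L) {
    region <- rep(1L, n_cell)
  } else {
    km <- stats::kmeans(scale(grid[, c("lat", "lon")]), centers = n_regions,
                        nstart = 5L)
    region <- as.integer(km$cluster)
  }
  n_forest <- max(n_regions, round(forest_fraction * n_cell))
  forest <- rep(FALSE, n_cell)
  # one guaranteed forested cell per region, then fill up at random
  first <- vapply(seq_len(n_regions), function(r) {
    cells <- which(region == r)
    cells[sample.int(length(cells), 1L)]
  }, integer(1))
  forest[first] <- TRUE
  remaining <- setdiff(seq_len(n_cell), first)
  extra <- n_forest - n_regions
  if (extra > 0L && length(remaining) > 0L) {
    forest[sample(remaining, min(extra, length(remaining)))] <- TRUE
  }
  list(region = region, forest = forest)
}

#' Configuration of the generative burned-area model
#'
#' Annual area burned is generated as
#' `log10(AB_y) = beta0 + beta1 * metric_y + eps_y`, `eps_y ~ N(0, sigma^2)`,
#' the generative twin of the regression fitted downstream.
#'
#' @param beta0 Intercept on the log10(hectares) scale.
#' @param beta1 Slope per metric unit.
#' @param sigma Residual s.d. on the log10 scale (>= 0).
#' @param seed Integer seed.
#' @return A list of class `burned_area_config`.
#' @export
burned_area_config <- function(beta0 = 3, beta1 = 0.25, sigma = 0.4, seed = 1L) {
  .check_scalar(sigma, "sigma", lower = 0)
  structure(list(beta0 = beta0, beta1 = beta1, sigma = sigma,
                 seed = as.integer(seed)),
            class = "burned_area_config")
}

#' Generate annual burned area from an annual metric series
#'
#' @param metric A data.frame with columns `year` and `value` (the annual
#'   fire-weather metric driving burned area).
#' @param model A [burned_area_config()].
#' @return A data.frame with columns `year`, `area_burned_ha` (always > 0).
#' @export
generate_burned_area <- function(metric, model) {
  stopifnot(inherits(model, "burned_area_config"),
            is.data.frame(metric), all(c("year", "value") %in% names(metric)))
  set.seed(.stream_seed(model$seed, 3L))
  eps <- stats::rnorm(nrow(metric), 0, model$sigma)
  log_ab <- model$beta0 + model$beta1 * metric$value + eps
  data.frame(year = metric$year, area_burned_ha = 10^log_ab)
}
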