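#' Default run configuration
#'
#' Declarative configuration for the full pipeline. The defaults mirror the
#' analysis design: a 1951-2030 simulation period, a 1951-1980 anomaly base
#' period, regression training on 1972-2022 leaving out the 2023 event year,
#' a +1 deg C human-induced warming target matched at the 50th percentile of
#' 10,000 Gaussian draws, an early-decade (1951-1960) counterfactual, a 20%
#' R^2 floor for predictor selection, and 1000 bootstrap replicates. The
#' bundled problem size (6 x 6 grid, 3 regions, 8 realizations) keeps a full
#' run at desk scale.
#'
#' @param seed Integer master seed; every stochastic stage derives its own
#'   stream from it.
#' @param ... Named overrides of any default element (climate parameters are
#'   overridden by passing a full `climate` list).
#' @return A list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    climate = list(n_realizations = 8L, years = 1951:2030, n_lat = 6L, n_lon = 6L,
                   warming_trend = 0.35, precip_trend = 0),
    natural_climate = list(warming_trend = 0, precip_trend = 0),
    n_regions = 3L,
    forest_fraction = 0.8,
    burned_area = list(beta0 = 1.5, beta1 = 0.25, sigma = 0.35,
                       predictor = "FWI_7X"),
    base_period = 1951:1980,
    fit_years = 1972:2022,
    event_year = 2023L,
    warming = list(target_mean = 1.0, target_sd = 0.2, quantile = 0.5,
                   n_samples = 10000L),
    counterfactual = "early_decade",  # or "natural_forcing"
    natural_final_years = 25L,
    candidate_metrics = c("FFMC_7X", "DMC_7X", "ISI_7X", "BUI_7X", "FWI_7X",
                          "FWI_15X", "FWI_31X", "DC_season", "cDSR_season",
                          "VPD_p95"),
    attribution_metrics = c("FWI_7X", "season_length"),
    r2_floor = 0.20,
    n_boot = 1000L,
    compound_percentile = 95
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' Unspecified fields fall back to [default_run_config()]. Every seed is
#' explicit in the returned configuration.
#'
#' @param path Path to a YAML configuration file.
#' @return A list of class `run_config`.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  seed <- if (!is.null(user$seed)) user$seed else 1L
  cfg <- default_run_config(seed = seed)
  for (nm in setdiff(names(user), "seed")) {
    if (is.list(cfg[[nm]]) && is.list(user[[nm]])) {
      for (sub in names(user[[nm]])) cfg[[nm]][[sub]] <- user[[nm]][[sub]]
    } else {
      cfg[[nm]] <- user[[nm]]
    }
  }
  # year ranges may be given as [first, last] pairs in YAML
  expand_years <- function(x) {
    x <- as.integer(unlist(x))
    if (length(x) == 2L && diff(x) > 1L) seq(x[1], x[2]) else x
  }
  if (!is.null(user$climate$years)) cfg$climate$years <- expand_years(user$climate$years)
  if (!is.null(user$base_period)) cfg$base_period <- expand_years(user$base_period)
  if (!is.null(user$fit_years)) cfg$fit_years <- expand_years(user$fit_years)
  class(cfg) <- "run_config"
  cfg
}

# internal: build the climate_config for the factual ("historical") or
# natural-forcing ensemble from a run_config
.scenario_config <- function(config, scenario = c("factual", "natural")) {
  scenario <- match.arg(scenario)
  args <- config$climate
  if (scenario == "natural") {
    for (nm in names(config$natural_climate)) args[[nm]] <- config$natural_climate[[nm]]
    args$seed <- .stream_seed(config$seed, 101L)
  } else {
    args$seed <- config$seed
  }
  do.call(climate_config, args)
}

#' Compute daily FWI fields for one weather realization
#'
#' Runs per-cell fire-season detection, DMC/DC overwintering and the daily
#' FWI System updates over all years of one realization. FFMC restarts at
#' its default 85 each spring; the first simulated year uses the default DC
#' start-up of 15 and the rain-gap DMC rule within the spin-up window;
#' later years overwinter DC from the final fall value and the off-season
#' precipitation, and DMC from the days since the last qualifying rainfall.
#'
#' @param wr A [generate_weather_realization()] output.
#' @return A list with daily matrices (`ffmc`, `dmc`, `dc`, `isi`, `bui`,
#'   `fwi`, `dsr`, `vpd`; time x cell, `NA` outside each cell's season) and
#'   a `seasons` data.frame (`cell`, `year`, `start_day`, `end_day`,
#'   `length`).
#' @export
compute_fwi_fields <- function(wr) {
  stopifnot(inherits(wr, "weather_realization"))
  time <- wr$time
  years <- unique(time$year)
  n_cell <- nrow(wr$grid)
  n_t <- nrow(time)
  idx_names <- c("ffmc", "dmc", "dc", "isi", "bui", "fwi", "dsr", "vpd")
  fields <- lapply(idx_names, function(i) matrix(NA_real_, n_t, n_cell))
  names(fields) <- idx_names
  seasons <- vector("list", length(years))

  last_dc <- rep(NA_real_, n_cell)     # final fall DC of the previous season
  last_end <- rep(NA_integer_, n_cell) # global index of the previous season end

  for (yi in seq_along(years)) {
    t0 <- (yi - 1L) * 365L + 1L
    t1 <- yi * 365L
    tmax_y <- wr$tmax[t0:t1, , drop = FALSE]
    win <- apply(tmax_y, 2L, detect_fire_season)
    start <- vapply(win, function(w) if (is.null(w$start_day)) NA_integer_ else w$start_day, integer(1))
    end <- vapply(win, function(w) if (is.null(w$end_day)) NA_integer_ else w$end_day, integer(1))
    seasons[[yi]] <- data.frame(cell = seq_len(n_cell), year = years[yi],
                                start_day = start, end_day = end,
                                length = ifelse(is.na(start), 0L, end - start))
    gstart <- t0 - 1L + start
    gend <- t0 - 1L + end

    # overwintered start-up codes per cell
    dmc0 <- rep(NA_real_, n_cell)
    dc0 <- rep(NA_real_, n_cell)
    for (cc in which(!is.na(start))) {
      lo <- if (!is.na(last_end[cc])) last_end[cc] + 1L else t0
      prior <- wr$precip[seq(lo, gstart[cc] - 1L), cc]
      dmc0[cc] <- overwinter_dmc_startup(days_since_rain(prior))
      dc0[cc] <- if (!is.na(last_dc[cc])) {
        overwinter_dc_startup(last_dc[cc], sum(prior))
      } else 15
    }

    ffmc <- rep(NA_real_, n_cell)
    dmc <- rep(NA_real_, n_cell)
    dc <- rep(NA_real_, n_cell)
    for (d in t0:t1) {
      starting <- !is.na(gstart) & gstart == d
      if (any(starting)) {
        ffmc[starting] <- 85
        dmc[starting] <- dmc0[starting]
        dc[starting] <- dc0[starting]
      }
      act <- which(!is.na(gstart) & d >= gstart & d <= gend)
      if (length(act) == 0L) next
      mo <- time$month[d]
      ffmc[act] <- update_ffmc(ffmc[act], wr$tmax[d, act], wr$rhmin[d, act],
                               wr$wind[d, act], wr$precip[d, act])
      dmc[act] <- update_dmc(dmc[act], wr$tmax[d, act], wr$rhmin[d, act],
                             wr$precip[d, act], mo)
      dc[act] <- update_dc(dc[act], wr$tmax[d, act], wr$precip[d, act], mo)
      isi <- fwi_isi(ffmc[act], wr$wind[d, act])
      bui <- fwi_bui(dmc[act], dc[act])
      fwi <- fwi_fwi(isi, bui)
      fields$ffmc[d, act] <- ffmc[act]
      fields$dmc[d, act] <- dmc[act]
      fields$dc[d, act] <- dc[act]
      fields$isi[d, act] <- isi
      fields$bui[d, act] <- bui
      fields$fwi[d, act] <- fwi
      fields$dsr[d, act] <- fwi_dsr(fwi)
      fields$vpd[d, act] <- compute_vpd(wr$tmax[d, act], wr$rhmin[d, act])
    }
    ended <- which(!is.na(gend))
    last_dc[ended] <- fields$dc[cbind(gend[ended], ended)]
    last_end[ended] <- gend[ended]
  }
  c(fields, list(seasons = do.call(rbind, seasons), time = time, grid = wr$grid))
}

# internal: area-weighted daily regional mean series over forested cells,
# skipping NA cells day by day
.regional_daily <- function(mat, sel, w) {
  m <- mat[, sel, drop = FALSE]
  ok <- !is.na(m)
  m0 <- m
  m0[!ok] <- 0
  num <- as.numeric(m0 %*% w)
  den <- as.numeric(ok %*% w)
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Annual region-level metrics for one realization
#'
#' Area-weighted regional-mean daily index series are built over forested
#' cells, the regional fire season is detected from the regional-mean tmax,
#' and the annual metric registry is evaluated per region and year.
#'
#' @param wr A [generate_weather_realization()] output.
#' @param fields A [compute_fwi_fields()] output for the same realization.
#' @param masks Region/forest masks from [generate_region_masks()].
#' @return A list with `metrics` (long data.frame: `realization`, `region`,
#'   `year`, `metric`, `value`), `seasons` (regional windows: `region`,
#'   `year`, `start_day`, `end_day`, `length`) and `gmst` (data.frame
#'   `year`, `gmst`: area-weighted annual-mean tmax over all cells).
#' @export
realization_metrics <- function(wr, fields, masks) {
  time <- wr$time
  years <- unique(time$year)
  grid <- wr$grid
  idx_names <- c("ffmc", "dmc", "dc", "isi", "bui", "fwi", "dsr", "vpd")
  regions <- sort(unique(masks$region))

  w_all <- grid$area_km2 / sum(grid$area_km2)
  gmst_daily <- as.numeric(wr$tmax %*% w_all)
  gmst <- data.frame(year = years,
                     gmst = vapply(years, function(y) mean(gmst_daily[time$year == y]),
                                   numeric(1)))

  rows <- list()
  season_rows <- list()
  for (r in regions) {
    sel <- masks$forest & masks$region == r
    if (!any(sel)) stop(sprintf("region %s has no forested cells", r), call. = FALSE)
    w <- grid$area_km2[sel]
    daily <- data.frame(lapply(fields[idx_names], .regional_daily, sel = sel, w = w))
    tmax_r <- .regional_daily(wr$tmax, sel, w)
    for (yi in seq_along(years)) {
      t0 <- (yi - 1L) * 365L + 1L
      win <- detect_fire_season(tmax_r[t0:(t0 + 364L)])
      vals <- annual_metrics_one(daily[t0:(t0 + 364L), , drop = FALSE], win)
      rows[[length(rows) + 1L]] <- data.frame(
        realization = wr$realization, region = r, year = years[yi],
        metric = names(vals), value = unname(vals))
      season_rows[[length(season_rows) + 1L]] <- data.frame(
        realization = wr$realization, region = r, year = years[yi],
        start_day = if (is.null(win$start_day)) NA_integer_ else win$start_day,
        end_day = if (is.null(win$end_day)) NA_integer_ else win$end_day,
        length = win$length)
    }
  }
  list(metrics = do.call(rbind, rows), seasons = do.call(rbind, season_rows),
       gmst = gmst)
}

#' Cumulative high fire-risk area series for one realization
#'
#' @param fields A [compute_fwi_fields()] output.
#' @param masks Region/forest masks.
#' @param base_years Base-period years for the local thresholds.
#' @param p Threshold percentile (default 95).
#' @return A data.frame `year`, `cumulative_area` (km^2 x days).
#' @export
realization_compound <- function(fields, masks, base_years, p = 95) {
  time <- fields$time
  years <- unique(time$year)
  thr <- local_threshold(fields$fwi, time$year, base_years, p = p)
  area <- vapply(years, function(y) {
    cumulative_high_risk_area(fields$fwi[time$year == y, , drop = FALSE],
                              thr, fields$grid$area_km2, masks$forest)
  }, numeric(1))
  data.frame(year = years, cumulative_area = area)
}

# internal: process one ensemble (factual or natural): per-realization FWI,
# metrics, compound statistic and gmst, chunked by realization so only one
# realization's gridded fields are in memory at a time
.process_ensemble <- function(config, scenario, masks, realizations = NULL) {
  ccfg <- .scenario_config(config, scenario)
  if (is.null(realizations)) realizations <- seq_len(ccfg$n_realizations)
  metrics <- list(); seasons <- list(); compound <- list(); gmst <- list()
  for (r in realizations) {
    wr <- generate_weather_realization(ccfg, r)
    fields <- compute_fwi_fields(wr)
    rm_ <- realization_metrics(wr, fields, masks)
    comp <- realization_compound(fields, masks, config$base_period,
                                 p = config$compound_percentile)
    comp$realization <- r
    rm_$gmst$realization <- r
    metrics[[length(metrics) + 1L]] <- rm_$metrics
    seasons[[length(seasons) + 1L]] <- rm_$seasons
    compound[[length(compound) + 1L]] <- comp
    gmst[[length(gmst) + 1L]] <- rm_$gmst
  }
  list(metrics = do.call(rbind, metrics), seasons = do.call(rbind, seasons),
       compound = do.call(rbind, compound), gmst = do.call(rbind, gmst))
}

#' Run the full attribution pipeline
#'
#' Executes the stages in dependency order: synthetic ensemble generation,
#' FWI fields and annual metrics (chunked by realization), pseudo-observed
#' burned area and per-region regression fitting with predictor selection,
#' warming-level matching, and risk ratios for area burned, fire-weather
#' metric anomalies and the compound cumulative high-risk-area statistic.
#' Realization id 0 of the factual ensemble plays the role of the
#' observational record (reanalysis + burned-area composite): burned area is
#' generated from its metric series, regressions are trained on it, and
#' event thresholds are its event-year values.
#'
#' @param config A [default_run_config()] / [read_run_config()] list.
#' @param outdir Optional output directory; when given, tables are written
#'   as CSV, models and the run manifest as JSON.
#' @return A list with elements `obs` (pseudo-observation tables), `hist`
#'   (factual ensemble tables), `models`, `warming_match`, `risk_ratios`
#'   (data.frame), `compound_rr`, `manifest`.
#' @export
run_pipeline <- function(config = default_run_config(), outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  ccfg <- .scenario_config(config, "factual")
  grid <- grid_geometry(ccfg)
  masks <- generate_region_masks(grid, config$n_regions, config$forest_fraction,
                                 seed = config$seed)
  regions <- sort(unique(masks$region))
  years <- ccfg$years
  event_year <- config$event_year
  base_years <- config$base_period

  # --- pseudo-observations: realization 0 of the factual scenario ---
  obs <- .process_ensemble(config, "factual", masks, realizations = 0L)
  obs$metrics <- compute_anomalies(obs$metrics, base_years)

  ab_list <- lapply(regions, function(r) {
    pred <- obs$metrics[obs$metrics$region == r &
                          obs$metrics$metric == config$burned_area$predictor,
                        c("year", "value")]
    ba_cfg <- burned_area_config(config$burned_area$beta0, config$burned_area$beta1,
                                 config$burned_area$sigma,
                                 seed = .stream_seed(config$seed, 200L + r))
    ab <- generate_burned_area(pred, ba_cfg)
    ab$region <- r
    ab
  })
  obs$burned_area <- do.call(rbind, ab_list)

  # --- regression fitting and predictor selection on pseudo-observations ---
  models <- lapply(regions, function(r) {
    select_best_predictor(
      obs$burned_area[obs$burned_area$region == r, ],
      obs$metrics[obs$metrics$region == r, ],
      config$candidate_metrics, config$fit_years,
      r2_floor = config$r2_floor, region = r)
  })
  names(models) <- as.character(regions)

  # --- factual ensemble ---
  hist <- .process_ensemble(config, "factual", masks)
  hist$metrics <- compute_anomalies(hist$metrics, base_years)

  # --- warming-level matching on the ensemble-mean gmst ---
  gmst_ens <- stats::aggregate(gmst ~ year, data = hist$gmst, FUN = mean)
  wlm <- match_warming_level(
    gmst_ens$gmst, gmst_ens$year,
    target_mean = config$warming$target_mean,
    target_sd = config$warming$target_sd,
    counterfactual_years = years[1:10],
    n_samples = config$warming$n_samples,
    quantile = config$warming$quantile,
    seed = config$seed)
  factual_years <- wlm$matched_years

  # --- counterfactual pool definition ---
  if (identical(config$counterfactual, "natural_forcing")) {
    nat <- .process_ensemble(config, "natural", masks)
    # paired baseline preserves the factual-counterfactual offset
    nat$metrics <- compute_anomalies(nat$metrics, base_years,
                                     baseline = hist$metrics)
    cf_years <- utils::tail(years, config$natural_final_years)
    cf_source <- nat
  } else {
    cf_years <- years[1:10]
    # counterfactual year count scaled to the factual window length so each
    # model's proportion of the ensemble is consistent
    if (length(factual_years) < 10L) {
      cf_years <- utils::tail(cf_years, length(factual_years))
    }
    cf_source <- hist
  }

  results <- list()
  # --- area burned attribution per region ---
  for (r in regions) {
    model <- models[[as.character(r)]]
    if (isTRUE(model$excluded)) next
    obs_ab <- obs$burned_area[obs$burned_area$region == r, ]
    threshold <- log10(max(obs_ab$area_burned_ha[obs_ab$year == event_year], 1))
    pred_metric <- function(src, yrs) {
      m <- src$metrics[src$metrics$region == r &
                         src$metrics$metric == model$predictor, ]
      m[m$year %in% yrs, c("realization", "year", "value")]
    }
    sim_base <- mean(pred_metric(hist, base_years)$value, na.rm = TRUE)
    ref_base <- mean(obs$metrics$value[obs$metrics$region == r &
                                         obs$metrics$metric == model$predictor &
                                         obs$metrics$year %in% base_years],
                     na.rm = TRUE)
    make_pool <- function(src, yrs) {
      m <- pred_metric(src, yrs)
      m <- m[!is.na(m$value), ]
      x <- bias_correct_predictor(m$value, sim_base, ref_base)
      predict_with_se(model, x)
    }
    res <- attribute_event(make_pool(hist, factual_years),
                           make_pool(cf_source, cf_years),
                           threshold, event_type = "area_burned",
                           n_boot = config$n_boot,
                           seed = .stream_seed(config$seed, 300L + r))
    results[[length(results) + 1L]] <-
      data.frame(region = r, event = "area_burned",
                 p_factual = res$p_factual, p_counterfactual = res$p_counterfactual,
                 rr = res$rr, ci_low = res$ci_low, ci_high = res$ci_high,
                 finite = res$finite)
  }

  # --- fire-weather metric anomaly attribution per region ---
  for (r in regions) {
    for (m in config$attribution_metrics) {
      obs_anom <- obs$metrics$anomaly[obs$metrics$region == r &
                                        obs$metrics$metric == m &
                                        obs$metrics$year == event_year]
      if (length(obs_anom) != 1L || is.na(obs_anom)) next
      pool <- function(src, yrs) {
        v <- src$metrics$anomaly[src$metrics$region == r &
                                   src$metrics$metric == m &
                                   src$metrics$year %in% yrs]
        v[!is.na(v)]
      }
      res <- attribute_event(pool(hist, factual_years), pool(cf_source, cf_years),
                             obs_anom, event_type = "metric_anomaly",
                             n_boot = config$n_boot,
                             seed = .stream_seed(config$seed, 400L + 10L * r))
      results[[length(results) + 1L]] <-
        data.frame(region = r, event = m,
                   p_factual = res$p_factual, p_counterfactual = res$p_counterfactual,
                   rr = res$rr, ci_low = res$ci_low, ci_high = res$ci_high,
                   finite = res$finite)
    }
  }

  # --- compound cumulative high-risk-area attribution (national) ---
  obs_compound <- obs$compound$cumulative_area[obs$compound$year == event_year]
  pool_c <- function(src, yrs) {
    src$compound$cumulative_area[src$compound$year %in% yrs]
  }
  compound_rr <- attribute_event(pool_c(hist, factual_years),
                                 pool_c(cf_source, cf_years),
                                 obs_compound, event_type = "metric_anomaly",
                                 n_boot = config$n_boot,
                                 seed = .stream_seed(config$seed, 500L))
  results[[length(results) + 1L]] <-
    data.frame(region = NA_integer_, event = "compound_high_risk_area",
               p_factual = compound_rr$p_factual,
               p_counterfactual = compound_rr$p_counterfactual,
               rr = compound_rr$rr, ci_low = compound_rr$ci_low,
               ci_high = compound_rr$ci_high, finite = compound_rr$finite)

  risk_ratios <- do.call(rbind, results)
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  manifest <- list(config = unclass(config), config_hash = .fnv1a(cfg_json),
                   matched_factual_years = factual_years,
                   counterfactual_years = cf_years,
                   package_version = as.character(utils::packageVersion("fireattr")))
  out <- list(obs = obs, hist = hist, models = models, masks = masks,
              warming_match = wlm, risk_ratios = risk_ratios,
              compound_rr = compound_rr, manifest = manifest)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(hist$metrics, file.path(outdir, "annual_metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(hist$seasons, file.path(outdir, "seasons.csv"),
                     row.names = FALSE)
    utils::write.csv(hist$compound, file.path(outdir, "compound.csv"),
                     row.names = FALSE)
    utils::write.csv(obs$burned_area, file.path(outdir, "burned_area.csv"),
                     row.names = FALSE)
    utils::write.csv(risk_ratios, file.path(outdir, "risk_ratios.csv"),
                     row.names = FALSE)
    jsonlite::write_json(lapply(models, function(m) m[setdiff(names(m), "fit")]),
                         file.path(outdir, "models.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  out
}
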