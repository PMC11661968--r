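# brute-force oracles kept local and independent of the implementations
brute_running_mean_max <- function(x, w) {
  n <- length(x)
  if (n < w) return(mean(x))
  max(vapply(1:(n - w + 1), function(i) mean(x[i:(i + w - 1)]), numeric(1)))
}
brute_percentile <- function(x, p) {
  # type-7: linear interpolation between order statistics
  x <- sort(x)
  h <- (length(x) - 1) * p / 100 + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
}

test_that("running-mean maxima equal the exhaustive window scan", {
  expect_equal(running_mean_max(rep(3.2, 50), 7), 3.2)
  x <- c(rep(0, 30), 7, rep(0, 29))
  expect_equal(running_mean_max(x, 7), 1)
  set.seed(31)
  for (w in c(7L, 15L, 31L)) {
    x <- rexp(60, 1 / 10)
    expect_equal(running_mean_max(x, w), brute_running_mean_max(x, w))
  }
  # window 1 is the series maximum
  x <- rnorm(40)
  expect_equal(running_mean_max(x, 1), max(x))
  # season shorter than the window: whole-season mean fallback
  expect_equal(running_mean_max(x[1:5], 7), mean(x[1:5]))
  expect_true(is.na(running_mean_max(numeric(0), 7)))
})

test_that("seasonal aggregates and percentiles match direct evaluation", {
  expect_equal(season_aggregate(rep(1, 100), "sum"), 100)
  expect_equal(season_aggregate(rep(1, 100), "mean"), 1)
  set.seed(17)
  x <- rgamma(80, 2, 0.5)
  expect_equal(season_aggregate(x, "sum"), sum(x))
  expect_equal(season_aggregate(x, "mean"), mean(x))
  expect_true(is.na(season_aggregate(numeric(0), "mean")))
  # percentile convention: linear interpolation
  expect_equal(percentile_metric(1:100, 50), 50.5)
  expect_equal(percentile_metric(1:100, 95), 95.05)
  expect_equal(percentile_metric(rep(4.2, 30), 95), 4.2)
  for (p in c(5, 50, 95)) {
    expect_equal(percentile_metric(x, p), brute_percentile(x, p))
  }
})

test_that("regional means are area-weighted over forested cells only", {
  vals <- c(0, 10, 99, 99)
  area <- c(1, 3, 5, 5)
  forest <- c(TRUE, TRUE, FALSE, TRUE)
  region <- c(1L, 1L, 1L, 2L)
  expect_equal(regional_mean(vals, area, forest, region, 1L), 7.5)
  expect_equal(regional_mean(vals, area, forest, region, 2L), 99)
  # uniform field: the weights cancel
  expect_equal(regional_mean(rep(5, 4), area, forest, region, 1L), 5)
  # invariance under region-preserving permutation and area scaling
  set.seed(8)
  v <- rnorm(20); a <- runif(20, 1, 4); f <- rep(TRUE, 20); r <- rep(1L, 20)
  perm <- sample(20)
  expect_equal(regional_mean(v, a, f, r, 1L),
               regional_mean(v[perm], a[perm], f[perm], r[perm], 1L))
  expect_equal(regional_mean(v, a, f, r, 1L),
               regional_mean(v, 13 * a, f, r, 1L))
  expect_error(regional_mean(vals, area, c(FALSE, FALSE, FALSE, TRUE), region, 1L),
               "no forested")
})

test_that("anomalies subtract the designated base-period mean", {
  tab <- data.frame(region = 1L, metric = "FWI_7X", year = 1951:1990,
                    value = 10)
  a <- compute_anomalies(tab, 1951:1980)
  expect_equal(a$anomaly, rep(0, 40))
  tab$value <- 10 + 2 * (tab$year > 1980)
  a <- compute_anomalies(tab, 1951:1980)
  expect_equal(a$anomaly[a$year > 1980], rep(2, 10))
  # anomaly of the base-period mean is 0
  set.seed(3)
  tab$value <- rnorm(40)
  a <- compute_anomalies(tab, 1951:1980)
  expect_equal(mean(a$anomaly[a$year <= 1980]), 0)
  # paired baseline preserves the factual-counterfactual offset
  cf <- tab; cf$value <- tab$value
  a_cf <- compute_anomalies(cf, 1951:1980, baseline = tab)
  expect_equal(a_cf$anomaly, a$anomaly)
  expect_error(compute_anomalies(tab, 1940:1980), "base years")
})

test_that("the metric registry is complete and canonically ordered", {
  reg <- metric_registry()
  expect_true(all(c("FWI_7X", "FWI_15X", "FWI_31X", "DC_season", "cDSR_season",
                    "VPD_p95", "season_length", "season_start") %in% reg$metric))
  expect_false(any(duplicated(reg$metric)))
  # annual_metrics_one covers the registry and handles empty seasons
  daily <- data.frame(ffmc = rep(80, 365), dmc = 20, dc = 100, isi = 5,
                      bui = 30, fwi = 10, dsr = 2, vpd = 1)
  win <- fire_season_window(100, 250)
  vals <- annual_metrics_one(daily, win)
  expect_identical(names(vals), reg$metric)
  expect_equal(unname(vals["FWI_7X"]), 10)
  expect_equal(unname(vals["DC_season"]), 100)
  expect_equal(unname(vals["cDSR_season"]), 2 * 151)
  expect_equal(unname(vals["season_length"]), 150)
  empty <- annual_metrics_one(daily, fire_season_window(NULL))
  expect_equal(unname(empty["season_length"]), 0)
  expect_true(is.na(empty["FWI_7X"]))
})
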