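# closed-form normal-equation oracle
ols_oracle <- function(x, y) {
  b1 <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  b0 <- mean(y) - b1 * mean(x)
  e <- y - b0 - b1 * x
  list(b0 = b0, b1 = b1,
       r2 = 1 - sum(e^2) / sum((y - mean(y))^2),
       s2 = sum(e^2) / (length(y) - 2))
}

make_data <- function(n, beta0, beta1, sigma, seed) {
  set.seed(seed)
  x <- rnorm(n, 10, 2)
  y <- beta0 + beta1 * x + rnorm(n, 0, sigma)
  list(ab = data.frame(year = seq_len(n), area_burned_ha = 10^y),
       metric = data.frame(year = seq_len(n), value = x))
}

test_that("the fit matches the closed-form normal equations", {
  for (s in 1:5) {
    d <- make_data(51, 1.5, 0.3, 0.4, seed = 100 + s)
    m <- fit_region_model(d$ab, d$metric, fit_years = 1:51)
    o <- ols_oracle(d$metric$value, log10(d$ab$area_burned_ha))
    expect_equal(m$beta0, o$b0, tolerance = 1e-10)
    expect_equal(m$beta1, o$b1, tolerance = 1e-10)
    expect_equal(m$r2, o$r2, tolerance = 1e-10)
    expect_equal(m$residual_var, o$s2, tolerance = 1e-10)
  }
})

test_that("noise-free data are recovered exactly with R^2 = 1", {
  d <- make_data(30, 2, 0.5, 0, seed = 1)
  m <- fit_region_model(d$ab, d$metric, 1:30)
  expect_equal(m$beta0, 2, tolerance = 1e-9)
  expect_equal(m$beta1, 0.5, tolerance = 1e-9)
  expect_equal(m$r2, 1, tolerance = 1e-12)
  expect_equal(m$residual_var, 0, tolerance = 1e-18)
  # degenerate predictor refused
  d$metric$value <- 7
  expect_error(fit_region_model(d$ab, d$metric, 1:30), "degenerate")
  expect_error(fit_region_model(d$ab[1:2, ], d$metric[1:2, ], 1:2), "fewer than 3")
})

test_that("zero-burn years are floored at 1 ha and counted", {
  ab <- data.frame(year = 1:10, area_burned_ha = c(rep(100, 8), 0, 0.5))
  metric <- data.frame(year = 1:10, value = 1:10)
  m <- fit_region_model(ab, metric, 1:10)
  expect_identical(m$n_floored, 2L)
})

test_that("prediction standard errors follow the new-observation formula", {
  d <- make_data(51, 1.5, 0.3, 0.4, seed = 77)
  m <- fit_region_model(d$ab, d$metric, 1:51)
  # at the predictor mean
  p <- predict_with_se(m, m$xbar)
  expect_equal(p$sd, sqrt(m$residual_var * (1 + 1 / m$n)), tolerance = 1e-12)
  # textbook formula at arbitrary x0
  x0 <- 14.2
  p <- predict_with_se(m, x0)
  expect_equal(p$mean, m$beta0 + m$beta1 * x0)
  expect_equal(p$sd,
               sqrt(m$residual_var * (1 + 1 / m$n + (x0 - m$xbar)^2 / m$sxx)))
  # mean-response form drops the residual term
  pc <- predict_with_se(m, x0, include_residual = FALSE)
  expect_lt(pc$sd, p$sd)
  # noise-free: sd exactly 0
  d0 <- make_data(30, 2, 0.5, 0, seed = 2)
  m0 <- fit_region_model(d0$ab, d0$metric, 1:30)
  expect_equal(predict_with_se(m0, 11)$sd, 0, tolerance = 1e-9)
})

test_that("bias correction recenters the simulated predictor exactly", {
  set.seed(4)
  sim <- rnorm(50, 20, 3)
  expect_equal(bias_correct_predictor(sim, mean(sim), mean(sim)), sim)
  corrected <- bias_correct_predictor(sim, mean(sim), 12.5)
  expect_equal(mean(corrected), 12.5)
  expect_equal(bias_correct_predictor(rep(7, 5), 7, 9), rep(9, 5))
})

test_that("predictor selection picks the generating metric and rejects noise", {
  set.seed(55)
  n <- 51
  x_true <- rnorm(n, 10, 2)
  y <- 1 + 0.4 * x_true  # noise-free link to the generating metric
  metrics <- rbind(
    data.frame(year = 1:n, metric = "FWI_7X", value = x_true),
    data.frame(year = 1:n, metric = "DC_season", value = rnorm(n)),
    data.frame(year = 1:n, metric = "VPD_p95", value = rnorm(n))
  )
  ab <- data.frame(year = 1:n, area_burned_ha = 10^y)
  sel <- select_best_predictor(ab, metrics, c("FWI_7X", "DC_season", "VPD_p95"),
                               1:n, region = "east")
  expect_identical(sel$predictor, "FWI_7X")
  expect_false(sel$excluded)
  expect_equal(nrow(attr(sel, "diagnostics")), 3L)
  # identical candidates: deterministic first-in-registry tie-break
  metrics2 <- rbind(
    data.frame(year = 1:n, metric = "A", value = x_true),
    data.frame(year = 1:n, metric = "B", value = x_true)
  )
  sel2 <- select_best_predictor(ab, metrics2, c("A", "B"), 1:n)
  expect_identical(sel2$predictor, "A")
  # all-noise candidates fall below the 0.20 floor
  set.seed(56)
  ab_noise <- data.frame(year = 1:n, area_burned_ha = 10^rnorm(n, 2, 0.5))
  sel3 <- select_best_predictor(ab_noise, metrics, c("DC_season", "VPD_p95"), 1:n)
  expect_true(sel3$excluded)
  expect_error(predict_with_se(sel3, 10), "excluded")
})

test_that("detrending leaves trendless fits unchanged and removes shared trends", {
  d <- make_data(51, 1.5, 0.3, 0.3, seed = 200)
  r <- detrended_r2_check(d$ab, d$metric, 1:51)
  expect_equal(r$r2_raw, r$r2_detrended, tolerance = 0.05)
  # a strong shared linear trend inflates the raw R^2 only
  trend <- 0.08 * (1:51)
  ab_tr <- data.frame(year = 1:51,
                      area_burned_ha = 10^(log10(d$ab$area_burned_ha) + trend))
  met_tr <- data.frame(year = 1:51, value = d$metric$value + 10 * trend)
  set.seed(201)
  met_tr$value <- met_tr$value + rnorm(51, 0, 0.5)
  r_tr <- detrended_r2_check(ab_tr, met_tr, 1:51)
  expect_gt(r_tr$r2_raw, r_tr$r2_detrended)
  # noise-free linear relation: both exactly 1
  d0 <- make_data(30, 2, 0.5, 0, seed = 3)
  r0 <- detrended_r2_check(d0$ab, d0$metric, 1:30)
  expect_equal(r0$r2_raw, 1, tolerance = 1e-9)
  expect_equal(r0$r2_detrended, 1, tolerance = 1e-9)
})
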