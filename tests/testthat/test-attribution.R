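test_that("mixture tail probabilities match closed-form cases", {
  # single component, threshold at the mean
  expect_equal(mixture_tail_probability(3, 1, 3), 0.5)
  # equal-weight average of two known tails (0.2 and 0.4)
  thr <- qnorm(0.8)
  mu2 <- thr - qnorm(0.6)
  expect_equal(mixture_tail_probability(c(0, mu2), c(1, 1), thr), 0.3)
  # single normal for K = 1
  expect_equal(mixture_tail_probability(1.2, 0.7, 2),
               pnorm(2, 1.2, 0.7, lower.tail = FALSE))
  # zero-sd components are indicators
  expect_equal(mixture_tail_probability(c(1, 3), c(0, 0), 2), 0.5)
  expect_equal(mixture_tail_probability(2, 0, 2), 1)  # ties exceed
  # monotone non-increasing in threshold, bounded in [0, 1]
  set.seed(12)
  mu <- rnorm(30); sd <- runif(30, 0, 2)
  thr <- seq(-4, 4, length.out = 30)
  p <- vapply(thr, function(t) mixture_tail_probability(mu, sd, t), numeric(1))
  expect_true(all(diff(p) <= 0))
  expect_true(all(p >= 0 & p <= 1))
  expect_error(mixture_tail_probability(numeric(0), 1, 0), "empty")
  expect_error(mixture_tail_probability(0, -1, 0), "sd")
})

test_that("mixture probability agrees with Monte-Carlo sampling", {
  set.seed(99)
  for (case in 1:5) {
    k <- sample(5:50, 1)
    mu <- rnorm(k, 1, 1.5)
    sd <- runif(k, 0.1, 1.5)
    thr <- quantile(mu, 0.8) + 0.5
    p <- mixture_tail_probability(mu, sd, thr)
    n_mc <- 2e5
    comp <- sample.int(k, n_mc, replace = TRUE)
    draws <- rnorm(n_mc, mu[comp], sd[comp])
    p_mc <- mean(draws >= thr)
    se <- sqrt(p_mc * (1 - p_mc) / n_mc)
    expect_lt(abs(p - p_mc), 3 * se + 1e-12)
  }
})

test_that("empirical exceedance uses the at-least-as-large convention", {
  expect_equal(empirical_tail_probability(1:100, 0), 1)
  expect_equal(empirical_tail_probability(1:100, 101), 0)
  expect_equal(empirical_tail_probability(1:100, 50), 51 / 100)
  expect_error(empirical_tail_probability(numeric(0), 1), "empty")
})

test_that("risk ratios handle finite, infinite and undefined cases", {
  expect_equal(risk_ratio(0.3, 0.3)$rr, 1)
  expect_equal(risk_ratio(0.02, 0.01)$rr, 2)
  inf <- risk_ratio(0.01, 0)
  expect_identical(inf$rr, Inf)
  expect_false(inf$finite)
  und <- risk_ratio(0, 0)
  expect_true(und$undefined)
  expect_true(is.na(und$rr))
  expect_error(risk_ratio(1.2, 0.5))
})

test_that("bootstrap intervals are seeded, point-mass-exact and sane", {
  set.seed(2)
  f <- rnorm(200, 1); cf <- rnorm(200)
  a <- bootstrap_rr_ci(f, cf, 1.5, n_boot = 200, seed = 42)
  b <- bootstrap_rr_ci(f, cf, 1.5, n_boot = 200, seed = 42)
  expect_identical(a, b)
  expect_lte(a$ci_low, a$ci_high)
  # point-mass pools collapse to the point risk ratio
  pm <- bootstrap_rr_ci(rep(2, 50), rep(2, 50), 1, n_boot = 100, seed = 1)
  expect_equal(pm$ci_low, 1)
  expect_equal(pm$ci_high, 1)
  # infinite replicates propagate to the upper bound
  rare <- bootstrap_rr_ci(c(rep(0, 40), 5), c(rep(0, 40), 5), 4,
                          n_boot = 200, seed = 3)
  expect_true(is.infinite(rare$ci_high))
})

test_that("warming-level matching finds the decade at the target anomaly", {
  years <- 1950:2030
  gmst <- 10 + 0.02 * (years - 1950)
  m <- match_warming_level(gmst, years, target_mean = 1, target_sd = 0,
                           seed = 5)
  # anomaly of the trailing decade ending y is 0.02 * (y - 4.5 - 1954.5)
  expect_identical(m$matched_years, 2000:2009)
  expect_equal(m$matched_anomaly, 1, tolerance = 0.011)
  # zero target sd: deterministic across seeds
  m2 <- match_warming_level(gmst, years, 1, 0, seed = 99)
  expect_identical(m$matched_end_year, m2$matched_end_year)
  # stochastic series: matched decade brackets the deterministic one
  ends <- vapply(1:20, function(s) {
    set.seed(s)
    match_warming_level(gmst + rnorm(81, 0, 0.05), years, 1, 0.1,
                        n_samples = 500, seed = s)$matched_end_year
  }, numeric(1))
  expect_gt(mean(ends), 1995)
  expect_lt(mean(ends), 2025)
  expect_error(match_warming_level(gmst, years, 1, 0.1,
                                   counterfactual_years = 1900:1909),
               "counterfactual")
})

test_that("attribute_event composes probabilities, ratio and interval", {
  set.seed(7)
  f <- data.frame(mean = rnorm(100, 3.4, 0.3), sd = runif(100, 0.2, 0.4))
  cf <- data.frame(mean = rnorm(100, 3.0, 0.3), sd = runif(100, 0.2, 0.4))
  res <- attribute_event(f, cf, threshold = 4, event_type = "area_burned",
                         n_boot = 200, seed = 11)
  expect_s3_class(res, "risk_ratio_result")
  expect_gt(res$rr, 1)
  expect_equal(res$rr, res$p_factual / res$p_counterfactual)
  # threshold below all mass in both pools: probabilities 1, RR 1
  res1 <- attribute_event(f, cf, threshold = -50, event_type = "area_burned",
                          n_boot = 50, seed = 1)
  expect_equal(res1$p_factual, 1)
  expect_equal(res1$rr, 1)
  expect_equal(res1$ci_low, 1)
  # empirical pools for metric anomalies
  res2 <- attribute_event(rnorm(500, 1), rnorm(500, 0), 1.5,
                          event_type = "metric_anomaly", n_boot = 100, seed = 2)
  expect_gt(res2$rr, 1)
  expect_error(attribute_event(rnorm(5), rnorm(5), 0, event_type = "area_burned"),
               "prediction pools")
})
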