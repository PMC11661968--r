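#' Match a model's years to a target global warming level
#'
#' Computes 10-year trailing moving-mean anomalies of a global-mean
#' temperature series relative to the counterfactual decade, draws
#' `n_samples` Gaussian targets for the human-induced warming, and for each
#' draw selects the window whose anomaly is closest. The reported match is
#' the window selected by the requested percentile of the sampled targets
#' (best estimate = 50th percentile). Windows are trailing (ending at the
#' indexed year); truncated windows at the series end are permitted, and
#' the factual year count is reported so counterfactual pools can be scaled
#' to keep per-model proportions consistent.
#'
#' @param gmst Annual global-mean temperature series.
#' @param years Years corresponding to `gmst`.
#' @param target_mean,target_sd Gaussian parameters of the human-induced
#'   warming estimate (deg C); `target_sd = 0` makes the match deterministic.
#' @param counterfactual_years Years defining the reference decade
#'   (default the first 10 years of the series).
#' @param n_samples Number of Gaussian draws (default 10000).
#' @param quantile Percentile of the sampled targets to report (default 0.5).
#' @param window Window length in years (default 10).
#' @param seed Integer seed for the draws.
#' @return A list of class `warming_level_match`: `anomaly` (data.frame
#'   `year`, `anomaly` for each complete trailing window), `matched_end_year`,
#'   `matched_years`, `matched_anomaly`, `target`, `target_samples`.
#' @export
match_warming_level <- function(gmst, years, target_mean, target_sd,
                                counterfactual_years = years[1:10],
                                n_samples = 10000L, quantile = 0.5,
                                window = 10L, seed = 1L) {
  stopifnot(length(gmst) == length(years), target_sd >= 0)
  if (!all(counterfactual_years %in% years)) {
    stop("series does not cover the counterfactual decade", call. = FALSE)
  }
  base <- mean(gmst[years %in% counterfactual_years])
  ends <- seq(window, length(years))
  anom <- vapply(ends, function(i) mean(gmst[(i - window + 1L):i]) - base,
                 numeric(1))
  anomaly <- data.frame(year = years[ends], anomaly = anom)

  set.seed(.stream_seed(seed, 11L))
  samples <- stats::rnorm(n_samples, target_mean, target_sd)
  target <- percentile(samples, quantile * 100)
  pick <- which.min(abs(anom - target))
  end_year <- anomaly$year[pick]
  matched <- seq(end_year - window + 1L, end_year)
  matched <- matched[matched %in% years]
  structure(list(anomaly = anomaly, matched_end_year = end_year,
                 matched_years = matched, matched_anomaly = anom[pick],
                 target = target, target_samples = samples),
            class = "warming_level_match")
}

#' Tail probability of an equal-weight normal mixture
#'
#' `p = mean_k [1 - Phi((threshold - mu_k) / sigma_k)]`; zero-sd components
#' contribute the indicator `mu_k >= threshold`. This is the exceedance
#' probability of a single year's log10 area burned under the pooled
#' regression-prediction distributions.
#'
#' @param mu Component means (one per pooled realization-year).
#' @param sd Component standard deviations (>= 0), recycled against `mu`.
#' @param threshold Event threshold on the same scale.
#' @return The exceedance probability in `[0, 1]`.
#' @export
mixture_tail_probability <- function(mu, sd, threshold) {
  if (length(mu) == 0L) stop("empty pool", call. = FALSE)
  if (any(sd < 0)) stop("sd must be >= 0", call. = FALSE)
  k <- pmax(length(mu), length(sd))
  mu <- rep_len(mu, k)
  sd <- rep_len(sd, k)
  tails <- ifelse(sd > 0,
                  stats::pnorm(threshold, mean = mu, sd = pmax(sd, 1e-300),
                               lower.tail = FALSE),
                  as.numeric(mu >= threshold))
  mean(tails)
}

#' Empirical tail probability of a pooled sample
#'
#' Fraction of pooled values at least as large as the threshold (ties count
#' as exceedances, matching the "at least as strong as observed" event
#' definition).
#'
#' @param x Pooled values.
#' @param threshold Event threshold.
#' @return The exceedance fraction in `[0, 1]`.
#' @export
empirical_tail_probability <- function(x, threshold) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("empty pool", call. = FALSE)
  mean(x >= threshold)
}

#' Risk ratio from factual and counterfactual probabilities
#'
#' @param p_factual,p_counterfactual Probabilities in `[0, 1]`.
#' @return A list with `rr`, `finite` and `undefined`: `rr = p_f / p_cf`
#'   when `p_cf > 0`; `Inf` (with `finite = FALSE`) when the event never
#'   occurs in the counterfactual but does in the factual climate; both
#'   zero gives an explicit undefined result (`rr = NA`).
#' @export
risk_ratio <- function(p_factual, p_counterfactual) {
  stopifnot(p_factual >= 0, p_factual <= 1,
            p_counterfactual >= 0, p_counterfactual <= 1)
  if (p_counterfactual > 0) {
    list(rr = p_factual / p_counterfactual, finite = TRUE, undefined = FALSE)
  } else if (p_factual > 0) {
    list(rr = Inf, finite = FALSE, undefined = FALSE)
  } else {
    list(rr = NA_real_, finite = FALSE, undefined = TRUE)
  }
}

# internal: exceedance probability of one pool, either empirical values or
# mixture components (data.frame with mean/sd)
.pool_probability <- function(pool, threshold) {
  if (is.data.frame(pool)) {
    mixture_tail_probability(pool$mean, pool$sd, threshold)
  } else {
    empirical_tail_probability(pool, threshold)
  }
}

#' Bootstrap 5th-95th percentile interval for a risk ratio
#'
#' Resamples pooled realization-year entries with replacement independently
#' within the factual and counterfactual pools, recomputes the risk ratio
#' for each replicate, and reports the 5th and 95th percentiles. Infinite
#' replicates are retained, so the upper bound may be infinite; replicates
#' with both probabilities zero are dropped.
#'
#' @param factual,counterfactual Pools: numeric vectors (empirical) or
#'   data.frames with columns `mean`, `sd` (mixture components).
#' @param threshold Event threshold.
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @return A list with `ci_low`, `ci_high` and the replicate vector `rr`.
#' @export
bootstrap_rr_ci <- function(factual, counterfactual, threshold,
                            n_boot = 1000L, seed = 1L) {
  n_f <- if (is.data.frame(factual)) nrow(factual) else length(factual)
  n_c <- if (is.data.frame(counterfactual)) nrow(counterfactual) else length(counterfactual)
  if (n_f == 0L || n_c == 0L) stop("empty pool", call. = FALSE)
  take <- function(pool, idx) if (is.data.frame(pool)) pool[idx, , drop = FALSE] else pool[idx]
  set.seed(.stream_seed(seed, 13L))
  rrs <- vapply(seq_len(n_boot), function(b) {
    pf <- .pool_probability(take(factual, sample.int(n_f, n_f, replace = TRUE)),
                            threshold)
    pc <- .pool_probability(take(counterfactual, sample.int(n_c, n_c, replace = TRUE)),
                            threshold)
    risk_ratio(pf, pc)$rr
  }, numeric(1))
  ok <- rrs[!is.na(rrs)]
  if (length(ok) == 0L) return(list(ci_low = NA_real_, ci_high = NA_real_, rr = rrs))
  # type-7 quantiles on a vector possibly containing Inf: order statistics
  qs <- stats::quantile(ok, c(0.05, 0.95), type = 1, names = FALSE)
  list(ci_low = qs[1], ci_high = qs[2], rr = rrs)
}

#' End-to-end attribution of one event
#'
#' Composes the exceedance probabilities, risk ratio and bootstrap interval
#' for one region and event type. For `event_type = "area_burned"` the pools
#' are regression predictions (`mean`, `sd` per pooled realization-year) and
#' the mixture probability is used; for `"metric_anomaly"` the pools are
#' pooled anomaly values and the empirical probability is used.
#'
#' @param factual,counterfactual Pools as in [bootstrap_rr_ci()].
#' @param threshold The observed event value (log10 area burned, or metric
#'   anomaly).
#' @param event_type `"area_burned"` or `"metric_anomaly"`.
#' @param n_boot,seed Bootstrap settings.
#' @return A list of class `risk_ratio_result`: `event_type`, `p_factual`,
#'   `p_counterfactual`, `rr`, `ci_low`, `ci_high`, `finite`, `undefined`,
#'   `n_factual`, `n_counterfactual`.
#' @export
attribute_event <- function(factual, counterfactual, threshold,
                            event_type = c("metric_anomaly", "area_burned"),
                            n_boot = 1000L, seed = 1L) {
  event_type <- match.arg(event_type)
  if (event_type == "area_burned" &&
      (!is.data.frame(factual) || !is.data.frame(counterfactual))) {
    stop("area_burned attribution requires prediction pools (mean, sd)",
         call. = FALSE)
  }
  pf <- .pool_probability(factual, threshold)
  pc <- .pool_probability(counterfactual, threshold)
  rr <- risk_ratio(pf, pc)
  ci <- bootstrap_rr_ci(factual, counterfactual, threshold,
                        n_boot = n_boot, seed = seed)
  structure(list(
    event_type = event_type, p_factual = pf, p_counterfactual = pc,
    rr = rr$rr, ci_low = ci$ci_low, ci_high = ci$ci_high,
    finite = rr$finite, undefined = rr$undefined,
    n_factual = if (is.data.frame(factual)) nrow(factual) else length(factual),
    n_counterfactual = if (is.data.frame(counterfactual)) nrow(counterfactual)
                       else length(counterfactual)
  ), class = "risk_ratio_result")
}
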