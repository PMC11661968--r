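---
title: "Attribution of extreme wildfire seasons with fireattr: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attribution of extreme wildfire seasons with fireattr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fireattr)
```

## The question the pipeline answers

Given a record-breaking wildfire season, how much did long-term climate
change alter the probability of a season at least that extreme? `fireattr`
answers this with the standard probabilistic event-attribution recipe:
estimate the probability `p_f` of exceeding the observed event value in the
*factual* climate (the world as it is) and the probability `p_cf` in a
*counterfactual* climate with little long-term warming, and report the risk
ratio `RR = p_f / p_cf` with a bootstrap uncertainty interval. The chain runs
from daily weather to fire danger to burned area:

1. daily weather → Canadian Fire Weather Index (FWI) System indices per grid
   cell and day;
2. daily indices → annual, region-level fire-weather metrics;
3. annual metrics → regression-predicted log10 annual area burned per region;
4. pooled factual and counterfactual distributions → exceedance
   probabilities, risk ratios, bootstrap intervals.

Because the real driving archives (reanalyses, coupled-model ensembles,
national burned-area composites) are terabyte-scale external resources, the
package ships a statistically controlled synthetic generator that emulates
their structure. Every stage is therefore testable end to end, and the
attribution machinery is identical whether the inputs are synthetic or real.

## The FWI System engine

The engine implements the standard CFFDRS equations (Van Wagner & Pickett
1985): three fuel-moisture codes with increasing memory — the Fine Fuel
Moisture Code (FFMC, ~1 day), the Duff Moisture Code (DMC, ~2 weeks) and
the Drought Code (DC, ~2 months) — and the behavior indices derived from
them: Initial Spread Index (ISI, from FFMC and wind), Buildup Index (BUI,
from DMC and DC), the Fire Weather Index itself and the Daily Severity
Rating (DSR). Vapour pressure deficit (VPD) is carried alongside as an
additional dryness metric, using the Tetens saturation vapour pressure over
water, `es(T) = 0.6108 exp(17.27 T / (T + 237.3))` kPa; Tetens is the common
hydrometeorological choice where no formula is otherwise mandated.

The system is conventionally driven by local-noon weather. Hourly data are
rarely available from climate models, so the engine uses the daily maximum
temperature and daily minimum relative humidity directly as noon surrogates,
assuming the RH minimum co-occurs with the temperature maximum. This
convention shifts absolute index values slightly relative to true noon
inputs, but anomalies — which carry the attribution — are much less
sensitive. Day-length factors use the standard Northern Hemisphere monthly
tables; a latitude-band variant is a documented possible extension but is
not enabled, since the analysis domain is boreal/temperate North America.

### Fire season and overwintering

The fire season starts on the day after three consecutive days with daily
maximum temperature strictly above 12 °C and ends on the day after three
consecutive days strictly below 5 °C following the start; "after" is read
literally (the alternative — the third day itself — is a one-line change in
`detect_fire_season()`). Ties do not qualify. A year has at most one season
window: a warm spell after the ending cold triple does not restart the
season, a deliberate simplification flagged here because the source
convention is unstated.

The fast FFMC restarts each spring at its default 85. The slow codes
overwinter:

* DMC start-up = `6 + 1.2 × (days since the last rainfall event > 1.5 mm)`.
  The day count runs backward from the season start, searching as far as the
  previous season's end, and is capped at 90 days (configurable) when no
  qualifying event is found — the formula is unbounded otherwise.
* DC start-up follows the Lawson & Armitage (2008) moisture-equivalent
  carry-over: `Qf = 800 exp(-DC_fall/400)`,
  `Qs = a·Qf + b·(3.94·r_w)` with the carry-over fraction `a` and wetting
  efficiency `b` both 0.75, and `DC_start = max(0, 400 ln(800/Qs))`, with
  `Qs` capped at 800. `r_w` is the total off-season precipitation between
  the previous season's end and the current start; whether a sub-window
  should be used instead is unstated in the source convention, so the full
  off-season sum is used.
* The first simulated year has no previous season: DMC uses the rain-gap
  rule within the spin-up window at the start of that year, DC uses the
  system default of 15.

Missing weather inside a detected season aborts that cell-year with an
error rather than gap-filling: deterministic and auditable.

## Annual metrics

Daily index fields are reduced to annual, region-level metrics in two steps.
First, area-weighted regional means over *forested* cells are formed day by
day, with cell areas proportional to `cos(latitude)`; cells outside their
own fire season are excluded from that day's mean. Second, the regional
fire season is detected from the regional-mean daily maximum temperature,
and each registry metric is evaluated over in-season days:

* `7X` / `15X` / `31X`: the fire-season maximum of 7-, 15- and 31-day
  running means (windows fully contained in the season; a season shorter
  than the window falls back to the whole-season mean). These are computed
  for all indices except DC and DSR.
* DC uses the seasonal mean (`DC_season`); DSR the seasonal sum
  (`cDSR_season`); `p95` metrics use the 95th percentile of in-season days.
* `season_length` (= end − start, days) and `season_start` (day of year).

All percentiles in the package — annual p95 metrics and compound-event
thresholds alike — use linear interpolation between order statistics
(`quantile(type = 7)`); the convention is fixed once because different
conventions shift extreme percentiles noticeably on short seasons.

Anomalies are taken relative to a 30-year base period (default 1951–1980).
For a counterfactual ensemble generated under natural-only forcing, the
anomaly baseline is the *paired* factual table, so that any mean offset
between the two worlds is preserved rather than subtracted away.

## Burned-area regression

Per region, ordinary least squares relates `log10` annual area burned to a
single annual metric. The log transform makes the response closer to normal
and prevents extreme seasons from dominating the fit; single-predictor
models are used because the candidate metrics are strongly correlated.
Training years default to a 51-year record that deliberately excludes the
event year. Zero-burn years are floored at 1 ha before the log (the count is
recorded on the model). The best predictor is the candidate with the largest
R²; exact ties break deterministically by registry order. If the best R²
falls below 0.20 the region is excluded from burned-area attribution — the
analog of dropping a region where no robust regression exists.

Predictions carry the *new-observation* standard error,
`sd = sqrt(s² (1 + 1/n + (x0 − x̄)²/Sxx))`. The residual-variance term is
included because the downstream mixture represents the distribution of a
single year's area burned, and year-to-year scatter not explained by fire
weather is physically part of that distribution; `include_residual = FALSE`
switches to the mean-response form if only parameter uncertainty is wanted.
Simulated predictors are mean-shift bias-corrected before prediction:
subtract the simulation's base-period mean, add the observational one. A
detrended-R² check (both series linearly detrended on year before refitting)
guards against fits driven purely by common trends.

## Attribution

**Pools.** Values from all realizations and years of the designated windows
are pooled, factual and counterfactual alike. The factual window is found by
*global-warming-level matching*: 10-year trailing moving-mean anomalies of
the global-mean temperature relative to the counterfactual decade are
compared against Gaussian draws (default 10,000) of the estimated
human-induced warming (default 1.0 °C), and the window whose anomaly is
closest to the requested percentile of the draws (default the 50th) is
selected. Trailing windows were chosen because leading/centered alignments
are equivalent up to a relabeling and the trailing form never uses data
after the matched year. When the matched window is truncated at the series
end, the counterfactual year count is scaled down correspondingly so every
model keeps the same proportional contribution in both pools. The
counterfactual is either the first simulated decade (warming there is small)
or the final 25 years of a natural-forcing ensemble.

**Probabilities.** For area burned, each pooled realization-year contributes
a normal distribution centered on its regression prediction with the
prediction standard error as spread; the equal-weight mixture of these
normals gives the exceedance probability analytically
(`p = mean_k [1 − Φ((T − μ_k)/σ_k)]`, zero-σ components contributing
indicators). For fire-weather metrics and season length, the pools are large
enough that probabilities are estimated empirically — no extra parametric
fit — as the fraction of pooled values `≥` the observed event value ("at
least as extreme" makes the threshold closed).

**Risk ratios.** `RR = p_f / p_cf`. If the event never occurs in the
counterfactual pool but does in the factual one, `RR = ∞` — a meaningful
statement (all of the event's probability is attributable), kept explicit
rather than clamped. Both probabilities zero yields an explicit undefined
result, never silent NaN. Uncertainty is the 5th–95th percentile of risk
ratios across bootstrap replicates (default 1000) that resample pooled
realization-year entries with replacement, independently within each pool;
the resampling unit matches the pooling construction, and infinite
replicates legitimately push the upper bound to infinity. Order-statistic
(type-1) quantiles are used on the replicate set because interpolation is
ill-defined between finite and infinite replicates.

## The compound statistic

National-scale synchrony of extreme fire weather is measured as the
*cumulative high fire-risk area*: for every in-season day, the summed area
of forested cells whose FWI strictly exceeds their local 95th percentile
(computed per cell from in-season days of the base period), accumulated over
the season — units km²·days. In a stationary climate the expected per-day
exceedance fraction is 5% by construction, which the tests verify; under
warming the statistic grows through both more exceedances and longer
seasons, which is exactly the compounding it is meant to capture. Thresholds
are computed from in-season days only (the statistic itself is a seasonal
sum); a calendar-day alternative would lower thresholds by including
shoulder-season days. Cells with no in-season base-period days are excluded
from the statistic entirely rather than imputed.

## The synthetic generator

The generator emulates the statistical skeleton of a gridded initial-
condition ensemble, not any particular model's physics:

* Each variable follows a sinusoidal seasonal cycle plus independent daily
  Gaussian noise (AR(0)); defaults give boreal-plausible fire seasons of
  roughly 150–180 days. Cross-variable dependence is limited to a negative
  tmax–RH coupling (−1.5 %/°C of temperature noise), the dominant covariance
  fire danger responds to.
* Precipitation is Bernoulli wet-day occurrence (default probability 0.35)
  times exponential intensity (mean 4 mm) — enough dry-spell structure to
  exercise DMC/DC dynamics and the overwintering rules.
* Warming is a linear trend on tmax (default 0.35 °C/decade for the factual
  scenario — a regionally amplified rate consistent with ~1 °C of global
  human-induced warming between a 1950s baseline and the 2020s); an optional
  per-realization trend jitter stands in for differing model climate
  sensitivities, a deliberately thin representation of multi-model spread.
* RH is clipped to [0, 100] and wind to ≥ 0 after trend and noise; clip
  counts are recorded on the object.
* The calendar is 365-day no-leap; annual burned area follows
  `log10(AB) = β0 + β1·metric + ε`, `ε ~ N(0, σ²)`, the generative twin of
  the regression stage.
* All generators are seeded; each realization derives an independent stream
  from the base seed, so member 2 is identical whether or not member 1 was
  generated.

What the generator does **not** emulate: realistic spatial covariance,
synoptic persistence (blocking, dry lightning), multi-model structure
beyond trend jitter, or multivariate bias-correction artifacts. Passing
tests therefore demonstrate that the *machinery* is correct and calibrated
under controlled conditions, not that any particular real-world risk ratio
is right.

## Numerical choices and problem sizes

* Guarded logarithms keep vectorized branches finite where the unused branch
  of an `ifelse` would otherwise produce NaN; the guards never affect the
  selected branch.
* Degenerate regression inputs (zero predictor variance, fewer than three
  overlapping years, negative burned area) raise errors; they are not
  silently patched.
* Bootstrap calibration of risk-ratio intervals is an asymptotic property:
  with pools of ~2000 realization-year entries (the scale at which pooled
  ensembles operate) the 5–95% interval covers a null RR of 1 close to the
  nominal 90%; with pools an order of magnitude smaller, percentile
  bootstrap intervals for tail-probability ratios undercover noticeably.
  This is a known property of the estimator, stated here so small-pool runs
  are interpreted accordingly.
* The bundled configuration uses a 6×6 grid, 3 regions, 8 realizations and
  80 years; the test suite uses smaller grids still. These sizes were chosen
  so a complete run is a coffee-break job on one core while every stage
  remains statistically exercised; all sizes scale through the
  configuration.

## Known limitations

* Gridded intermediate fields live in memory per realization (the pipeline
  chunks by realization); there is no NetCDF round-trip in this
  implementation, and tabular artifacts are CSV/JSON.
* Season detection allows one window per year; climates with reliable
  mid-season cold snaps would need the multi-window extension.
* The warming-level match uses a single synthetic "model"; multi-model
  proportional pooling is implemented in the pool construction but exercised
  with one model in the bundled configuration.
* The regression assumes the non-climatic contribution to burned-area
  variance is stationary; the detrended-R² check probes, but cannot prove,
  that assumption.
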