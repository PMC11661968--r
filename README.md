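# fireattr

Probabilistic attribution of extreme wildfire seasons, from daily weather to
risk ratios.

`fireattr` is for climate-impact and fire-ecology researchers who want to ask:
*how much did long-term warming change the probability of a fire season at
least as extreme as an observed one?* It implements the complete chain used
in end-to-end wildfire attribution studies:

1. **FWI System engine** — the Canadian Fire Weather Index System (FFMC, DMC,
   DC, ISI, BUI, FWI, DSR; standard Van Wagner & Pickett 1985 equations) plus
   vapour pressure deficit, driven by daily maximum temperature and daily
   minimum relative humidity as noon surrogates, with temperature-rule fire
   season detection (start after 3 consecutive days > 12 °C, end after 3
   consecutive days < 5 °C) and overwintering of the slow codes
   (DMC start-up = 6 + 1.2 × days since rain > 1.5 mm; DC via the Lawson &
   Armitage carry-over with both fractions at 0.75).
2. **Annual metrics** — fire-season maxima of 7/15/31-day running means,
   seasonal means/sums, p95 metrics, season length and start, as area-weighted
   means over forested grid cells per region, with base-period anomalies.
3. **Burned-area regression** — per-region OLS of log₁₀ annual area burned on
   a single annual metric, best-predictor selection by R² with a 20% floor,
   mean-shift bias correction of simulated predictors, and the
   standard error of prediction
   `sd = √(s²(1 + 1/n + (x₀−x̄)²/Sxx))`.
4. **Attribution** — factual pools selected by global-warming-level matching
   (10-year moving anomalies vs. Gaussian draws of the human-induced warming
   estimate), counterfactual pools from an early decade or natural-forcing
   runs, exceedance probabilities from an equal-weight mixture of normals
   (area burned) or empirically (metric anomalies), and risk ratios
   `RR = p_factual / p_counterfactual` with bootstrap 5th–95th percentile
   intervals (infinite RRs kept explicit).
5. **Compound statistic** — the cumulative high fire-risk area: forested area
   exceeding the local base-period 95th-percentile FWI, summed over every day
   of the fire season.
6. **Synthetic generator** — seeded gridded daily-weather ensembles
   (seasonal cycles, configurable warming/precipitation trends, wet-day ×
   exponential precipitation, tmax–RH coupling), region/forest masks, and
   annual burned area generated from `log10(AB) = β0 + β1·metric + ε`, so the
   whole pipeline runs and is tested without any external data archive.

## Worked example

A complete run on the bundled problem size (6×6 grid, 3 regions, 8
realizations, 1951–2030, +0.35 °C/decade, ~1 minute on one core):

```r
library(fireattr)
cfg <- default_run_config(seed = 1)
res <- run_pipeline(cfg)
print(res$risk_ratios, digits = 3)
```

```
   region                   event p_factual p_counterfactual    rr ci_low ci_high finite
1       1             area_burned    0.2950          0.13160  2.24   1.64    3.08   TRUE
2       2             area_burned    0.0325          0.01301  2.50   1.09    7.17   TRUE
3       3             area_burned    0.0376          0.00592  6.35   2.30   18.77   TRUE
4       1                  FWI_7X    0.4250          0.17500  2.43   1.63    4.20   TRUE
5       1           season_length    0.3750          0.01250 30.00  10.50     Inf   TRUE
6       2                  FWI_7X    0.0125          0.01250  1.00   0.00     Inf   TRUE
7       2           season_length    0.0375          0.00000   Inf    Inf     Inf  FALSE
8       3                  FWI_7X    0.1125          0.02500  4.50   1.50     Inf   TRUE
9       3           season_length    0.0000          0.00000    NA     NA      NA  FALSE
10     NA compound_high_risk_area    0.0250          0.00000   Inf    Inf     Inf  FALSE
```

Reading the table: in region 1 an area burned at least as large as the
pseudo-observed 2023 value has probability 0.295 in the warming-level-matched
factual decade versus 0.132 in the 1951–1960 counterfactual — a risk ratio of
2.2 (90% bootstrap interval 1.6–3.1), i.e. the event was made more than twice
as likely by the imposed warming. A season at least as long as the 2023 one
in region 1 was made ~30 times as likely. `Inf` rows are events that never
occurred in the counterfactual pool (all of their probability is attributable
to the warming); the `NA` row is an event so extreme it appeared in neither
pool — reported as explicitly undefined. Regression details sit in
`res$models`:

```
region 1: predictor FWI_7X, R2 = 0.63, beta1 = 0.227
region 2: predictor FWI_7X, R2 = 0.54, beta1 = 0.249
region 3: predictor FWI_7X, R2 = 0.58, beta1 = 0.267
```

Predictor selection recovered `FWI_7X` — the metric the synthetic burned-area
model was generated from (true β1 = 0.25) — in all three regions.

A command-line wrapper is included for shell use:

```sh
inst/cli/fireattr all --config inst/extdata/config-small.yaml --outdir run1/
```

writing `annual_metrics.csv`, `seasons.csv`, `compound.csv`,
`burned_area.csv`, `risk_ratios.csv`, `models.json` and a `manifest.json`
with the config hash and seeds.

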