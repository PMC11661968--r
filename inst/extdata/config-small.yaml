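# Desk-scale example configuration: 3x3 grid, 2 regions, 2 realizations,
# 1951-2023 with an imposed warming trend of 0.35 degC/decade.
seed: 1
n_regions: 2
forest_fraction: 0.8
counterfactual: early_decade
climate:
  n_realizations: 2
  n_lat: 3
  n_lon: 3
  warming_trend: 0.35
  years: [1951, 2023]  # inclusive range
burned_area:
  beta0: 1.5
  beta1: 0.25
  sigma: 0.35
  predictor: FWI_7X
warming:
  target_mean: 1.0
  target_sd: 0.1
  quantile: 0.5
  n_samples: 2000
attribution_metrics: [FWI_7X, season_length]
n_boot: 200
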