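Package: fireattr
Title: Fire Weather Indices, Burned-Area Regression and Extreme Fire-Season Attribution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end, seeded pipeline for probabilistic attribution of
    extreme wildfire seasons. Computes the Canadian Fire Weather Index (FWI)
    System indices (FFMC, DMC, DC, ISI, BUI, FWI, DSR) and vapour pressure
    deficit from daily weather using the daily-maximum temperature /
    daily-minimum relative humidity convention, detects fire seasons and
    overwinters the slow moisture codes, reduces daily index fields to annual
    region-level fire-weather metrics, fits per-region regressions of log10
    annual area burned on those metrics, and contrasts factual against
    counterfactual climates through mixture-of-normals and empirical exceedance
    probabilities, risk ratios with bootstrap intervals, global-warming-level
    ensemble matching, and a spatially compound cumulative high-fire-risk-area
    statistic. A statistically controlled synthetic-data generator stands in
    for reanalysis and climate-model ensembles so the whole pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
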