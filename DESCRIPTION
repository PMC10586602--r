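Package: musselpatch
Title: Density-Dependent Survival, Condition and Patch Shape in Seasonal
    Blue-Mussel Cage Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing density-dependent cooperation and
    competition in blue-mussel (Mytilus edulis) patches across seasons.
    Provides a seeded synthetic-data generator for a one-year cage
    experiment (seasonal environment series, overdispersed cage survival,
    condition index, binary cover masks), per-cage field metrics
    (condition index, survival standardization to a common horizon with
    non-integer binomial counts), binary-mask patch morphometry
    (perimeter-to-area ratio), a from-scratch quasi-binomial GLM engine
    with Pearson dispersion, heteroskedasticity-robust (sandwich)
    standard errors and Holm correction, per-run log-log density-
    dependence slope statistics, and a reproducible pipeline that
    orchestrates simulation, metrics, model fits and slope profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    yaml,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    withr
Config/testthat/edition: 3
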