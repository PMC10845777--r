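Package: no2burden
Title: Three-Stage Time-Series Analysis of NO2 and Cardiovascular
    Hospital Admissions with Attributable Burden
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for multi-county time-series studies linking short-term
    nitrogen dioxide (NO2) exposure to cause-specific hospital admissions
    and their attributable economic burden, with an urban-rural lens.
    Stage one fits county-level quasi-Poisson distributed-lag regressions
    with natural-spline control for season, temperature and humidity;
    stage two pools county estimates by random-effects meta-analysis,
    transforms them to percentage changes per 10 ug/m3, tests urban-rural
    differences, runs meta-regression on county social covariates and
    meta-smooths nonlinear concentration-response curves; stage three
    converts pooled effects into attributable admissions, hospital days
    and expenses under counterfactual WHO air-quality-guideline
    concentrations. A synthetic-panel generator with known ground truth,
    Kaplan-Meier urban-rural survival contrasts and a health-service
    utilization summary complete the pipeline, which is exercised
    end-to-end on simulated county-day panels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    metafor,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
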