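# no2burden

Tools for multi-county time-series studies of short-term nitrogen
dioxide (NO₂) exposure and cause-specific hospital admissions, with an
urban–rural lens: who is harmed, by how much, and what it costs.

The package is aimed at environmental epidemiologists and health
economists who need the standard three-stage design as a tested,
reusable pipeline rather than a one-off script:

1. **County models** — per-county quasi-Poisson regression with a
   distributed linear lag (0–4 days) for NO₂ and natural-spline control
   for season (7 df/year), 3-day moving-average temperature (6 df) and
   relative humidity (3 df), plus day-of-week and holiday indicators:

   `log E(Y_t) = α + β·NO₂ + DOW + holiday + ns(t) + ns(temp) + ns(rh)`

2. **Pooling** — random-effects meta-analysis (REML, DerSimonian–Laird
   fallback/option) of county log relative risks, overall and by
   urban/rural zone; effects reported as percentage change per
   10 µg/m³, `(e^β − 1)·100`; urban–rural contrasts via
   `Z = (E_u − E_r)/√(SE_u² + SE_r²)`; meta-regression on county social
   covariates; meta-smoothed nonlinear concentration–response curves
   (spline knots at 20 and 40 µg/m³).

3. **Burden** — attributable admissions under counterfactual WHO air
   quality guidelines (10 and 40 µg/m³ annual NO₂),
   `AN = Σ N_ic (RR_ic − 1)/RR_ic` with
   `RR_ic = exp(β · max(D_ic − AQG, 0)/10)`, converted to hospital days
   and expenses through county mean length of stay and mean expense per
   admission.

Because the individual-level admission data behind such studies are
private, the package ships a synthetic county-day panel generator with
known ground truth (seasonal overdispersed counts, lagged NO₂ effects,
meteorological confounding, urban/rural strata), so the whole pipeline
is testable end to end, plus Kaplan–Meier/log-rank urban–rural survival
contrasts and a health-service utilization summary. Published aggregate
tables from a 39-county Shandong study (2015–2017) are included for
arithmetic-identity checks and examples.

## Worked example

```r
library(no2burden)
library(dplyr)

cfg <- sim_config(seed = 2024)   # 10 urban + 10 rural counties, 2 years,
                                 # true effect 1.42% per 10 µg/m³ over lags 0-4
sim <- simulate_panel(cfg)
res <- run_pipeline(pipeline_config(sim$panel, sim$counties,
                                    annual = sim$annual))

filter(res$pooled, lag %in% c("lag0", "lag0-4 cumulative")) |>
  select(stratum, lag, pct, lo, hi, I2, k)
#> # A tibble: 6 × 7
#>   stratum lag                 pct     lo    hi    I2     k
#>   <chr>   <chr>             <dbl>  <dbl> <dbl> <dbl> <dbl>
#> 1 overall lag0              0.884  0.246  1.52  2.68    20
#> 2 overall lag0-4 cumulative 1.80   1.02   2.60  2.08    20
#> 3 urban   lag0              0.594 -0.392  1.59 20.6     10
#> 4 urban   lag0-4 cumulative 1.54   0.463  2.62  0       10
#> 5 rural   lag0              1.17   0.285  2.06  0       10
#> 6 rural   lag0-4 cumulative 2.06   0.706  3.44 32.4     10
```

The generator spreads the injected 1.42%-per-10 µg/m³ effect over lags
0–4 with weights (0.6, 0.2, 0.1, 0.07, 0.03), so the cumulative 0–4
estimate (1.80%, CI 1.02–2.60) covers the full injected truth while the
lag-0 estimate centres near its 0.85% lag-0 component. `I2` is the
between-county heterogeneity share, `k` the number of counties pooled.

```r
filter(res$burden, aqg == 10, outcome == "admissions") |>
  mutate(across(where(is.numeric), ~ round(.x, 1)))
#> # A tibble: 2 × 11
#>   stratum cause outcome      aqg    an an_lo an_hi    af af_lo af_hi total
#> 1 urban   cvd   admissions    10  864. -580. 2272    1.5  -1     4   56540
#> 2 rural   cvd   admissions    10 1648.  408  2861.   3     0.7   5.2 55551
```

Read: had annual NO₂ been at the WHO 2021 guideline (10 µg/m³), about
864 urban and 1648 rural admissions (1.5% and 3.0% of the simulated
totals) would have been avoided; intervals propagate the pooled β's CI.
`plot_lag_effects()`, `autoplot()` on curves/KM objects, and
`tidy()`/`glance()` on fitted objects give the usual tidyverse views.

A thin command-line wrapper (`inst/cli/no2burden-cli.R`) exposes
`simulate`, `validate` and `run` subcommands over the same functions.

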