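#' Simulation configuration for synthetic county-day panels
#'
#' Bundles and validates every parameter of the synthetic-data generator.
#' The defaults describe a two-year, 20-county (10 urban, 10 rural) study
#' in which a 10-ug/m3 rise in NO2 raises expected admissions by 1.42%,
#' distributed over exposure lags 0-4, on top of seasonal, weekday and
#' holiday structure in both the exposure and the counts.
#'
#' @param n_urban_counties,n_rural_counties Number of counties per zone.
#' @param n_years Panel length in years (days = `round(365.25 * n_years)`).
#' @param true_pct_per_10 True percentage change in admissions per
#'   10 ug/m3 NO2; the generative log-relative-risk per ug/m3 is
#'   `log(1 + true_pct_per_10/100) / 10`.
#' @param lag_weights Nonnegative weights over lags 0-4 summing to 1 that
#'   distribute the true effect across exposure days. With
#'   `allow_displacement = TRUE` the weights at lags 2-4 may be negative
#'   (an early excess offset by a later deficit); the sum must still be 1.
#' @param overdispersion Target Pearson dispersion (>= 1) of the counts at
#'   the baseline mean; 1 gives Poisson counts, above 1 negative-binomial
#'   counts with `size = baseline_daily_mean / (overdispersion - 1)`.
#' @param baseline_daily_mean Expected admissions per county-day for a
#'   county of median size.
#' @param no2_mean,no2_sd,no2_ar1 Marginal mean and SD (ug/m3) and lag-1
#'   autocorrelation of the daily NO2 series.
#' @param seasonal_amplitude_no2 Amplitude (ug/m3) of the winter-peaking
#'   annual sinusoid in NO2; the residual AR(1) noise variance is reduced
#'   so the marginal SD stays near `no2_sd`.
#' @param seasonal_amplitude_temp Amplitude (deg C) of the annual
#'   temperature cycle.
#' @param dow_effects Seven multiplicative day-of-week factors on the
#'   count mean, Monday first.
#' @param holiday_effect Multiplicative holiday factor on the count mean.
#' @param confounding_strength Scalar scaling the built-in confounder
#'   coefficients (temperature slope -0.01 per deg C on the log mean and a
#'   winter-peaking seasonal log-amplitude of 0.15); 0 removes all
#'   meteorological/seasonal confounding of the counts.
#' @param copollutant_cor Correlation between the daily NO2 anomaly and
#'   the simulated co-pollutant (PM2.5-like) series.
#' @param allow_displacement Permit negative `lag_weights` at lags 2-4.
#' @param age_groups If `TRUE`, each county-day count is split into
#'   `"60+"` and `"<60"` rows (70% elderly) so elderly-subsample analyses
#'   can be exercised.
#' @param seed Master integer seed; every county draws from its own
#'   substream derived from it.
#'
#' @return A validated list of class `no2_sim_config`.
#' @export
sim_config <- function(n_urban_counties = 10L,
                       n_rural_counties = 10L,
                       n_years = 2L,
                       true_pct_per_10 = 1.42,
                       lag_weights = c(0.6, 0.2, 0.1, 0.07, 0.03),
                       overdispersion = 1.5,
                       baseline_daily_mean = 8,
                       no2_mean = 36.1,
                       no2_sd = 16.0,
                       no2_ar1 = 0.6,
                       seasonal_amplitude_no2 = 8,
                       seasonal_amplitude_temp = 13,
                       dow_effects = c(1.05, 1.05, 1.05, 1.05, 1.05, 0.9, 0.85),
                       holiday_effect = 0.8,
                       confounding_strength = 1,
                       copollutant_cor = 0.7,
                       allow_displacement = FALSE,
                       age_groups = FALSE,
                       seed = 1L) {
  cfg <- list(
    n_urban_counties = check_count(n_urban_counties, "n_urban_counties"),
    n_rural_counties = check_count(n_rural_counties, "n_rural_counties"),
    n_years = check_count(n_years, "n_years"),
    true_pct_per_10 = check_number(true_pct_per_10, "true_pct_per_10",
                                   lower = -99, allow_lower = FALSE),
    lag_weights = lag_weights,
    overdispersion = check_number(overdispersion, "overdispersion", lower = 1),
    baseline_daily_mean = check_number(baseline_daily_mean,
                                       "baseline_daily_mean",
                                       lower = 0, allow_lower = FALSE),
    no2_mean = check_number(no2_mean, "no2_mean", lower = 0, allow_lower = FALSE),
    no2_sd = check_number(no2_sd, "no2_sd", lower = 0),
    no2_ar1 = check_number(no2_ar1, "no2_ar1", lower = -1, upper = 1,
                           allow_lower = FALSE, allow_upper = FALSE),
    seasonal_amplitude_no2 = check_number(seasonal_amplitude_no2,
                                          "seasonal_amplitude_no2", lower = 0),
    seasonal_amplitude_temp = check_number(seasonal_amplitude_temp,
                                           "seasonal_amplitude_temp", lower = 0),
    dow_effects = dow_effects,
    holiday_effect = check_number(holiday_effect, "holiday_effect",
                                  lower = 0, allow_lower = FALSE),
    confounding_strength = check_number(confounding_strength,
                                        "confounding_strength"),
    copollutant_cor = check_number(copollutant_cor, "copollutant_cor",
                                   lower = -1, upper = 1),
    allow_displacement = isTRUE(allow_displacement),
    age_groups = isTRUE(age_groups),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (length(cfg$lag_weights) != 5L || any(!is.finite(cfg$lag_weights))) {
    invalid_argument("`lag_weights` must be 5 finite weights for lags 0-4.")
  }
  if (abs(sum(cfg$lag_weights) - 1) > 1e-12) {
    invalid_argument("`lag_weights` must sum to 1 (within 1e-12).")
  }
  if (!cfg$allow_displacement && any(cfg$lag_weights < 0)) {
    invalid_argument(paste0(
      "negative `lag_weights` require `allow_displacement = TRUE` ",
      "(and are only meaningful at lags 2-4)."))
  }
  if (cfg$allow_displacement && any(cfg$lag_weights[1:2] < 0)) {
    invalid_argument("displacement scenarios allow negative weights at lags 2-4 only.")
  }
  if (length(cfg$dow_effects) != 7L || any(cfg$dow_effects <= 0)) {
    invalid_argument("`dow_effects` must be 7 positive factors (Monday first).")
  }
  structure(cfg, class = "no2_sim_config")
}

# Internal generator constants (scaled by confounding_strength where noted).
.sim_const <- list(
  temp_mean = 14.8, temp_noise_sd = 3,
  rh_mean = 66, rh_amp = 10, rh_noise_sd = 11,
  cop_mean = 63.3, cop_sd = 39.8,
  temp_coef = -0.01,     # log-mean slope per deg C (x strength)
  season_log_amp = 0.15, # winter-peaking seasonal log-amplitude (x strength)
  winter_peak_day = 15   # day-of-year at which NO2/season/counts peak
)

season_cos <- function(day_index) {
  cos(2 * pi * (day_index - .sim_const$winter_peak_day) / 365.25)
}

#' Simulate daily exposure and meteorology series for one county
#'
#' Generates NO2 (winter-peaking sinusoid plus AR(1) noise, truncated at
#' 0.1 ug/m3), a correlated PM2.5-like co-pollutant, daily mean
#' temperature (summer-peaking sinusoid plus noise) and relative humidity
#' (bounded in (0, 100)).
#'
#' @param n_days Series length (>= 30).
#' @param cfg A [sim_config()] object.
#' @param county_seed Integer seed for this county's substream.
#' @return A tibble with columns `day`, `no2`, `copollutant`, `temp`, `rh`.
#' @export
simulate_exposure_series <- function(n_days, cfg, county_seed = cfg$seed) {
  n_days <- check_count(n_days, "n_days", min = 30L)
  stopifnot(inherits(cfg, "no2_sim_config"))
  k <- .sim_const
  with_seed(county_seed, {
    t <- seq_len(n_days)
    seas <- cfg$seasonal_amplitude_no2 * season_cos(t)
    resid_var <- max(cfg$no2_sd^2 - cfg$seasonal_amplitude_no2^2 / 2, 0)
    innov_sd <- sqrt(resid_var * (1 - cfg$no2_ar1^2))
    noise <- as.numeric(stats::filter(rnorm(n_days, 0, innov_sd),
                                      cfg$no2_ar1, method = "recursive"))
    no2 <- pmax(cfg$no2_mean + seas + noise, 0.1)
    # co-pollutant shares the standardized NO2 anomaly at the set correlation
    z_no2 <- if (sd(no2) > 0) (no2 - mean(no2)) / sd(no2) else rep(0, n_days)
    z_cop <- cfg$copollutant_cor * z_no2 +
      sqrt(1 - cfg$copollutant_cor^2) * rnorm(n_days)
    cop <- pmax(k$cop_mean + k$cop_sd * z_cop, 0.1)
    temp <- k$temp_mean -
      cfg$seasonal_amplitude_temp * season_cos(t) +  # peaks in summer
      rnorm(n_days, 0, k$temp_noise_sd)
    rh <- pmin(pmax(k$rh_mean + k$rh_amp * -season_cos(t) +
                      rnorm(n_days, 0, k$rh_noise_sd), 1), 99)
    tibble(day = t, no2 = no2, copollutant = cop, temp = temp, rh = rh)
  })
}

# Synthetic holiday calendar: 10 fixed month-day dates per year plus a
# movable 7-day block starting between Jan 21 and Feb 20 (drawn once per
# year from the master seed).
synthetic_holidays <- function(years, seed) {
  fixed_md <- c("01-01", "04-05", "05-01", "06-22", "08-15",
                "09-10", "10-01", "10-02", "10-03", "12-25")
  starts <- with_seed(seed + 211L, sample(21:51, length(years), replace = TRUE))
  out <- lapply(seq_along(years), function(i) {
    y <- years[i]
    fixed <- as.Date(paste0(y, "-", fixed_md))
    block <- as.Date(paste0(y, "-01-01")) + (starts[i] - 1L) + 0:6
    c(fixed, block)
  })
  sort(unique(do.call(c, out)))
}

#' Simulate a multi-county admission panel with known ground truth
#'
#' Draws, for each county, an exposure/meteorology series and daily
#' admission counts from a negative-binomial (Poisson when
#' `overdispersion = 1`) log-linear model: county intercept + distributed
#' NO2 lag effects + day-of-week + holiday + seasonal and temperature
#' confounding. County intercepts are log-uniform around
#' `log(baseline_daily_mean)` so counties differ in size. Exposure series
#' include a 4-day burn-in so every panel day has a full lag history.
#'
#' @param cfg A [sim_config()] object.
#' @return A list of class `no2_panel_sim` with elements
#'   \describe{
#'     \item{panel}{county-day tibble: `county_id, date, cause, admissions,
#'       no2, copollutant, temp, rh, holiday` (plus `age_group` when
#'       requested).}
#'     \item{counties}{county metadata: `county_id, zone, avg_expense,
#'       avg_stay, gdp_per_capita, beds_per_1000`.}
#'     \item{annual}{long annual table: `county_id, year, n_admissions,
#'       no2_annual_mean`.}
#'     \item{truth}{ground truth: `beta_true` (log-RR per ug/m3), per-lag
#'       `beta_lags`, county intercepts `alpha`, confounder coefficients.}
#'   }
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "no2_sim_config"))
  k <- .sim_const
  n_c <- cfg$n_urban_counties + cfg$n_rural_counties
  n_days <- round(365.25 * cfg$n_years)
  start <- as.Date("2015-01-01")
  dates <- start + seq_len(n_days) - 1L
  years <- sort(unique(as.integer(format(dates, "%Y"))))
  holidays <- synthetic_holidays(years, cfg$seed)

  county_id <- sprintf("C%02d", seq_len(n_c))
  zone <- c(rep("urban", cfg$n_urban_counties), rep("rural", cfg$n_rural_counties))
  seeds <- county_seeds(cfg$seed, n_c)

  beta_true <- log(1 + cfg$true_pct_per_10 / 100) / 10
  beta_lags <- cfg$lag_weights * beta_true  # per ug/m3, lags 0-4
  # log-uniform county size from each county's own substream, so that
  # subsetting counties never shifts another county's draws
  alpha <- log(cfg$baseline_daily_mean) + vapply(
    seq_len(n_c), function(i) with_seed(seeds[i] + 3L, stats::runif(1, -0.5, 0.5)),
    numeric(1))

  dow <- as.integer(format(dates, "%u"))  # 1 = Monday
  hol <- as.integer(dates %in% holidays)
  theta <- if (cfg$overdispersion > 1) {
    cfg$baseline_daily_mean / (cfg$overdispersion - 1)
  } else Inf

  one_county <- function(i) {
    expo <- simulate_exposure_series(n_days + 4L, cfg, seeds[i])
    idx <- 5:(n_days + 4L)  # panel days, with 4 burn-in days behind them
    lagged <- vapply(0:4, function(l) expo$no2[idx - l], numeric(n_days))
    # 3-day moving-average temperature enters the true mean (lags 0-2)
    ma_temp <- (expo$temp[idx] + expo$temp[idx - 1L] + expo$temp[idx - 2L]) / 3
    log_mu <- alpha[i] + drop(lagged %*% beta_lags) +
      log(cfg$dow_effects[dow]) + hol * log(cfg$holiday_effect) +
      cfg$confounding_strength *
        (k$temp_coef * ma_temp + k$season_log_amp * season_cos(idx))
    mu <- exp(log_mu)
    y <- with_seed(seeds[i] + 1L, {
      if (is.finite(theta)) rnbinom(n_days, size = theta, mu = mu)
      else rpois(n_days, mu)
    })
    out <- tibble(
      county_id = county_id[i], date = dates, cause = "cvd",
      admissions = y, no2 = expo$no2[idx], copollutant = expo$copollutant[idx],
      temp = expo$temp[idx], rh = expo$rh[idx], holiday = hol
    )
    if (cfg$age_groups) {
      eld <- with_seed(seeds[i] + 2L, rbinom(n_days, y, 0.7))
      out <- bind_rows(
        mutate(out, age_group = "60+", admissions = eld),
        mutate(out, age_group = "<60", admissions = y - eld)
      ) |> arrange(.data$date, .data$age_group)
    }
    out
  }
  panel <- purrr::map_dfr(seq_len(n_c), one_county)

  counties <- with_seed(cfg$seed + 97L, tibble(
    county_id = county_id, zone = zone,
    avg_expense = pmax(rnorm(n_c, ifelse(zone == "urban", 10.9, 7.0),
                             ifelse(zone == "urban", 1.5, 1.0)), 1),
    avg_stay = pmax(rnorm(n_c, ifelse(zone == "urban", 19, 9),
                          ifelse(zone == "urban", 2, 1)), 1),
    gdp_per_capita = pmax(rnorm(n_c, ifelse(zone == "urban", 82000, 77000), 8000), 1e4),
    beds_per_1000 = pmax(rnorm(n_c, ifelse(zone == "urban", 6, 4),
                               ifelse(zone == "urban", 1, 0.8)), 0.5)
  ))

  annual <- panel |>
    mutate(year = as.integer(format(.data$date, "%Y"))) |>
    group_by(.data$county_id, .data$year) |>
    summarise(n_admissions = sum(.data$admissions),
              no2_annual_mean = mean(.data$no2), .groups = "drop")

  truth <- structure(list(
    beta_true = beta_true, beta_lags = beta_lags,
    alpha = stats::setNames(alpha, county_id),
    confounders = list(
      temp_coef = cfg$confounding_strength * k$temp_coef,
      season_log_amp = cfg$confounding_strength * k$season_log_amp,
      dow_effects = cfg$dow_effects, holiday_effect = cfg$holiday_effect),
    config = unclass(cfg)), class = "no2_truth")

  structure(list(panel = panel, counties = counties, annual = annual,
                 truth = truth, holidays = holidays),
            class = "no2_panel_sim")
}

#' Simulate urban/rural survival records
#'
#' Exponential event times per zone with independent exponential
#' censoring; the rural hazard is `hazard_ratio_rural` times the urban
#' hazard. The censoring rate sets the marginal probability that a record
#' is censored before its event.
#'
#' @param n_per_zone Subjects per zone.
#' @param hazard_ratio_rural Rural/urban hazard ratio (> 0).
#' @param censor_rate Probability of censoring, in `[0, 1)`.
#' @param seed Integer seed.
#' @param baseline_hazard Urban hazard rate per unit follow-up time.
#' @return A tibble `id, zone, time, event` (event is 0/1).
#' @export
simulate_survival <- function(n_per_zone, hazard_ratio_rural = 1,
                              censor_rate = 0.3, seed = 1L,
                              baseline_hazard = 0.1) {
  n_per_zone <- check_count(n_per_zone, "n_per_zone")
  check_number(hazard_ratio_rural, "hazard_ratio_rural",
               lower = 0, allow_lower = FALSE)
  check_number(censor_rate, "censor_rate", lower = 0, upper = 1,
               allow_upper = FALSE)
  check_number(baseline_hazard, "baseline_hazard", lower = 0, allow_lower = FALSE)
  with_seed(seed, {
    zone <- rep(c("urban", "rural"), each = n_per_zone)
    rate <- ifelse(zone == "rural", baseline_hazard * hazard_ratio_rural,
                   baseline_hazard)
    t_event <- rexp(2 * n_per_zone, rate)
    if (censor_rate > 0) {
      # exponential censoring with P(C < T) = censor_rate within each zone
      c_rate <- rate * censor_rate / (1 - censor_rate)
      t_cens <- rexp(2 * n_per_zone, c_rate)
    } else {
      t_cens <- rep(Inf, 2 * n_per_zone)
    }
    tibble(id = seq_len(2 * n_per_zone), zone = zone,
           time = pmin(t_event, t_cens),
           event = as.integer(t_event <= t_cens))
  })
}

#' Write a simulated panel to CSV files with a ground-truth sidecar
#'
#' Writes `panel.csv`, `counties.csv` and `annual.csv` (UTF-8, comma
#' separated, ISO dates) plus `truth.json`.
#'
#' @param sim A [simulate_panel()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_panel <- function(sim, dir) {
  stopifnot(inherits(sim, "no2_panel_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(sim$panel, file.path(dir, "panel.csv"))
  readr::write_csv(sim$counties, file.path(dir, "counties.csv"))
  readr::write_csv(sim$annual, file.path(dir, "annual.csv"))
  truth <- sim$truth
  truth$alpha <- as.list(truth$alpha)
  jsonlite::write_json(unclass(truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
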