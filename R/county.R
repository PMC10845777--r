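# Stage 1: county-level overdispersed Poisson log-linear models with
# distributed NO2 lags and natural-spline confounder control.

#' Confounder configuration for the county model
#'
#' Degrees of freedom mirror the standard specification for admission
#' time series: a calendar-time spline with 7 df per year, 6 df for the
#' 3-day moving-average temperature, 3 df for the 3-day moving-average
#' relative humidity, plus day-of-week and holiday indicators.
#'
#' @param time_df_per_year Calendar-time spline df per year.
#' @param temp_df,rh_df Spline df for smoothed temperature / humidity.
#' @param ma_window Moving-average window (days) for temperature and
#'   humidity, covering the present and previous days.
#' @return A list of class `no2_confounders`.
#' @export
confounder_config <- function(time_df_per_year = 7, temp_df = 6, rh_df = 3,
                              ma_window = 3L) {
  structure(list(
    time_df_per_year = check_number(time_df_per_year, "time_df_per_year",
                                    lower = 0, allow_lower = FALSE),
    temp_df = check_count(temp_df, "temp_df"),
    rh_df = check_count(rh_df, "rh_df"),
    ma_window = check_count(ma_window, "ma_window")
  ), class = "no2_confounders")
}

#' Quasi-Poisson fit by iteratively reweighted least squares
#'
#' Poisson log-linear point estimates with standard errors inflated by
#' the square root of the Pearson dispersion (Pearson chi-square over
#' residual df). The design matrix is used as given (include an intercept
#' column if one is wanted).
#'
#' @param y Nonnegative integer response.
#' @param X Numeric design matrix of full column rank.
#' @return An object of class `no2_qpfit`: coefficients, dispersion-scaled
#'   covariance, Pearson dispersion, deviance, fitted values.
#' @export
fit_quasi_poisson <- function(y, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (any(!is.finite(y)) || any(y < 0) || any(y != floor(y))) {
    invalid_argument("`y` must be nonnegative integers.")
  }
  if (nrow(X) != length(y)) invalid_argument("`X` rows must match length(y).")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("design matrix is rank deficient; collinear column(s): ",
                 paste(bad, collapse = ", ")),
          class = "no2burden_rank_deficiency")
  }
  fit <- suppressWarnings(stats::glm.fit(
    x = X, y = y, family = quasipoisson(link = "log"),
    control = list(epsilon = 1e-8, maxit = 100)))
  if (!fit$converged) {
    abort(sprintf("IRLS did not converge within %d iterations (deviance %.6g).",
                  100L, fit$deviance),
          class = "no2burden_convergence")
  }
  mu <- fit$fitted.values
  n <- length(y); p <- ncol(X)
  pearson <- sum((y - mu)^2 / mu)
  dispersion <- if (n > p) pearson / (n - p) else 0
  xtwx <- crossprod(X * sqrt(mu))
  vc <- dispersion * chol2inv(chol(xtwx))
  dimnames(vc) <- list(colnames(X), colnames(X))
  structure(list(
    coefficients = stats::setNames(fit$coefficients, colnames(X)),
    vcov = vc, dispersion = dispersion, deviance = fit$deviance,
    n_obs = n, df_residual = n - p, fitted = mu, y = y,
    iter = fit$iter, converged = fit$converged
  ), class = "no2_qpfit")
}

#' @export
print.no2_qpfit <- function(x, ...) {
  cat(sprintf("Quasi-Poisson fit: %d obs, %d coefficients, dispersion %.3f\n",
              x$n_obs, length(x$coefficients), x$dispersion))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.no2_qpfit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  z <- x$coefficients / se
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients),
         std.error = unname(se), statistic = unname(z),
         p.value = unname(2 * pnorm(-abs(z))))
}

#' @exportS3Method generics::glance
glance.no2_qpfit <- function(x, ...) {
  tibble(dispersion = x$dispersion, deviance = x$deviance,
         df.residual = x$df_residual, nobs = x$n_obs, niter = x$iter)
}

# Assemble the stage-1 design matrix for one county's records.
# Returns list(X, y, keep, exposure_cols) or NULL when too short.
build_county_design <- function(data, holidays, confounders, lag,
                                co_pollutant = NULL, no2_basis = NULL) {
  n <- nrow(data)
  drop_n <- max(if (inherits(lag, "no2_lag_spec")) lag$max_lag else 0L,
                confounders$ma_window - 1L)
  keep <- seq_len(n) > drop_n
  cal <- calendar_design(data$date, holidays)
  ma_temp <- moving_average_met(data$temp, confounders$ma_window)
  ma_rh <- moving_average_met(data$rh, confounders$ma_window)
  temp_b <- ns_basis(ma_temp[keep], df = confounders$temp_df)$basis
  colnames(temp_b) <- paste0("temp", seq_len(ncol(temp_b)))
  rh_b <- ns_basis(ma_rh[keep], df = confounders$rh_df)$basis
  colnames(rh_b) <- paste0("rh", seq_len(ncol(rh_b)))
  if (!is.null(no2_basis)) {
    expo <- eval_basis(no2_basis, data$no2)
    colnames(expo) <- paste0("no2_ns", seq_len(ncol(expo)))
  } else {
    expo <- lag_matrix(data$no2, lag)$matrix
  }
  X <- cbind(`(Intercept)` = 1, expo[keep, , drop = FALSE],
             cal[keep, , drop = FALSE], temp_b, rh_b)
  if (!is.null(co_pollutant)) {
    X <- cbind(X, copollutant = data[[co_pollutant]][keep])
  }
  list(X = X, y = data$admissions[keep], keep = keep,
       exposure_cols = colnames(expo))
}

#' Fit one county's distributed-lag NO2 model
#'
#' A single quasi-Poisson model containing NO2 at lags 0-4
#' simultaneously plus the full confounder set (calendar-time spline,
#' day-of-week, holiday, smoothed temperature and humidity splines, and
#' optionally a lag-0 co-pollutant term). Effects are reported per
#' 10 ug/m3: single-day effects are the individual lag coefficients
#' scaled by 10; the cumulative lag 0-k effect is 10 times the sum of
#' the first k+1 lag coefficients with variance `1' V 1` over that
#' coefficient block. With `lag$kind = "moving_average"` a separate model
#' with one moving-average exposure term is fitted instead.
#'
#' @param data One county's records (columns `county_id, date, cause,
#'   admissions, no2, temp, rh, holiday`, optionally a co-pollutant and
#'   `age_group`).
#' @param cause Cause label to filter on.
#' @param confounders A [confounder_config()].
#' @param lag A [lag_spec()]; default single-day lags 0-4.
#' @param co_pollutant Optional co-pollutant column name, entered linearly
#'   at lag 0.
#' @param holidays Optional `Date` vector; defaults to the panel's
#'   `holiday` flag column.
#' @param elderly_only If `TRUE`, keep only `age_group == "60+"` rows
#'   before aggregating to county-days.
#' @param min_days Minimum usable days after lag trimming (default 365);
#'   shorter series are flagged excluded rather than fitted.
#' @return An object of class `no2_county_fit` with elements `estimates`
#'   (tibble `county_id, cause, lag, beta_per10, se, dispersion, n_days`),
#'   `fit` (the [fit_quasi_poisson()] object) and `excluded` (logical,
#'   with a `reason` when `TRUE`).
#' @export
fit_county_dlm <- function(data, cause = "cvd",
                           confounders = confounder_config(),
                           lag = lag_spec("single", 4L),
                           co_pollutant = NULL, holidays = NULL,
                           elderly_only = FALSE, min_days = 365L) {
  stopifnot(inherits(confounders, "no2_confounders"),
            inherits(lag, "no2_lag_spec"))
  data <- dplyr::filter(data, .data$cause == !!cause)
  if (elderly_only) {
    if (!"age_group" %in% names(data)) {
      invalid_argument("`elderly_only = TRUE` needs an `age_group` column.")
    }
    data <- dplyr::filter(data, .data$age_group == "60+")
  }
  if ("age_group" %in% names(data)) {
    data <- data |>
      group_by(across(dplyr::all_of(
        setdiff(names(data), c("admissions", "age_group"))))) |>
      summarise(admissions = sum(.data$admissions), .groups = "drop")
  }
  data <- arrange(data, .data$date)
  county <- if (nrow(data)) data$county_id[1] else NA_character_
  if (is.null(holidays)) holidays <- data$date[data$holiday == 1]

  drop_n <- max(lag$max_lag, confounders$ma_window - 1L)
  usable <- nrow(data) - drop_n
  if (usable < min_days) {
    return(structure(list(
      county_id = county, cause = cause, excluded = TRUE,
      reason = sprintf("only %d usable days after lag trimming (< %d)",
                       max(usable, 0), min_days),
      estimates = tibble(), fit = NULL), class = "no2_county_fit"))
  }

  d <- build_county_design(data, holidays, confounders, lag, co_pollutant)
  fit <- fit_quasi_poisson(d$y, d$X)
  ec <- d$exposure_cols
  b <- fit$coefficients[ec]
  V <- fit$vcov[ec, ec, drop = FALSE]
  n_days <- length(d$y)

  if (lag$kind == "moving_average") {
    est <- tibble(lag = sprintf("lag0-%d MA", lag$max_lag),
                  beta_per10 = 10 * unname(b),
                  se = 10 * sqrt(unname(diag(V))))
  } else {
    single <- tibble(lag = paste0("lag", 0:lag$max_lag),
                     beta_per10 = 10 * unname(b),
                     se = 10 * sqrt(unname(diag(V))))
    cum <- purrr::map_dfr(0:lag$max_lag, function(k) {
      idx <- seq_len(k + 1)
      tibble(lag = sprintf("lag0-%d cumulative", k),
             beta_per10 = 10 * sum(b[idx]),
             se = 10 * sqrt(sum(V[idx, idx])))
    })
    est <- bind_rows(single, cum)
  }
  est <- mutate(est, county_id = county, cause = cause,
                dispersion = fit$dispersion, n_days = n_days,
                .before = 1)
  structure(list(county_id = county, cause = cause, excluded = FALSE,
                 estimates = est, fit = fit, exposure_cols = ec),
            class = "no2_county_fit")
}

#' Fit the distributed-lag model in every county
#'
#' @param panel County-day panel for all counties.
#' @param counties County metadata with `county_id` and `zone`.
#' @param ... Passed to [fit_county_dlm()].
#' @return A tibble of per-county effect estimates (`county_id, zone,
#'   cause, lag, beta_per10, se, dispersion, n_days`) with an
#'   `"exclusions"` attribute listing counties flagged excluded and why.
#' @export
fit_all_counties <- function(panel, counties, ...) {
  fits <- panel |>
    dplyr::group_split(.data$county_id) |>
    purrr::map(fit_county_dlm, ...)
  excl <- purrr::keep(fits, ~ .x$excluded)
  if (length(excl)) {
    warn(sprintf("%d county(ies) excluded at stage 1: %s", length(excl),
                 paste(purrr::map_chr(excl, "county_id"), collapse = ", ")))
  }
  ok <- purrr::discard(fits, ~ .x$excluded)
  est <- if (length(ok)) {
    purrr::map_dfr(ok, "estimates") |>
      left_join(select(counties, "county_id", "zone"), by = "county_id") |>
      dplyr::relocate("zone", .after = "county_id")
  } else {
    tibble(county_id = character(), zone = character(), cause = character(),
           lag = character(), beta_per10 = numeric(), se = numeric(),
           dispersion = numeric(), n_days = integer())
  }
  attr(est, "exclusions") <- tibble(
    county_id = purrr::map_chr(excl, "county_id"),
    reason = purrr::map_chr(excl, "reason"))
  est
}

#' Fit one county's nonlinear concentration-response model
#'
#' NO2 at lag 0 enters as a natural cubic spline with explicit internal
#' knots (defaults 20 and 40 ug/m3); all other confounders are as in the
#' linear model. Returns the exposure-basis coefficient block and its
#' covariance for meta-smoothing.
#'
#' @param data One county's records.
#' @param cause Cause label.
#' @param knots Internal knot concentrations (ug/m3); must lie inside the
#'   county's observed NO2 range.
#' @param boundary Optional common boundary knots (ug/m3) shared across
#'   counties so the bases are identical for pooling; defaults to the
#'   county's observed range.
#' @param confounders A [confounder_config()].
#' @param holidays Optional holiday dates.
#' @return List of class `no2_curve_fit`: `coef`, `vcov`, `basis`
#'   (the exposure [ns_basis()]), `county_id`.
#' @export
fit_nonlinear_no2 <- function(data, cause = "cvd", knots = c(20, 40),
                              boundary = NULL,
                              confounders = confounder_config(),
                              holidays = NULL) {
  data <- dplyr::filter(data, .data$cause == !!cause) |> arrange(.data$date)
  rng <- range(data$no2)
  if (any(knots <= rng[1]) || any(knots >= rng[2])) {
    invalid_argument(sprintf(
      "knots (%s) must lie strictly inside the observed NO2 range [%.1f, %.1f].",
      paste(knots, collapse = ", "), rng[1], rng[2]))
  }
  if (is.null(holidays)) holidays <- data$date[data$holiday == 1]
  basis <- ns_basis(data$no2, df = length(knots) + 1L, knots = knots,
                    boundary = boundary %||% rng)
  d <- build_county_design(data, holidays, confounders,
                           lag = lag_spec("single", 0L), no2_basis = basis)
  fit <- fit_quasi_poisson(d$y, d$X)
  ec <- d$exposure_cols
  structure(list(coef = fit$coefficients[ec],
                 vcov = fit$vcov[ec, ec, drop = FALSE],
                 basis = basis, county_id = data$county_id[1],
                 dispersion = fit$dispersion),
            class = "no2_curve_fit")
}
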