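# Stage 3: attributable admissions, hospital days and expenses under
# counterfactual WHO air-quality-guideline (AQG) concentrations.

#' Relative risk at an annual concentration versus a guideline
#'
#' `RR = exp(beta_per10 * max(D - AQG, 0) / 10)`. Concentrations at or
#' below the guideline contribute no excess risk (the counterfactual is
#' a reduction to the guideline, never an increase).
#'
#' @param beta_per10 Pooled log relative risk per 10 ug/m3.
#' @param D Annual mean NO2 concentration(s), ug/m3.
#' @param aqg Guideline concentration, ug/m3 (> 0).
#' @return Relative risk(s), >= 1 when `beta_per10 >= 0`.
#' @export
rr_at_concentration <- function(beta_per10, D, aqg) {
  check_number(aqg, "aqg", lower = 0, allow_lower = FALSE)
  if (any(!is.finite(beta_per10)) || any(!is.finite(D))) {
    invalid_argument("`beta_per10` and `D` must be finite.")
  }
  exp(beta_per10 * pmax(D - aqg, 0) / 10)
}

an_for_beta <- function(beta, exposures, aqg) {
  rr <- rr_at_concentration(beta, exposures$no2_annual_mean, aqg)
  exposures$n_admissions * (rr - 1) / rr
}

#' Attributable admissions under a counterfactual guideline
#'
#' County-year attributable numbers `AN_ic = N_ic (RR_ic - 1)/RR_ic` with
#' `RR_ic = exp(beta (D_ic - AQG)/10)` (clamped at the guideline), summed
#' into a stratum total; the attributable fraction is
#' `AF = 100 AN / sum(N_ic)`. Interval endpoints come from pushing the
#' pooled beta's CI endpoints through the same (monotone) formula.
#'
#' @param pooled A [pool_random_effects()] object (or list with `beta`,
#'   `ci_lo`, `ci_hi` on the per-10 log-RR scale).
#' @param exposures Tibble of county-years: `county_id, year,
#'   n_admissions, no2_annual_mean`.
#' @param aqg Guideline concentration, ug/m3.
#' @return A list of class `no2_burden`: `an`, `an_lo`, `an_hi`, `af`,
#'   `af_lo`, `af_hi` (AF in percent), `total` (sum of `N_ic`), and
#'   `by_county` (tibble `county_id, an, an_lo, an_hi`).
#' @export
attributable_admissions <- function(pooled, exposures, aqg) {
  if (is.null(exposures) || nrow(exposures) == 0) {
    invalid_argument("`exposures` must be non-empty.")
  }
  total <- sum(exposures$n_admissions)
  ans <- lapply(c(pooled$beta, pooled$ci_lo, pooled$ci_hi),
                an_for_beta, exposures = exposures, aqg = aqg)
  an_ic <- tibble(county_id = exposures$county_id,
                  an = ans[[1]], an_lo = ans[[2]], an_hi = ans[[3]]) |>
    group_by(.data$county_id) |>
    summarise(across(c("an", "an_lo", "an_hi"), sum), .groups = "drop")
  an <- vapply(ans, sum, numeric(1))
  structure(list(an = an[1], an_lo = an[2], an_hi = an[3],
                 af = 100 * an[1] / total, af_lo = 100 * an[2] / total,
                 af_hi = 100 * an[3] / total, total = total,
                 outcome = "admissions", aqg = aqg, by_county = an_ic),
            class = "no2_burden")
}

#' Attributable hospital days and expenses
#'
#' Converts per-county attributable admissions into hospital days and
#' expenses via the county mean length of stay (`avg_stay`, days) and
#' mean expense per admission (`avg_expense`, thousand CNY):
#' `AN_days_c = avg_stay_c * AN_c`, `AN_exp_c = avg_expense_c * AN_c`.
#' Attributable fractions divide the stratum totals of days/expenses.
#'
#' @param adm An [attributable_admissions()] result (uses `by_county`).
#' @param costs Tibble `county_id, avg_expense, avg_stay` covering every
#'   county with a nonzero attributable number.
#' @param total_days,total_expenses Stratum totals of observed hospital
#'   days and expenses (thousand CNY) forming the AF denominators.
#' @return A list with elements `days` and `expenses`, each of class
#'   `no2_burden`.
#' @export
attributable_days_expenses <- function(adm, costs, total_days, total_expenses) {
  stopifnot(inherits(adm, "no2_burden"))
  bc <- adm$by_county
  missing <- setdiff(bc$county_id[abs(bc$an) > 0], costs$county_id)
  if (length(missing)) {
    invalid_argument(paste0("missing cost record for county(ies): ",
                            paste(missing, collapse = ", ")))
  }
  d <- left_join(bc, costs, by = "county_id") |>
    mutate(avg_stay = dplyr::coalesce(.data$avg_stay, 0),
           avg_expense = dplyr::coalesce(.data$avg_expense, 0))
  mk <- function(weight, total, outcome) {
    an <- sum(d[["an"]] * weight); lo <- sum(d[["an_lo"]] * weight)
    hi <- sum(d[["an_hi"]] * weight)
    structure(list(an = an, an_lo = lo, an_hi = hi,
                   af = 100 * an / total, af_lo = 100 * lo / total,
                   af_hi = 100 * hi / total, total = total,
                   outcome = outcome, aqg = adm$aqg,
                   by_county = tibble(county_id = d$county_id,
                                      an = d$an * weight,
                                      an_lo = d$an_lo * weight,
                                      an_hi = d$an_hi * weight)),
              class = "no2_burden")
  }
  list(days = mk(d$avg_stay, total_days, "days"),
       expenses = mk(d$avg_expense, total_expenses, "expenses"))
}

#' @export
print.no2_burden <- function(x, ...) {
  cat(sprintf("Attributable %s at AQG %.0f: AN %.0f (%.0f, %.0f); AF %.2f%% (%.2f, %.2f)\n",
              x$outcome, x$aqg, x$an, x$an_lo, x$an_hi, x$af, x$af_lo, x$af_hi))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.no2_burden <- function(x, ...) {
  tibble(outcome = x$outcome, aqg = x$aqg, an = x$an, an_lo = x$an_lo,
         an_hi = x$an_hi, af = x$af, af_lo = x$af_lo, af_hi = x$af_hi,
         total = x$total)
}

#' Attributable-burden scenario table across guidelines and strata
#'
#' One row per stratum x cause x outcome x guideline, using the
#' stratum-specific pooled effect, the stratum's county-year exposures,
#' and the county cost table. Stratum totals of hospital days and
#' expenses default to `sum(N_c * avg_stay_c)` and
#' `sum(N_c * avg_expense_c)` over the stratum's counties.
#'
#' @param pooled_tbl Tibble with columns `stratum`, `cause`, `beta`,
#'   `se` (per-10 log-RR scale), e.g. a filtered [pool_by_stratum()]
#'   output for the chosen lag.
#' @param exposures County-year exposures (`county_id, year,
#'   n_admissions, no2_annual_mean`).
#' @param costs County costs (`county_id, avg_expense, avg_stay`).
#' @param counties County metadata mapping `county_id` to `zone`.
#' @param aqg Guideline concentrations, ug/m3 (defaults WHO 2021 = 10
#'   and WHO 2005 = 40).
#' @return A tibble `stratum, cause, outcome, aqg, an, an_lo, an_hi, af,
#'   af_lo, af_hi, total`.
#' @export
scenario_report <- function(pooled_tbl, exposures, costs, counties,
                            aqg = c(10, 40)) {
  purrr::pmap_dfr(
    expand.grid(row = seq_len(nrow(pooled_tbl)), g = aqg), function(row, g) {
      p <- pooled_tbl[row, ]
      ids <- if (p$stratum == "overall") counties$county_id
             else counties$county_id[counties$zone == p$stratum]
      ex <- dplyr::filter(exposures, .data$county_id %in% ids)
      pe <- list(beta = p$beta, ci_lo = p$beta - qnorm(0.975) * p$se,
                 ci_hi = p$beta + qnorm(0.975) * p$se)
      adm <- attributable_admissions(pe, ex, g)
      totals <- ex |>
        group_by(.data$county_id) |>
        summarise(n = sum(.data$n_admissions), .groups = "drop") |>
        left_join(costs, by = "county_id")
      de <- attributable_days_expenses(
        adm, costs,
        total_days = sum(totals$n * totals$avg_stay),
        total_expenses = sum(totals$n * totals$avg_expense))
      purrr::map_dfr(list(adm, de$days, de$expenses), tidy) |>
        mutate(stratum = p$stratum, cause = p$cause, .before = 1)
    })
}

#' Attributable fraction from published stratum counts
#'
#' The bookkeeping identity `AF = 100 * AN / total`, applied to printed
#' attributable numbers and stratum outcome totals.
#'
#' @param an Attributable number (admissions, days, or thousand CNY).
#' @param total Stratum total of the same outcome.
#' @return AF in percent.
#' @export
attributable_fraction <- function(an, total) {
  if (any(total <= 0)) invalid_argument("`total` must be positive.")
  100 * an / total
}
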