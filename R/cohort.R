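# Explanatory cohort analyses: health-service utilization by facility
# level and urban/rural Kaplan-Meier survival contrast.

.facility_levels <- c("primary", "secondary", "tertiary")

#' Health-service utilization by zone and facility level
#'
#' Per-zone admission counts and percentage shares by facility level,
#' and median (Q1, Q3) expense per admission by zone x level and per
#' zone overall.
#'
#' @param records Tibble of admission records: `zone` (urban/rural),
#'   `facility_level` (primary/secondary/tertiary), `expense`
#'   (nonnegative, thousand CNY).
#' @param zone_totals Optional named vector of zone admission totals to
#'   use as share denominators (for registers whose totals include
#'   admissions without a classified facility); defaults to the zone
#'   record counts.
#' @return A list of class `no2_utilization`: `counts` (tibble `zone,
#'   facility_level, n, share` with share in percent of the zone total)
#'   and `expenses` (tibble `zone, facility_level, median, q1, q3`,
#'   including a `total` row per zone).
#' @export
utilization_table <- function(records, zone_totals = NULL) {
  if (is.null(records) || nrow(records) == 0) {
    invalid_argument("`records` must be non-empty.")
  }
  bad <- setdiff(unique(records$facility_level), .facility_levels)
  if (length(bad)) {
    invalid_argument(paste0("unknown facility level(s): ",
                            paste(bad, collapse = ", ")))
  }
  counts <- records |>
    dplyr::count(.data$zone, .data$facility_level, name = "n") |>
    group_by(.data$zone) |>
    mutate(share = 100 * .data$n /
             (if (is.null(zone_totals)) sum(.data$n)
              else zone_totals[[dplyr::cur_group()$zone]])) |>
    ungroup()
  summarise_exp <- function(d, lvl) {
    d |>
      group_by(.data$zone) |>
      summarise(facility_level = lvl,
                median = median(.data$expense),
                q1 = quantile(.data$expense, 0.25, names = FALSE),
                q3 = quantile(.data$expense, 0.75, names = FALSE),
                .groups = "drop")
  }
  expenses <- if ("expense" %in% names(records)) {
    bind_rows(
      summarise_exp(records, "total"),
      records |>
        dplyr::group_split(.data$facility_level) |>
        purrr::map_dfr(~ summarise_exp(.x, .x$facility_level[1]))
    )
  } else tibble()
  structure(list(counts = counts, expenses = expenses),
            class = "no2_utilization")
}

#' @export
print.no2_utilization <- function(x, ...) {
  cat("Health-service utilization by zone and facility level:\n")
  print(as.data.frame(x$counts))
  invisible(x)
}

#' Kaplan-Meier survival curves by zone
#'
#' Product-limit estimator per zone (events precede censorings at tied
#' times): `S(0) = 1`, right-continuous non-increasing steps at event
#' times; censored subjects leave the risk set without a step.
#'
#' @param records Tibble `zone, time, event` (event 0/1; time > 0).
#' @return A tibble of class `no2_km`: `zone, time, n_risk, n_event,
#'   n_censor, surv` (one row per distinct observed time per zone, plus
#'   the `time = 0, surv = 1` origin). Attribute `degenerate` is `TRUE`
#'   when no events occurred.
#' @export
km_curve <- function(records) {
  if (any(records$time <= 0)) invalid_argument("all `time` values must be > 0.")
  n_events <- sum(records$event)
  fit <- survival::survfit(survival::Surv(time, event) ~ zone, data = records)
  st <- summary(fit, censored = TRUE)
  zone <- sub("^zone=", "", as.character(st$strata))
  out <- tibble(zone = zone, time = st$time, n_risk = st$n.risk,
                n_event = st$n.event, n_censor = st$n.censor,
                surv = st$surv)
  origin <- tibble(zone = unique(zone), time = 0,
                   n_risk = as.numeric(table(records$zone)[unique(zone)]),
                   n_event = 0, n_censor = 0, surv = 1)
  out <- bind_rows(origin, out) |> arrange(.data$zone, .data$time)
  attr(out, "degenerate") <- n_events == 0
  if (n_events == 0) warn("no events observed; survival curves are flat at 1.")
  class(out) <- c("no2_km", class(out))
  out
}

#' Log-rank test for a zone difference in survival
#'
#' Unweighted log-rank test comparing the two zones, with a 1-df
#' chi-square p-value.
#'
#' @param records Tibble `zone, time, event` containing exactly two
#'   zones and at least one event.
#' @return A tibble `chisq, df, p`.
#' @export
log_rank_test <- function(records) {
  if (length(unique(records$zone)) != 2) {
    invalid_argument("log-rank test needs exactly two zones.")
  }
  if (sum(records$event) < 1) invalid_argument("need at least one event.")
  sd <- survival::survdiff(survival::Surv(time, event) ~ zone, data = records)
  tibble(chisq = unname(sd$chisq), df = 1L,
         p = stats::pchisq(unname(sd$chisq), df = 1, lower.tail = FALSE))
}
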