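# ggplot2 displays for the main result types.

#' Plot pooled percentage changes by lag and stratum
#'
#' Point estimates with 95% CIs per lag, faceted by cause, coloured by
#' stratum — the usual lag-structure display for multi-site time-series
#' studies.
#'
#' @param pooled A [pool_by_stratum()] tibble.
#' @return A ggplot object.
#' @export
plot_lag_effects <- function(pooled) {
  ggplot2::ggplot(pooled, ggplot2::aes(x = .data$lag, y = .data$pct,
                                       colour = .data$stratum)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::facet_wrap(~cause) +
    ggplot2::labs(x = NULL, y = "Percentage change per 10 µg/m³ NO₂",
                  colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a pooled concentration-response curve
#'
#' @param object A [pool_curves()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.no2_pooled_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$no2, y = .data$logrr)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "NO₂ (µg/m³)",
                  y = "Log relative risk vs reference") +
    ggplot2::theme_minimal()
}

#' Plot Kaplan-Meier curves by zone
#'
#' @param object A [km_curve()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.no2_km <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$surv,
                                       colour = .data$zone)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Follow-up time", y = "Survival probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an attributable-burden scenario table
#'
#' Attributable numbers with intervals per stratum and outcome, faceted
#' by guideline and cause.
#'
#' @param burden A [scenario_report()] tibble.
#' @return A ggplot object.
#' @export
plot_burden <- function(burden) {
  ggplot2::ggplot(burden, ggplot2::aes(x = .data$outcome, y = .data$an,
                                       fill = .data$stratum)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$an_lo, ymax = .data$an_hi),
                           position = ggplot2::position_dodge(width = 0.9),
                           width = 0.2) +
    ggplot2::facet_grid(cause ~ aqg, labeller = ggplot2::label_both,
                        scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Attributable number", fill = NULL) +
    ggplot2::theme_minimal()
}
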