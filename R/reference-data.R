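#' Published reference tables from a Shandong urban-rural NO2 study
#'
#' Aggregate summary tables published by a 39-county urban-rural study
#' of short-term NO2 exposure and cardiovascular admissions in Shandong
#' Province, China (2015-2017; about 303,000 CVD admissions). Three
#' tables are packaged:
#' \describe{
#'   \item{burden}{attributable numbers (with 95% CIs) of admissions,
#'     hospital days and expenses (thousand CNY) under the WHO 2021
#'     annual guideline (10 ug/m3), together with the stratum outcome
#'     totals forming the attributable-fraction denominators. The rural
#'     hypertension expense total is reproduced as printed even though
#'     it is inconsistent with its column total; it is not used by any
#'     function here.}
#'   \item{effects}{pooled percentage changes (95% CI) in admissions per
#'     10 ug/m3 NO2 at lag 0 and the lag 0-4 moving average, by stratum
#'     and cause.}
#'   \item{utilization}{admission counts by zone and facility level,
#'     with the published zone admission totals used as share
#'     denominators.}
#' }
#' These support arithmetic-identity checks (AF = 100 AN / total,
#' facility shares, urban-rural Z tests recovered from printed CIs) and
#' worked examples; the study's individual-level data are not public.
#'
#' @return A list of tibbles: `burden`, `effects`, `utilization`.
#' @export
shandong_reference_tables <- function() {
  rd <- function(f) readr::read_csv(
    system.file("extdata", f, package = "no2burden", mustWork = TRUE),
    show_col_types = FALSE)
  list(burden = rd("shandong_burden_2021aqg.csv"),
       effects = rd("shandong_effects_lag.csv"),
       utilization = rd("shandong_utilization.csv"))
}
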