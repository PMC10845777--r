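# Regression design components: natural cubic spline bases, exposure lag
# matrices, calendar indicators, and moving-average smoothing.

#' Natural cubic spline basis
#'
#' Builds an `ns()`-style natural cubic spline basis (no intercept
#' column): `df` columns, linear beyond the boundary knots. Internal
#' knots default to the `i/df` quantiles (i = 1..df-1) of the unique
#' values of `x`; explicit `knots` (e.g. 20 and 40 ug/m3 for the
#' nonlinear concentration-response model) override quantile placement.
#'
#' @param x Numeric vector.
#' @param df Basis dimension (>= 1).
#' @param knots Optional explicit internal knot positions.
#' @param boundary Optional boundary knots (default `range(x)`). Passing
#'   a common boundary across counties makes their bases identical, a
#'   requirement for meta-smoothing.
#' @return An object of class `no2_spline_basis`: list with `basis`
#'   (n x df matrix), `df`, `knots`, `boundary`, `x`.
#' @export
ns_basis <- function(x, df, knots = NULL, boundary = NULL) {
  df <- check_count(df, "df")
  if (!is.numeric(x) || length(x) == 0) invalid_argument("`x` must be numeric.")
  ux <- sort(unique(x[is.finite(x)]))
  if (is.null(knots)) {
    if (length(ux) <= df) {
      abort(sprintf(
        "rank deficiency: df = %d needs more than %d distinct values.",
        df, length(ux)), class = "no2burden_rank_deficiency")
    }
    knots <- if (df > 1) quantile(ux, probs = seq_len(df - 1) / df, names = FALSE)
             else numeric(0)
  } else {
    knots <- sort(as.numeric(knots))
    df <- length(knots) + 1L
  }
  boundary <- if (is.null(boundary)) range(ux) else sort(as.numeric(boundary))
  B <- splines::ns(x, knots = knots, Boundary.knots = boundary, intercept = FALSE)
  stopifnot(ncol(B) == df)
  structure(list(basis = unclass(B)[, , drop = FALSE], df = df,
                 knots = as.numeric(knots), boundary = boundary, x = x),
            class = "no2_spline_basis")
}

#' Evaluate a spline basis at new values
#'
#' @param object A [ns_basis()] result.
#' @param newx Numeric values (may lie outside the boundary knots, where
#'   the basis continues linearly).
#' @return A `length(newx)` x `df` matrix.
#' @export
eval_basis <- function(object, newx) {
  stopifnot(inherits(object, "no2_spline_basis"))
  unclass(splines::ns(newx, knots = object$knots,
                      Boundary.knots = object$boundary, intercept = FALSE))
}

#' Lag specification
#'
#' @param kind One of `"single"`, `"cumulative"`, `"moving_average"`.
#' @param max_lag Maximum lag in days, 0-4.
#' @return A list of class `no2_lag_spec`.
#' @export
lag_spec <- function(kind = c("single", "cumulative", "moving_average"),
                     max_lag = 4L) {
  kind <- match.arg(kind)
  max_lag <- check_count(max_lag, "max_lag", min = 0L)
  if (max_lag > 4L) invalid_argument("`max_lag` must be between 0 and 4.")
  structure(list(kind = kind, max_lag = max_lag), class = "no2_lag_spec")
}

#' Lagged exposure matrix
#'
#' For `single`/`cumulative` kinds, returns one column per lag
#' 0..`max_lag` (column `l` at row `t` is `series[t - l]`); for
#' `moving_average`, one column holding the mean of lags 0..`max_lag`.
#' The first `max_lag` rows have incomplete lag history and are reported
#' in `dropped`.
#'
#' @param series Numeric exposure series (length > `max_lag`).
#' @param spec A [lag_spec()].
#' @return List of class `no2_lag_matrix`: `matrix` (rows aligned with
#'   `series`, leading rows `NA`), `dropped` (row indices to discard).
#' @export
lag_matrix <- function(series, spec) {
  stopifnot(inherits(spec, "no2_lag_spec"))
  n <- length(series)
  L <- spec$max_lag
  if (!is.numeric(series) || n <= L) {
    invalid_argument("`series` must be numeric with length > max_lag.")
  }
  shift <- function(l) c(rep(NA_real_, l), series[seq_len(n - l)])
  cols <- vapply(0:L, shift, numeric(n))
  if (spec$kind == "moving_average") {
    m <- matrix(rowMeans(cols), ncol = 1,
                dimnames = list(NULL, sprintf("no2_ma0_%d", L)))
  } else {
    m <- cols
    colnames(m) <- sprintf("no2_lag%d", 0:L)
  }
  structure(list(matrix = m, dropped = seq_len(L)), class = "no2_lag_matrix")
}

# round-half-up, used for spline df arithmetic
round_half_up <- function(x) floor(x + 0.5)

#' Calendar design matrix
#'
#' Day-of-week indicators (six columns, Monday as reference), a holiday
#' indicator, and a natural cubic spline of the day index with
#' `round(7 * n_years)` degrees of freedom, where `n_years` defaults to
#' `n_days / 365.25` so a fractional final year contributes
#' proportionally.
#'
#' @param dates Consecutive `Date` vector.
#' @param holidays `Date` vector of holidays.
#' @param n_years Span in years; computed from `dates` when `NULL`.
#' @return A numeric matrix with named columns `dow_tue`..`dow_sun`,
#'   `holiday`, `time1`..`timeK`; the spline basis is attached as
#'   attribute `"time_basis"`.
#' @export
calendar_design <- function(dates, holidays = as.Date(character()),
                            n_years = NULL) {
  if (!inherits(dates, "Date") || length(dates) < 2) {
    invalid_argument("`dates` must be a Date vector of length >= 2.")
  }
  if (any(diff(as.integer(dates)) != 1L)) {
    invalid_argument("`dates` must be consecutive calendar days.")
  }
  n <- length(dates)
  n_years <- n_years %||% (n / 365.25)
  df_time <- max(round_half_up(7 * n_years), 1L)
  dow <- as.integer(format(dates, "%u"))  # 1 = Monday
  dow_m <- vapply(2:7, function(d) as.numeric(dow == d), numeric(n))
  colnames(dow_m) <- paste0("dow_", c("tue", "wed", "thu", "fri", "sat", "sun"))
  hol <- as.numeric(dates %in% holidays)
  tb <- ns_basis(seq_len(n), df = df_time)
  time_m <- tb$basis
  colnames(time_m) <- paste0("time", seq_len(ncol(time_m)))
  out <- cbind(dow_m, holiday = hol, time_m)
  attr(out, "time_basis") <- tb
  out
}

#' Trailing moving average of a meteorological series
#'
#' Value at day `t` is the mean of days `t, t-1, ..., t-window+1`; the
#' first `window - 1` values are `NA`.
#'
#' @param series Numeric series (length >= `window`).
#' @param window Window length in days (default 3).
#' @return Numeric vector the length of `series`.
#' @export
moving_average_met <- function(series, window = 3L) {
  window <- check_count(window, "window")
  n <- length(series)
  if (!is.numeric(series) || n < window) {
    invalid_argument("`series` must be numeric with length >= window.")
  }
  cs <- cumsum(series)
  out <- rep(NA_real_, n)
  idx <- window:n
  out[idx] <- (cs[idx] - c(0, cs)[idx - window + 1L]) / window
  out
}
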