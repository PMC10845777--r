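# Stage 2: random-effects pooling of county estimates, percentage-change
# transforms, urban-rural difference tests, meta-regression, and
# meta-smoothing of concentration-response curves.

#' Percentage change per 10 ug/m3 from a log relative risk
#'
#' `pct = (exp(beta) - 1) * 100` with Wald 95% CI endpoints
#' `(exp(beta -/+ 1.96 se) - 1) * 100`.
#'
#' @param beta Log relative risk (per 10 ug/m3).
#' @param se Standard error on the same scale.
#' @return A tibble with columns `pct`, `lo`, `hi`.
#' @export
percentage_change <- function(beta, se) {
  if (any(!is.finite(beta)) || any(!is.finite(se)) || any(se < 0)) {
    invalid_argument("`beta` and `se` must be finite with se >= 0.")
  }
  z <- qnorm(0.975)
  tibble(pct = (exp(beta) - 1) * 100,
         lo = (exp(beta - z * se) - 1) * 100,
         hi = (exp(beta + z * se) - 1) * 100)
}

#' Recover a log-scale estimate from a printed percentage CI
#'
#' Inverse of [percentage_change()]: `beta = log(1 + pct/100)` and
#' `se = [log(1 + hi/100) - log(1 + lo/100)] / (2 * 1.96)`. Used to work
#' with published percentage changes and their confidence intervals.
#'
#' @param pct,lo,hi Point estimate and 95% CI in percent (all > -100,
#'   `lo < pct < hi`).
#' @return A tibble with columns `beta`, `se`.
#' @export
ci_to_log_scale <- function(pct, lo, hi) {
  if (any(c(pct, lo, hi) <= -100) || any(lo >= pct) || any(pct >= hi)) {
    invalid_argument("need -100 < lo < pct < hi.")
  }
  z <- qnorm(0.975)
  tibble(beta = log(1 + pct / 100),
         se = (log(1 + hi / 100) - log(1 + lo / 100)) / (2 * z))
}

# Fixed-effect Q statistic and the Higgins I^2 derived from it.
q_i2 <- function(beta, se) {
  w <- 1 / se^2
  yw <- sum(w * beta) / sum(w)
  Q <- sum(w * (beta - yw)^2)
  k <- length(beta)
  I2 <- if (Q > 0) max(0, (Q - (k - 1)) / Q) * 100 else 0
  list(Q = Q, I2 = I2)
}

#' Random-effects pooling of county effect estimates
#'
#' Pools per-county log relative risks by random-effects meta-analysis:
#' between-county variance tau^2 by REML (default) or DerSimonian-Laird,
#' pooled effect as the inverse-variance weighted mean with weights
#' `1/(se^2 + tau^2)`, Wald 95% interval, and Higgins I^2 computed from
#' the fixed-effect Q statistic. A single estimate is returned as-is
#' with `tau2 = 0` and a degenerate flag.
#'
#' @param estimates Tibble with columns `beta_per10` and `se` (extra
#'   columns such as `county_id`, `cause`, `lag` are carried through to
#'   the label fields when constant).
#' @param method `"REML"` (default), `"DL"`, or `"FE"` for the classical
#'   fixed-effect inverse-variance pool (tau^2 forced to zero).
#' @param stratum Label recorded in the result (e.g. `"urban"`).
#' @return An object of class `no2_pooled`: `beta`, `se`, `ci_lo`,
#'   `ci_hi`, `tau2`, `I2`, `Q`, `k`, `pct`, `pct_lo`, `pct_hi`,
#'   `stratum`, `cause`, `lag`, `degenerate`.
#' @export
pool_random_effects <- function(estimates, method = c("REML", "DL", "FE"),
                                stratum = "overall") {
  method <- match.arg(method)
  if (nrow(estimates) == 0) invalid_argument("no estimates to pool (k = 0).")
  if (any(!is.finite(estimates$beta_per10)) || any(estimates$se <= 0)) {
    invalid_argument("all estimates need finite beta and se > 0.")
  }
  lab <- function(col) {
    v <- estimates[[col]]
    if (!is.null(v) && length(unique(v)) == 1) v[1] else NA_character_
  }
  b <- estimates$beta_per10; s <- estimates$se; k <- length(b)
  if (k == 1) {
    pc <- percentage_change(b, s)
    return(structure(list(beta = b, se = s,
                          ci_lo = b - qnorm(0.975) * s,
                          ci_hi = b + qnorm(0.975) * s,
                          tau2 = 0, I2 = 0, Q = 0, k = 1L,
                          pct = pc$pct, pct_lo = pc$lo, pct_hi = pc$hi,
                          stratum = stratum, cause = lab("cause"),
                          lag = lab("lag"), method = method,
                          degenerate = TRUE), class = "no2_pooled"))
  }
  fit <- tryCatch(
    metafor::rma(yi = b, sei = s, method = method,
                 control = list(maxiter = 200, threshold = 1e-10)),
    error = function(e) {
      if (method == "REML") {
        warn("REML pooling did not converge; falling back to DerSimonian-Laird.")
        metafor::rma(yi = b, sei = s, method = "DL")
      } else {
        abort(conditionMessage(e), class = "no2burden_convergence")
      }
    })
  qi <- q_i2(b, s)
  beta <- as.numeric(fit$beta); se <- as.numeric(fit$se)
  pc <- percentage_change(beta, se)
  structure(list(beta = beta, se = se,
                 ci_lo = beta - qnorm(0.975) * se,
                 ci_hi = beta + qnorm(0.975) * se,
                 tau2 = as.numeric(fit$tau2), I2 = qi$I2, Q = qi$Q,
                 k = k, pct = pc$pct, pct_lo = pc$lo, pct_hi = pc$hi,
                 stratum = stratum, cause = lab("cause"), lag = lab("lag"),
                 method = method, degenerate = FALSE),
            class = "no2_pooled")
}

#' @export
print.no2_pooled <- function(x, ...) {
  cat(sprintf(
    "Pooled effect [%s, %s, %s]: %.2f%% (%.2f to %.2f) per 10 ug/m3; tau2 %.3g, I2 %.1f%%, k %d\n",
    x$stratum, x$cause %||% "?", x$lag %||% "?", x$pct, x$pct_lo, x$pct_hi,
    x$tau2, x$I2, x$k))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.no2_pooled <- function(x, ...) {
  tibble(stratum = x$stratum, cause = x$cause, lag = x$lag,
         beta = x$beta, se = x$se, ci_lo = x$ci_lo, ci_hi = x$ci_hi,
         pct = x$pct, pct_lo = x$pct_lo, pct_hi = x$pct_hi)
}

#' @exportS3Method generics::glance
glance.no2_pooled <- function(x, ...) {
  tibble(tau2 = x$tau2, I2 = x$I2, Q = x$Q, k = x$k, method = x$method,
         degenerate = x$degenerate)
}

#' Pool estimates overall and by stratum for every cause and lag
#'
#' @param estimates Output of [fit_all_counties()] (needs a `zone`
#'   column when `by = "zone"`).
#' @param by Stratification column, or `NULL` for overall only.
#' @param method Passed to [pool_random_effects()].
#' @return A tibble `stratum, cause, lag, beta, se, pct, lo, hi, tau2,
#'   I2, k`, one row per stratum x cause x lag (strata are `overall`
#'   plus each level of `by`).
#' @export
pool_by_stratum <- function(estimates, by = "zone", method = "REML") {
  strata <- list(overall = estimates)
  if (!is.null(by)) {
    lv <- unique(estimates[[by]])
    strata <- c(strata,
                stats::setNames(lapply(lv, function(z)
                  estimates[estimates[[by]] == z, , drop = FALSE]), lv))
  }
  purrr::imap_dfr(strata, function(d, nm) {
    d |>
      dplyr::group_split(.data$cause, .data$lag) |>
      purrr::map_dfr(function(g) {
        p <- pool_random_effects(g, method = method, stratum = nm)
        tibble(stratum = nm, cause = p$cause, lag = p$lag,
               beta = p$beta, se = p$se, pct = p$pct, lo = p$pct_lo,
               hi = p$pct_hi, tau2 = p$tau2, I2 = p$I2, k = p$k)
      })
  })
}

#' Two-sample test for an urban-rural difference in pooled effects
#'
#' `Z = (E_urban - E_rural) / sqrt(SE_urban^2 + SE_rural^2)` with a
#' two-sided p-value from the standard normal.
#'
#' @param pooled_urban,pooled_rural [pool_random_effects()] objects for
#'   the same cause and lag (or lists with `beta` and `se`).
#' @return A tibble of class `no2_difference`: `cause, lag, e_urban,
#'   se_urban, e_rural, se_rural, z, p`.
#' @export
urban_rural_test <- function(pooled_urban, pooled_rural) {
  same <- function(f) {
    a <- pooled_urban[[f]]; b <- pooled_rural[[f]]
    is.null(a) || is.null(b) || is.na(a) || is.na(b) || identical(a, b)
  }
  if (!same("cause") || !same("lag")) {
    invalid_argument("urban and rural estimates must be for the same cause and lag.")
  }
  z <- (pooled_urban$beta - pooled_rural$beta) /
    sqrt(pooled_urban$se^2 + pooled_rural$se^2)
  out <- tibble(cause = pooled_urban$cause %||% NA_character_,
                lag = pooled_urban$lag %||% NA_character_,
                e_urban = pooled_urban$beta, se_urban = pooled_urban$se,
                e_rural = pooled_rural$beta, se_rural = pooled_rural$se,
                z = z, p = 2 * pnorm(-abs(z)))
  class(out) <- c("no2_difference", class(out))
  out
}

#' Meta-regression of county effects on county-level covariates
#'
#' Mixed-effects (REML) meta-regression of per-county log relative risks
#' on county-level social covariates such as GDP per capita or hospital
#' beds per 1000 residents.
#'
#' @param estimates Per-county estimates (one row per county for a fixed
#'   cause and lag) with `county_id`, `beta_per10`, `se`.
#' @param county_covariates Tibble with `county_id` and the moderator
#'   columns.
#' @param moderators Character vector of moderator column names.
#' @return A tibble of moderator coefficients (`term, estimate,
#'   std.error, statistic, p.value`) with attributes `residual_I2`
#'   (from the residual Q statistic) and `k`.
#' @export
meta_regression <- function(estimates, county_covariates,
                            moderators = c("gdp_per_capita", "beds_per_1000")) {
  d <- left_join(estimates, county_covariates, by = "county_id")
  if (anyNA(d[moderators])) {
    invalid_argument("covariates missing for some pooled counties.")
  }
  k <- nrow(d); p <- length(moderators)
  if (k <= p + 1) invalid_argument("need k > p + 1 counties for meta-regression.")
  M <- cbind(1, as.matrix(d[moderators]))
  if (qr(M)$rank < ncol(M)) {
    abort("collinear (or constant) moderators; coefficients undefined.",
          class = "no2burden_rank_deficiency")
  }
  fit <- metafor::rma(yi = d$beta_per10, sei = d$se,
                      mods = stats::as.formula(
                        paste("~", paste(moderators, collapse = " + "))),
                      data = d, method = "REML",
                      control = list(maxiter = 200, threshold = 1e-10))
  res_I2 <- if (fit$QE > 0) max(0, (fit$QE - (k - ncol(M))) / fit$QE) * 100 else 0
  out <- tibble(term = rownames(fit$beta), estimate = as.numeric(fit$beta),
                std.error = as.numeric(fit$se),
                statistic = as.numeric(fit$zval),
                p.value = as.numeric(fit$pval))
  attr(out, "residual_I2") <- res_I2
  attr(out, "tau2") <- as.numeric(fit$tau2)
  attr(out, "k") <- k
  out
}

#' Meta-smooth county concentration-response curves
#'
#' Pools county-specific exposure-spline coefficient vectors by
#' multivariate random-effects (REML) meta-analysis and evaluates the
#' pooled curve on a concentration grid, centered to zero log relative
#' risk at the reference concentration. When the multivariate fit fails
#' to converge, pooling falls back to coefficient-wise univariate
#' random-effects pooling (ignoring cross-coefficient covariance) with a
#' warning.
#'
#' @param fits List of [fit_nonlinear_no2()] objects sharing identical
#'   internal and boundary knots.
#' @param grid Concentrations at which to evaluate the curve; defaults
#'   to 100 points across the shared boundary range.
#' @param reference Centering concentration; defaults to the midpoint of
#'   the shared boundary range (use the grand-mean NO2 of the study).
#' @return A tibble of class `no2_pooled_curve`: `no2, logrr, lo, hi`;
#'   attributes `coef`, `vcov`, `reference`, `pooling`.
#' @export
pool_curves <- function(fits, grid = NULL, reference = NULL) {
  stopifnot(length(fits) >= 1)
  b0 <- fits[[1]]$basis
  for (f in fits) {
    if (!isTRUE(all.equal(f$basis$knots, b0$knots)) ||
        !isTRUE(all.equal(f$basis$boundary, b0$boundary))) {
      invalid_argument("all counties must share identical spline knots and boundaries.")
    }
  }
  p <- length(fits[[1]]$coef)
  k <- length(fits)
  if (k == 1) {
    bpool <- fits[[1]]$coef
    Vpool <- fits[[1]]$vcov
    pooling <- "single-county"
  } else {
    long <- purrr::imap_dfr(fits, function(f, i)
      tibble(county = i, coef_id = factor(seq_len(p)), yi = unname(f$coef)))
    Vlist <- purrr::map(fits, "vcov")
    mv <- tryCatch(
      metafor::rma.mv(yi = long$yi,
                      V = as.matrix(Matrix::bdiag(Vlist)),
                      mods = ~ coef_id - 1,
                      random = ~ coef_id | county, struct = "UN",
                      data = long,
                      control = list(iter.max = 200, rel.tol = 1e-8)),
      error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(mv)) {
      bpool <- as.numeric(mv$beta)
      Vpool <- as.matrix(stats::vcov(mv))
      pooling <- "multivariate REML"
    } else {
      warn("multivariate meta-smoothing did not converge; falling back to coefficient-wise univariate pooling.")
      uni <- purrr::map(seq_len(p), function(j) {
        est <- tibble(beta_per10 = purrr::map_dbl(fits, ~ unname(.x$coef[j])),
                      se = purrr::map_dbl(fits, ~ sqrt(.x$vcov[j, j])))
        pool_random_effects(est)
      })
      bpool <- purrr::map_dbl(uni, "beta")
      Vpool <- diag(purrr::map_dbl(uni, "se")^2, nrow = p)
      pooling <- "univariate fallback"
    }
  }
  reference <- reference %||% mean(b0$boundary)
  grid <- grid %||% seq(b0$boundary[1], b0$boundary[2], length.out = 100)
  Bg <- eval_basis(b0, grid)
  Br <- eval_basis(b0, reference)
  D <- sweep(Bg, 2, as.numeric(Br))
  logrr <- drop(D %*% bpool)
  se <- sqrt(pmax(rowSums((D %*% Vpool) * D), 0))
  out <- tibble(no2 = grid, logrr = logrr,
                lo = logrr - qnorm(0.975) * se,
                hi = logrr + qnorm(0.975) * se)
  attr(out, "coef") <- bpool
  attr(out, "vcov") <- Vpool
  attr(out, "reference") <- reference
  attr(out, "pooling") <- pooling
  class(out) <- c("no2_pooled_curve", class(out))
  out
}
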