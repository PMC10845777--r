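# Stage-1 quasi-Poisson distributed-lag fitting.

test_that("intercept-only fit on constant counts is exact", {
  y <- rep(7L, 40)
  f <- fit_quasi_poisson(y, matrix(1, 40, 1, dimnames = list(NULL, "int")))
  expect_equal(unname(f$coefficients), log(7), tolerance = 1e-10)
  expect_equal(f$dispersion, 0, tolerance = 1e-10)
})

test_that("IRLS coefficients match an independent Newton maximizer", {
  set.seed(11)
  X <- cbind(1, rnorm(50), runif(50))
  colnames(X) <- c("int", "a", "b")
  y <- rpois(50, exp(0.5 + 0.3 * X[, 2] - 0.2 * X[, 3]))
  f <- fit_quasi_poisson(y, X)
  oracle <- newton_poisson(y, X)
  expect_lt(max(abs(f$coefficients - oracle)), 1e-6)
})

test_that("Pearson dispersion of Poisson data is near one", {
  set.seed(12)
  X <- cbind(1, rnorm(1000))
  y <- rpois(1000, exp(1 + 0.2 * X[, 2]))
  f <- fit_quasi_poisson(y, X)
  expect_gt(f$dispersion, 0.85)
  expect_lt(f$dispersion, 1.15)
})

test_that("rank-deficient designs are rejected with the offending column", {
  X <- cbind(int = 1, a = 1:20, dup = 2 * (1:20))
  expect_error(fit_quasi_poisson(rpois(20, 5), X), regexp = "dup",
               class = "no2burden_rank_deficiency")
  expect_error(fit_quasi_poisson(c(1.5, 2), cbind(1, 1:2)),
               class = "no2burden_invalid_argument")
})

make_lag0_sim <- function(seed = 19) {
  simulate_panel(sim_config(n_urban_counties = 1, n_rural_counties = 1,
                            n_years = 3, lag_weights = c(1, 0, 0, 0, 0),
                            baseline_daily_mean = 15, seed = seed))
}

test_that("the distributed-lag model recovers a pure lag-0 effect", {
  sim <- make_lag0_sim()
  f <- fit_county_dlm(dplyr::filter(sim$panel, county_id == "C01"))
  e <- f$estimates
  truth10 <- sim$truth$beta_true * 10
  lag0 <- e[e$lag == "lag0", ]
  expect_lt(abs(lag0$beta_per10 - truth10), 2 * lag0$se)
  for (l in paste0("lag", 1:4)) {
    row <- e[e$lag == l, ]
    expect_lt(abs(row$beta_per10), 2.5 * row$se)
  }
})

test_that("cumulative lag 0-0 equals the single-day lag 0 exactly", {
  sim <- make_lag0_sim(23)
  f <- fit_county_dlm(dplyr::filter(sim$panel, county_id == "C01"))
  e <- f$estimates
  expect_identical(e$beta_per10[e$lag == "lag0"],
                   e$beta_per10[e$lag == "lag0-0 cumulative"])
  expect_identical(e$se[e$lag == "lag0"], e$se[e$lag == "lag0-0 cumulative"])
})

test_that("the cumulative 0-4 effect is the coefficient sum times ten", {
  sim <- make_lag0_sim(29)
  f <- fit_county_dlm(dplyr::filter(sim$panel, county_id == "C01"))
  single <- f$estimates[grepl("^lag[0-4]$", f$estimates$lag), ]
  cum <- f$estimates[f$estimates$lag == "lag0-4 cumulative", ]
  expect_equal(cum$beta_per10, sum(single$beta_per10), tolerance = 1e-12)
})

test_that("rescaling the exposure rescales the reported effect exactly", {
  sim <- make_lag0_sim(31)
  d <- dplyr::filter(sim$panel, county_id == "C01")
  f1 <- fit_county_dlm(d)
  d10 <- dplyr::mutate(d, no2 = no2 * 10)
  f10 <- fit_county_dlm(d10)
  e1 <- f1$estimates[f1$estimates$lag == "lag0", ]
  e10 <- f10$estimates[f10$estimates$lag == "lag0", ]
  expect_equal(e10$beta_per10 * 10, e1$beta_per10, tolerance = 1e-6)
  expect_equal(f1$fit$fitted, f10$fit$fitted, tolerance = 1e-6)
})

test_that("day-of-week signals do not leak into the NO2 effect", {
  base <- list(n_urban_counties = 1, n_rural_counties = 1, n_years = 3,
               lag_weights = c(1, 0, 0, 0, 0), baseline_daily_mean = 15,
               seed = 37)
  flat <- simulate_panel(do.call(sim_config, c(base, list(
    dow_effects = rep(1, 7)))))
  spiked <- simulate_panel(do.call(sim_config, c(base, list(
    dow_effects = c(2, 1, 1, 1, 1, 1, 1)))))
  f_flat <- fit_county_dlm(dplyr::filter(flat$panel, county_id == "C01"))
  f_spk <- fit_county_dlm(dplyr::filter(spiked$panel, county_id == "C01"))
  e_flat <- f_flat$estimates[f_flat$estimates$lag == "lag0", ]
  e_spk <- f_spk$estimates[f_spk$estimates$lag == "lag0", ]
  expect_lt(abs(e_flat$beta_per10 - e_spk$beta_per10),
            2 * sqrt(e_flat$se^2 + e_spk$se^2))
  # the Tuesday contrast (vs spiked Monday reference) must move a lot
  expect_gt(abs(coef(f_spk$fit)[["dow_tue"]] - coef(f_flat$fit)[["dow_tue"]]),
            2 * sqrt(f_spk$fit$vcov["dow_tue", "dow_tue"]))
})

test_that("quadrupling the dispersion roughly doubles standard errors", {
  res <- vapply(1:30, function(s) {
    out <- numeric(4)
    for (i in 1:2) {
      disp <- c(1, 4)[i]
      sim <- simulate_panel(sim_config(
        n_urban_counties = 1, n_rural_counties = 1, n_years = 2,
        lag_weights = c(1, 0, 0, 0, 0), overdispersion = disp,
        baseline_daily_mean = 15, confounding_strength = 0, seed = 600 + s))
      f <- fit_county_dlm(dplyr::filter(sim$panel, county_id == "C01"))
      e <- f$estimates[f$estimates$lag == "lag0", ]
      out[2 * i - 1] <- e$beta_per10; out[2 * i] <- e$se
    }
    out
  }, numeric(4))
  truth10 <- log(1.0142)
  se_ratio <- mean(res[4, ]) / mean(res[2, ])
  expect_gt(se_ratio, 1.6)
  expect_lt(se_ratio, 2.4)
  for (row in c(1, 3)) {
    mc_se <- sd(res[row, ]) / sqrt(ncol(res))
    expect_lt(abs(mean(res[row, ]) - truth10), 3 * mc_se)
  }
})

test_that("short series are flagged excluded, not fitted", {
  sim <- make_lag0_sim(41)
  short <- dplyr::filter(sim$panel, county_id == "C01",
                         date < as.Date("2015-07-01"))
  f <- fit_county_dlm(short)
  expect_true(f$excluded)
  expect_match(f$reason, "usable days")
  est <- suppressWarnings(
    fit_all_counties(dplyr::bind_rows(
      short, dplyr::filter(sim$panel, county_id == "C02")), sim$counties))
  expect_equal(attr(est, "exclusions")$county_id, "C01")
  expect_true(all(est$county_id == "C02"))
})

test_that("two-pollutant adjustment keeps a co-pollutant column in the model", {
  sim <- make_lag0_sim(43)
  f <- fit_county_dlm(dplyr::filter(sim$panel, county_id == "C01"),
                      co_pollutant = "copollutant")
  expect_true("copollutant" %in% names(coef(f$fit)))
  e <- f$estimates[f$estimates$lag == "lag0", ]
  expect_lt(abs(e$beta_per10 - sim$truth$beta_true * 10), 3 * e$se)
})

test_that("nonlinear exposure model is centered and recovers linearity", {
  sims <- lapply(1:4, function(s)
    simulate_panel(sim_config(n_urban_counties = 1, n_rural_counties = 1,
                              n_years = 2, lag_weights = c(1, 0, 0, 0, 0),
                              baseline_daily_mean = 15, seed = 50 + s)))
  panels <- purrr::imap_dfr(sims, ~ dplyr::mutate(
    dplyr::filter(.x$panel, county_id == "C01"),
    county_id = paste0("X", .y)))
  boundary <- range(panels$no2)
  fits <- panels |>
    dplyr::group_split(county_id) |>
    purrr::map(~ fit_nonlinear_no2(.x, knots = c(20, 40), boundary = boundary))
  ref <- mean(panels$no2)
  curve <- pool_curves(fits, reference = ref)
  # exact centering at the reference concentration
  at_ref <- pool_curves(fits, grid = ref, reference = ref)
  expect_equal(at_ref$logrr, 0, tolerance = 1e-12)
  # linear truth: curve within 2 pooled SEs of its own secant over the
  # 5th-95th percentile band, using the SE of the deviation contrast
  # (the pointwise SE vanishes at the centering concentration)
  grid <- seq(quantile(panels$no2, 0.05), quantile(panels$no2, 0.95),
              length.out = 25)
  cv <- suppressWarnings(pool_curves(fits, grid = grid, reference = ref))
  b <- attr(cv, "coef"); V <- attr(cv, "vcov")
  D <- eval_basis(fits[[1]]$basis, grid)
  C <- D - matrix(D[1, ], 25, ncol(D), byrow = TRUE) -
    outer((grid - grid[1]) / (grid[25] - grid[1]), D[25, ] - D[1, ])
  dev <- drop(C %*% b)
  dev_se <- sqrt(pmax(rowSums((C %*% V) * C), 0))
  expect_true(all(abs(dev) <= 2 * pmax(dev_se, 1e-10)))
  expect_error(fit_nonlinear_no2(dplyr::filter(sims[[1]]$panel,
                                               county_id == "C01"),
                                 knots = c(0.01, 40)),
               class = "no2burden_invalid_argument")
})
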