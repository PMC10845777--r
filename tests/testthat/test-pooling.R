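# Stage-2 pooling, transforms, difference tests, meta-regression and
# curve meta-smoothing.

test_that("identical estimates pool to themselves with no heterogeneity", {
  est <- tibble::tibble(beta_per10 = rep(0.014, 6), se = rep(0.003, 6),
                        cause = "cvd", lag = "lag0")
  p <- pool_random_effects(est)
  expect_equal(p$beta, 0.014, tolerance = 1e-10)
  expect_equal(p$tau2, 0, tolerance = 1e-12)
  expect_equal(p$I2, 0)
  expect_false(p$degenerate)
})

test_that("DerSimonian-Laird pooling matches its closed form", {
  est <- tibble::tibble(beta_per10 = c(0.010, 0.020), se = c(0.002, 0.002))
  p <- pool_random_effects(est, method = "DL")
  oracle <- dl_pool(est$beta_per10, est$se)
  expect_lt(abs(p$beta - oracle$beta), 1e-10)
  expect_lt(abs(p$se - oracle$se), 1e-10)
  expect_lt(abs(p$tau2 - oracle$tau2), 1e-10)

  set.seed(5)
  b <- rnorm(12, 0.01, 0.004); s <- runif(12, 0.002, 0.006)
  p2 <- pool_random_effects(tibble::tibble(beta_per10 = b, se = s), "DL")
  o2 <- dl_pool(b, s)
  expect_lt(abs(p2$beta - o2$beta), 1e-10)
  expect_lt(abs(p2$tau2 - o2$tau2), 1e-10)
})

test_that("degenerate and empty inputs are handled per contract", {
  one <- tibble::tibble(beta_per10 = 0.01, se = 0.002)
  p <- pool_random_effects(one)
  expect_true(p$degenerate)
  expect_equal(p$beta, 0.01)
  expect_equal(p$tau2, 0)
  expect_error(pool_random_effects(one[0, ]),
               class = "no2burden_invalid_argument")
})

test_that("pooled estimates stay within the county range", {
  for (s in 1:20) {
    set.seed(s)
    k <- sample(3:15, 1)
    est <- tibble::tibble(beta_per10 = rnorm(k, 0.01, 0.01),
                          se = runif(k, 0.001, 0.01))
    p <- pool_random_effects(est)
    expect_gte(p$beta, min(est$beta_per10) - 1e-12)
    expect_lte(p$beta, max(est$beta_per10) + 1e-12)
  }
})

test_that("REML and DL agree on homogeneous inputs", {
  set.seed(9)
  est <- tibble::tibble(beta_per10 = rnorm(30, 0.014, 0.003),
                        se = rep(0.003, 30))
  p_reml <- pool_random_effects(est, "REML")
  p_dl <- pool_random_effects(est, "DL")
  expect_lt(abs(p_reml$beta - p_dl$beta), 0.1 * p_reml$se)
})

test_that("percentage change transform and its inverse round-trip", {
  expect_equal(percentage_change(0, 0.001)$pct, 0)
  expect_equal(percentage_change(log(1.0142), 0.001)$pct, 1.42,
               tolerance = 1e-10)
  neg <- percentage_change(-0.02, 0.005)
  expect_lt(neg$pct, 0)
  expect_lt(neg$lo, neg$pct); expect_gt(neg$hi, neg$pct)

  # closed-form check of the CI inversion
  inv <- ci_to_log_scale(0, -1.96, 1.96)
  expect_equal(inv$beta, 0)
  expect_equal(inv$se, (log(1.0196) - log(0.9804)) / (2 * qnorm(0.975)),
               tolerance = 1e-10)

  rt <- percentage_change(log(1.0151), 0.0034929)
  back <- ci_to_log_scale(rt$pct, rt$lo, rt$hi)
  expect_equal(back$beta, log(1.0151), tolerance = 1e-12)
  expect_equal(back$se, 0.0034929, tolerance = 1e-12)

  # published urban lag-0 row: 1.51 (0.82, 2.21) percent
  expect_equal(ci_to_log_scale(1.51, 0.82, 2.21)$beta, 0.01499,
               tolerance = 1e-3)
  expect_error(ci_to_log_scale(1, 2, 3), class = "no2burden_invalid_argument")
})

test_that("urban-rural test is zero for identical strata and validates labels", {
  est <- tibble::tibble(beta_per10 = c(0.01, 0.012, 0.014),
                        se = c(0.003, 0.003, 0.003),
                        cause = "cvd", lag = "lag0")
  u <- pool_random_effects(est, stratum = "urban")
  r <- pool_random_effects(est, stratum = "rural")
  dt <- urban_rural_test(u, r)
  expect_equal(dt$z, 0)
  expect_equal(dt$p, 1)
  r2 <- pool_random_effects(dplyr::mutate(est, lag = "lag1"), stratum = "rural")
  expect_error(urban_rural_test(u, r2), class = "no2burden_invalid_argument")
})

test_that("fixed-effect pooling equals the classical inverse-variance mean", {
  set.seed(13)
  b <- rnorm(10, 0.01, 0.003); s <- runif(10, 0.002, 0.008)
  p <- pool_random_effects(tibble::tibble(beta_per10 = b, se = s), "FE")
  w <- 1 / s^2
  expect_lt(abs(p$beta - sum(w * b) / sum(w)), 1e-12)
  expect_lt(abs(p$se - sqrt(1 / sum(w))), 1e-12)
})

test_that("meta-regression recovers a moderator slope and rejects constants", {
  set.seed(21)
  k <- 24
  x <- runif(k, 2, 8)
  slope <- 0.002
  est <- tibble::tibble(county_id = sprintf("C%02d", 1:k),
                        beta_per10 = 0.005 + slope * x + rnorm(k, 0, 0.002),
                        se = runif(k, 0.002, 0.004))
  cov <- tibble::tibble(county_id = est$county_id, beds_per_1000 = x,
                        const = 1)
  mr <- meta_regression(est, cov, moderators = "beds_per_1000")
  got <- mr[mr$term == "beds_per_1000", ]
  expect_lt(abs(got$estimate - slope), 2 * got$std.error)
  expect_error(meta_regression(est, cov, moderators = "const"),
               class = "no2burden_rank_deficiency")
})

test_that("a null moderator leaves heterogeneity roughly unchanged", {
  deltas <- vapply(1:30, function(s) {
    set.seed(700 + s)
    k <- 20
    est <- tibble::tibble(county_id = sprintf("C%02d", 1:k),
                          beta_per10 = rnorm(k, 0.014, 0.004),
                          se = runif(k, 0.003, 0.005))
    cov <- tibble::tibble(county_id = est$county_id, noise = rnorm(k))
    un <- pool_random_effects(est)
    mr <- meta_regression(est, cov, moderators = "noise")
    attr(mr, "residual_I2") - un$I2
  }, numeric(1))
  expect_lt(abs(mean(deltas)), 10)
})

test_that("meta-smoothing of a single county returns that county's curve", {
  sim <- simulate_panel(sim_config(n_urban_counties = 1, n_rural_counties = 1,
                                   n_years = 2, lag_weights = c(1, 0, 0, 0, 0),
                                   baseline_daily_mean = 15, seed = 61))
  d <- dplyr::filter(sim$panel, county_id == "C01")
  f <- fit_nonlinear_no2(d, knots = c(20, 40))
  cv <- pool_curves(list(f), grid = c(15, 30, 45), reference = 30)
  B <- eval_basis(f$basis, c(15, 30, 45))
  Br <- eval_basis(f$basis, 30)
  manual <- drop(sweep(B, 2, as.numeric(Br)) %*% f$coef)
  expect_equal(cv$logrr, manual, tolerance = 1e-12)
  expect_equal(cv$logrr[2], 0, tolerance = 1e-12)
})

test_that("meta-smoothing under a linear truth yields increasing curves", {
  monotone <- vapply(1:10, function(s) {
    sims <- lapply(1:6, function(i)
      simulate_panel(sim_config(n_urban_counties = 1, n_rural_counties = 1,
                                n_years = 2, lag_weights = c(1, 0, 0, 0, 0),
                                baseline_daily_mean = 15, seed = 900 + 10 * s + i)))
    panels <- purrr::imap(sims, ~ dplyr::mutate(
      dplyr::filter(.x$panel, county_id == "C01"), county_id = paste0("X", .y)))
    boundary <- range(purrr::map_dbl(panels, ~ min(.x$no2)),
                      purrr::map_dbl(panels, ~ max(.x$no2)))
    fits <- purrr::map(panels, ~ fit_nonlinear_no2(.x, knots = c(20, 40),
                                                   boundary = boundary))
    grid <- seq(20, 55, length.out = 12)
    cv <- suppressWarnings(pool_curves(fits, grid = grid, reference = 36))
    all(diff(cv$logrr) > 0)
  }, logical(1))
  expect_gte(mean(monotone), 0.9)

  # basis mismatch across counties is refused
  sim <- simulate_panel(sim_config(n_urban_counties = 1, n_rural_counties = 1,
                                   n_years = 2, seed = 77))
  d <- dplyr::filter(sim$panel, county_id == "C01")
  f1 <- fit_nonlinear_no2(d, knots = c(20, 40), boundary = c(0, 100))
  f2 <- fit_nonlinear_no2(d, knots = c(25, 40), boundary = c(0, 100))
  expect_error(pool_curves(list(f1, f2)), class = "no2burden_invalid_argument")
})
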