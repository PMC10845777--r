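# Independent oracles used to cross-check the package implementations.
# These deliberately use different algorithms from the code under test.

# Newton-Raphson maximizer of the Poisson log-likelihood (log link).
newton_poisson <- function(y, X, iter = 100, tol = 1e-12) {
  b <- rep(0, ncol(X))
  b[1] <- log(mean(y) + 0.1)
  for (i in seq_len(iter)) {
    mu <- exp(drop(X %*% b))
    score <- drop(crossprod(X, y - mu))
    info <- crossprod(X * mu, X)
    step <- solve(info, score)
    b <- b + step
    if (max(abs(step)) < tol) break
  }
  b
}

# Closed-form DerSimonian-Laird (method-of-moments) random-effects pool.
dl_pool <- function(beta, se) {
  w <- 1 / se^2
  yw <- sum(w * beta) / sum(w)
  Q <- sum(w * (beta - yw)^2)
  k <- length(beta)
  c_dl <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (Q - (k - 1)) / c_dl)
  wr <- 1 / (se^2 + tau2)
  list(beta = sum(wr * beta) / sum(wr), se = sqrt(1 / sum(wr)), tau2 = tau2)
}

# Truncated-power natural cubic spline basis (without intercept):
# columns {x, d_k(x) - d_{K-1}(x)} where
# d_k(x) = [(x - t_k)_+^3 - (x - t_K)_+^3] / (t_K - t_k)
# over the full knot sequence t_1 < ... < t_K (boundary + internal).
tp_natural_basis <- function(x, internal, boundary) {
  t_all <- sort(c(boundary, internal))
  K <- length(t_all)
  pp3 <- function(u) pmax(u, 0)^3
  d <- function(k) (pp3(x - t_all[k]) - pp3(x - t_all[K])) / (t_all[K] - t_all[k])
  cols <- lapply(seq_len(K - 2), function(k) d(k) - d(K - 1))
  cbind(x, do.call(cbind, cols))
}

# Small deterministic county-day fixture (no NO2 effect unless injected).
make_fixture_panel <- function(n_days = 400, seed = 7, beta = 0,
                               county = "F01") {
  set.seed(seed)
  dates <- as.Date("2015-01-01") + seq_len(n_days) - 1
  no2 <- pmax(36 + 8 * cos(2 * pi * seq_len(n_days) / 365.25) +
                rnorm(n_days, 0, 10), 0.1)
  temp <- 15 - 12 * cos(2 * pi * seq_len(n_days) / 365.25) + rnorm(n_days, 0, 3)
  rh <- pmin(pmax(66 + rnorm(n_days, 0, 12), 1), 99)
  holiday <- as.integer(format(dates, "%m-%d") %in%
                          c("01-01", "05-01", "10-01", "10-02"))
  mu <- exp(log(10) + beta * no2)
  tibble::tibble(county_id = county, date = dates, cause = "cvd",
                 admissions = rpois(n_days, mu), no2 = no2,
                 copollutant = no2 * 1.5 + rnorm(n_days, 0, 8),
                 temp = temp, rh = rh, holiday = holiday)
}
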