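test_that("constant power integrates to P0 * T * 3600 joules", {
  t <- seq(0, 10, by = 0.1)
  s <- heatflow_series(t, rep(2e-6, length(t)))
  q <- baseline_and_integrate(s, baseline_window = 0)
  expect_equal(q$heat_J[length(q$heat_J)], 2e-6 * 10 * 3600, tolerance = 1e-12)
  expect_equal(q$heat_J[1], 0)
})

test_that("trapezoidal integration matches the closed-form integral of exponential power", {
  t <- seq(0, 10, by = 0.01)
  A <- 2e-6; mu <- 0.5
  s <- heatflow_series(t, A * exp(mu * t))
  q <- baseline_and_integrate(s, baseline_window = 0)
  expected <- (A / mu) * (exp(mu * t) - 1) * 3600
  expect_rel_equal(q$heat_J[-1], expected[-1], 1e-3)
})

test_that("baseline subtraction removes a constant offset", {
  t <- seq(0, 12, by = 0.01)
  p <- ifelse(t < 2, 0, 2e-6 * exp(0.5 * (t - 2)))
  clean <- baseline_and_integrate(heatflow_series(t, p), baseline_window = 0)
  offset <- baseline_and_integrate(heatflow_series(t, p + 3e-6),
                                   baseline_window = 1.5)
  expect_equal(offset$heat_J, clean$heat_J, tolerance = 1e-9)
  expect_equal(offset$baseline_W, 3e-6)
  expect_error(baseline_and_integrate(heatflow_series(t, p),
                                      baseline_window = 20), "shorter")
})

test_that("growth-rate estimation recovers the log-slope exactly", {
  s <- exp_series(0.5, A = 2e-6, t = seq(0, 10, by = 0.01))
  ph <- estimate_growth_rate(s, window = c(1, 8))
  expect_equal(ph$mu, 0.5, tolerance = 1e-6 / 0.5)
  expect_equal(ph$fit_r2, 1.0, tolerance = 1e-9)
  flat <- heatflow_series(seq(0, 5, 0.1), rep(1e-6, 51))
  ph0 <- estimate_growth_rate(flat, window = c(0, 5))
  expect_equal(ph0$mu, 0)
  expect_error(estimate_growth_rate(exp_series(0.5, lag = 3), window = c(0, 2)),
               "non-positive")
})

test_that("the total-heat log slope approaches the heat-flow slope late but is biased up early", {
  s <- exp_series(0.5, t = seq(0, 20, by = 0.01))
  q <- baseline_and_integrate(s, 0)
  late <- estimate_growth_rate(q, window = c(14, 20), method = "heat-log")
  expect_equal(late$mu, 0.5, tolerance = 0.01)
  early <- estimate_growth_rate(q, window = c(0.5, 2), method = "heat-log")
  expect_gt(early$mu, 0.55)
})

test_that("growth-rate estimate is invariant to power rescaling", {
  s <- exp_series(0.7)
  s2 <- heatflow_series(s$time_h, s$power_W * 137)
  expect_equal(estimate_growth_rate(s, c(1, 8))$mu,
               estimate_growth_rate(s2, c(1, 8))$mu)
})

test_that("integration is linear in the power signal", {
  t <- seq(0, 8, by = 0.05)
  p1 <- 1e-6 * exp(0.3 * t)
  p2 <- 5e-7 * (1 + sin(t))
  q <- function(p) baseline_and_integrate(heatflow_series(t, p), 0)$heat_J
  expect_equal(q(2 * p1 + 3 * p2), 2 * q(p1) + 3 * q(p2), tolerance = 1e-12)
})

test_that("resampling interpolates linearly and refuses extrapolation", {
  s <- heatflow_series(c(0, 1, 2), c(0, 2, 4) * 1e-6, replicate = "rA",
                       passage = 3L, condition = "c")
  r <- resample_to_grid(s, c(0.5, 1.0, 1.5))
  expect_equal(r$power_W, c(1, 2, 3) * 1e-6)
  expect_identical(r$replicate, "rA")
  expect_identical(r$passage, 3L)
  same <- resample_to_grid(s, s$time_h)
  expect_equal(same$power_W, s$power_W)
  expect_error(resample_to_grid(s, c(-1, 1)), "span")
})

test_that("linear interpolation error on a smooth signal shrinks with the square of the source step", {
  f <- function(t) 1e-6 * (2 + sin(t))
  coarse <- heatflow_series(seq(0, 2 * pi, by = 0.2), f(seq(0, 2 * pi, by = 0.2)))
  fine_grid <- seq(0.1, 2 * pi - 0.1, by = 0.05)
  r <- resample_to_grid(coarse, fine_grid)
  # second-order bound: max error <= h^2/8 * max|f''|
  expect_lt(max(abs(r$power_W - f(fine_grid))), 0.2^2 / 8 * 1e-6 * 1.01)
})

test_that("heat-biomass linearity diagnostics behave on exact and degenerate data", {
  x <- c(1, 2, 3, 4)
  fit <- check_heat_biomass_linearity(2 * x, x)
  expect_equal(fit$slope, 2)
  expect_equal(fit$r2, 1)
  flat <- check_heat_biomass_linearity(rep(3, 4), x)
  expect_equal(flat$slope, 0)
  expect_equal(flat$r2, 0)
  expect_error(check_heat_biomass_linearity(1:2, 1:2), "3 paired")
})

test_that("simulator endpoints across substrate levels confirm heat-biomass proportionality", {
  heats <- biomass <- numeric(5)
  for (i in 1:5) {
    p <- one_strain_params(mu = 0.5, S0 = 5 * i)
    sim <- simulate_batch(p, duration = 30, dt = 0.05)
    nT <- length(sim$time)
    heats[i] <- sim$cum_heat_total[nT]
    biomass[i] <- sim$biomass[nT, 1]
  }
  expect_gt(check_heat_biomass_linearity(heats, biomass)$r2, 0.999)
})

test_that("noisy growth-rate recovery stays within 5 percent in the median", {
  set.seed(11)
  for (mu in c(0.07, 0.2, 0.5, 1.0)) {
    t <- seq(0, 6 / mu, by = 0.05 / mu)
    p <- 2e-6 * exp(mu * t)
    errs <- replicate(25, {
      noisy <- heatflow_series(t, pmax(p + stats::rnorm(length(t), 0, 0.02 * max(p)),
                                       1e-12))
      win <- c(0.55, 0.95) * max(t)  # window where signal dominates noise
      abs(estimate_growth_rate(noisy, win)$mu - mu) / mu
    })
    expect_lt(stats::median(errs), 0.05)
  }
})
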