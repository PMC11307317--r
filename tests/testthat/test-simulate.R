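test_that("single-strain batch reduces to exponential growth when substrate is saturating", {
  p <- one_strain_params(mu = 0.5, S0 = 1000, K = 0.001)
  sim <- simulate_batch(p, duration = 8, dt = 0.01)
  sel <- sim$time >= 1 & sim$time <= 6
  fit <- stats::lm(log(sim$heat_flow_total[sel]) ~ sim$time[sel])
  expect_equal(unname(stats::coef(fit)[2]), 0.5, tolerance = 0.01 / 0.5)
  # biomass itself grows as exp(0.5 t)
  expect_equal(sim$biomass[sel, 1][1] * exp(0.5 * (sim$time[sel] - sim$time[sel][1])),
               unname(sim$biomass[sel, 1]), tolerance = 1e-3)
})

test_that("no substrate means no growth and zero heat", {
  p <- one_strain_params(mu = 0.5, S0 = 0)
  sim <- simulate_batch(p, duration = 5, dt = 0.05)
  expect_true(all(abs(sim$biomass[, 1] - sim$biomass[1, 1]) < 1e-12))
  expect_true(all(sim$heat_flow_total == 0))
})

test_that("strains on disjoint substrates superpose: consortium heat equals the sum of monocultures", {
  p12 <- two_disjoint_params()
  both <- simulate_batch(p12, duration = 20, dt = 0.02)
  p1 <- one_strain_params(mu = 0.5, S0 = 20)
  p2 <- one_strain_params(mu = 0.3, S0 = 20)
  # monocultures on the same grid, matching substrate names
  s1 <- simulate_batch(community_params(
    strains = list(strain_params("s1", mu_max = c(S1 = 0.5), K = c(S1 = 0.001),
                                 yield_X = c(S1 = 0.02), heat_yield = 1500)),
    substrates = c(S1 = 20), initial_biomass = c(s1 = 0.001)),
    duration = 20, dt = 0.02)
  s2 <- simulate_batch(community_params(
    strains = list(strain_params("s2", mu_max = c(S2 = 0.3), K = c(S2 = 0.001),
                                 yield_X = c(S2 = 0.02), heat_yield = 1500)),
    substrates = c(S2 = 20), initial_biomass = c(s2 = 0.001)),
    duration = 20, dt = 0.02)
  expect_rel_equal(both$heat_flow_total + 1e-30,
                   s1$heat_flow_total + s2$heat_flow_total + 1e-30, 1e-6)
})

test_that("mass balance: substrate consumed times yield equals biomass formed", {
  p <- one_strain_params(mu = 0.5, S0 = 30, yield_X = 0.02)
  sim <- simulate_batch(p, duration = 24, dt = 0.02)
  nT <- length(sim$time)
  consumed <- sim$compounds[1, "S"] - sim$compounds[nT, "S"]
  formed <- sim$biomass[nT, 1] - sim$biomass[1, 1]
  expect_equal(unname(consumed * 0.02), unname(formed), tolerance = 1e-4)
})

test_that("cumulative heat is exactly proportional to biomass increment and flows add up", {
  fx <- load_fixture("consortium")
  sim <- simulate_batch(fx$params, duration = 18, dt = 0.05)
  nT <- length(sim$time)
  for (s in colnames(sim$biomass)) {
    yq <- fx$params$strains[[s]]$heat_yield
    expect_rel_equal(sim$cum_heat[nT, s] + 1e-30,
                     yq * (sim$biomass[nT, s] - sim$biomass[1, s]) *
                       fx$params$volume_L + 1e-30, 1e-6)
  }
  expect_equal(sim$heat_flow_total, rowSums(sim$heat_flow))
  expect_true(all(diff(sim$cum_heat_total) > -1e-12))
})

test_that("serial passages transfer 1 percent and a drift-free community reaches a passage fixed point", {
  p <- two_disjoint_params()
  sims <- simulate_serial_passages(p, n_passages = 4, duration = 24, dt = 0.05)
  end1 <- sims[[1]]$biomass[nrow(sims[[1]]$biomass), ]
  expect_equal(unname(sims[[2]]$biomass[1, ]), unname(0.01 * end1))
  # composition identical across late passages
  frac <- function(sim) {
    x <- sim$biomass[nrow(sim$biomass), ]
    x / sum(x)
  }
  expect_equal(frac(sims[[3]]), frac(sims[[4]]), tolerance = 1e-6)
})

test_that("per-strain dilution perturbs the first passage only", {
  p <- two_disjoint_params()
  sims <- simulate_serial_passages(p, n_passages = 2, duration = 24, dt = 0.05,
                                   per_strain_dilution = c(s1 = 0.01, s2 = 1))
  expect_equal(unname(sims[[1]]$biomass[1, ]), c(0.001 * 0.01, 0.001))
  expect_error(simulate_serial_passages(p, n_passages = 0),
               "n_passages")
})

test_that("multinomial read sampling follows biomass-times-copies weighting", {
  expect_equal(unname(sample_reads(c(1, 0, 0), c(3, 5, 6), 1000, seed = 1)),
               c(1000L, 0L, 0L))
  # equal fractions with copies 3/5/6: expected proportions 3/14, 5/14, 6/14
  reads <- sample_reads(rep(1 / 3, 3), c(3, 5, 6), 1e6, seed = 42)
  expect_equal(unname(reads / 1e6), c(3, 5, 6) / 14, tolerance = 0.01)
  expect_error(sample_reads(c(-0.1, 1.1), c(1, 1), 100), "fractions")
  # reproducible under a fixed seed
  expect_identical(sample_reads(c(0.4, 0.6), c(3, 5), 1e4, seed = 7),
                   sample_reads(c(0.4, 0.6), c(3, 5), 1e4, seed = 7))
})

test_that("endpoint metabolite tables reproduce trajectory endpoints and stoichiometry", {
  p <- community_params(
    strains = list(strain_params("s1", mu_max = c(S = 0.5), K = c(S = 0.001),
                                 yield_X = c(S = 0.02),
                                 yield_P = list(P = c(S = 2)))),
    substrates = c(S = 5), initial_biomass = c(s1 = 0.001))
  sim <- simulate_batch(p, duration = 30, dt = 0.05)
  tab <- endpoint_metabolites(sim, noise_sd = 0, n_replicates = 3)
  d <- concentration_deltas(tab)
  # all 5 mmol/L consumed; product = 2 per substrate -> +10
  expect_equal(d$mean_delta[d$metabolite == "S"], -5, tolerance = 1e-3)
  expect_equal(d$mean_delta[d$metabolite == "P"], 10, tolerance = 1e-3)
  expect_true(all(d$sd_delta == 0))
  expect_equal(unique(table(tab$replicate)), 4L)  # 2 metabolites x 2 timepoints
})

test_that("measurement noise and drift are additive, seeded and leave the input untouched", {
  s <- exp_series(0.4)
  expect_identical(add_measurement_noise(s, 0, 0)$power_W, s$power_W)
  d <- add_measurement_noise(s, 0, drift = 2e-6)
  expect_equal(d$power_W, s$power_W + 2e-6 * s$time_h)
  n1 <- add_measurement_noise(s, sd = 1e-6, seed = 5)
  n2 <- add_measurement_noise(s, sd = 1e-6, seed = 5)
  expect_identical(n1$power_W, n2$power_W)
  expect_false(identical(n1$power_W, s$power_W))
})

test_that("adaptation drift converges geometrically to the asymptotic parameters", {
  ad <- list(lag_excess = 0.5, mu_deficit = 0.2, factor = 0.5)
  p <- one_strain_params(mu = 0.5, S0 = 1000)
  p$adaptation <- list(lag_excess = c(s1 = 0.5), mu_deficit = c(s1 = 0.2),
                       factor = 0.5)
  sims <- simulate_serial_passages(p, n_passages = 3, duration = 4, dt = 0.02)
  mu_at <- function(sim) {
    sel <- sim$time >= 2 & sim$time <= 4
    unname(stats::coef(stats::lm(log(sim$heat_flow_total[sel]) ~ sim$time[sel]))[2])
  }
  # passage p growth rate = 0.5 * (1 - 0.2 * 0.5^(p-1))
  expect_equal(mu_at(sims[[1]]), 0.5 * 0.8, tolerance = 0.01)
  expect_equal(mu_at(sims[[2]]), 0.5 * 0.9, tolerance = 0.01)
  expect_equal(mu_at(sims[[3]]), 0.5 * 0.95, tolerance = 0.01)
  expect_identical(convergence_passage(list(lag_excess = c(a = 0.64),
                                            mu_deficit = c(a = 0),
                                            factor = 0.5)), 7L)
})
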