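toy <- function(name) load_gem(system.file("extdata", "gems", name,
                                           package = "calorimix"))

test_that("toy models load with the expected structure from JSON and SBML", {
  g <- toy("toynet_linear.json")
  expect_identical(length(g$reactions), 3L)
  expect_identical(g$objective_id, "BIOMASS")
  expect_setequal(names(g$exchanges), c("EX_A", "BIOMASS"))
  gx <- toy("toynet_linear.xml")
  expect_identical(g$S, gx$S)
  expect_identical(unname(g$lb), unname(gx$lb))
  expect_identical(unname(g$ub), unname(gx$ub))
  expect_identical(unname(g$obj), unname(gx$obj))
})

test_that("invalid models are rejected with informative errors", {
  S <- matrix(c(-1, 1), 1, 2, dimnames = list("A", c("r1", "r2")))
  expect_error(gem(S, lb = c(5, 0), ub = c(1, 10), obj = c(0, 1)),
               "lower bound exceeds")
  expect_error(gem(S, lb = c(0, 0), ub = c(1, 1), obj = c(0, 0)),
               "no objective")
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(list(metabolites = list(list(id = "A")),
                            reactions = list(list(
                              id = "r1", metabolites = list(A = -1, ZZZ = 1),
                              lower_bound = 0, upper_bound = 1,
                              objective_coefficient = 1))),
                       tmp, auto_unbox = TRUE)
  expect_error(load_gem(tmp), "inconsistent stoichiometry")
})

test_that("FBA finds the bottleneck optimum on the linear and branched toys", {
  expect_equal(fba(toy("toynet_linear.json"))$objective, 10, tolerance = 1e-9)
  expect_equal(fba(toy("toynet_branch.json"))$objective, 5, tolerance = 1e-9)
  sol <- fba(toy("toynet_linear.json"))
  expect_identical(sol$status, "optimal")
  expect_lt(flux_balance_residual(toy("toynet_linear.json"), sol$fluxes), 1e-9)
})

test_that("an over-constrained model reports infeasible instead of erroring", {
  g <- toy("toynet_linear.json")
  g$lb["BIOMASS"] <- 50  # demands more flux than the uptake allows
  g$ub["BIOMASS"] <- 60
  expect_identical(fba(g)$status, "infeasible")
})

test_that("LP optima equal brute-force vertex enumeration on random bounded networks", {
  set.seed(1234)
  n_match <- 0
  for (i in 1:60) {
    g <- random_gem(n = sample(4:8, 1), m = sample(2:4, 1))
    sol <- fba(g)
    oracle <- vertex_enum_optimum(g)
    expect_identical(sol$status, "optimal")
    expect_true(is.finite(oracle))
    expect_equal(sol$objective, oracle, tolerance = 1e-7)
    expect_lt(flux_balance_residual(g, sol$fluxes), 1e-9)
    expect_true(all(sol$fluxes >= g$lb - 1e-9 & sol$fluxes <= g$ub + 1e-9))
    n_match <- n_match + 1
  }
  expect_gte(n_match, 50)
})

test_that("measured rates constrain exchange bounds with clipping and depletion semantics", {
  g <- toy("toynet_linear.json")
  g2 <- apply_measured_constraints(
    g, data.frame(metabolite = "A", rate = 0, sd = 0))
  expect_equal(unname(g2$lb["EX_A"]), 0)
  expect_equal(unname(g2$ub["EX_A"]), 0)
  # production window rate 5 +/- 1 -> bounds [4, 6]
  gp <- toy("fp_like_synthetic.json")
  gp$ub["EX_but_e"] <- 1000
  gp2 <- apply_measured_constraints(
    gp, data.frame(metabolite = "but", rate = 5, sd = 1))
  expect_equal(unname(gp2$lb["EX_but_e"]), 4)
  expect_equal(unname(gp2$ub["EX_but_e"]), 6)
  # constraining the only substrate to -2 +/- 0 fixes the optimum at 2
  g3 <- apply_measured_constraints(
    g, data.frame(metabolite = "A", rate = -2, sd = 0))
  expect_equal(fba(g3)$objective, 2, tolerance = 1e-9)
  expect_error(apply_measured_constraints(
    g, data.frame(metabolite = "nonexistent", rate = 1, sd = 0)),
    "no exchange reaction")
  # infeasible orientation: forcing production of a pure substrate
  expect_error(apply_measured_constraints(
    g, data.frame(metabolite = "A", rate = 5, sd = 0)),
    "orientation")
})

test_that("depleting the only substrate stops growth; redundant substrates are dispensable", {
  scr <- depletion_screen(toy("toynet_linear.json"), exchanges = "EX_A")
  expect_equal(scr$mu_pred, 0, tolerance = 1e-9)
  expect_identical(scr$classification, "essential")
  bt <- toy("bt_like_synthetic.json")
  scr2 <- depletion_screen(bt)
  cls <- stats::setNames(scr2$classification, scr2$exchange)
  expect_identical(unname(cls[c("EX_glca_e", "EX_glcb_e", "EX_gln_e")]),
                   rep("dispensable", 3))
  expect_identical(unname(cls[c("EX_nacgam_e", "EX_asp_e")]),
                   rep("limiting", 2))
})

test_that("strain-patterned toy models reproduce their designed essentiality structure", {
  am <- depletion_screen(toy("am_like_synthetic.json"))
  cls <- stats::setNames(am$classification, am$exchange)
  expect_identical(unname(cls[c("EX_nacgam_e", "EX_asn_e", "EX_thr_e")]),
                   rep("essential", 3))
  expect_identical(unname(cls["EX_ser_e"]), "dispensable")
  fp <- depletion_screen(toy("fp_like_synthetic.json"))
  cls2 <- stats::setNames(fp$classification, fp$exchange)
  expect_identical(unname(cls2[c("EX_ser_e", "EX_thr_e", "EX_ura_e")]),
                   rep("essential", 3))
  expect_identical(unname(cls2["EX_ac_e"]), "dispensable")
})

test_that("FVA intervals behave: fully determined at the optimum, nested across fractions", {
  g <- toy("toynet_linear.json")
  fv1 <- fva(g, 1.0)
  expect_equal(fv1$min, fv1$max, tolerance = 1e-9)
  expect_equal(fv1$max[fv1$reaction == "BIOMASS"], 10, tolerance = 1e-9)
  fv9 <- fva(g, 0.9)
  expect_true(all(fv9$min <= fv1$min + 1e-9))
  expect_true(all(fv9$max >= fv1$max - 1e-9))
  # FVA(1.0) contains the FBA flux componentwise
  sol <- fba(g)
  expect_true(all(sol$fluxes >= fv1$min - 1e-9 & sol$fluxes <= fv1$max + 1e-9))
})

test_that("parallel pathways share a fixed sum but have full individual FVA width", {
  S <- matrix(c(1, -1, -1, -1, 0,
                0, 1, 1, 0, -1,
                0, 0, 0, 1, -1),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"),
                              c("EX_A", "R_AB1", "R_AB2", "R_AC", "BIO")))
  # EX_A written as production of A with ub 10 (source form)
  g <- gem(S, lb = c(0, 0, 0, 0, 0), ub = c(10, 1000, 1000, 1000, 1000),
           obj = c(0, 0, 0, 0, 1))
  fv <- fva(g, 1.0)
  ab1 <- fv[fv$reaction == "R_AB1", ]
  ab2 <- fv[fv$reaction == "R_AB2", ]
  expect_equal(ab1$min, 0, tolerance = 1e-9)
  expect_equal(ab1$max, 5, tolerance = 1e-9)
  expect_equal(ab2$min, 0, tolerance = 1e-9)
  expect_equal(ab2$max, 5, tolerance = 1e-9)
  sm <- sample_fluxes(g, 400, fraction = 1.0, seed = 3)
  expect_equal(sm$mean[sm$reaction == "R_AB1"], 2.5, tolerance = 0.5)
  expect_equal(sm$mean[sm$reaction == "R_AB2"], 2.5, tolerance = 0.5)
})

test_that("flux sampling collapses on a fully determined polytope and flags n = 1", {
  g <- toy("toynet_linear.json")
  sm <- sample_fluxes(g, 20, fraction = 1.0, seed = 2)
  expect_true(all(sm$sd < 1e-9))
  one <- sample_fluxes(g, 1, fraction = 0.9, seed = 2)
  expect_false(attr(one, "sd_defined"))
  expect_true(all(one$sd == 0))
  # sampling objective never exceeds the FBA optimum
  gb <- toy("toynet_branch.json")
  mu_star <- fba(gb)$objective
  sm2 <- sample_fluxes(gb, 100, fraction = 0.9, seed = 4)
  expect_lte(max(sm2$mean[sm2$reaction == "BIOMASS"]), mu_star + 1e-9)
  expect_identical(sample_fluxes(gb, 25, 0.9, seed = 7),
                   sample_fluxes(gb, 25, 0.9, seed = 7))
})

test_that("depleting a substrate unused at the optimum leaves growth unchanged", {
  am <- toy("am_like_synthetic.json")
  ref <- fba(am)$objective
  fv <- fva(am, 1.0)
  ser <- fv[fv$reaction == "EX_ser_e", ]
  # serine has zero width at zero uptake in this model's optimal face?
  # if not fully determined, the objective must still be unchanged:
  scr <- depletion_screen(am, exchanges = "EX_ser_e")
  expect_equal(scr$mu_pred, ref, tolerance = 1e-9)
})
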