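test_that("covariate model reduces to the typical values at the reference", {
  pop <- reference_pop_params()
  ip <- apply_covariates(pop, asat = 36.5)
  expect_equal(ip$V, pop$V_pop)
  expect_equal(ip$Cl, pop$Cl_pop)
  expect_equal(ip$ka, pop$ka_pop)
  expect_equal(ip$ke, ip$Cl / ip$V, tolerance = 1e-12)

  # doubled ASAT with the published exponent halves-ish the volume
  ip2 <- apply_covariates(pop, asat = 73)
  expect_equal(ip2$V, 22.3 * (73 / 36.5)^(-0.838), tolerance = 1e-12)
  expect_equal(ip2$V, 12.47, tolerance = 1e-3)

  # null covariate exponent
  pop0 <- reference_pop_params(beta_V_asat = 0)
  expect_equal(apply_covariates(pop0, asat = 120)$V, pop0$V_pop)

  expect_error(apply_covariates(pop, asat = -1), "positive")
})

test_that("volume is monotone in ASAT when the exponent is negative", {
  pop <- reference_pop_params()
  asats <- seq(10, 150, by = 5)
  vols <- vapply(asats, function(a) apply_covariates(pop, a)$V, 0)
  expect_true(all(diff(vols) < 0))
})

test_that("single-dose concentration matches the ODE system", {
  expect_equal(conc_single_dose(800, 0, ref_ip$ka, ref_ip$V, ref_ip$Cl), 0)
  expect_equal(conc_single_dose(800, 24, ref_ip$ka, ref_ip$V, ref_ip$Cl),
               22.4, tolerance = 1e-3)

  set.seed(101)
  for (i in 1:100) {
    ka <- runif(1, 0.2, 3); V <- runif(1, 5, 60); Cl <- runif(1, 0.1, 3)
    times <- sort(runif(5, 0.1, 96))
    analytic <- conc_single_dose(800, times, ka, V, Cl)
    numeric <- ode_conc(800, times, ka, V, Cl)
    expect_equal(analytic, unname(numeric), tolerance = 1e-6)
  }
})

test_that("the flip-flop degeneracy switches to the analytic limit continuously", {
  V <- 20; dose <- 400
  ka <- 0.5
  # exactly equal rates use the limit form
  lim <- conc_single_dose(dose, 10, ka, V, Cl = ka * V)
  expect_equal(lim, (dose / V) * ka * 10 * exp(-ka * 10))
  # continuity across the switch tolerance
  for (eps in c(1e-12, 1e-9, 1e-7, 1e-5)) {
    near <- conc_single_dose(dose, 10, ka, V, Cl = ka * V * (1 + eps))
    expect_equal(near, lim, tolerance = 1e-4)
  }
  expect_true(all(conc_single_dose(dose, seq(0, 96, 0.5), ka, V, ka * V) >= 0))
})

test_that("steady state equals the superposition of repeated doses", {
  trough <- conc_steady_state(800, 24, ref_ip$ka, ref_ip$V, ref_ip$Cl)
  expect_equal(trough, 57.5, tolerance = 1e-3)
  for (t in c(0, 2, 11.5, 24)) {
    expect_equal(conc_steady_state(800, t, ref_ip$ka, ref_ip$V, ref_ip$Cl),
                 superposition_conc(800, t, ref_ip$ka, ref_ip$V, ref_ip$Cl,
                                    tau = 24),
                 tolerance = 1e-6)
  }
  # 10-dose partial sum approaches the closed form within the accumulation
  # envelope exp(-10 ke tau)
  ke <- 0.02; V <- 20; Cl <- ke * V * 1.0001; ka <- 1.1
  cs <- conc_steady_state(800, 12, ka, V, Cl, tau = 24)
  s10 <- superposition_conc(800, 12, ka, V, Cl, tau = 24, n_doses = 10)
  expect_lt(abs(cs - s10) / cs, exp(-10 * ke * 24))
  # no accumulation when elimination clears the interval
  fastCl <- 10  # ke*tau >> 1
  expect_equal(conc_steady_state(800, 12, 1.2, 20, fastCl),
               conc_single_dose(800, 12, 1.2, 20, fastCl), tolerance = 1e-4)
  # steady state dominates the single dose everywhere in the interval
  tt <- seq(0, 24, by = 0.5)
  expect_true(all(conc_steady_state(800, tt, ref_ip$ka, ref_ip$V, ref_ip$Cl) >=
                    conc_single_dose(800, tt, ref_ip$ka, ref_ip$V, ref_ip$Cl)))
})

test_that("the steady-state curve integrates to dose/Cl over one interval", {
  # trapezoid integral converges to the closed-form AUC as the grid refines
  auc_exact <- auc_from_clearance(800, ref_ip$Cl)
  err <- vapply(c(200, 800, 3200), function(m) {
    tt <- seq(0, 24, length.out = m + 1)
    cc <- conc_steady_state(800, tt, ref_ip$ka, ref_ip$V, ref_ip$Cl)
    abs(sum((cc[-1] + cc[-length(cc)]) / 2 * diff(tt)) - auc_exact) / auc_exact
  }, 0)
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 1e-5)
})

test_that("AUC from clearance is exact division", {
  expect_equal(auc_from_clearance(800, 0.458), 800 / 0.458)
  expect_equal(auc_from_clearance(800, 0.458), 1746.7, tolerance = 1e-4)
  expect_equal(auc_from_clearance(200, 0.458), 436.7, tolerance = 1e-3)
  expect_identical(auc_from_clearance(623, 0.37) * 0.37, 623)
  expect_error(auc_from_clearance(800, 0), "positive")
})

test_that("combined residual error follows the additive + proportional form", {
  expect_equal(residual_sd(7, pop_params(1, 1, 1, err_add = 2, err_prop = 0)), 2)
  expect_equal(residual_sd(10, pop_params(1, 1, 1, err_add = 0, err_prop = 0.2)), 2)
  expect_equal(residual_sd(20, pop_params(1, 1, 1, err_add = 1, err_prop = 0.2)), 5)
  p2 <- pop_params(1, 1, 1, err_add = 3, err_prop = 0.4, err_model = "combined2")
  expect_equal(residual_sd(10, p2), sqrt(9 + 16))
  expect_error(residual_sd(-1, p2), "non-negative")
})
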