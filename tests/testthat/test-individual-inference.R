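test_that("a typical observation yields zero random effects and the typical clearance", {
  pop <- reference_pop_params(err_prop = 0, gamma_V = 0, gamma_Cl = 0)
  f24 <- conc_steady_state(800, 24, pop$ka_pop, pop$V_pop, pop$Cl_pop)
  tab <- one_subject_tab(dv = f24, tad = 24)
  est <- map_estimate(tab, pop)
  expect_equal(est$eta_ka, 0, tolerance = 1e-4)
  expect_equal(est$eta_V, 0, tolerance = 1e-4)
  expect_equal(est$eta_Cl, 0, tolerance = 1e-4)
  expect_equal(est$Cl, pop$Cl_pop, tolerance = 1e-4)
  expect_equal(est$auc * est$Cl, 800)
})

test_that("an overwhelming prior pins the mode at zero", {
  pop <- reference_pop_params(omega_ka = 1e-6, omega_V = 1e-6,
                              omega_Cl = 1e-6, gamma_V = 0, gamma_Cl = 0)
  tab <- one_subject_tab(dv = 90, tad = 24)  # far from the typical 57.5
  est <- map_estimate(tab, pop)
  expect_lt(abs(est$eta_Cl), 1e-4)
  expect_equal(est$Cl, pop$Cl_pop, tolerance = 1e-3)
})

test_that("the MAP mode matches an exhaustive grid search", {
  pop <- reference_pop_params(omega_ka = 0, gamma_V = 0, gamma_Cl = 0)
  tab <- one_subject_tab(dv = 30, tad = 6)
  est <- map_estimate(tab, pop)

  obj <- function(ev, ec) {
    f <- conc_steady_state(800, 6, pop$ka_pop, pop$V_pop * exp(ev),
                           pop$Cl_pop * exp(ec))
    sd <- pop$err_add + pop$err_prop * f
    (30 - f)^2 / sd^2 + 2 * log(sd) + (ev / pop$omega_V)^2 + (ec / pop$omega_Cl)^2
  }
  # coarse-to-fine grid refinement over [-2, 2]^2
  ctr <- c(0, 0); width <- 2
  for (lvl in 1:6) {
    ev <- seq(ctr[1] - width, ctr[1] + width, length.out = 41)
    ec <- seq(ctr[2] - width, ctr[2] + width, length.out = 41)
    vals <- outer(ev, ec, Vectorize(obj))
    ix <- arrayInd(which.min(vals), dim(vals))
    ctr <- c(ev[ix[1]], ec[ix[2]]); width <- width / 10
  }
  expect_lt(abs(est$eta_V - ctr[1]), 1e-3)
  expect_lt(abs(est$eta_Cl - ctr[2]), 1e-3)
  # optimiser sanity: the mode is no worse than the prior centre
  expect_lte(est$objective, obj(0, 0) + 1e-9)
})

test_that("a full noise-free profile recovers the generating random effects", {
  pop <- reference_pop_params()
  eta <- c(ka = 0.2, V = -0.25, Cl = 0.31)
  ip <- apply_covariates(pop, asat = 36.5, eta_ka = eta[1], eta_V = eta[2],
                         eta_Cl = eta[3])
  tad <- c(0, 0.5, 1, 2, 4, 6, 8, 24)
  dv <- conc_steady_state(800, tad, ip$ka, ip$V, ip$Cl)
  pop_noiov <- reference_pop_params(gamma_V = 0, gamma_Cl = 0,
                                    err_add = 0.001, err_prop = 0.001)
  est <- map_estimate(one_subject_tab(dv = dv, tad = tad), pop_noiov)
  expect_equal(est$eta_ka, eta[["ka"]], tolerance = 0.01)
  expect_equal(est$eta_V, eta[["V"]], tolerance = 0.01)
  expect_equal(est$eta_Cl, eta[["Cl"]], tolerance = 0.01)
  expect_equal(est$Cl, unname(ip$Cl), tolerance = 0.01)
})

test_that("single noise-free samples give consistent clearance and AUC", {
  gen <- reference_pop_params(gamma_V = 0, gamma_Cl = 0)
  eta <- c(ka = -0.1, V = 0.15, Cl = -0.2)
  ip <- apply_covariates(gen, asat = 36.5, eta_ka = eta[1], eta_V = eta[2],
                         eta_Cl = eta[3])
  tad <- c(0.5, 1, 2, 4, 6, 8, 24)
  dv <- conc_steady_state(800, tad, ip$ka, ip$V, ip$Cl)
  tab <- one_subject_tab(dv = dv, tad = tad)
  auc_true <- unname(800 / ip$Cl)
  # estimation under a small assumed residual error, matching the
  # noise-free data
  pop <- reference_pop_params(gamma_V = 0, gamma_Cl = 0,
                              err_add = 0.05, err_prop = 0.005)

  a_trough <- auc_single_sample(tab, pop, id = 1, sample_index = 7)
  # one point identifies clearance only partially; ~2% is the prior-resolved
  # floor for this subject's random-effect draw
  expect_lt(abs(a_trough$auc - auc_true) / auc_true, 0.025)
  a_6h <- auc_single_sample(tab, pop, id = 1, sample_index = 5)
  expect_lt(abs(a_6h$auc - a_trough$auc) / a_trough$auc, 0.05)
  # a sample near the concentration peak is flagged as weakly informative
  # for clearance (individual tmax is ~4.7 h here)
  a_peak <- auc_single_sample(tab, pop, id = 1, sample_index = 4)
  expect_true(a_peak$near_cmax)
  expect_false(a_trough$near_cmax)
})

test_that("subjects without usable observations are rejected", {
  tab <- one_subject_tab(dv = 0.4, tad = 24)
  tab$BLQ[tab$EVID == 0] <- 1L
  expect_error(map_estimate(tab, reference_pop_params()), "non-BLQ")
})
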