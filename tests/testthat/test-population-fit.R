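test_that("noise-free rich profiles identify the fixed effects to within 1%", {
  pop0 <- reference_pop_params(beta_V_asat = 0, omega_ka = 0, omega_V = 0,
                               omega_Cl = 0, gamma_V = 0, gamma_Cl = 0,
                               err_add = 0.01, err_prop = 0)
  alloc <- tibble::tibble(subject = rep(1:12, each = 2),
                          cycle = rep(c(1L, 2L), 12),
                          n_points = 8L, ss = rep(c(FALSE, TRUE), 12))
  des <- cohort_design(n_tdm_subjects = 0, tdm_visit_counts = integer(0),
                       rich_allocation = alloc, covariate_miss_rate = 0,
                       seed = 5)
  coh <- simulate_cohort(des, pop0)
  init <- reference_pop_params(ka_pop = 1.3, V_pop = 30, Cl_pop = 0.6,
                               beta_V_asat = 0, err_add = 0.5,
                               err_prop = 0.05)
  ft <- fit_saem(coh, init = init, covariates = list(),
                 control = saem_control(n_explore = 150, n_smooth = 100,
                                        compute_rse = FALSE,
                                        compute_ofv = FALSE))
  est <- ft$estimates
  expect_equal(est$ka_pop, 0.976, tolerance = 0.01)
  expect_equal(est$V_pop, 22.3, tolerance = 0.01)
  expect_equal(est$Cl_pop, 0.458, tolerance = 0.01)
})

test_that("the fit is deterministic given the seed", {
  coh <- shared_rich_cohort()
  ctl <- saem_control(n_explore = 30, n_smooth = 20, seed = 11,
                      compute_rse = FALSE, compute_ofv = FALSE)
  f1 <- fit_saem(coh, control = ctl)
  f2 <- fit_saem(coh, control = ctl)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$coefficients$estimate, f2$coefficients$estimate)
})

test_that("AIC equals OFV plus twice the parameter count", {
  ft <- shared_rich_fit()
  expect_identical(ft$aic, ft$ofv + 2 * ft$n_params)
  # relative standard errors from the empirical Fisher information exist
  # and are positive for every estimated parameter
  expect_true(all(is.finite(ft$coefficients$rse)))
  expect_true(all(ft$coefficients$rse > 0))
  expect_equal(ft$n_params, 3 + 1 + 3 + 2)  # fixed, ASAT, IIV, error (no IOV)
  g <- glance(ft)
  expect_identical(g$aic, g$ofv + 2 * g$n_params)
})

test_that("the importance-sampling likelihood matches closed forms and quadrature", {
  # no random effects: the marginal is the exact Gaussian residual density
  tab <- one_subject_tab(dv = c(30, 50), tad = c(2, 8))
  pop0 <- reference_pop_params(omega_ka = 0, omega_V = 0, omega_Cl = 0,
                               gamma_V = 0, gamma_Cl = 0)
  ll <- log_likelihood_is(tab, pop0, mc_size = 500, seed = 1)
  f <- pazopk:::predict_conc(c(2, 8), c(800, 800), c(TRUE, TRUE),
                             pop0$ka_pop, pop0$V_pop, pop0$Cl_pop)
  sd <- residual_sd(f, pop0)
  exact <- -2 * sum(dnorm(c(30, 50), f, sd, log = TRUE))
  expect_equal(ll$ofv, exact, tolerance = 1e-9)
  expect_equal(ll$se, 0)

  # one subject, one observation, one random effect: adaptive quadrature
  popc <- reference_pop_params(omega_ka = 0, omega_V = 0, omega_Cl = 0.3,
                               gamma_V = 0, gamma_Cl = 0)
  tab1 <- one_subject_tab(dv = 25, tad = 24)
  llc <- log_likelihood_is(tab1, popc, mc_size = 20000, seed = 2)
  integrand <- function(eta) {
    vapply(eta, function(e) {
      fe <- pazopk:::predict_conc(24, 800, TRUE, popc$ka_pop, popc$V_pop,
                                  popc$Cl_pop * exp(e))
      dnorm(25, fe, residual_sd(fe, popc)) * dnorm(e, 0, 0.3)
    }, 0)
  }
  quad <- integrate(integrand, -4, 4, rel.tol = 1e-10)$value
  expect_lt(abs(llc$ofv - (-2 * log(quad))), 3 * max(llc$se, 1e-6))

  # doubling the Monte Carlo size moves the estimate by less than 3 SE
  ll_a <- log_likelihood_is(tab1, popc, mc_size = 5000, seed = 3)
  ll_b <- log_likelihood_is(tab1, popc, mc_size = 10000, seed = 4)
  expect_lt(abs(ll_a$ofv - ll_b$ofv), 3 * sqrt(ll_a$se^2 + ll_b$se^2))

  expect_error(log_likelihood_is(tab1, popc, mc_size = 50), "100")
})

test_that("forward stepwise selects the generating covariate and applies both cuts", {
  coh <- simulate_cohort(rich_ss_design(n_subjects = 60,
                                        covariate_miss_rate = 0,
                                        asat_sdlog = 0.5, seed = 8))
  ctl <- saem_control(n_explore = 80, n_smooth = 40, compute_rse = FALSE,
                      mc_size = 1000, seed = 8)
  base <- fit_saem(coh, covariates = list(), control = ctl)
  cands <- list(covariate_term("V", "ASAT"), covariate_term("Cl", "CREAT"))
  sw <- stepwise_covariates(coh, base, cands)

  expect_gte(length(sw$selected), 1)
  expect_equal(sw$selected[[1]]$cov, "ASAT")
  expect_equal(sw$selected[[1]]$param, "V")
  # each accepted candidate met both the OFV and the AIC cut
  accepted <- sw$log[sw$log$accepted, ]
  expect_true(all(accepted$dofv >= 3.84))
  expect_true(all(accepted$daic >= 2))
  # one extra parameter: the AIC change is the OFV change minus 2, exactly
  ok <- !sw$log$failed
  expect_equal(sw$log$daic[ok], sw$log$dofv[ok] - 2, tolerance = 1e-9)
  # exponent recovered within the stochastic band
  est <- sw$final_fit$coefficients
  beta <- est$estimate[est$parameter == "beta_V_ASAT"]
  expect_lt(abs(beta - (-0.838)) / 0.838, 0.30)
})

test_that("eta-shrinkage is 0% at full dispersion and 100% at collapse", {
  pop <- reference_pop_params()
  ebe <- tibble::tibble(eta_ka = c(-0.3, 0, 0.3) / sqrt(0.09 / 0.3^2) * 1,
                        eta_V = rep(0, 3),
                        eta_Cl = c(-0.3, 0, 0.3))
  ebe$eta_ka <- c(-1, 0, 1) * pop$omega_ka  # SD exactly omega_ka
  sh <- pazopk:::shrinkage_from_ebe(ebe, pop)
  expect_equal(sh$shrinkage[sh$effect == "eta_ka"], 0, tolerance = 1e-9)
  expect_equal(sh$shrinkage[sh$effect == "eta_V"], 100)
  # dense sampling keeps clearance shrinkage low
  ft <- shared_rich_fit()
  cl_shrink <- eta_shrinkage(ft)$shrinkage[3]
  expect_lt(cl_shrink, 20)
})
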