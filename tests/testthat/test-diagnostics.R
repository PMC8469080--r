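test_that("VPC bands are nested, bins partition the time range, and a
           zero-variability model collapses the band", {
  coh <- shared_rich_cohort()
  pop <- reference_pop_params()
  v <- vpc(coh, pop, n_replicates = 200, seed = 3)
  expect_true(all(v$band_lo <= v$band_med & v$band_med <= v$band_hi))
  bins <- unique(v[, c("bin", "t_lo", "t_hi")])
  bins <- bins[order(bins$bin), ]
  expect_true(all(diff(bins$t_lo) > 0))
  expect_true(all(bins$t_hi[-nrow(bins)] <= bins$t_lo[-1]))
  obs_tads <- unique(c(0, 0.5, 1, 2, 4, 6, 8, 24))
  expect_equal(min(bins$t_lo), min(obs_tads))
  expect_equal(max(bins$t_hi), max(obs_tads))

  pop0 <- reference_pop_params(omega_ka = 0, omega_V = 0, omega_Cl = 0,
                               gamma_V = 0, gamma_Cl = 0, err_add = 0,
                               err_prop = 0)
  v0 <- vpc(coh, pop0, n_replicates = 120, seed = 3)
  expect_true(all(abs(v0$band_hi - v0$band_lo) < 1e-9))
})

test_that("VPC covers the empirical percentiles of self-simulated data", {
  pop <- reference_pop_params()
  cover <- vapply(1:3, function(s) {
    coh <- simulate_cohort(rich_ss_design(n_subjects = 12,
                                          covariate_miss_rate = 0,
                                          seed = 100 + s), pop)
    v <- vpc(coh, pop, n_replicates = 150, seed = s)
    mean(v$observed >= v$band_lo & v$observed <= v$band_hi)
  }, 0)
  expect_gte(mean(cover), 0.80)
})

test_that("NPDE of self-simulated data is standard normal and detects bias", {
  pop <- reference_pop_params()
  coh <- simulate_cohort(rich_ss_design(n_subjects = 30,
                                        covariate_miss_rate = 0,
                                        seed = 19), pop)
  nd <- npde(coh, pop, n_replicates = 600, seed = 5)
  expect_lt(abs(mean(nd$npde)), 0.15)
  expect_gt(var(nd$npde), 0.75)
  expect_lt(var(nd$npde), 1.25)

  # evaluating with a doubled clearance underpredicts: observations exceed
  # simulations, shifting the errors positive
  pop_bad <- reference_pop_params(Cl_pop = 2 * 0.458)
  nd_bad <- npde(coh, pop_bad, n_replicates = 600, seed = 5)
  expect_gt(mean(nd_bad$npde), 0.5)
})

test_that("individual weighted residuals reduce to their closed forms", {
  pop <- reference_pop_params(beta_V_asat = 0, omega_ka = 0, omega_V = 0,
                              omega_Cl = 0, gamma_V = 0, gamma_Cl = 0,
                              err_prop = 0, err_add = 1)
  tad <- c(1, 4, 24)
  f <- conc_steady_state(800, tad, pop$ka_pop, pop$V_pop, pop$Cl_pop)
  build_fit <- function(dv) {
    tab <- one_subject_tab(dv = dv, tad = tad)
    tab2 <- tab; tab2$ID <- 2L  # fits need two subjects
    tab <- dplyr::bind_rows(tab, tab2)
    structure(list(estimates = pop, ebe = map_estimate(tab, pop),
                   .subjects = pazopk:::prep_cohort(tab)),
              class = "pazo_fit")
  }
  r0 <- iwres(build_fit(f))
  expect_equal(r0$iwres, rep(0, 6), tolerance = 1e-6)
  r1 <- iwres(build_fit(f + 1))  # one additive-error unit above prediction
  expect_equal(r1$iwres, rep(1, 6), tolerance = 1e-6)
})

test_that("residual tails of a well-specified fit stay near normal", {
  ft <- shared_rich_fit()
  r <- iwres(ft)
  expect_lt(mean(abs(r$iwres) > 3), 0.01)
})

test_that("bootstrap quartiles bracket the estimates on a stable cohort", {
  coh <- shared_rich_cohort()
  ft <- shared_rich_fit()
  bt <- bootstrap_fit(coh, n_iterations = 20,
                      control = saem_control(n_explore = 50, n_smooth = 30,
                                             compute_rse = FALSE,
                                             compute_ofv = FALSE),
                      fit = ft, seed = 4)
  expect_equal(bt$n_effective, 20)
  expect_true(all(c("q1", "median", "q3", "within_iqr") %in% names(bt$quartiles)))
  expect_true(all(bt$quartiles$q1 <= bt$quartiles$q3))
  fixed <- bt$quartiles[bt$quartiles$parameter %in%
                          c("ka_pop", "V_pop", "Cl_pop"), ]
  expect_gte(sum(fixed$within_iqr), 2)
  expect_error(bootstrap_fit(coh, n_iterations = 5), "20")
})

test_that("leave-one-out on near-noise-free profiles is near exact", {
  # the identifiable limit: assay noise removed, a single dose level (so
  # the AUC and trough criteria cannot structurally discord), no covariate
  # channel, and enough subjects that the n-1 refit sampling error -- the
  # floor of this procedure -- stays small
  pop_ln <- reference_pop_params(beta_V_asat = 0, err_add = 0.05,
                                 err_prop = 0.005)
  coh <- simulate_cohort(rich_ss_design(n_subjects = 16,
                                        covariate_miss_rate = 0,
                                        dose_probs = c(0, 0, 0, 1),
                                        seed = 14),
                         pop_ln)
  loo <- loo_crossvalidate(
    coh, init = pop_ln, covariates = list(),
    control = saem_control(n_explore = 100, n_smooth = 60,
                           compute_rse = FALSE, compute_ofv = FALSE),
    seed = 14)
  expect_equal(loo$folds_failed, 0)
  expect_lt(loo$summary$mean_abs_rel_dev, 5)
  expect_equal(loo$summary$agreement, 100)
  expect_equal(nrow(loo$records), loo$summary$n_decisions)
})
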