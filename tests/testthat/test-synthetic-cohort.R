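test_that("the default cohort reproduces the published database dimensions", {
  coh <- simulate_cohort(cohort_design(seed = 1))
  expect_equal(sum(coh$EVID == 0), 406)
  expect_equal(sum(coh$EVID == 0 & coh$ARM == "tdm"), 126)
  expect_equal(sum(coh$EVID == 0 & coh$ARM == "rich"), 280)
  expect_equal(length(unique(coh$ID)), 73)
  expect_equal(length(unique(coh$ID[coh$ARM == "rich"])), 15)
  # 36 rich occasion-profiles
  rich <- coh[coh$ARM == "rich" & coh$EVID == 1, ]
  expect_equal(nrow(unique(rich[, c("ID", "OCC")])), 36)
  # observation times non-decreasing within subject
  for (id in unique(coh$ID)) {
    expect_false(is.unsorted(coh$TIME[coh$ID == id]))
  }
})

test_that("an identical seed reproduces the dataset byte for byte", {
  a <- simulate_cohort(cohort_design(seed = 7))
  b <- simulate_cohort(cohort_design(seed = 7))
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- simulate_cohort(cohort_design(seed = 8))
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
})

test_that("TDM sampling times centre on the design mean", {
  coh <- simulate_cohort(cohort_design(seed = 1))
  tdm <- coh[coh$EVID == 0 & coh$ARM == "tdm", ]
  doses <- coh[coh$EVID == 1, ]
  key <- paste(tdm$ID, tdm$OCC)
  tads <- tdm$TIME - doses$TIME[match(key, paste(doses$ID, doses$OCC))]
  expect_lt(abs(mean(tads) - 24.6), 0.5)
  expect_true(all(tads >= 20 & tads <= 30))
})

test_that("covariate and random-effect distributions match their targets", {
  des <- cohort_design(n_tdm_subjects = 10000,
                       tdm_visit_counts = rep(1L, 10000),
                       rich_allocation = default_rich_allocation(0),
                       covariate_miss_rate = 0, seed = 3)
  coh <- simulate_cohort(des)
  truth <- cohort_truth(coh, "subject")
  expect_lt(abs(median(truth$ASAT) / 36.5 - 1), 0.02)
  # dispersion of individual log V at fixed covariates is omega_V
  expect_lt(abs(sd(truth$eta_V) / 0.248 - 1), 0.05)
})

test_that("the noise-free generator returns the population-typical curve", {
  pop0 <- reference_pop_params(beta_V_asat = 0, omega_ka = 0, omega_V = 0,
                               omega_Cl = 0, gamma_V = 0, gamma_Cl = 0,
                               err_add = 0, err_prop = 0)
  des <- cohort_design(n_tdm_subjects = 4, tdm_visit_counts = rep(2L, 4),
                       rich_allocation = default_rich_allocation(2),
                       covariate_miss_rate = 0, seed = 9)
  coh <- simulate_cohort(des, pop0)
  obs <- coh[coh$EVID == 0, ]
  doses <- coh[coh$EVID == 1, ]
  key <- paste(obs$ID, obs$OCC)
  tad <- obs$TIME - doses$TIME[match(key, paste(doses$ID, doses$OCC))]
  f <- pazopk:::predict_conc(tad, obs$DOSE_DAILY, obs$SS == 1,
                             pop0$ka_pop, pop0$V_pop, pop0$Cl_pop)
  expect_equal(obs$DV, f, tolerance = 1e-12)
  # on the rich schedule at 800 mg nothing post-absorption falls below the
  # quantification limit
  rich800 <- obs$ARM == "rich" & obs$DOSE_DAILY == 800 & tad >= 0.5
  if (any(rich800)) expect_true(all(obs$DV[rich800] >= 1))
  expect_true(all(obs$BLQ[rich800] == 0))
})

test_that("covariate imputation follows patient-median-then-population-median", {
  tab <- tibble::tibble(
    ID = c(1, 1, 1, 2, 2, 3),
    ASAT = c(30, NA, 40, NA, NA, 36.5)
  )
  out <- impute_covariates(tab, covariates = "ASAT")
  expect_equal(out$ASAT[2], 35)          # patient median
  expect_equal(out$ASAT[4:5], c(36.5, 36.5))  # population median 36.5
  expect_equal(out$ASAT[c(1, 3, 6)], c(30, 40, 36.5))  # untouched

  full <- tibble::tibble(ID = 1:3, ASAT = c(20, 30, 40))
  expect_identical(impute_covariates(full, "ASAT"), full)

  allna <- tibble::tibble(ID = 1:2, ASAT = c(NA_real_, NA_real_))
  expect_error(impute_covariates(allna, "ASAT"), "ASAT")
})

test_that("quantification-limit censoring flags strictly-below values", {
  tab <- one_subject_tab(dv = c(0.5, 1.0, 2.0), tad = c(1, 2, 3))
  out <- censor_blq(tab, lloq = 1)
  expect_equal(out$BLQ[out$EVID == 0], c(1L, 0L, 0L))
  out0 <- censor_blq(tab, lloq = 0)
  expect_true(all(out0$BLQ == 0))
})
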