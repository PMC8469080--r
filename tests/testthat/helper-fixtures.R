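# Shared fixtures and independent oracles, all built in code at test time.

# deterministic one-compartment parameters for oracle comparisons
ref_ip <- list(ka = 0.976, V = 22.3, Cl = 0.458)

# ODE oracle: depot/central two-compartment system integrated numerically
ode_conc <- function(dose, times, ka, V, Cl, rtol = 1e-10, atol = 1e-12) {
  ke <- Cl / V
  rhs <- function(t, y, p) {
    list(c(-ka * y[1], ka * y[1] - ke * y[2]))
  }
  out <- deSolve::lsoda(c(A = dose, C = 0), times = c(0, times), rhs,
                        parms = NULL, rtol = rtol, atol = atol)
  out[-1, "C"] / V
}

# brute-force superposition oracle for repeated dosing
superposition_conc <- function(dose, t_after_last, ka, V, Cl, tau,
                               n_doses = 200) {
  tt <- t_after_last + tau * (seq_len(n_doses) - 1)
  sum(conc_single_dose(dose, tt, ka, V, Cl))
}

# small rich steady-state cohort + fitted model, computed once per session
.shared <- new.env()
shared_rich_cohort <- function() {
  if (is.null(.shared$coh)) {
    .shared$coh <- simulate_cohort(
      rich_ss_design(n_subjects = 10, covariate_miss_rate = 0, seed = 42))
  }
  .shared$coh
}
shared_rich_fit <- function() {
  if (is.null(.shared$fit)) {
    .shared$fit <- fit_saem(
      shared_rich_cohort(),
      control = saem_control(n_explore = 100, n_smooth = 60, seed = 42,
                             mc_size = 1000, rse_sweeps = 40))
  }
  .shared$fit
}

# a minimal hand-built single-subject dataset
one_subject_tab <- function(dv, tad, dose = 800, ss = 1L, asat = 36.5) {
  tibble::tibble(
    ID = 1L,
    TIME = c(0, tad),
    AMT = c(dose, rep(NA_real_, length(tad))),
    DV = c(NA_real_, dv),
    EVID = c(1L, rep(0L, length(tad))),
    MDV = c(1L, rep(0L, length(tad))),
    OCC = 1L, SS = ss, BLQ = 0L,
    ASAT = asat
  )
}
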