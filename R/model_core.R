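#' Individual parameters from population parameters, covariates and random
#' effects
#'
#' Assembles the individual apparent volume, clearance and absorption rate
#' for one occasion:
#' \deqn{V_i = V_{pop} (ASAT_i/ASAT_{ref})^{\beta} e^{\eta_V + \kappa_V},
#'       \quad Cl_i = Cl_{pop} e^{\eta_{Cl} + \kappa_{Cl}},
#'       \quad ka_i = ka_{pop} e^{\eta_{ka}}}
#' where the eta terms are subject-level (inter-individual) deviations and
#' the kappa terms occasion-level (inter-occasion) deviations, all on the
#' log scale.
#'
#' @param pop A [pop_params()] object.
#' @param asat ASAT covariate value (UI/L, > 0).
#' @param eta_ka,eta_V,eta_Cl Subject-level random effects (log scale).
#' @param kappa_V,kappa_Cl Occasion-level random effects (log scale).
#' @return A named list with `ka`, `V`, `Cl` and the derived elimination
#'   rate `ke = Cl/V` (1/h).
#' @export
#' @examples
#' apply_covariates(reference_pop_params(), asat = 36.5)
apply_covariates <- function(pop, asat,
                             eta_ka = 0, eta_V = 0, eta_Cl = 0,
                             kappa_V = 0, kappa_Cl = 0) {
  if (!is.numeric(asat) || any(!is.finite(asat)) || any(asat <= 0)) {
    stop("`asat` must be strictly positive")
  }
  V <- pop$V_pop * (asat / pop$asat_ref)^pop$beta_V_asat *
    exp(eta_V + kappa_V)
  Cl <- pop$Cl_pop * exp(eta_Cl + kappa_Cl)
  ka <- pop$ka_pop * exp(eta_ka)
  list(ka = ka, V = V, Cl = Cl, ke = Cl / V)
}

#' Plasma concentration after a single oral dose
#'
#' One-compartment model with first-order absorption and first-order
#' elimination:
#' \deqn{C(t) = \frac{D}{V}\frac{ka}{ka - ke}(e^{-ke t} - e^{-ka t})}
#' When ka is within a relative tolerance of ke the analytic limit
#' \eqn{(D/V) ka t e^{-ka t}} is used so the flip-flop degeneracy never
#' produces a division blow-up.
#'
#' @param dose Dose amount (mg).
#' @param t Time since dose (h, vectorised, >= 0).
#' @param ka,V,Cl Individual absorption rate (1/h), apparent volume (L)
#'   and apparent clearance (L/h).
#' @param tol Relative switch tolerance for the ka = ke degeneracy.
#' @return Concentration (mg/L), same length as `t`.
#' @export
#' @examples
#' conc_single_dose(800, t = 24, ka = 0.976, V = 22.3, Cl = 0.458)
conc_single_dose <- function(dose, t, ka, V, Cl, tol = 1e-8) {
  if (any(t < 0)) stop("`t` must be non-negative")
  n <- max(length(t), length(dose), length(ka), length(V), length(Cl))
  t <- rep_len(t, n); dose <- rep_len(dose, n)
  ka <- rep_len(ka, n); V <- rep_len(V, n); Cl <- rep_len(Cl, n)
  ke <- Cl / V
  deg <- abs(ka - ke) < tol * ke
  out <- numeric(n)
  if (any(!deg)) {
    i <- !deg
    out[i] <- (dose[i] / V[i]) * (ka[i] / (ka[i] - ke[i])) *
      (exp(-ke[i] * t[i]) - exp(-ka[i] * t[i]))
  }
  if (any(deg)) {
    i <- deg
    out[i] <- (dose[i] / V[i]) * ka[i] * t[i] * exp(-ka[i] * t[i])
  }
  out
}

#' Plasma concentration at steady state under repeated dosing
#'
#' Superposition of the single-dose solution for doses every `tau` hours,
#' carried to steady state:
#' \deqn{C_{ss}(t) = \frac{D}{V}\frac{ka}{ka-ke}\left(
#'   \frac{e^{-ke t}}{1 - e^{-ke\tau}} - \frac{e^{-ka t}}{1 - e^{-ka\tau}}
#' \right)}
#' with `t` the time since the last administered dose. The formula is the
#' exact sum over all past doses, so it remains valid for `t > tau` (a
#' delayed sample before the next intake) as long as no further dose has
#' been taken.
#'
#' @inheritParams conc_single_dose
#' @param tau Dosing interval (h), default 24 (once daily).
#' @param t Time since last dose (h, vectorised, >= 0).
#' @return Concentration (mg/L).
#' @export
#' @examples
#' conc_steady_state(800, t = 24, ka = 0.976, V = 22.3, Cl = 0.458)
conc_steady_state <- function(dose, t, ka, V, Cl, tau = 24, tol = 1e-8) {
  if (any(t < 0)) stop("`t` must be non-negative")
  if (tau <= 0) stop("`tau` must be positive")
  n <- max(length(t), length(dose), length(ka), length(V), length(Cl))
  t <- rep_len(t, n); dose <- rep_len(dose, n)
  ka <- rep_len(ka, n); V <- rep_len(V, n); Cl <- rep_len(Cl, n)
  ke <- Cl / V
  deg <- abs(ka - ke) < tol * ke
  out <- numeric(n)
  if (any(!deg)) {
    i <- !deg
    out[i] <- (dose[i] / V[i]) * (ka[i] / (ka[i] - ke[i])) *
      (exp(-ke[i] * t[i]) / (1 - exp(-ke[i] * tau)) -
         exp(-ka[i] * t[i]) / (1 - exp(-ka[i] * tau)))
  }
  if (any(deg)) {
    # limit of the superposition sum as ka -> ke
    i <- deg
    r <- exp(-ka[i] * tau)
    out[i] <- (dose[i] / V[i]) * ka[i] * exp(-ka[i] * t[i]) *
      (t[i] / (1 - r) + tau * r / (1 - r)^2)
  }
  out
}

#' AUC over a dosing interval from clearance
#'
#' At steady state the area under the concentration-time curve over one
#' dosing interval equals Dose / (Cl/F).
#'
#' @param dose Dose administered per interval (mg).
#' @param cl Apparent clearance Cl/F (L/h, > 0).
#' @return AUC (mg*h/L).
#' @export
#' @examples
#' auc_from_clearance(800, 0.458)
auc_from_clearance <- function(dose, cl) {
  if (any(!is.finite(cl)) || any(cl <= 0)) {
    stop("`cl` must be strictly positive")
  }
  dose / cl
}

#' Residual-error standard deviation
#'
#' Combined residual-error model for an observation with model prediction
#' `pred`: the default "combined1" convention gives
#' sd = err_add + err_prop * pred; the alternative "combined2" gives
#' sd = sqrt(err_add^2 + err_prop^2 * pred^2). Observations are modelled as
#' y = pred + sd * epsilon with standard-normal epsilon.
#'
#' @param pred Model-predicted concentration (mg/L, vectorised, >= 0).
#' @param pop A [pop_params()] object supplying `err_add`, `err_prop` and
#'   the `err_model` convention.
#' @return Residual SD (mg/L), same length as `pred`.
#' @export
residual_sd <- function(pred, pop) {
  if (any(pred < 0)) stop("`pred` must be non-negative")
  if (identical(pop$err_model, "combined2")) {
    sqrt(pop$err_add^2 + pop$err_prop^2 * pred^2)
  } else {
    pop$err_add + pop$err_prop * pred
  }
}

# internal vectorised prediction over observation rows.
# tad: time after (last) dose; ss: steady-state flag per row; dose per row;
# ka/V/Cl scalars or vectors recycled per row.
predict_conc <- function(tad, dose, ss, ka, V, Cl, tau = 24, tol = 1e-8) {
  ke <- Cl / V
  deg <- abs(ka - ke) < tol * ke
  out <- numeric(length(tad))
  a <- (dose / V) * ifelse(deg, 1, ka / (ka - ke))
  if (length(a) == 1L) a <- rep(a, length(tad))
  if (length(ke) == 1L) ke <- rep(ke, length(tad))
  if (length(deg) == 1L) deg <- rep(deg, length(tad))
  ka_v <- if (length(ka) == 1L) rep(ka, length(tad)) else ka
  sd_rows <- !ss
  if (any(sd_rows & !deg)) {
    i <- sd_rows & !deg
    out[i] <- a[i] * (exp(-ke[i] * tad[i]) - exp(-ka_v[i] * tad[i]))
  }
  if (any(sd_rows & deg)) {
    i <- sd_rows & deg
    # a[i] is D/V for degenerate rows, so this is (D/V) ka t e^{-ka t}
    out[i] <- a[i] * ka_v[i] * tad[i] * exp(-ka_v[i] * tad[i])
  }
  if (any(ss & !deg)) {
    i <- ss & !deg
    out[i] <- a[i] * (exp(-ke[i] * tad[i]) / (1 - exp(-ke[i] * tau)) -
                        exp(-ka_v[i] * tad[i]) / (1 - exp(-ka_v[i] * tau)))
  }
  if (any(ss & deg)) {
    i <- ss & deg
    r <- exp(-ka_v[i] * tau)
    out[i] <- a[i] * ka_v[i] * exp(-ka_v[i] * tad[i]) *
      (tad[i] / (1 - r) + tau * r / (1 - r)^2)
  }
  pmax(out, 0)
}
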