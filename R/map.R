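#' MAP (empirical-Bayes) estimation of individual parameters
#'
#' Estimates each subject's random effects as the mode of their conditional
#' (posterior) distribution given fixed population parameters, from as
#' little as a single concentration drawn at any time. The objective
#' minimised over the random effects eta is
#' \deqn{\sum_{obs} \left[\frac{(y - f)^2}{sd(f)^2} + 2\log sd(f)\right]
#'       + \eta^\top \Omega^{-1} \eta}
#' with f the model prediction, sd the combined residual error, and Omega
#' the diagonal covariance of the inter-individual plus (for each sampled
#' occasion) inter-occasion effects. Optimisation restarts from eta = 0
#' plus four jittered starts and keeps the lowest objective.
#'
#' Samples flagged `BLQ` are never used. Occasions whose dose history is at
#' steady state (`SS = 1`) are evaluated against the steady-state curve;
#' treatment-start profiles against the single-dose curve.
#'
#' @param data A cohort tibble (NONMEM-style; see [simulate_cohort()]).
#' @param pop Fixed population parameters ([pop_params()]), e.g. the
#'   published reference set or a [fit_saem()] estimate.
#' @param ids Subjects to estimate (default all).
#' @param obs_subset Optional integer indices selecting, within each
#'   subject's usable (non-BLQ) observations in time order, which are used.
#' @param n_starts Number of optimisation starts (first is eta = 0).
#' @param seed Seed for the jittered starts.
#' @return A tibble with one row per subject: random-effect modes, the
#'   individual `ka`, `V`, `Cl` (of the last sampled occasion), the derived
#'   `auc` = daily dose / Cl (mg*h/L), the objective value at the mode, a
#'   `near_cmax` flag marking estimates driven by samples near the
#'   concentration peak (where clearance is weakly identified), and a
#'   convergence flag.
#' @export
#' @examples
#' coh <- simulate_cohort(rich_ss_design(n_subjects = 3))
#' map_estimate(coh, reference_pop_params())
map_estimate <- function(data, pop, ids = NULL, obs_subset = NULL,
                         n_starts = 5, seed = 1) {
  tau <- attr(data, "design")$tau %||% 24
  subjects <- prep_cohort(data, asat_ref = pop$asat_ref, tau = tau)
  if (!is.null(ids)) {
    subjects <- subjects[vapply(subjects, function(s) s$id %in% ids, TRUE)]
    if (length(subjects) == 0) stop("no matching subjects in `ids`")
  }
  rows <- lapply(seq_along(subjects), function(k) {
    s <- subjects[[k]]
    use <- seq_len(s$n_obs)
    if (!is.null(obs_subset)) {
      if (any(obs_subset > s$n_obs)) {
        stop(sprintf("obs_subset index out of range for subject %s", s$id))
      }
      use <- obs_subset
    }
    if (length(use) == 0 || s$n_obs == 0) {
      stop(sprintf("subject %s has no usable (non-BLQ) observation", s$id))
    }
    map_one(s, pop, use, n_starts = n_starts,
            seed = substream_seed(seed, "map") + k)
  })
  dplyr::bind_rows(rows)
}

# core MAP solver for one prepared subject
map_one <- function(s, pop, use, n_starts = 5, seed = 1) {
  active_occ <- sort(unique(s$occ_idx[use]))
  iiv_on <- c(ka = pop$omega_ka > 0, V = pop$omega_V > 0, Cl = pop$omega_Cl > 0)
  iov_on <- c(V = pop$gamma_V > 0, Cl = pop$gamma_Cl > 0)
  # parameter vector layout: active IIV etas, then per active occasion the
  # active IOV kappas
  sds <- c(pop$omega_ka, pop$omega_V, pop$omega_Cl)[iiv_on]
  for (o in active_occ) sds <- c(sds, c(pop$gamma_V, pop$gamma_Cl)[iov_on])
  d <- length(sds)

  unpack <- function(x) {
    eta <- c(ka = 0, V = 0, Cl = 0)
    j <- 0L
    for (nm in c("ka", "V", "Cl")) {
      if (iiv_on[[nm]]) { j <- j + 1L; eta[[nm]] <- x[j] }
    }
    kap_V <- numeric(s$n_occ); kap_Cl <- numeric(s$n_occ)
    for (o in active_occ) {
      if (iov_on[["V"]]) { j <- j + 1L; kap_V[o] <- x[j] }
      if (iov_on[["Cl"]]) { j <- j + 1L; kap_Cl[o] <- x[j] }
    }
    list(eta = eta, kap_V = kap_V, kap_Cl = kap_Cl)
  }

  phi_base <- c(log(pop$ka_pop),
                log(pop$V_pop) + pop$beta_V_asat * s$c_asat,
                log(pop$Cl_pop))
  errp <- list(a = pop$err_add, b = pop$err_prop, model = pop$err_model)

  objective <- function(x) {
    u <- unpack(x)
    phi <- phi_base + c(u$eta[["ka"]], u$eta[["V"]], u$eta[["Cl"]])
    oi <- s$occ_idx[use]
    f <- predict_conc(s$tad[use], s$dose[use], s$ss[use],
                      exp(phi[1]), exp(phi[2] + u$kap_V[oi]),
                      exp(phi[3] + u$kap_Cl[oi]), tau = s$tau)
    sd <- if (identical(errp$model, "combined2")) {
      sqrt(errp$a^2 + errp$b^2 * f^2)
    } else errp$a + errp$b * f
    sd <- pmax(sd, 1e-10)
    sum((s$dv[use] - f)^2 / sd^2 + 2 * log(sd)) + sum((x / sds)^2)
  }

  if (d == 0) {
    # no random effects to estimate: typical-value prediction
    u <- unpack(numeric(0))
    best <- list(par = numeric(0), objective = objective(numeric(0)),
                 convergence = 0L)
  } else {
    starts <- with_seed_(seed, {
      c(list(rep(0, d)),
        lapply(seq_len(max(0, n_starts - 1)), function(i) {
          stats::rnorm(d, 0, 0.5) * sds
        }))
    })
    fits <- lapply(starts, function(x0) {
      tryCatch(stats::nlminb(x0, objective,
                             control = list(iter.max = 500, eval.max = 800)),
               error = function(e) NULL)
    })
    fits <- fits[!vapply(fits, is.null, TRUE)]
    best <- fits[[which.min(vapply(fits, function(f) f$objective, 0))]]
  }

  u <- unpack(best$par)
  occ_used <- max(s$occ_idx[use])
  ip <- apply_covariates(pop, asat = if (is.na(s$asat)) pop$asat_ref else s$asat,
                         eta_ka = u$eta[["ka"]], eta_V = u$eta[["V"]],
                         eta_Cl = u$eta[["Cl"]],
                         kappa_V = u$kap_V[occ_used],
                         kappa_Cl = u$kap_Cl[occ_used])
  dose_used <- s$occ$dose[occ_used]
  tmax <- log(ip$ka / ip$ke) / (ip$ka - ip$ke)
  near_cmax <- all(abs(s$tad[use] - tmax) <= 2)
  tibble::tibble(
    ID = s$id, n_obs_used = length(use), occasion = s$occ$occ[occ_used],
    eta_ka = u$eta[["ka"]], eta_V = u$eta[["V"]], eta_Cl = u$eta[["Cl"]],
    kappa_V = u$kap_V[occ_used], kappa_Cl = u$kap_Cl[occ_used],
    ka = ip$ka, V = ip$V, Cl = ip$Cl,
    auc = auc_from_clearance(dose_used, ip$Cl),
    objective = best$objective,
    near_cmax = near_cmax,
    converged = identical(best$convergence, 0L) || best$convergence == 0,
    kappas = list(tibble::tibble(occ = s$occ$occ, kappa_V = u$kap_V,
                                 kappa_Cl = u$kap_Cl))
  )
}

#' Individual AUC from a single sample
#'
#' Restricts MAP estimation to one indexed sample of a subject and converts
#' the resulting clearance to the AUC over the dosing interval,
#' AUC = daily dose / (Cl/F).
#'
#' @inheritParams map_estimate
#' @param id The subject.
#' @param sample_index Index of the sample within the subject's usable
#'   (non-BLQ) observations, in time order.
#' @return A one-row tibble (see [map_estimate()]).
#' @export
auc_single_sample <- function(data, pop, id, sample_index, seed = 1) {
  map_estimate(data, pop, ids = id, obs_subset = sample_index, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
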