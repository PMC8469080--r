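# Internal preparation of a NONMEM-style cohort table for likelihood work.
# BLQ observations are excluded from all likelihood computations (simple
# exclusion handling); they remain in the table for provenance.

required_cols <- c("ID", "TIME", "AMT", "DV", "EVID", "MDV", "OCC", "BLQ")

prep_cohort <- function(data, asat_ref = 36.5, tau = 24) {
  miss <- setdiff(required_cols, names(data))
  if (length(miss) > 0) {
    stop(sprintf("dataset is missing mandatory column(s): %s",
                 paste(miss, collapse = ", ")))
  }
  if (!"SS" %in% names(data)) data$SS <- 1L
  has_asat <- "ASAT" %in% names(data)
  ids <- unique(data$ID)
  subjects <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    d <- data[data$ID == ids[k], , drop = FALSE]
    d <- d[order(d$TIME, -d$EVID), , drop = FALSE]
    if (is.unsorted(d$TIME)) stop(sprintf("non-monotone TIME for subject %s", ids[k]))
    doses <- d[d$EVID == 1, , drop = FALSE]
    obs <- d[d$EVID == 0 & d$BLQ == 0 & !is.na(d$DV), , drop = FALSE]
    if (nrow(doses) == 0) {
      stop(sprintf("subject %s has no dose record", ids[k]))
    }
    occ_labels <- unique(doses$OCC)
    occ_df <- tibble::tibble(
      occ = occ_labels,
      dose = vapply(occ_labels, function(o) doses$AMT[doses$OCC == o][1], 0),
      t_dose = vapply(occ_labels, function(o) doses$TIME[doses$OCC == o][1], 0),
      ss = vapply(occ_labels, function(o) doses$SS[doses$OCC == o][1] == 1, TRUE)
    )
    occ_idx <- match(obs$OCC, occ_df$occ)
    if (anyNA(occ_idx) && nrow(obs) > 0) {
      stop(sprintf("subject %s has observations in an occasion with no dose row",
                   ids[k]))
    }
    tad <- obs$TIME - occ_df$t_dose[occ_idx]
    if (any(tad < 0)) {
      stop(sprintf("subject %s has an observation before its occasion dose",
                   ids[k]))
    }
    asat <- NA_real_
    if (has_asat) {
      av <- d$ASAT[!is.na(d$ASAT)]
      if (length(av) > 0) asat <- stats::median(av)
    }
    subjects[[k]] <- list(
      id = ids[k],
      asat = asat,
      c_asat = if (is.na(asat)) 0 else log(asat / asat_ref),
      occ = occ_df,
      tad = tad,
      dv = obs$DV,
      occ_idx = occ_idx,
      dose = occ_df$dose[occ_idx],
      ss = occ_df$ss[occ_idx],
      obs_time = obs$TIME,
      obs_by_occ = lapply(seq_len(nrow(occ_df)), function(j) which(occ_idx == j)),
      n_occ = nrow(occ_df),
      n_obs = nrow(obs),
      n_blq = sum(d$EVID == 0 & d$BLQ == 1),
      tau = tau
    )
  }
  if (has_asat && any(vapply(subjects, function(s) is.na(s$asat), TRUE))) {
    stop("missing ASAT values remain; run impute_covariates() first")
  }
  subjects
}

# conditional log-likelihood of one subject's observations given the
# individual log-parameters. phi = c(log ka, log V_base, log Cl_base);
# kap_V / kap_Cl are per-occasion deviations (length n_occ, zeros allowed).
# errp = list(a, b, model)
subj_loglik <- function(s, phi, kap_V, kap_Cl, errp, rows = NULL) {
  if (is.null(rows)) rows <- seq_len(s$n_obs)
  if (length(rows) == 0) return(0)
  oi <- s$occ_idx[rows]
  ka <- exp(phi[1])
  V <- exp(phi[2] + kap_V[oi])
  Cl <- exp(phi[3] + kap_Cl[oi])
  f <- predict_conc(s$tad[rows], s$dose[rows], s$ss[rows], ka, V, Cl,
                    tau = s$tau)
  sd <- if (identical(errp$model, "combined2")) {
    sqrt(errp$a^2 + errp$b^2 * f^2)
  } else {
    errp$a + errp$b * f
  }
  sd <- pmax(sd, 1e-10)
  sum(stats::dnorm(s$dv[rows], f, sd, log = TRUE))
}

# individual predictions for one subject at given log-parameters
subj_pred <- function(s, phi, kap_V, kap_Cl, rows = NULL) {
  if (is.null(rows)) rows <- seq_len(s$n_obs)
  oi <- s$occ_idx[rows]
  predict_conc(s$tad[rows], s$dose[rows], s$ss[rows],
               exp(phi[1]), exp(phi[2] + kap_V[oi]), exp(phi[3] + kap_Cl[oi]),
               tau = s$tau)
}

# theta: internal parameter state of the SAEM machinery
theta_from_pop <- function(pop, estimate_beta = TRUE) {
  list(mu = c(ka = log(pop$ka_pop), V = log(pop$V_pop), Cl = log(pop$Cl_pop)),
       beta = if (estimate_beta) pop$beta_V_asat else NULL,
       beta_fixed = if (estimate_beta) NULL else pop$beta_V_asat,
       omega = c(ka = pop$omega_ka, V = pop$omega_V, Cl = pop$omega_Cl),
       gamma = c(V = pop$gamma_V, Cl = pop$gamma_Cl),
       a = pop$err_add, b = pop$err_prop,
       err_model = pop$err_model, asat_ref = pop$asat_ref)
}

theta_to_pop <- function(theta) {
  beta <- if (is.null(theta$beta)) theta$beta_fixed else theta$beta
  if (is.null(beta)) beta <- 0
  pop_params(ka_pop = exp(theta$mu[["ka"]]), V_pop = exp(theta$mu[["V"]]),
             Cl_pop = exp(theta$mu[["Cl"]]),
             beta_V_asat = beta, asat_ref = theta$asat_ref,
             omega_ka = theta$omega[["ka"]], omega_V = theta$omega[["V"]],
             omega_Cl = theta$omega[["Cl"]],
             gamma_V = theta$gamma[["V"]], gamma_Cl = theta$gamma[["Cl"]],
             err_add = theta$a, err_prop = theta$b,
             err_model = theta$err_model)
}

# prior mean of phi for one subject under theta
phi_prior_mean <- function(s, theta) {
  beta <- if (is.null(theta$beta)) theta$beta_fixed else theta$beta
  if (is.null(beta)) beta <- 0
  c(theta$mu[["ka"]], theta$mu[["V"]] + beta * s$c_asat, theta$mu[["Cl"]])
}
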