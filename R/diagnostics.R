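# Model-evaluation tools: VPC, NPDE, IWRES, bootstrap, leave-one-out.

# flatten prepared subjects into one observation-level frame and simulate
# n_rep replicate datasets on the same design; returns the obs frame and a
# n_obs x n_rep matrix of simulated observations (with residual noise)
simulate_replicates <- function(subjects, pop, n_rep, seed) {
  obs <- dplyr::bind_rows(lapply(seq_along(subjects), function(k) {
    s <- subjects[[k]]
    if (s$n_obs == 0) return(NULL)
    tibble::tibble(subj = k, ID = s$id, occ_local = s$occ_idx,
                   tad = s$tad, dose = s$dose, ss = s$ss, dv = s$dv,
                   time = s$obs_time, c_asat = s$c_asat, tau = s$tau)
  }))
  occ_key <- paste(obs$subj, obs$occ_local)
  occ_levels <- unique(occ_key)
  occ_idx <- match(occ_key, occ_levels)
  n_subj <- length(subjects)
  n_occ <- length(occ_levels)
  occ_subj <- obs$subj[match(occ_levels, occ_key)]
  sim <- matrix(0, nrow(obs), n_rep)
  with_seed_(seed, {
    for (r in seq_len(n_rep)) {
      eta_ka <- stats::rnorm(n_subj, 0, pop$omega_ka)
      eta_V <- stats::rnorm(n_subj, 0, pop$omega_V)
      eta_Cl <- stats::rnorm(n_subj, 0, pop$omega_Cl)
      kap_V <- stats::rnorm(n_occ, 0, pop$gamma_V)
      kap_Cl <- stats::rnorm(n_occ, 0, pop$gamma_Cl)
      ka <- pop$ka_pop * exp(eta_ka[obs$subj])
      V <- pop$V_pop * exp(pop$beta_V_asat * obs$c_asat +
                             eta_V[obs$subj] + kap_V[occ_idx])
      Cl <- pop$Cl_pop * exp(eta_Cl[obs$subj] + kap_Cl[occ_idx])
      f <- predict_conc(obs$tad, obs$dose, obs$ss, ka, V, Cl,
                        tau = obs$tau[1])
      sim[, r] <- f + residual_sd(f, pop) * stats::rnorm(nrow(obs))
    }
  })
  list(obs = obs, sim = sim)
}

#' Visual predictive check
#'
#' Simulates `n_replicates` datasets from the model on the observed design,
#' bins observation times by one-dimensional least-squares (k-means)
#' clustering, and compares the observed 10th/50th/90th percentiles per bin
#' with the 90% prediction band of the same percentiles across replicates.
#' No stratification is applied.
#'
#' @param data Cohort tibble (BLQ observations excluded).
#' @param pop [pop_params()] to simulate from.
#' @param n_replicates Simulation replicates (default 1000, >= 100).
#' @param bins Number of time bins (default 8); automatically reduced, with
#'   a warning, if a bin would be empty.
#' @param seed Simulation seed.
#' @return A tibble of class `pazo_vpc`: one row per bin and percentile
#'   with the observed value (`observed`) and the simulated band
#'   (`band_lo`, `band_med`, `band_hi`).
#' @export
vpc <- function(data, pop, n_replicates = 1000, bins = 8, seed = 1) {
  if (n_replicates < 100) stop("`n_replicates` must be at least 100")
  tau <- attr(data, "design")$tau %||% 24
  subjects <- prep_cohort(data, asat_ref = pop$asat_ref, tau = tau)
  rep_res <- simulate_replicates(subjects, pop, n_replicates,
                                 substream_seed(seed, "vpc"))
  obs <- rep_res$obs
  bin_id <- lsq_bins(obs$tad, bins)
  probs <- c(0.1, 0.5, 0.9)
  rows <- lapply(sort(unique(bin_id)), function(b) {
    in_bin <- bin_id == b
    obs_q <- stats::quantile(obs$dv[in_bin], probs, names = FALSE)
    sim_q <- apply(rep_res$sim[in_bin, , drop = FALSE], 2, stats::quantile,
                   probs = probs, names = FALSE)
    band <- apply(sim_q, 1, stats::quantile,
                  probs = c(0.05, 0.5, 0.95), names = FALSE)
    tibble::tibble(bin = b,
                   t_lo = min(obs$tad[in_bin]), t_hi = max(obs$tad[in_bin]),
                   t_mid = stats::median(obs$tad[in_bin]),
                   n_obs = sum(in_bin),
                   percentile = 100 * probs,
                   observed = obs_q,
                   band_lo = band[1, ], band_med = band[2, ],
                   band_hi = band[3, ])
  })
  out <- dplyr::bind_rows(rows)
  out <- tibble::new_tibble(out, nrow = nrow(out), class = "pazo_vpc")
  attr(out, "n_replicates") <- n_replicates
  out
}

# 1-D least-squares (k-means) binning of observation times
lsq_bins <- function(x, k) {
  k <- min(k, length(unique(x)))
  repeat {
    centers <- stats::quantile(unique(x), probs = seq(0, 1, length.out = k),
                               names = FALSE)
    km <- suppressWarnings(
      stats::kmeans(x, centers = unique(centers), iter.max = 50))
    sizes <- tabulate(km$cluster, nbins = length(km$size))
    if (all(sizes > 0) || k <= 1) break
    k <- k - 1
    warning("empty time bin; reducing bin count to ", k)
  }
  # relabel clusters in time order
  ord <- order(km$centers[, 1])
  match(km$cluster, ord)
}

#' Normalised prediction distribution errors
#'
#' Simulates the model on the observed design, decorrelates each subject's
#' observations with the Cholesky factor of the simulated covariance, ranks
#' the decorrelated observations within the decorrelated simulations and
#' maps the ranks to standard-normal quantiles. Under the true model the
#' result is standard normal.
#'
#' @inheritParams vpc
#' @param n_replicates Simulation replicates (default 1000, >= 500).
#' @return A tibble with one row per observation: `ID`, `time`, `tad`,
#'   `dv`, `npde`.
#' @export
npde <- function(data, pop, n_replicates = 1000, seed = 1) {
  if (n_replicates < 500) stop("`n_replicates` must be at least 500")
  tau <- attr(data, "design")$tau %||% 24
  subjects <- prep_cohort(data, asat_ref = pop$asat_ref, tau = tau)
  rep_res <- simulate_replicates(subjects, pop, n_replicates,
                                 substream_seed(seed, "npde"))
  obs <- rep_res$obs
  out_npde <- numeric(nrow(obs))
  for (k in unique(obs$subj)) {
    rows <- which(obs$subj == k)
    Y <- rep_res$sim[rows, , drop = FALSE]
    m <- rowMeans(Y)
    S <- stats::cov(t(Y))
    L <- tryCatch(chol(S), error = function(e) {
      warning("singular simulated covariance; ridge-stabilised")
      chol(S + diag(1e-6 * mean(diag(S)), nrow(S)))
    })
    ystar <- backsolve(L, obs$dv[rows] - m, transpose = TRUE)
    sstar <- backsolve(L, Y - m, transpose = TRUE)
    pde <- (rowSums(sstar < ystar) + 0.5) / (n_replicates + 1)
    out_npde[rows] <- stats::qnorm(pde)
  }
  tibble::tibble(ID = obs$ID, time = obs$time, tad = obs$tad,
                 dv = obs$dv, npde = out_npde)
}

#' Individual weighted residuals
#'
#' (observed - individual prediction) / residual SD at the individual
#' prediction, using the empirical-Bayes modes of a fitted model.
#'
#' @param fit A `pazo_fit`.
#' @return A tibble with one row per observation: `ID`, `time`, `tad`,
#'   `dv`, `ipred`, `iwres`.
#' @export
iwres <- function(fit) {
  stopifnot(inherits(fit, "pazo_fit"))
  pop <- fit$estimates
  rows <- lapply(seq_along(fit$.subjects), function(k) {
    s <- fit$.subjects[[k]]
    e <- fit$ebe[fit$ebe$ID == s$id, ]
    kaps <- e$kappas[[1]]
    phi <- c(log(pop$ka_pop) + e$eta_ka,
             log(pop$V_pop) + pop$beta_V_asat * s$c_asat + e$eta_V,
             log(pop$Cl_pop) + e$eta_Cl)
    f <- subj_pred(s, phi, kaps$kappa_V, kaps$kappa_Cl)
    tibble::tibble(ID = s$id, time = s$obs_time, tad = s$tad, dv = s$dv,
                   ipred = f,
                   iwres = (s$dv - f) / pmax(residual_sd(f, pop), 1e-10))
  })
  dplyr::bind_rows(rows)
}

#' Nonparametric bootstrap of the population fit
#'
#' Resamples subjects with replacement, refits each replicate with a
#' shortened SAEM schedule, and summarises the per-parameter distribution
#' by quartiles. When the original fit is supplied, each point estimate is
#' checked against its bootstrap interquartile range.
#'
#' @param data Cohort tibble.
#' @param n_iterations Bootstrap replicates (default 100, >= 20).
#' @param init,covariates Passed to [fit_saem()].
#' @param control SAEM settings for the replicate fits; default a
#'   100 + 50 iteration schedule without OFV/RSE computation.
#' @param fit Optional original `pazo_fit` for the quartile check.
#' @param seed Resampling seed.
#' @return A list of class `pazo_boot`: `samples` (replicate x parameter
#'   tibble), `quartiles`, `n_effective`, `failures`.
#' @export
bootstrap_fit <- function(data, n_iterations = 100,
                          init = reference_pop_params(),
                          covariates = final_covariate_model(),
                          control = saem_control(n_explore = 100,
                                                 n_smooth = 50,
                                                 compute_rse = FALSE,
                                                 compute_ofv = FALSE),
                          fit = NULL, seed = 1) {
  if (n_iterations < 20) stop("`n_iterations` must be at least 20")
  ids <- unique(data$ID)
  samples <- vector("list", n_iterations)
  failures <- 0L
  boot_ids <- with_seed_(substream_seed(seed, "bootstrap"), {
    lapply(seq_len(n_iterations), function(i) sample(ids, replace = TRUE))
  })
  for (i in seq_len(n_iterations)) {
    res <- dplyr::bind_rows(lapply(seq_along(boot_ids[[i]]), function(j) {
      d <- data[data$ID == boot_ids[[i]][j], , drop = FALSE]
      d$ID <- j
      d
    }))
    res <- tibble::new_tibble(res, nrow = nrow(res), class = "pazo_cohort")
    attr(res, "design") <- attr(data, "design")
    ctl <- control; ctl$seed <- seed + i
    ft <- tryCatch(fit_saem(res, init = init, covariates = covariates,
                            control = ctl),
                   error = function(e) NULL)
    if (is.null(ft)) { failures <- failures + 1L; next }
    row <- stats::setNames(as.list(ft$coefficients$estimate),
                           ft$coefficients$parameter)
    samples[[i]] <- tibble::as_tibble(c(list(iteration = i), row))
  }
  samples <- dplyr::bind_rows(samples)
  qs <- samples |>
    tidyr::pivot_longer(-"iteration", names_to = "parameter") |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(q1 = stats::quantile(.data$value, 0.25),
                     median = stats::median(.data$value),
                     q3 = stats::quantile(.data$value, 0.75),
                     .groups = "drop")
  if (!is.null(fit)) {
    qs <- dplyr::left_join(
      qs, dplyr::select(fit$coefficients, "parameter",
                        estimate = "estimate"),
      by = "parameter")
    qs$within_iqr <- qs$estimate >= qs$q1 & qs$estimate <= qs$q3
  }
  structure(list(samples = samples, quartiles = qs,
                 n_effective = n_iterations - failures,
                 failures = failures),
            class = "pazo_boot")
}

#' Leave-one-out cross-validation of the single-sample AUC procedure
#'
#' For each steady-state rich-profile subject: refit the population model
#' without them, MAP-estimate their clearance from each of their profile
#' samples individually, convert each clearance to an AUC
#' (daily dose / Cl), and compare against the subject's non-compartmental
#' reference AUC. The summary reports the mean absolute relative AUC
#' deviation and how often the below-target AUC classification
#' (AUC < `target`) agrees with the below-criterion observed-trough
#' classification (24 h sample < `trough_criterion`).
#'
#' @param data Cohort of steady-state rich profiles (>= 3 subjects), e.g.
#'   from [simulate_cohort()] with [rich_ss_design()].
#' @param init,covariates Passed to the fold refits.
#' @param control SAEM settings for fold refits (default 100 + 50
#'   iterations without OFV/RSE).
#' @param target Target AUC (mg*h/L).
#' @param trough_criterion Trough efficacy criterion (mg/L).
#' @param seed Seed for fold refits and MAP starts.
#' @return A list of class `pazo_loo`: `records` (one row per left-out
#'   subject and sample: estimated AUC/Cl, reference NCA AUC/Cl, relative
#'   deviation, agreement flag), `summary` (mean absolute relative
#'   deviation %, agreement %), `folds_failed`.
#' @export
loo_crossvalidate <- function(data,
                              init = reference_pop_params(),
                              covariates = final_covariate_model(),
                              control = saem_control(n_explore = 100,
                                                     n_smooth = 50,
                                                     compute_rse = FALSE,
                                                     compute_ofv = FALSE),
                              target = 750, trough_criterion = 20.5,
                              seed = 1) {
  ids <- unique(data$ID)
  if (length(ids) < 3) stop("at least 3 steady-state rich-profile subjects required")
  records <- list()
  folds_failed <- 0L
  for (i in seq_along(ids)) {
    id <- ids[i]
    train <- data[data$ID != id, , drop = FALSE]
    train <- tibble::new_tibble(train, nrow = nrow(train),
                                class = "pazo_cohort")
    attr(train, "design") <- attr(data, "design")
    ctl <- control; ctl$seed <- seed + i
    ft <- tryCatch(fit_saem(train, init = init, covariates = covariates,
                            control = ctl),
                   error = function(e) NULL)
    if (is.null(ft)) {
      message("fold for subject ", id, " failed; skipped")
      folds_failed <- folds_failed + 1L
      next
    }
    ref <- nca_reference(data, id)
    subj <- data[data$ID == id, , drop = FALSE]
    obs <- subj[subj$EVID == 0 & subj$BLQ == 0, , drop = FALSE]
    dose_t <- subj$TIME[subj$EVID == 1][1]
    tads <- obs$TIME - dose_t
    trough_obs <- obs$DV[which.min(abs(tads - 24))]
    for (j in seq_len(nrow(obs))) {
      est <- map_estimate(data, ft$estimates, ids = id, obs_subset = j,
                          seed = seed + 1000L * i + j)
      records[[length(records) + 1L]] <- tibble::tibble(
        ID = id, sample = j, tad = tads[j], dv = obs$DV[j],
        auc_est = est$auc, cl_est = est$Cl,
        auc_nca = ref$auc, cl_nca = ref$cl_nca,
        rel_dev = (est$auc - ref$auc) / ref$auc,
        trough_obs = trough_obs,
        below_target = est$auc < target,
        below_criterion = trough_obs < trough_criterion,
        agree = (est$auc < target) == (trough_obs < trough_criterion)
      )
    }
  }
  records <- dplyr::bind_rows(records)
  summary <- list(
    mean_abs_rel_dev = 100 * mean(abs(records$rel_dev)),
    agreement = 100 * mean(records$agree),
    n_decisions = nrow(records),
    n_subjects = length(ids) - folds_failed
  )
  structure(list(records = records, summary = summary,
                 folds_failed = folds_failed,
                 target = target, trough_criterion = trough_criterion),
            class = "pazo_loo")
}

#' @export
print.pazo_loo <- function(x, ...) {
  cat(sprintf(
    "Leave-one-out single-sample AUC validation (%d subjects, %d decisions)\n",
    x$summary$n_subjects, x$summary$n_decisions))
  cat(sprintf("  mean |relative AUC deviation| : %.1f%%\n",
              x$summary$mean_abs_rel_dev))
  cat(sprintf("  exposure-classification agreement (AUC < %g vs trough < %g): %.1f%%\n",
              x$target, x$trough_criterion, x$summary$agreement))
  invisible(x)
}
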