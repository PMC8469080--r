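#' Synthetic cohort design
#'
#' Describes the two-arm study design that the simulator emulates: a sparse
#' therapeutic-drug-monitoring (TDM) arm of 58 patients contributing 126
#' trough samples drawn around 24.6 h post-dose (1 to 6 visits each, mean
#' 2.17), and a rich-profile trial arm of 15 patients contributing 280
#' samples over 36 occasion-profiles sampled at 0, 0.5, 1, 2, 4, 6, 8 and
#' 24 h post-dose on day 1 of treatment cycles 1, 2 and 4. With the default
#' allocation the database totals 406 observations.
#'
#' The printed per-profile sample counts of the source study cannot be
#' reconciled exactly with its totals, so the default allocation preserves
#' the totals: 28 full 8-point profiles plus 8 seven-point profiles (the
#' 0.5 h sample dropped) = 280 samples over 36 profiles. All 15 rich
#' subjects have cycle-1 and cycle-2 profiles; 6 also have a cycle-4
#' profile. TDM visit counts are a fixed multiset
#' (19x1, 22x2, 9x3, 5x4, 2x5, 1x6 = 126 samples over 58 patients, mean
#' 2.17) permuted across subjects by the seed.
#'
#' @param n_tdm_subjects Number of sparse TDM patients (default 58).
#' @param tdm_visit_counts Integer vector of per-patient visit counts for
#'   the TDM arm; its length must equal `n_tdm_subjects`.
#' @param tdm_time_mean,tdm_time_sd Mean and SD (h) of the post-dose
#'   sampling-time distribution of TDM troughs, truncated to
#'   `tdm_time_range`.
#' @param tdm_time_range Truncation bounds (h) for TDM sampling times.
#' @param rich_allocation Tibble with columns `subject`, `cycle`,
#'   `n_points`, `ss` describing each rich profile; see
#'   [default_rich_allocation()].
#' @param rich_schedule Nominal rich sampling times (h post-dose).
#' @param dose_menu Allowed daily doses (mg).
#' @param dose_probs Sampling probabilities over `dose_menu`.
#' @param asat_median,asat_sdlog Median (UI/L) and log-scale SD of the
#'   lognormal ASAT distribution.
#' @param covariate_miss_rate Missing-at-random rate injected into the
#'   recorded (not the generating) covariate values, exercising the
#'   imputation rule.
#' @param lloq Lower limit of quantification (mg/L).
#' @param tau Dosing interval (h).
#' @param seed Integer seed making the generated cohort reproducible.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(n_tdm_subjects = 58,
                          tdm_visit_counts = default_tdm_visit_counts(n_tdm_subjects),
                          tdm_time_mean = 24.6,
                          tdm_time_sd = 2.0,
                          tdm_time_range = c(20, 30),
                          rich_allocation = default_rich_allocation(),
                          rich_schedule = c(0, 0.5, 1, 2, 4, 6, 8, 24),
                          dose_menu = c(200, 400, 600, 800),
                          dose_probs = c(0.10, 0.20, 0.20, 0.50),
                          asat_median = 36.5,
                          asat_sdlog = 0.40,
                          covariate_miss_rate = 0.10,
                          lloq = 1,
                          tau = 24,
                          seed = 1L) {
  if (length(tdm_visit_counts) != n_tdm_subjects) {
    stop("`tdm_visit_counts` must have length `n_tdm_subjects`")
  }
  if (n_tdm_subjects > 0 &&
      (any(tdm_visit_counts < 1) || any(tdm_visit_counts != round(tdm_visit_counts)))) {
    stop("`tdm_visit_counts` must be positive integers")
  }
  if (!is.null(rich_allocation) && nrow(rich_allocation) > 0) {
    stopifnot(all(c("subject", "cycle", "n_points", "ss") %in%
                    names(rich_allocation)))
    if (any(rich_allocation$n_points > length(rich_schedule))) {
      stop("profile `n_points` exceeds the length of `rich_schedule`")
    }
  }
  if (length(dose_probs) != length(dose_menu)) {
    stop("`dose_probs` must match `dose_menu`")
  }
  structure(
    list(n_tdm_subjects = n_tdm_subjects,
         tdm_visit_counts = tdm_visit_counts,
         tdm_time_mean = tdm_time_mean, tdm_time_sd = tdm_time_sd,
         tdm_time_range = tdm_time_range,
         rich_allocation = rich_allocation,
         rich_schedule = rich_schedule,
         dose_menu = dose_menu, dose_probs = dose_probs,
         asat_median = asat_median, asat_sdlog = asat_sdlog,
         covariate_miss_rate = covariate_miss_rate,
         lloq = lloq, tau = tau, seed = as.integer(seed)),
    class = "cohort_design"
  )
}

#' Default TDM visit-count multiset
#'
#' For the default 58-patient arm, a fixed multiset of visit counts summing
#' to 126 samples (mean 2.17 per patient). For other sizes, counts are
#' filled to approximate the same mean.
#'
#' @param n Number of TDM patients.
#' @return Integer vector of length `n`.
#' @export
default_tdm_visit_counts <- function(n = 58) {
  if (n == 0) return(integer(0))
  if (n == 58) {
    return(rep(c(1L, 2L, 3L, 4L, 5L, 6L), times = c(19L, 22L, 9L, 5L, 2L, 1L)))
  }
  counts <- rep(2L, n)
  extra <- round(0.17 * n)
  if (extra > 0) counts[seq_len(min(extra, n))] <- 3L
  counts
}

#' Default rich-profile allocation
#'
#' 15 subjects; all have day-1 profiles in cycles 1 and 2, the first 6 also
#' in cycle 4 (36 profiles). Cycle-1 profiles are single-dose (treatment
#' start), later cycles are at steady state. The cycle-2 profiles of
#' subjects 8-15 carry 7 points (0.5 h dropped), all others the full 8, so
#' the arm totals 280 samples.
#'
#' @param n_subjects Number of rich-arm subjects.
#' @return A tibble with columns `subject`, `cycle`, `n_points`, `ss`.
#' @export
default_rich_allocation <- function(n_subjects = 15) {
  if (n_subjects == 0) {
    return(tibble::tibble(subject = integer(0), cycle = integer(0),
                          n_points = integer(0), ss = logical(0)))
  }
  alloc <- dplyr::bind_rows(
    tibble::tibble(subject = seq_len(n_subjects), cycle = 1L),
    tibble::tibble(subject = seq_len(n_subjects), cycle = 2L),
    tibble::tibble(subject = seq_len(min(6L, n_subjects)), cycle = 4L)
  )
  alloc$ss <- alloc$cycle > 1L
  alloc$n_points <- 8L
  if (n_subjects == 15) {
    alloc$n_points[alloc$cycle == 2L & alloc$subject >= 8L] <- 7L
  }
  dplyr::arrange(alloc, .data$subject, .data$cycle)
}

#' Design for a steady-state rich-profile validation cohort
#'
#' A cohort of `n_subjects` patients each contributing one full 8-point
#' steady-state profile — the design used for leave-one-out validation of
#' the single-sample AUC procedure.
#'
#' @param n_subjects Number of subjects (default 10).
#' @param ... Passed to [cohort_design()].
#' @return A `cohort_design`.
#' @export
rich_ss_design <- function(n_subjects = 10, ...) {
  alloc <- tibble::tibble(subject = seq_len(n_subjects), cycle = 2L,
                          n_points = 8L, ss = TRUE)
  cohort_design(n_tdm_subjects = 0, tdm_visit_counts = integer(0),
                rich_allocation = alloc, ...)
}

# deterministic local RNG scope
with_seed_ <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

# named substream seeds derived from one master seed (kept below 2^31)
substream_seed <- function(seed, stream) {
  offset <- c(simulate = 11L, fit = 23L, vpc = 37L, npde = 41L,
              bootstrap = 53L, loo = 67L, map = 71L)[[stream]]
  as.integer((as.double(seed) * 1103L + offset * 12289L) %% 2147483629)
}

rtrunc_norm <- function(n, mean, sd, lower, upper) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad) > 0) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < lower | out > upper)
  }
  out
}

#' Simulate a synthetic pazopanib cohort
#'
#' Draws per-subject covariates and lognormal random effects, per-occasion
#' inter-occasion deviations, simulates concentrations from the
#' one-compartment model with combined residual error, and assembles a
#' NONMEM-style long table (one dose row per occasion followed by its
#' observation rows). Values below the limit of quantification are flagged
#' `BLQ = 1`. The generating per-subject and per-occasion parameters are
#' retained as attributes for recovery testing, retrievable with
#' [cohort_truth()].
#'
#' Occasions are spaced far apart (TDM visits a week apart, trial cycles
#' four weeks apart); steady-state occasions are simulated from the
#' steady-state curve, the treatment-start (cycle 1) profile from the
#' single-dose curve. Covariates are drawn once per subject; the recorded
#' values are masked missing-at-random at the design's
#' `covariate_miss_rate` (the generating values are never masked).
#'
#' @param design A [cohort_design()].
#' @param pop A [pop_params()] object; defaults to the published reference
#'   estimates.
#' @param seed Overrides the design's seed if given.
#' @return A tibble of class `pazo_cohort` with columns ID, TIME, AMT, DV,
#'   EVID, MDV, OCC, SS, BLQ, ARM, ASAT, ALAT, ALB, CREAT, AGE, SEX, FOOD,
#'   DOSE_DAILY.
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_design(seed = 1))
#' sum(coh$EVID == 0)  # 406 observations
simulate_cohort <- function(design = cohort_design(),
                            pop = reference_pop_params(),
                            seed = NULL) {
  seed <- if (is.null(seed)) design$seed else as.integer(seed)
  with_seed_(substream_seed(seed, "simulate"), {
    subjects <- build_subjects(design)
    simulate_observations(subjects, design, pop)
  })
}

# draw subject-level frames: id, arm, dose, covariates, occasions
build_subjects <- function(design) {
  n_tdm <- design$n_tdm_subjects
  rich_ids <- unique(design$rich_allocation$subject)
  n_rich <- length(rich_ids)
  n <- n_tdm + n_rich
  ids <- seq_len(n)

  dose <- sample(design$dose_menu, n, replace = TRUE, prob = design$dose_probs)
  covs <- tibble::tibble(
    ID = ids,
    ASAT = exp(stats::rnorm(n, log(design$asat_median), design$asat_sdlog)),
    ALAT = exp(stats::rnorm(n, log(30), 0.45)),
    ALB = rtrunc_norm(n, 40, 5, 20, 55),
    CREAT = exp(stats::rnorm(n, log(75), 0.30)),
    AGE = round(rtrunc_norm(n, 55, 13, 12, 85)),
    SEX = sample(0:1, n, replace = TRUE),
    FOOD = sample(c("fasted", "fed", "unknown"), n, replace = TRUE,
                  prob = c(52, 15, 6) / 73),
    DOSE_DAILY = dose
  )

  occ <- list()
  if (n_tdm > 0) {
    counts <- sample(design$tdm_visit_counts)  # permute across subjects
    for (i in seq_len(n_tdm)) {
      k <- counts[i]
      occ[[length(occ) + 1L]] <- tibble::tibble(
        ID = i, ARM = "tdm", OCC = seq_len(k),
        occ_start = (seq_len(k) - 1) * 168, ss = TRUE, n_points = 1L)
    }
  }
  if (n_rich > 0) {
    for (j in seq_along(rich_ids)) {
      al <- design$rich_allocation[design$rich_allocation$subject == rich_ids[j], ]
      occ[[length(occ) + 1L]] <- tibble::tibble(
        ID = n_tdm + j, ARM = "rich", OCC = al$cycle,
        occ_start = (al$cycle - 1) * 672, ss = al$ss,
        n_points = al$n_points)
    }
  }
  list(covs = covs, occasions = dplyr::bind_rows(occ), n_tdm = n_tdm)
}

simulate_observations <- function(subjects, design, pop) {
  covs <- subjects$covs
  occs <- subjects$occasions
  n <- nrow(covs)

  eta <- tibble::tibble(
    ID = covs$ID,
    eta_ka = stats::rnorm(n, 0, pop$omega_ka),
    eta_V = stats::rnorm(n, 0, pop$omega_V),
    eta_Cl = stats::rnorm(n, 0, pop$omega_Cl)
  )

  m <- nrow(occs)
  kap <- tibble::tibble(
    ID = occs$ID, OCC = occs$OCC,
    kappa_V = stats::rnorm(m, 0, pop$gamma_V),
    kappa_Cl = stats::rnorm(m, 0, pop$gamma_Cl)
  )

  rows <- vector("list", m)
  truth_occ <- vector("list", m)
  for (r in seq_len(m)) {
    id <- occs$ID[r]
    cv <- covs[covs$ID == id, ]
    et <- eta[eta$ID == id, ]
    kp <- kap[r, ]
    ip <- apply_covariates(pop, asat = cv$ASAT,
                           eta_ka = et$eta_ka, eta_V = et$eta_V,
                           eta_Cl = et$eta_Cl,
                           kappa_V = kp$kappa_V, kappa_Cl = kp$kappa_Cl)
    if (occs$ARM[r] == "tdm") {
      tad <- rtrunc_norm(1, design$tdm_time_mean, design$tdm_time_sd,
                         design$tdm_time_range[1], design$tdm_time_range[2])
    } else {
      tad <- design$rich_schedule
      if (occs$n_points[r] < length(tad)) {
        # drop the 0.5 h point first for short profiles
        drop <- order(tad == 0.5, decreasing = TRUE)[
          seq_len(length(tad) - occs$n_points[r])]
        tad <- sort(tad[-drop])
      }
    }
    ss <- occs$ss[r]
    f <- predict_conc(tad, dose = cv$DOSE_DAILY, ss = rep(ss, length(tad)),
                      ka = ip$ka, V = ip$V, Cl = ip$Cl, tau = design$tau)
    dv <- f + residual_sd(f, pop) * stats::rnorm(length(f))
    dv <- pmax(dv, 0)  # assay never reports negative concentrations
    blq <- as.integer(dv < design$lloq)
    base <- occs$occ_start[r]
    dose_row <- tibble::tibble(
      ID = id, TIME = base, AMT = cv$DOSE_DAILY, DV = NA_real_,
      EVID = 1L, MDV = 1L, OCC = occs$OCC[r], SS = as.integer(ss),
      BLQ = 0L, ARM = occs$ARM[r])
    obs_rows <- tibble::tibble(
      ID = id, TIME = base + tad, AMT = NA_real_, DV = dv,
      EVID = 0L, MDV = 0L, OCC = occs$OCC[r], SS = as.integer(ss),
      BLQ = blq, ARM = occs$ARM[r])
    rows[[r]] <- dplyr::bind_rows(dose_row, obs_rows)
    truth_occ[[r]] <- tibble::tibble(
      ID = id, OCC = occs$OCC[r], ka = ip$ka, V = ip$V, Cl = ip$Cl,
      kappa_V = kp$kappa_V, kappa_Cl = kp$kappa_Cl,
      auc = cv$DOSE_DAILY / ip$Cl,
      trough = predict_conc(design$tau, dose = cv$DOSE_DAILY, ss = ss,
                            ka = ip$ka, V = ip$V, Cl = ip$Cl,
                            tau = design$tau))
  }
  tab <- dplyr::bind_rows(rows)
  tab <- dplyr::left_join(tab, covs, by = "ID")
  tab <- dplyr::arrange(tab, .data$ID, .data$TIME, dplyr::desc(.data$EVID))

  # mask recorded covariates missing-at-random (generating values retained
  # in the truth attribute via eta/individual parameters)
  if (design$covariate_miss_rate > 0) {
    for (cc in c("ASAT", "ALAT", "ALB", "CREAT")) {
      per_occ <- dplyr::distinct(tab, .data$ID, .data$OCC)
      mask <- stats::runif(nrow(per_occ)) < design$covariate_miss_rate
      miss <- per_occ[mask, ]
      if (nrow(miss) > 0) {
        key <- paste(tab$ID, tab$OCC)
        tab[[cc]][key %in% paste(miss$ID, miss$OCC)] <- NA_real_
      }
    }
  }

  truth_subject <- dplyr::left_join(eta, covs, by = "ID")
  out <- tibble::new_tibble(tab, nrow = nrow(tab),
                            class = "pazo_cohort")
  attr(out, "truth_subject") <- truth_subject
  attr(out, "truth_occasion") <- dplyr::bind_rows(truth_occ)
  attr(out, "design") <- design
  attr(out, "pop") <- pop
  out
}

#' Generating ground truth of a simulated cohort
#'
#' @param cohort A `pazo_cohort` from [simulate_cohort()].
#' @param level `"subject"` for per-subject random effects and covariates,
#'   `"occasion"` for per-occasion individual parameters, true AUC and true
#'   model trough.
#' @return A tibble.
#' @export
cohort_truth <- function(cohort, level = c("subject", "occasion")) {
  level <- match.arg(level)
  at <- attr(cohort, paste0("truth_", level))
  if (is.null(at)) stop("cohort carries no ground truth (was it read from disk?)")
  at
}

#' Impute missing covariate values
#'
#' Each missing covariate value is replaced by the patient's median of the
#' non-missing values of that covariate; patients with no value at all
#' receive the cohort-wide median. Non-missing values are never touched.
#'
#' @param data A cohort tibble with covariate columns.
#' @param covariates Character vector of covariate columns to impute.
#' @return The tibble with no missing values in `covariates`.
#' @export
impute_covariates <- function(data,
                              covariates = c("ASAT", "ALAT", "ALB", "CREAT")) {
  covariates <- intersect(covariates, names(data))
  for (cc in covariates) {
    v <- data[[cc]]
    if (!anyNA(v)) next
    if (all(is.na(v))) {
      stop(sprintf("covariate `%s` is entirely missing across the cohort", cc))
    }
    pop_med <- stats::median(v, na.rm = TRUE)
    med_by_id <- tapply(v, data$ID, function(x) {
      if (all(is.na(x))) NA_real_ else stats::median(x, na.rm = TRUE)
    })
    fill <- med_by_id[as.character(data$ID)]
    fill[is.na(fill)] <- pop_med
    v[is.na(v)] <- fill[is.na(v)]
    data[[cc]] <- unname(v)
  }
  data
}

#' Flag observations below the limit of quantification
#'
#' Observation rows with DV strictly below `lloq` get `BLQ = 1`; values at
#' or above the limit (including exactly at it) are kept. Flagged rows are
#' excluded from likelihood computations but retained in the table.
#'
#' @param data A cohort tibble.
#' @param lloq Lower limit of quantification (mg/L, > 0; 0 clears flags).
#' @return The tibble with its `BLQ` column updated.
#' @export
censor_blq <- function(data, lloq = 1) {
  if (lloq < 0) stop("`lloq` must be non-negative")
  obs <- data$EVID == 0
  data$BLQ <- ifelse(obs & !is.na(data$DV) & data$DV < lloq, 1L, 0L)
  data
}
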