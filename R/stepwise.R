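#' Forward stepwise covariate selection
#'
#' Starting from a base fit, refits the model with each candidate
#' covariate term added in turn and accepts the best candidate if and only
#' if it lowers the objective function by at least `dofv_min` (3.84, the
#' 95% chi-squared quantile on one degree of freedom) and the AIC by at
#' least `daic_min` (2); iterates until no candidate qualifies. Every
#' tested candidate is recorded with its OFV/AIC change; candidate fits
#' that fail are recorded and skipped, never silently dropped.
#'
#' @param data Cohort tibble.
#' @param base_fit A converged `pazo_fit` for the base model.
#' @param candidates List of [covariate_term()]s to consider.
#' @param dofv_min,daic_min Acceptance thresholds on the OFV and AIC
#'   decreases (both must be met).
#' @param init Initial parameters for candidate refits (default: the base
#'   fit's estimates).
#' @param control SAEM settings for candidate refits (default: the base
#'   fit's settings).
#' @return A list of class `pazo_stepwise`: `final_fit`, `selected`
#'   (accepted terms in order), `log` (tibble of every tested candidate
#'   with `step`, `term`, `ofv`, `aic`, `dofv`, `daic`, `accepted`,
#'   `failed`).
#' @export
stepwise_covariates <- function(data, base_fit, candidates,
                                dofv_min = 3.84, daic_min = 2,
                                init = NULL, control = NULL) {
  stopifnot(inherits(base_fit, "pazo_fit"))
  if (!isTRUE(base_fit$converged)) {
    warning("base fit did not meet the convergence check; proceeding anyway")
  }
  if (is.null(control)) control <- base_fit$control
  current <- base_fit
  selected <- list()
  remaining <- candidates
  log_rows <- list()
  step <- 0L
  while (length(remaining) > 0) {
    step <- step + 1L
    fits <- vector("list", length(remaining))
    for (j in seq_along(remaining)) {
      terms_j <- c(current$covariates, list(remaining[[j]]))
      ini <- if (is.null(init)) current$estimates else init
      ctl <- control; ctl$seed <- control$seed + 100L * step + j
      ft <- tryCatch(
        fit_saem(data, init = ini, covariates = terms_j, control = ctl),
        error = function(e) e)
      failed <- inherits(ft, "error")
      log_rows[[length(log_rows) + 1L]] <- tibble::tibble(
        step = step, term = format(remaining[[j]]),
        ofv = if (failed) NA_real_ else ft$ofv,
        aic = if (failed) NA_real_ else ft$aic,
        dofv = if (failed) NA_real_ else current$ofv - ft$ofv,
        daic = if (failed) NA_real_ else current$aic - ft$aic,
        accepted = FALSE,
        failed = failed,
        note = if (failed) conditionMessage(ft) else NA_character_)
      fits[[j]] <- if (failed) NULL else ft
    }
    dofv <- vapply(seq_along(fits), function(j) {
      if (is.null(fits[[j]])) -Inf else current$ofv - fits[[j]]$ofv
    }, 0)
    best <- which.max(dofv)
    ok <- is.finite(dofv[best]) && dofv[best] >= dofv_min &&
      (current$aic - fits[[best]]$aic) >= daic_min
    if (!ok) break
    # mark the accepted row (last block of tested candidates)
    idx <- length(log_rows) - length(remaining) + best
    log_rows[[idx]]$accepted <- TRUE
    selected[[length(selected) + 1L]] <- remaining[[best]]
    current <- fits[[best]]
    remaining <- remaining[-best]
  }
  structure(list(final_fit = current, selected = selected,
                 log = dplyr::bind_rows(log_rows)),
            class = "pazo_stepwise")
}

#' @export
print.pazo_stepwise <- function(x, ...) {
  cat("Forward stepwise covariate selection\n")
  cat(sprintf("  candidates tested: %d, accepted: %d\n",
              nrow(x$log), length(x$selected)))
  for (tm in x$selected) cat("  + ", format(tm), "\n")
  invisible(x)
}
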