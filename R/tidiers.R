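#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted population model
#'
#' @param x A `pazo_fit`.
#' @param ... Unused.
#' @return A tibble with one row per estimated parameter: `parameter`,
#'   `estimate`, `rse` (relative standard error, %).
#' @export
tidy.pazo_fit <- function(x, ...) {
  x$coefficients
}

#' One-row summary of a fitted population model
#'
#' @param x A `pazo_fit`.
#' @param ... Unused.
#' @return A tibble: `ofv`, `aic`, `n_params`, `n_subjects`, `n_obs`,
#'   `n_blq`, `converged`.
#' @export
glance.pazo_fit <- function(x, ...) {
  tibble::tibble(ofv = x$ofv, aic = x$aic, n_params = x$n_params,
                 n_subjects = x$n_subjects, n_obs = x$n_obs,
                 n_blq = x$n_blq, converged = x$converged)
}

#' @export
print.pazo_fit <- function(x, ...) {
  cat("Population PK fit (SAEM)\n")
  cat(sprintf("  %d subjects, %d observations (%d BLQ excluded)\n",
              x$n_subjects, x$n_obs, x$n_blq))
  cat(sprintf("  OFV %.2f (IS se %.3f), AIC %.2f, %d parameters, %s\n",
              x$ofv, x$ofv_se, x$aic, x$n_params,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  print(x$coefficients, n = Inf)
  invisible(x)
}

#' Tidy a threshold scan
#'
#' @param x A `pazo_scan`.
#' @param ... Unused.
#' @return The per-threshold tibble.
#' @export
tidy.pazo_scan <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a threshold scan
#'
#' @param x A `pazo_scan`.
#' @param ... Unused.
#' @return A tibble with the chosen threshold and its operating point.
#' @export
glance.pazo_scan <- function(x, ...) {
  ch <- attr(x, "chosen")
  row <- x[which(x$threshold == ch)[1], ]
  tibble::tibble(chosen = ch,
                 sensitivity = row$sensitivity,
                 specificity = row$specificity,
                 trough_criterion = attr(x, "trough_criterion"),
                 method = attr(x, "method"))
}

#' Tidy leave-one-out results
#'
#' @param x A `pazo_loo`.
#' @param ... Unused.
#' @return The per-sample record tibble.
#' @export
tidy.pazo_loo <- function(x, ...) {
  x$records
}

#' One-row summary of leave-one-out results
#'
#' @param x A `pazo_loo`.
#' @param ... Unused.
#' @return A tibble: mean absolute relative AUC deviation (%), exposure
#'   agreement (%), decision and subject counts.
#' @export
glance.pazo_loo <- function(x, ...) {
  tibble::tibble(mean_abs_rel_dev = x$summary$mean_abs_rel_dev,
                 agreement = x$summary$agreement,
                 n_decisions = x$summary$n_decisions,
                 n_subjects = x$summary$n_subjects)
}
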