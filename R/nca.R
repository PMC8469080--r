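#' Linear-up/log-down trapezoidal AUC
#'
#' Model-free area under the concentration-time curve. Each segment uses
#' the linear trapezoid (C1 + C2)/2 * dt while concentrations are rising
#' (or either endpoint is zero), and the log trapezoid
#' (C1 - C2) * dt / log(C1/C2) on strictly decreasing positive segments —
#' which integrates a mono-exponential decline exactly.
#'
#' @param times Sampling times (h), strictly increasing.
#' @param concs Concentrations (mg/L), non-negative.
#' @return AUC over the sampled interval (mg*h/L).
#' @export
#' @examples
#' auc_linuplogdown(c(0, 1, 2), c(0, 10, 5))
auc_linuplogdown <- function(times, concs) {
  if (length(times) < 2) stop("at least two points are required")
  if (length(times) != length(concs)) stop("`times` and `concs` lengths differ")
  if (is.unsorted(times, strictly = TRUE)) stop("`times` must be strictly increasing")
  if (any(concs < 0)) stop("`concs` must be non-negative")
  c1 <- concs[-length(concs)]
  c2 <- concs[-1]
  dt <- diff(times)
  logdown <- c2 < c1 & c2 > 0 & c1 > 0
  seg <- ifelse(logdown,
                (c1 - c2) * dt / log(c1 / pmax(c2, .Machine$double.xmin)),
                (c1 + c2) / 2 * dt)
  sum(seg)
}

#' Terminal slope by best-fit log-linear regression
#'
#' Fits a log-linear regression to every candidate terminal window of at
#' least three positive-concentration points starting after the observed
#' peak, and keeps the window with the highest adjusted R-squared (ties
#' resolved in favour of more points). Returns the magnitude of the slope,
#' the terminal elimination rate lambda_z.
#'
#' @inheritParams auc_linuplogdown
#' @return A list: `lambda_z` (1/h, or `NA` when fewer than 3 usable
#'   points), `adj_r2`, `points_used` (indices into `times`),
#'   `half_life` (h).
#' @export
lambda_z_bestfit <- function(times, concs) {
  if (is.unsorted(times, strictly = TRUE)) stop("`times` must be strictly increasing")
  i_max <- which.max(concs)
  cand <- which(seq_along(concs) > i_max & concs > 0)
  if (length(cand) < 3) {
    return(list(lambda_z = NA_real_, adj_r2 = NA_real_,
                points_used = integer(0), half_life = NA_real_,
                flag = "fewer than 3 usable post-peak points"))
  }
  best <- NULL
  for (start in seq_len(length(cand) - 2)) {
    idx <- cand[start:length(cand)]
    ft <- stats::lm(log(concs[idx]) ~ times[idx])
    # an exactly log-linear tail is a legitimate input; lm warns about it
    r2 <- suppressWarnings(summary(ft)$adj.r.squared)
    if (is.null(best) || r2 > best$adj_r2 + 1e-12 ||
        (abs(r2 - best$adj_r2) <= 1e-12 && length(idx) > length(best$points_used))) {
      best <- list(lambda_z = abs(unname(stats::coef(ft)[2])),
                   adj_r2 = r2, points_used = idx)
    }
  }
  best$half_life <- log(2) / best$lambda_z
  best$flag <- NA_character_
  best
}

#' Non-compartmental reference AUC and clearance for a rich profile
#'
#' Computes the reference ("real") exposure for one subject-occasion with a
#' rich profile: AUC over the dosing interval by linear-up/log-down
#' trapezoids, the terminal slope for reporting, and the non-compartmental
#' clearance dose/AUC. At steady state AUC over one interval needs no
#' extrapolation; for a single-dose profile the AUC is extrapolated to
#' infinity with the terminal slope before the clearance is formed.
#'
#' @param data Cohort tibble.
#' @param id Subject identifier.
#' @param occasion Occasion label (default: the subject's first occasion
#'   with at least `min_points` observations).
#' @param min_points Minimum profile size (default 5); sparser profiles
#'   are rejected — use [map_estimate()] for sparse data.
#' @return A one-row tibble: `ID`, `occasion`, `n_points`, `auc`
#'   (mg*h/L), `lambda_z`, `adj_r2`, `cl_nca` (L/h), `ss`, and an
#'   `inconsistent_predose` flag set when a steady-state predose sample
#'   exceeds the end-of-interval sample.
#' @export
nca_reference <- function(data, id, occasion = NULL, min_points = 5) {
  d <- data[data$ID == id, , drop = FALSE]
  if (nrow(d) == 0) stop(sprintf("subject %s not found", id))
  obs <- d[d$EVID == 0, , drop = FALSE]
  if (is.null(occasion)) {
    counts <- table(obs$OCC)
    ok <- names(counts)[counts >= min_points]
    if (length(ok) == 0) {
      stop("no occasion with a rich profile; use map_estimate() for sparse data")
    }
    occasion <- utils::type.convert(ok[1], as.is = TRUE)
  }
  obs <- obs[obs$OCC == occasion, , drop = FALSE]
  dose_row <- d[d$EVID == 1 & d$OCC == occasion, , drop = FALSE]
  if (nrow(dose_row) == 0) stop("no dose record for that occasion")
  if (nrow(obs) < min_points) {
    stop(sprintf("profile has %d points (< %d); use map_estimate() for sparse data",
                 nrow(obs), min_points))
  }
  tad <- obs$TIME - dose_row$TIME[1]
  ord <- order(tad)
  tad <- tad[ord]; conc <- obs$DV[ord]
  ss <- dose_row$SS[1] == 1
  tau <- attr(data, "design")$tau %||% 24

  lz <- lambda_z_bestfit(tad, conc)
  auc <- auc_linuplogdown(tad, conc)
  if (!ss) {
    # single dose: extrapolate to infinity for the clearance
    if (is.na(lz$lambda_z)) stop("cannot extrapolate single-dose AUC: no terminal slope")
    auc <- auc + conc[length(conc)] / lz$lambda_z
  }
  incons <- ss && conc[1] > conc[length(conc)] && tad[1] == 0
  tibble::tibble(
    ID = id, occasion = occasion, n_points = length(tad),
    auc = auc, lambda_z = lz$lambda_z, adj_r2 = lz$adj_r2,
    cl_nca = dose_row$AMT[1] / auc, ss = ss,
    inconsistent_predose = incons
  )
}
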