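#' Sensitivity/specificity scan for a target AUC threshold
#'
#' Determines the AUC threshold that best reproduces the
#' trough-concentration efficacy criterion. For each candidate threshold,
#' condition positive means the trough is at or above the criterion
#' (adequate exposure), test positive means the AUC is at or above the
#' threshold; sensitivity = TP/(TP+FN), specificity = TN/(TN+FP). The
#' chosen threshold maximises Youden's J = sensitivity + specificity - 1
#' (ties resolved toward the lower threshold); alternatively the lowest
#' threshold holding sensitivity at or above a floor can be requested.
#'
#' @param data Tibble (or data frame) with columns `ctrough` (mg/L) and
#'   `auc` (mg*h/L), one row per subject or sample.
#' @param trough_criterion Trough efficacy criterion (mg/L, default 20.5).
#' @param thresholds Candidate AUC thresholds (default 250 to 1500 by 50).
#' @param method `"youden"` or `"sensitivity"` (lowest threshold with
#'   sensitivity >= `min_sensitivity`).
#' @param min_sensitivity Sensitivity floor for `method = "sensitivity"`.
#' @return A tibble of class `pazo_scan` with one row per threshold
#'   (`threshold`, `tp`, `fp`, `tn`, `fn`, `sensitivity`, `specificity`,
#'   `youden`); the chosen threshold and settings are attached as
#'   attributes (`chosen`, `trough_criterion`).
#' @export
#' @examples
#' d <- tibble::tibble(ctrough = c(25, 25, 15, 15), auc = c(800, 900, 600, 760))
#' scan <- sensitivity_specificity_scan(d, thresholds = 750)
#' scan$sensitivity  # 100
sensitivity_specificity_scan <- function(data, trough_criterion = 20.5,
                                         thresholds = seq(250, 1500, by = 50),
                                         method = c("youden", "sensitivity"),
                                         min_sensitivity = 99) {
  method <- match.arg(method)
  ct <- data$ctrough; auc <- data$auc
  if (is.null(ct) || is.null(auc)) stop("`data` needs columns `ctrough` and `auc`")
  pos <- ct >= trough_criterion
  if (all(pos) || all(!pos)) {
    stop("all pairs fall on one side of the trough criterion; scan undefined")
  }
  rows <- lapply(thresholds, function(th) {
    test_pos <- auc >= th
    tp <- sum(pos & test_pos); fn <- sum(pos & !test_pos)
    tn <- sum(!pos & !test_pos); fp <- sum(!pos & test_pos)
    tibble::tibble(threshold = th, tp = tp, fp = fp, tn = tn, fn = fn,
                   sensitivity = 100 * tp / (tp + fn),
                   specificity = 100 * tn / (tn + fp))
  })
  out <- dplyr::bind_rows(rows)
  out$youden <- out$sensitivity + out$specificity - 100
  chosen <- if (method == "youden") {
    out$threshold[which.max(out$youden)]
  } else {
    ok <- out$threshold[out$sensitivity >= min_sensitivity]
    if (length(ok) == 0) NA_real_ else max(ok)
  }
  out <- tibble::new_tibble(out, nrow = nrow(out), class = "pazo_scan")
  attr(out, "chosen") <- chosen
  attr(out, "trough_criterion") <- trough_criterion
  attr(out, "method") <- method
  out
}

#' Classify a patient's exposure against the target AUC
#'
#' @param auc Estimated AUC (mg*h/L, vectorised, > 0).
#' @param target Target AUC (mg*h/L, default 750). An AUC exactly at the
#'   target counts as adequate.
#' @return Factor with levels `below_target`, `at_or_above_target`.
#' @export
#' @examples
#' classify_exposure(c(436.7, 750, 1746.7))
classify_exposure <- function(auc, target = 750) {
  if (any(auc <= 0)) stop("`auc` must be strictly positive")
  factor(ifelse(auc < target, "below_target", "at_or_above_target"),
         levels = c("below_target", "at_or_above_target"))
}

#' Pearson correlation between trough concentration and AUC
#'
#' @param data Tibble with columns `ctrough` and `auc` (>= 3 rows).
#' @return The product-moment correlation expressed as a percentage.
#' @export
ctrough_auc_correlation <- function(data) {
  ct <- data$ctrough; auc <- data$auc
  if (is.null(ct) || is.null(auc)) stop("`data` needs columns `ctrough` and `auc`")
  if (length(ct) < 3) stop("at least 3 pairs are required")
  if (stats::sd(ct) == 0 || stats::sd(auc) == 0) {
    stop("zero variance in `ctrough` or `auc`; correlation undefined")
  }
  100 * stats::cor(ct, auc, method = "pearson")
}

#' Paired comparison of exposure between treatment cycles
#'
#' Wilcoxon signed-rank test on paired per-subject AUC values from two
#' cycles (exact distribution for n <= 25 pairs without ties, normal
#' approximation with continuity correction otherwise, as in
#' [stats::wilcox.test()]). All-zero differences return p = 1 with a
#' warning.
#'
#' @param auc_a,auc_b Matched per-subject AUC vectors (mg*h/L).
#' @return A tibble: `statistic` (V), `p_value`, `n`, `method`.
#' @export
#' @examples
#' paired_cycle_test(c(5, 6, 7, 8, 9), c(4, 5, 6, 7, 8))
paired_cycle_test <- function(auc_a, auc_b) {
  if (length(auc_a) != length(auc_b) || length(auc_a) == 0) {
    stop("`auc_a` and `auc_b` must be matched non-empty vectors")
  }
  diffs <- auc_a - auc_b
  if (all(diffs == 0)) {
    warning("all paired differences are zero; p = 1")
    return(tibble::tibble(statistic = NA_real_, p_value = 1,
                          n = length(diffs),
                          method = "Wilcoxon signed rank (degenerate)"))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(auc_a, auc_b, paired = TRUE, exact = length(diffs) <= 25,
                       correct = TRUE))
  tibble::tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
                 n = length(diffs), method = wt$method)
}
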