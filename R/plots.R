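#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a visual predictive check
#'
#' Observed percentiles per time bin over the simulated 90% prediction
#' bands.
#'
#' @param object A `pazo_vpc`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pazo_vpc <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$percentile <- factor(paste0("P", d$percentile),
                         levels = c("P10", "P50", "P90"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t_mid)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$band_lo, ymax = .data$band_hi,
                   fill = .data$percentile), alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$band_med,
                                    colour = .data$percentile),
                       linetype = 2) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed,
                                     colour = .data$percentile)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed,
                                    colour = .data$percentile)) +
    ggplot2::labs(x = "time after dose (h)",
                  y = "concentration (mg/L)",
                  title = "Visual predictive check",
                  colour = "percentile", fill = "percentile") +
    ggplot2::theme_minimal()
}

#' Plot the SAEM convergence trace
#'
#' @param object A `pazo_fit`.
#' @param ... Unused.
#' @return A ggplot with one facet per parameter.
#' @export
autoplot.pazo_fit <- function(object, ...) {
  d <- tidyr::pivot_longer(object$trace, -"iteration",
                           names_to = "parameter")
  ggplot2::ggplot(d, ggplot2::aes(.data$iteration, .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "SAEM iteration", y = NULL,
                  title = "Parameter convergence") +
    ggplot2::theme_minimal()
}

#' Plot a target-AUC threshold scan
#'
#' Sensitivity and specificity against the candidate AUC threshold, with
#' the chosen threshold marked.
#'
#' @param object A `pazo_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pazo_scan <- function(object, ...) {
  d <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("threshold", "sensitivity", "specificity")],
    -"threshold", names_to = "measure")
  ggplot2::ggplot(d, ggplot2::aes(.data$threshold, .data$value,
                                  colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = attr(object, "chosen"),
                        linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "AUC threshold (mg*h/L)", y = "%",
                  title = "Target-AUC determination") +
    ggplot2::theme_minimal()
}
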