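#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an ROC curve
#'
#' @param object An `lrs_roc` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lrs_roc <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = 1 - .data$specificity,
                               y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  subtitle = sprintf("AUC %.4f (SE %.4f)", object$auc,
                                     object$auc_se)) +
    ggplot2::theme_minimal()
}

#' Manhattan-style plot of a lipidome screen
#'
#' -log10 p-value per species with the nominal 0.05 line and the
#' largest-p species passing the FDR threshold marked.
#'
#' @param object An `lrs_screen` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lrs_screen <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d <- d[!is.na(d$p), , drop = FALSE]
  d$index <- match(d$species, sort(unique(d$species)))
  fdr_line <- if (any(d$significant)) max(d$p[d$significant]) else NA_real_
  gg <- ggplot2::ggplot(d, ggplot2::aes(x = .data$index,
                                        y = -log10(.data$p),
                                        colour = .data$significant)) +
    ggplot2::geom_point(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(0.05), colour = "blue",
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = "Lipid species", y = "-log10 p") +
    ggplot2::theme_minimal()
  if (!is.na(fdr_line)) {
    gg <- gg + ggplot2::geom_hline(yintercept = -log10(fdr_line),
                                   colour = "red", linetype = "dashed")
  }
  gg
}

#' Kaplan-Meier curves by score tertile
#'
#' @param object An `lrs_tertile_hazards` object.
#' @param ... Unused.
#' @return A ggplot of diabetes-free survival by tertile.
#' @export
autoplot.lrs_tertile_hazards <- function(object, ...) {
  ggplot2::ggplot(object$km,
                  ggplot2::aes(x = .data$time, y = .data$surv,
                               colour = .data$tertile)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Years of follow-up", y = "Diabetes-free survival",
                  colour = "LRS tertile") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness plane
#'
#' Expected cost against expected QALYs per strategy, marker size
#' proportional to the expected risk reduction in diabetes incidence.
#'
#' @param object A `cea_result` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cea_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$qaly, y = .data$cost,
                                       size = .data$risk_reduction,
                                       colour = .data$strategy)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Expected QALYs (5 years)",
                  y = "Expected cost (2015 US$)",
                  size = "Risk reduction") +
    ggplot2::theme_minimal()
}

#' Tornado diagram
#'
#' @param object A `cea_tornado` tibble.
#' @param ... Unused.
#' @return A ggplot of expected-value swings, widest first.
#' @export
autoplot.cea_tornado <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$parameter <- factor(d$parameter, levels = rev(d$parameter))
  base_ev <- attr(object, "base_ev")
  ggplot2::ggplot(d, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$ev_low,
                                       xend = .data$ev_high,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base_ev, linetype = "dashed") +
    ggplot2::labs(x = "Expected value", y = NULL) +
    ggplot2::theme_minimal()
}

#' Smoothed microsimulation curves
#'
#' Fourth-order polynomial fits of the expected value against the swept
#' parameter, per strategy.
#'
#' @param object A `cea_microsim` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cea_microsim <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$param_value, y = .data$fitted,
                               colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = object$parameter, y = object$value) +
    ggplot2::theme_minimal()
}
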