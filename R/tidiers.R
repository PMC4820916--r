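#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a kinship-frailty Cox fit
#'
#' @param x A `frailty_cox` object.
#' @param exponentiate Report hazard ratios instead of log hazard ratios?
#' @param conf_level Wald CI level.
#' @param ... Unused.
#' @return One row per coefficient: `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`, `conf.low`, `conf.high`.
#' @export
tidy.frailty_cox <- function(x, exponentiate = FALSE, conf_level = 0.95,
                             ...) {
  z <- x$coefficients / x$se
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$se),
    statistic = unname(z),
    p.value = unname(2 * stats::pnorm(-abs(z))),
    conf.low = unname(x$coefficients - q * x$se),
    conf.high = unname(x$coefficients + q * x$se))
  if (exponentiate) {
    out$estimate <- exp(out$estimate)
    out$conf.low <- exp(out$conf.low)
    out$conf.high <- exp(out$conf.high)
  }
  out
}

#' @rdname tidy.frailty_cox
#' @export
glance.frailty_cox <- function(x, ...) {
  tibble::tibble(n = x$n, nevent = x$nevent, logLik = x$loglik,
                 AIC = x$AIC, df = x$df, sigma2 = x$sigma2,
                 sigma2_estimated = x$sigma2_estimated,
                 converged = x$converged)
}

#' Tidy a Poisson person-time fit
#'
#' @param x A `poisson_fit` object.
#' @param ... Unused.
#' @return The incidence-rate-ratio tibble of the predictors of interest.
#' @export
tidy.poisson_fit <- function(x, ...) x$irr

#' @rdname tidy.poisson_fit
#' @export
glance.poisson_fit <- function(x, ...) {
  tibble::tibble(deviance = x$deviance, AIC = x$AIC,
                 nobs = stats::nobs(x$glm))
}

#' Tidy a liability-threshold fit
#'
#' @param x A `liability_fit` object.
#' @param ... Unused.
#' @return One row per fixed effect (threshold/mean first).
#' @export
tidy.liability_fit <- function(x, ...) {
  tibble::tibble(term = c("(threshold)", names(x$beta)),
                 estimate = c(x$mu, unname(x$beta)))
}

#' @rdname tidy.liability_fit
#' @export
glance.liability_fit <- function(x, ...) {
  tibble::tibble(prevalence = x$prevalence, h2 = x$h2, logLik = x$loglik,
                 n = x$n, n_case = x$n_case, clamped = x$clamped)
}

#' Tidy an ROC curve
#'
#' @param x An `lrs_roc` object.
#' @param ... Unused.
#' @return The (cutoff, sensitivity, specificity) points.
#' @export
tidy.lrs_roc <- function(x, ...) x$points

#' @rdname tidy.lrs_roc
#' @export
glance.lrs_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, auc_se = x$auc_se, n_pos = x$n_pos,
                 n_neg = x$n_neg, h2 = x$h2)
}

#' Tidy an LRS model
#'
#' @param x An `lrs_model`.
#' @param ... Unused.
#' @return One row per species with its weight.
#' @export
tidy.lrs_model <- function(x, ...) {
  tibble::tibble(species = x$species, weight = x$weights)
}
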