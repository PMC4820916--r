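# Incremental value of an added marker: model fit (LR chi-square),
# information (AIC), accuracy (Uno's IPCW concordance), discrimination
# (IDI) and reclassification (continuous NRI), all censoring-corrected by
# inverse probability of censoring weighting (IPCW).

# Kaplan-Meier of the censoring distribution; returns a function G(t)
# (left-continuous evaluation available via eps).
censor_survival <- function(time, status) {
  sf <- survival::survfit(survival::Surv(time, 1 - status) ~ 1)
  step <- stats::stepfun(sf$time, c(1, sf$surv), right = FALSE)
  function(t) pmax(step(t), 1e-10)
}

#' Uno's censoring-weighted concordance
#'
#' IPCW concordance for survival predictions truncated at a horizon:
#' comparable pairs are `(i, j)` with an event for `i` before both `T_j`
#' and the horizon, weighted by the inverse squared Kaplan-Meier censoring
#' survival at `T_i`; tied scores count one half.
#'
#' @param time,status Follow-up times and event indicators.
#' @param score Risk score (higher = higher risk).
#' @param horizon Truncation time tau.
#' @return Concordance estimate in `[0, 1]`.
#' @export
uno_c <- function(time, status, score, horizon = max(time)) {
  stopifnot(length(time) == length(status), length(score) == length(time))
  if (sum(status == 1 & time < horizon) < 2L) {
    stop("need at least 2 events before the horizon", call. = FALSE)
  }
  G <- censor_survival(time, status)
  idx <- which(status == 1 & time < horizon)
  w_i <- 1 / G(time[idx] - 1e-10)^2
  num <- 0; den <- 0
  for (k in seq_along(idx)) {
    i <- idx[k]
    comp <- which(time > time[i])
    if (length(comp) == 0L) next
    conc <- sum(score[i] > score[comp]) + 0.5 * sum(score[i] == score[comp])
    num <- num + w_i[k] * conc
    den <- den + w_i[k] * length(comp)
  }
  if (den == 0) stop("no comparable pairs", call. = FALSE)
  num / den
}

# IPCW weights for event status at the horizon: events before tau weighted
# by 1/G(T-), survivors past tau by 1/G(tau), censored-before-tau zero.
ipcw_weights <- function(time, status, horizon) {
  G <- censor_survival(time, status)
  w <- numeric(length(time))
  ev <- status == 1 & time <= horizon
  sv <- time > horizon
  w[ev] <- 1 / G(time[ev] - 1e-10)
  w[sv] <- 1 / G(horizon)
  list(w = w, event = ev, nonevent = sv)
}

#' Integrated discrimination improvement and continuous NRI
#'
#' IDI is the gain in discrimination slope: the mean difference between new
#' and old predicted risks among events minus the same mean among
#' non-events, with event status at the horizon estimated by IPCW.
#' The continuous NRI is
#' `[P(up | event) - P(down | event)] + [P(down | non-event) -
#' P(up | non-event)]` where "up" means the new risk exceeds the old.
#'
#' @param time,status Follow-up times and event indicators.
#' @param risk_old,risk_new Predicted event probabilities at the horizon
#'   under the base and augmented models.
#' @param horizon Evaluation time.
#' @return Tibble with `idi` and `nri`. Identical risk vectors return
#'   zeros.
#' @export
idi_nri <- function(time, status, risk_old, risk_new, horizon) {
  stopifnot(length(risk_old) == length(time),
            length(risk_new) == length(time))
  if (isTRUE(all.equal(risk_old, risk_new))) {
    return(tibble::tibble(idi = 0, nri = 0))
  }
  wt <- ipcw_weights(time, status, horizon)
  d <- risk_new - risk_old
  wmean <- function(x, sel) {
    if (sum(wt$w[sel]) == 0) return(NA_real_)
    sum(wt$w[sel] * x[sel]) / sum(wt$w[sel])
  }
  idi <- wmean(d, wt$event) - wmean(d, wt$nonevent)
  up <- d > 0; down <- d < 0
  nri <- (wmean(up, wt$event) - wmean(down, wt$event)) +
    (wmean(down, wt$nonevent) - wmean(up, wt$nonevent))
  tibble::tibble(idi = idi, nri = nri)
}

#' Incremental value of adding a marker to a survival model
#'
#' Fits the base and augmented Cox models (optionally kinship-frailty) and
#' reports five improvement metrics: likelihood-ratio chi-square, change in
#' AIC, change in Uno's C, IDI and continuous NRI at a horizon. Confidence
#' intervals for the last three come from a bootstrap that resamples
#' families as units when a `cluster` column is given (respecting kinship
#' dependence) and subjects otherwise.
#'
#' @inheritParams fit_frailty_cox
#' @param base_covariates,added_covariates Character term vectors; the
#'   augmented model uses both, so it nests the base model.
#' @param horizon Evaluation horizon (years).
#' @param n_boot Bootstrap replicates for CIs (0 = point estimates only).
#' @param cluster Optional column name of the family/cluster id.
#' @param conf_level Bootstrap percentile CI level.
#' @return Object of class `incremental_report`: a tibble with one row per
#'   metric (`lr_chisq`, `delta_aic`, `delta_c`, `idi`, `nri`).
#' @export
incremental_report <- function(data, base_covariates, added_covariates,
                               time = "time", event = "event", horizon = 10,
                               kinship = NULL, sigma2 = NULL, n_boot = 0,
                               cluster = NULL, conf_level = 0.95) {
  point <- incremental_point(data, base_covariates, added_covariates,
                             time, event, horizon, kinship, sigma2)
  out <- point$metrics
  if (n_boot > 0) {
    ids <- if (!is.null(cluster)) data[[cluster]] else seq_len(nrow(data))
    groups <- split(seq_len(nrow(data)), ids)
    boots <- purrr::map(seq_len(n_boot), function(b) {
      take <- sample(length(groups), replace = TRUE)
      rows <- unlist(groups[take], use.names = FALSE)
      d <- data[rows, , drop = FALSE]
      d$id <- as.character(seq_len(nrow(d))) # resampled subjects are new ids
      k <- if (is.null(kinship)) NULL else {
        km <- kinship[rows, rows, drop = FALSE]
        dimnames(km) <- list(d$id, d$id)
        km
      }
      tryCatch(
        incremental_point(d, base_covariates, added_covariates, time,
                          event, horizon, k, sigma2)$metrics$estimate,
        error = function(e) rep(NA_real_, nrow(out)))
    })
    B <- do.call(rbind, boots)
    alpha <- (1 - conf_level) / 2
    out$conf.low <- apply(B, 2, stats::quantile, alpha, na.rm = TRUE)
    out$conf.high <- apply(B, 2, stats::quantile, 1 - alpha, na.rm = TRUE)
    sds <- apply(B, 2, stats::sd, na.rm = TRUE)
    boot_p <- 2 * stats::pnorm(-abs(out$estimate / sds))
    out$p.value <- ifelse(out$metric %in% c("delta_c", "idi", "nri"),
                          boot_p, out$p.value)
  }
  structure(out, class = c("incremental_report", class(out)),
            horizon = horizon, n_boot = n_boot)
}

incremental_point <- function(data, base_covariates, added_covariates,
                              time, event, horizon, kinship, sigma2) {
  fit_base <- fit_frailty_cox(data, base_covariates, time, event,
                              kinship = kinship, sigma2 = sigma2)
  fit_aug <- fit_frailty_cox(data, c(base_covariates, added_covariates),
                             time, event, kinship = kinship,
                             sigma2 = sigma2)
  lr <- lr_test(fit_base, fit_aug)
  risk_base <- if (length(base_covariates) > 0) {
    predict_risk(fit_base, horizon = horizon)
  } else {
    rep(mean(predict_risk(fit_aug, horizon = horizon)), nrow(data))
  }
  risk_aug <- predict_risk(fit_aug, horizon = horizon)
  y_time <- data[[time]]; y_event <- as.integer(data[[event]])
  c_base <- if (stats::sd(risk_base) == 0) 0.5 else
    uno_c(y_time, y_event, risk_base, horizon)
  c_aug <- uno_c(y_time, y_event, risk_aug, horizon)
  di <- idi_nri(y_time, y_event, risk_base, risk_aug, horizon)
  metrics <- tibble::tibble(
    metric = c("lr_chisq", "delta_aic", "delta_c", "idi", "nri"),
    estimate = c(lr$statistic, fit_aug$AIC - fit_base$AIC,
                 c_aug - c_base, di$idi, di$nri),
    conf.low = NA_real_, conf.high = NA_real_,
    p.value = c(lr$p.value, NA, NA, NA, NA))
  list(metrics = metrics, fits = list(base = fit_base, augmented = fit_aug))
}
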