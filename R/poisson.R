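# External-cohort validation when exact event dates are unknown: Poisson
# models with log person-time offsets, score recalibration, bootstrap CIs
# and the Cuzick trend test.

#' Clinical adjustment set for person-time validation models
#'
#' @return Character vector of model terms: age, sex, blood pressures, BMI,
#'   lipids, family history and drug use.
#' @export
validation_adjustment <- function() {
  c("age", "sex", "sbp", "dbp", "bmi", "total_chol", "hdl_chol",
    "triglycerides", "family_history", "bp_drug", "lipid_drug")
}

#' Poisson person-time regression
#'
#' Log-link Poisson model of event counts with the log person-time as an
#' offset, so coefficients are log incidence-rate ratios. Predictors listed
#' in `predictors` are (by default) standardized by their own standard
#' deviation in `data`, so a score's IRR is per SD of the score in the
#' cohort at hand.
#'
#' @param data Cohort data frame.
#' @param predictors Character vector of predictor columns of interest.
#' @param adjustment Optional character vector of adjustment terms (e.g.
#'   [validation_adjustment()], or `"glycemic_class"` for a
#'   prediabetes-adjusted model).
#' @param events,person_time Column names of the event count and exposure
#'   (person-years, all positive).
#' @param per_sd Standardize `predictors` to unit SD?
#' @return Object of class `poisson_fit`: `irr` tibble (term, irr,
#'   conf.low, conf.high, p.value for the predictors of interest),
#'   coefficients, deviance, AIC, and the underlying `glm` fit.
#' @export
fit_poisson_offset <- function(data, predictors, adjustment = NULL,
                               events = "events",
                               person_time = "person_years",
                               per_sd = TRUE) {
  assert_columns(data, c(predictors, events, person_time))
  pt <- data[[person_time]]
  if (any(pt <= 0)) stop("person-time must be positive", call. = FALSE)
  if (sum(data[[events]]) == 0) stop("zero total events", call. = FALSE)
  d <- tibble::as_tibble(data)
  if (per_sd) {
    for (p in predictors) d[[p]] <- d[[p]] / stats::sd(d[[p]])
  }
  f <- stats::reformulate(c(predictors, adjustment),
                          response = events)
  fit <- stats::glm(f, family = stats::poisson(), data = d,
                    offset = log(pt))
  sm <- summary(fit)$coefficients
  rows <- rownames(sm)
  keep <- unlist(lapply(predictors, function(p) grep(p, rows, fixed = TRUE)))
  keep <- rows[sort(unique(keep))]
  irr <- tibble::tibble(
    term = keep,
    irr = exp(sm[keep, "Estimate"]),
    conf.low = exp(sm[keep, "Estimate"] - 1.96 * sm[keep, "Std. Error"]),
    conf.high = exp(sm[keep, "Estimate"] + 1.96 * sm[keep, "Std. Error"]),
    p.value = sm[keep, "Pr(>|z|)"])
  structure(list(irr = irr, coefficients = stats::coef(fit),
                 deviance = stats::deviance(fit), AIC = stats::AIC(fit),
                 glm = fit, predictors = predictors,
                 adjustment = adjustment, per_sd = per_sd,
                 events = events, person_time = person_time),
            class = "poisson_fit")
}

#' @export
print.poisson_fit <- function(x, ...) {
  cat(sprintf("Poisson person-time model (AIC %.2f, deviance %.2f)\n",
              x$AIC, x$deviance))
  print(x$irr)
  invisible(x)
}

#' Run the three standard validation designs
#'
#' Unadjusted (U), clinical-covariate adjusted (C) and prediabetes-adjusted
#' (P) Poisson person-time models of a risk score.
#'
#' @inheritParams fit_poisson_offset
#' @param score_col Column holding the score to validate.
#' @param clinical Terms for the C design.
#' @param glycemic Column for the P design.
#' @return Tibble of per-SD IRRs with a `design` column.
#' @export
poisson_designs <- function(data, score_col, clinical = validation_adjustment(),
                            glycemic = "glycemic_class", events = "events",
                            person_time = "person_years") {
  designs <- list(U = NULL, C = clinical, P = glycemic)
  purrr::imap_dfr(designs, function(adj, nm) {
    fit <- fit_poisson_offset(data, score_col, adjustment = adj,
                              events = events, person_time = person_time)
    dplyr::mutate(fit$irr[fit$irr$term == score_col, ], design = nm,
                  .before = 1)
  })
}

#' Recalibrate an LRS on a person-time cohort
#'
#' Refits the score's species jointly in a Poisson person-time model on the
#' validation cohort; the fitted coefficients of the inverse-normalized
#' concentrations become the recalibrated weights.
#'
#' @inheritParams fit_poisson_offset
#' @param species The score's species columns (all must be present).
#' @param adjustment Optional adjustment terms for the recalibration model.
#' @return An [lrs_model()] tagged as recalibrated.
#' @export
recalibrate_lrs <- function(data, species, adjustment = NULL,
                            events = "events",
                            person_time = "person_years") {
  assert_columns(data, species)
  d <- tibble::as_tibble(data)
  inv <- paste0("inv_", species)
  for (i in seq_along(species)) {
    d[[inv[i]]] <- inverse_normalize(d[[species[i]]])
  }
  fit <- fit_poisson_offset(d, inv, adjustment = adjustment,
                            events = events, person_time = person_time,
                            per_sd = FALSE)
  lrs_model(species, unname(fit$coefficients[inv]),
            training = "recalibrated")
}

#' Bootstrap confidence interval for a per-SD incidence rate ratio
#'
#' Percentile CI over subject-resampled replicates of
#' [fit_poisson_offset()].
#'
#' @inheritParams fit_poisson_offset
#' @param term Which predictor's IRR to track (default the first).
#' @param n_reps Bootstrap replicates (>= 2; 1000 recommended).
#' @param conf_level CI level.
#' @param seed Optional seed; fixed seed gives identical CIs.
#' @return Tibble with the point estimate and percentile CI.
#' @export
bootstrap_validate <- function(data, predictors, adjustment = NULL,
                               events = "events",
                               person_time = "person_years",
                               term = predictors[1], n_reps = 1000,
                               conf_level = 0.95, seed = NULL) {
  if (n_reps < 2) stop("n_reps must be at least 2", call. = FALSE)
  point <- fit_poisson_offset(data, predictors, adjustment, events,
                              person_time)
  est <- point$irr$irr[point$irr$term == term]
  with_seed(seed, {
    reps <- vapply(seq_len(n_reps), function(b) {
      rows <- sample(nrow(data), replace = TRUE)
      f <- tryCatch(
        fit_poisson_offset(data[rows, , drop = FALSE], predictors,
                           adjustment, events, person_time),
        error = function(e) NULL)
      if (is.null(f)) return(NA_real_)
      f$irr$irr[f$irr$term == term]
    }, numeric(1))
    alpha <- (1 - conf_level) / 2
    tibble::tibble(term = term, irr = est,
                   conf.low = stats::quantile(reps, alpha, na.rm = TRUE),
                   conf.high = stats::quantile(reps, 1 - alpha,
                                               na.rm = TRUE),
                   n_reps = n_reps)
  })
}

#' Cuzick's nonparametric test for trend across ordered groups
#'
#' Wilcoxon-type linear rank statistic with group scores `1..k` and a
#' normal approximation; ties are handled through midranks.
#'
#' @param values Numeric vector.
#' @param groups Ordered factor (or coercible) of the same length with at
#'   least 2 levels.
#' @return Tibble with the standardized statistic `z` and two-sided
#'   `p.value`.
#' @export
cuzick_trend <- function(values, groups) {
  g <- if (is.ordered(groups)) groups else factor(groups, ordered = TRUE)
  if (nlevels(g) < 2L) stop("need at least 2 ordered groups", call. = FALSE)
  if (length(values) != length(g)) stop("length mismatch", call. = FALSE)
  l <- as.integer(g)
  r <- rank(values)
  n <- length(values)
  t_stat <- sum(l * r)
  e_t <- mean(r) * sum(l)
  v_t <- sum((l - mean(l))^2) * sum((r - mean(r))^2) / (n - 1)
  z <- (t_stat - e_t) / sqrt(v_t)
  tibble::tibble(statistic = t_stat, z = z,
                 p.value = 2 * stats::pnorm(-abs(z)))
}
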