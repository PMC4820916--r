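#' Adjustment covariate set for lipidome screening
#'
#' The standard clinical adjustment used throughout the survival analyses:
#' age, age squared, sex, their interactions, systolic and diastolic blood
#' pressure, waist circumference, BMI, total and HDL cholesterol, serum
#' triglycerides and anti-lipid / anti-hypertensive drug use. Terms are
#' returned as character model terms for [fit_frailty_cox()].
#'
#' @return Character vector of model terms.
#' @export
default_adjustment <- function() {
  c("age", "I(age^2)", "sex", "age:sex", "I(age^2):sex",
    "sbp", "dbp", "waist", "bmi", "total_chol", "hdl_chol",
    "triglycerides", "lipid_drug", "bp_drug")
}

# Align a relationship matrix to the rows of the cohort.
align_kinship <- function(kinship, data) {
  if (is.null(kinship)) return(NULL)
  if (!is.matrix(kinship) || nrow(kinship) != ncol(kinship)) {
    stop("`kinship` must be a square matrix", call. = FALSE)
  }
  if (!is.null(rownames(kinship)) && "id" %in% names(data)) {
    missing <- setdiff(data$id, rownames(kinship))
    if (length(missing) > 0L) {
      stop("kinship matrix lacks subjects: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
    kinship <- kinship[data$id, data$id, drop = FALSE]
  } else if (nrow(kinship) != nrow(data)) {
    stop("unnamed kinship matrix must match the number of rows of `data`",
         call. = FALSE)
  }
  kinship
}

kinship_inverse <- function(K) {
  ch <- tryCatch(chol(K), error = function(e) chol(K + 1e-8 * diag(nrow(K))))
  list(Kinv = chol2inv(ch), logdet = 2 * sum(log(diag(ch))))
}

#' Mixed-effects (kinship-frailty) Cox proportional hazards model
#'
#' Fits a Cox model with fixed covariate effects and a correlated Gaussian
#' random effect per subject whose covariance is `sigma2 * K`, `K` the
#' pedigree relationship matrix. Estimation is by penalized partial
#' likelihood: inner Newton iterations maximize the partial likelihood
#' penalized by the random-effect prior jointly in the coefficients and the
#' random effects, and the frailty variance is chosen to maximize a Laplace
#' approximation to the integrated (marginal) likelihood, searched on a log
#' grid and refined by golden-section ([stats::optimize()]). With
#' `sigma2 = 0` (or `kinship = NULL`) the model reduces to an ordinary Cox
#' partial-likelihood fit. Tied event times use the Efron approximation.
#'
#' @param data Cohort data frame; one row per subject.
#' @param covariates Character vector of model terms (may include
#'   `"I(age^2)"`, interactions, factors).
#' @param time,event Column names of the follow-up time (years) and event
#'   indicator.
#' @param kinship Relationship matrix on the self-equals-1 scale, rows
#'   named by subject id (or aligned to `data` rows). `NULL` for unrelated
#'   subjects.
#' @param sigma2 Frailty variance: `NULL` to profile it out (default when
#'   `kinship` is given), or a fixed non-negative value.
#' @param strata Optional column name of a stratification factor (separate
#'   baseline hazards per stratum).
#' @param sigma2_grid Log-spaced candidate grid for the outer profile
#'   search.
#' @return An object of class `frailty_cox` with coefficients, standard
#'   errors, the (integrated) log-likelihood, AIC, frailty variance and the
#'   ingredients needed for baseline-hazard prediction. Methods:
#'   [tidy.frailty_cox()], [glance.frailty_cox()], `print`.
#' @export
fit_frailty_cox <- function(data, covariates, time = "time", event = "event",
                            kinship = NULL, sigma2 = NULL, strata = NULL,
                            sigma2_grid = 10^seq(-2, 0.9, length.out = 7)) {
  assert_columns(data, c(time, event, strata))
  y_time <- data[[time]]
  y_event <- as.integer(data[[event]])
  if (any(y_time <= 0)) stop("all times must be positive", call. = FALSE)
  if (sum(y_event) < 1L) stop("at least one event is required", call. = FALSE)
  X <- design_matrix(data, covariates)
  if (ncol(X) > 0 && any(apply(X, 2, stats::sd) == 0)) {
    stop("singular information matrix (constant or collinear covariate?)",
         call. = FALSE)
  }
  strat <- if (is.null(strata)) NULL else data[[strata]]
  kinship <- align_kinship(kinship, data)
  use_frailty <- !is.null(kinship) && (is.null(sigma2) || sigma2 > 0)

  plain <- cox_newton(X, y_time, y_event, strata = strat)
  if (!use_frailty) {
    fit <- new_frailty_cox(plain$beta, plain$vcov, colnames(X),
                           loglik = plain$loglik,
                           loglik_partial = plain$loglik,
                           sigma2 = 0, sigma2_estimated = FALSE,
                           frailty = numeric(nrow(X)),
                           converged = plain$converged,
                           data = data, covariates = covariates,
                           time = time, event = event, strata = strata,
                           y_time = y_time, y_event = y_event,
                           lp = drop(X %*% plain$beta))
    return(fit)
  }

  ki <- kinship_inverse(kinship)
  n <- nrow(X)
  integrated <- function(fr, s2) {
    fr$loglik_pen - 0.5 * (n * log(s2) + ki$logdet + fr$logdet_Hbb)
  }
  fit_at <- function(s2, init = NULL) {
    fr <- cox_frailty_newton(X, y_time, y_event, ki$Kinv, s2,
                             strata = strat, init = init)
    fr$lint <- integrated(fr, s2)
    fr
  }

  if (!is.null(sigma2)) {
    s2_hat <- sigma2
    best <- fit_at(s2_hat)
    estimated <- FALSE
  } else {
    fits <- lapply(sigma2_grid, fit_at)
    lints <- vapply(fits, `[[`, numeric(1), "lint")
    i <- which.max(lints)
    lo <- sigma2_grid[max(i - 1L, 1L)]
    hi <- sigma2_grid[min(i + 1L, length(sigma2_grid))]
    opt <- stats::optimize(function(ls2) fit_at(exp(ls2))$lint,
                           interval = log(c(lo, hi)), maximum = TRUE,
                           tol = 1e-3)
    s2_hat <- exp(opt$maximum)
    best <- fit_at(s2_hat)
    # the boundary sigma2 -> 0 corresponds to the plain fit
    if (plain$loglik >= best$lint) {
      s2_hat <- 0
      best <- NULL
    }
    estimated <- TRUE
  }

  if (is.null(best)) {
    fit <- new_frailty_cox(plain$beta, plain$vcov, colnames(X),
                           loglik = plain$loglik,
                           loglik_partial = plain$loglik,
                           sigma2 = 0, sigma2_estimated = estimated,
                           frailty = numeric(n), converged = plain$converged,
                           data = data, covariates = covariates,
                           time = time, event = event, strata = strata,
                           y_time = y_time, y_event = y_event,
                           lp = drop(X %*% plain$beta))
    return(fit)
  }
  new_frailty_cox(best$beta, best$vcov, colnames(X),
                  loglik = best$lint, loglik_partial = best$loglik_partial,
                  sigma2 = s2_hat, sigma2_estimated = estimated,
                  frailty = best$b, converged = best$converged,
                  data = data, covariates = covariates,
                  time = time, event = event, strata = strata,
                  y_time = y_time, y_event = y_event,
                  lp = drop(X %*% best$beta))
}

new_frailty_cox <- function(beta, vcov, names_x, loglik, loglik_partial,
                            sigma2, sigma2_estimated, frailty, converged,
                            data, covariates, time, event, strata,
                            y_time, y_event, lp) {
  names(beta) <- names_x
  se <- sqrt(pmax(diag(vcov), 0))
  names(se) <- names_x
  df <- length(beta) + as.integer(sigma2_estimated && sigma2 > 0)
  structure(list(
    coefficients = beta, se = se, vcov = vcov,
    loglik = loglik, loglik_partial = loglik_partial,
    AIC = -2 * loglik + 2 * df, df = df,
    sigma2 = sigma2, sigma2_estimated = sigma2_estimated,
    frailty = frailty, converged = converged,
    covariates = covariates, time = time, event = event, strata = strata,
    n = length(y_time), nevent = sum(y_event),
    y_time = y_time, y_event = y_event, lp = lp
  ), class = "frailty_cox")
}

#' @export
print.frailty_cox <- function(x, ...) {
  cat("Kinship-frailty Cox model\n")
  cat(sprintf("  n = %d, events = %d, frailty variance = %.4g%s\n",
              x$n, x$nevent, x$sigma2,
              if (x$sigma2_estimated) " (profiled)" else " (fixed)"))
  cat(sprintf("  loglik = %.3f, AIC = %.2f, converged = %s\n",
              x$loglik, x$AIC, x$converged))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Likelihood-ratio test between nested fits
#'
#' @param base,augmented Nested `frailty_cox` fits (same likelihood type).
#' @return Tibble with the chi-square statistic, degrees of freedom and
#'   p-value; the statistic is floored at zero.
#' @export
lr_test <- function(base, augmented) {
  df <- augmented$df - base$df
  stat <- max(0, 2 * (augmented$loglik - base$loglik))
  tibble::tibble(statistic = stat, df = df,
                 p.value = stats::pchisq(stat, df = max(df, 1),
                                         lower.tail = FALSE))
}

#' Lipidome-wide survival screen
#'
#' Fits one kinship-frailty Cox model per lipid species: the
#' inverse-normalized concentration plus the clinical adjustment set. Wald
#' p-values are corrected by Benjamini-Hochberg and species passing the FDR
#' threshold are flagged. With a kinship matrix the frailty variance is, by
#' default, profiled once on the covariates-only model and then held fixed
#' across species (`sigma2 = "shared"`); `sigma2 = "per_species"` profiles
#' it inside every fit.
#'
#' @inheritParams fit_frailty_cox
#' @param species Character vector of lipid concentration columns.
#' @param fdr_threshold FDR level at which species are flagged
#'   (default 0.2).
#' @param sigma2 `"shared"`, `"per_species"`, or a fixed numeric value.
#' @return Tibble of class `lrs_screen`: `species`, `beta`, `se`, `p`,
#'   `p_adj`, `significant`, `error`, ordered by p-value. Failed fits are
#'   recorded, not fatal.
#' @export
screen_lipidome <- function(data, species, covariates = default_adjustment(),
                            time = "time", event = "event", kinship = NULL,
                            fdr_threshold = 0.2, sigma2 = "shared") {
  if (length(species) < 2L) stop("need at least 2 species", call. = FALSE)
  assert_fraction(fdr_threshold, "fdr_threshold")
  assert_columns(data, species)
  sigma2_fixed <- NULL
  if (!is.null(kinship)) {
    if (identical(sigma2, "shared")) {
      null_fit <- fit_frailty_cox(data, covariates, time, event,
                                  kinship = kinship)
      sigma2_fixed <- null_fit$sigma2
    } else if (is.numeric(sigma2)) {
      sigma2_fixed <- sigma2
    }
  } else {
    sigma2_fixed <- 0
  }
  rows <- purrr::map(species, function(s) {
    d <- data
    d$.inv_species <- inverse_normalize(d[[s]])
    fit <- tryCatch(
      fit_frailty_cox(d, c(covariates, ".inv_species"), time, event,
                      kinship = kinship, sigma2 = sigma2_fixed),
      error = function(e) e)
    if (inherits(fit, "error")) {
      return(tibble::tibble(species = s, beta = NA_real_, se = NA_real_,
                            p = NA_real_, error = conditionMessage(fit)))
    }
    b <- unname(fit$coefficients[".inv_species"])
    se <- unname(fit$se[".inv_species"])
    tibble::tibble(species = s, beta = b, se = se,
                   p = 2 * stats::pnorm(-abs(b / se)), error = NA_character_)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adj <- bh_fdr(out$p)
  out$significant <- !is.na(out$p_adj) & out$p_adj < fdr_threshold
  out <- dplyr::arrange(out, .data$p)
  class(out) <- c("lrs_screen", class(out))
  attr(out, "fdr_threshold") <- fdr_threshold
  out
}

#' Backward elimination over candidate species
#'
#' Starts from the joint adjusted model containing all candidates
#' (inverse-normalized) and iteratively removes the least significant
#' candidate (largest Wald p above `alpha_stay`), refitting until every
#' retained candidate satisfies `p <= alpha_stay`. Clinical covariates are
#' never eliminated.
#'
#' @inheritParams fit_frailty_cox
#' @param candidates Character vector of candidate species columns.
#' @param alpha_stay Wald significance level a candidate must meet to stay.
#' @return List of class `lrs_elimination`: `fit` (final model, `NULL` if
#'   nothing was retained), `retained` species, and a `steps` tibble of
#'   dropped terms.
#' @export
backward_eliminate <- function(data, candidates,
                               covariates = default_adjustment(),
                               alpha_stay = 0.05, time = "time",
                               event = "event", kinship = NULL,
                               sigma2 = NULL) {
  if (length(candidates) < 1L) stop("need at least 1 candidate", call. = FALSE)
  assert_fraction(alpha_stay, "alpha_stay")
  d <- data
  inv_names <- paste0("inv_", candidates)
  for (i in seq_along(candidates)) {
    d[[inv_names[i]]] <- inverse_normalize(d[[candidates[i]]])
  }
  active <- candidates
  steps <- list()
  fit <- NULL
  while (length(active) > 0L) {
    fit <- fit_frailty_cox(d, c(covariates, paste0("inv_", active)),
                           time, event, kinship = kinship, sigma2 = sigma2)
    terms <- paste0("inv_", active)
    b <- fit$coefficients[terms]
    se <- fit$se[terms]
    p <- 2 * stats::pnorm(-abs(b / se))
    worst <- which.max(p)
    if (p[worst] <= alpha_stay) break
    steps[[length(steps) + 1L]] <- tibble::tibble(
      dropped = active[worst], p = unname(p[worst]))
    active <- active[-worst]
    fit <- NULL
  }
  if (length(active) == 0L) {
    warning("no candidate species retained", call. = FALSE)
    fit <- NULL
  } else if (is.null(fit)) {
    fit <- fit_frailty_cox(d, c(covariates, paste0("inv_", active)),
                           time, event, kinship = kinship, sigma2 = sigma2)
  }
  structure(list(fit = fit, retained = active,
                 steps = dplyr::bind_rows(steps)),
            class = "lrs_elimination")
}

#' Lipidomic risk score models
#'
#' A lipidomic risk score (LRS) is a weighted sum of inverse-normalized
#' plasma concentrations, `sum_s w_s * i(conc_s)`. `lrs_model()` builds one
#' from explicit weights, [build_lrs()] extracts the weights from a fitted
#' elimination model, and [score_lrs()] evaluates the score on a cohort
#' (inverse normalization is computed within that cohort).
#'
#' @param species Character vector of species column names.
#' @param weights Numeric weights, one per species.
#' @param training Free-text tag recording where the weights come from.
#' @return An object of class `lrs_model`.
#' @export
lrs_model <- function(species, weights, training = NA_character_) {
  if (length(species) != length(weights)) {
    stop("species and weights must have equal length", call. = FALSE)
  }
  if (anyDuplicated(species)) stop("species must be distinct", call. = FALSE)
  if (any(!is.finite(weights))) stop("weights must be finite", call. = FALSE)
  structure(list(species = as.character(species),
                 weights = as.numeric(weights),
                 training = training),
            class = "lrs_model")
}

#' @rdname lrs_model
#' @param fit A converged `frailty_cox` fit whose terms include
#'   `inv_<species>` columns (as produced by [backward_eliminate()]).
#' @export
build_lrs <- function(fit, species, training = NA_character_) {
  if (is.null(fit) || !isTRUE(fit$converged)) {
    stop("fit must be a converged model", call. = FALSE)
  }
  terms <- paste0("inv_", species)
  missing <- setdiff(terms, names(fit$coefficients))
  if (length(missing) > 0L) {
    stop("fit lacks coefficients for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lrs_model(species, unname(fit$coefficients[terms]), training = training)
}

#' @rdname lrs_model
#' @param model An `lrs_model`.
#' @param data Cohort with the model's species columns.
#' @export
score_lrs <- function(model, data) {
  stopifnot(inherits(model, "lrs_model"))
  assert_columns(data, model$species)
  score <- numeric(nrow(data))
  for (i in seq_along(model$species)) {
    score <- score + model$weights[i] *
      inverse_normalize(data[[model$species[i]]])
  }
  score
}

#' @export
print.lrs_model <- function(x, ...) {
  cat("Lipidomic risk score:",
      paste(sprintf("%+.4f*i(%s)", x$weights, x$species), collapse = " "),
      "\n")
  if (!is.na(x$training)) cat("  trained on:", x$training, "\n")
  invisible(x)
}

#' Serialize an LRS model as JSON
#'
#' @param model An [lrs_model()].
#' @param path File path.
#' @return `read_lrs()` returns the model; `write_lrs()` the path,
#'   invisibly.
#' @export
write_lrs <- function(model, path) {
  stopifnot(inherits(model, "lrs_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lrs
#' @export
read_lrs <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  lrs_model(x$species, x$weights, x$training %||% NA_character_)
}

#' Tertile-based survival analysis of a risk score
#'
#' Classifies subjects into score tertiles and quantifies the relative
#' hazard of the middle and upper tertiles (lower tertile as reference)
#' under three designs: a prediabetes-stratified model, a model restricted
#' to normoglycemic (NGT) subjects, and a model with tertile-by-prediabetes
#' interactions. Also returns Kaplan-Meier curves by tertile.
#'
#' @inheritParams fit_frailty_cox
#' @param score Numeric risk score, one value per row of `data`.
#' @param glycemic Column holding the baseline glycemic class
#'   (`"NGT"` / `"prediabetes"`).
#' @param designs Subset of `c("stratified", "ngt_only", "interaction")`.
#' @return List of class `lrs_tertile_hazards` with `relative_hazards`
#'   (tibble: design, tertile, rh, conf.low, conf.high, p), `fits`, and
#'   `km` (tibble of Kaplan-Meier curves by tertile).
#' @export
tertile_hazards <- function(data, score, covariates = default_adjustment(),
                            time = "time", event = "event", kinship = NULL,
                            sigma2 = NULL, glycemic = "glycemic_class",
                            designs = c("stratified", "ngt_only",
                                        "interaction")) {
  designs <- match.arg(designs, several.ok = TRUE)
  assert_columns(data, glycemic)
  d <- tibble::as_tibble(data)
  # unordered factor so model.matrix uses treatment contrasts (lower = ref)
  d$lrs_tertile <- factor(as.character(tertile_groups(score)),
                          levels = c("lower", "middle", "upper"))
  d$.prediab <- as.integer(d[[glycemic]] != "NGT")
  fits <- list()
  if ("stratified" %in% designs) {
    fits$stratified <- fit_frailty_cox(
      d, c(covariates, "lrs_tertile"), time, event, kinship = kinship,
      sigma2 = sigma2, strata = glycemic)
  }
  if ("ngt_only" %in% designs) {
    sub <- d[d$.prediab == 0L, , drop = FALSE]
    if (nrow(sub) == 0L) stop("empty NGT stratum", call. = FALSE)
    k_sub <- if (is.null(kinship)) NULL else align_kinship(kinship, sub)
    fits$ngt_only <- fit_frailty_cox(
      sub, c(covariates, "lrs_tertile"), time, event, kinship = k_sub,
      sigma2 = sigma2)
  }
  if ("interaction" %in% designs) {
    fits$interaction <- fit_frailty_cox(
      d, c(covariates, "lrs_tertile * .prediab"), time, event,
      kinship = kinship, sigma2 = sigma2)
  }
  rh <- purrr::imap(fits, function(f, nm) {
    terms <- grep("^lrs_tertile", names(f$coefficients), value = TRUE)
    terms <- terms[!grepl(":", terms)]
    b <- f$coefficients[terms]; se <- f$se[terms]
    tibble::tibble(design = nm, term = terms, rh = exp(b),
                   conf.low = exp(b - 1.96 * se),
                   conf.high = exp(b + 1.96 * se),
                   p = 2 * stats::pnorm(-abs(b / se)))
  })
  sf <- survival::survfit(
    survival::Surv(d[[time]], d[[event]]) ~ tertile,
    data = data.frame(tertile = d$lrs_tertile))
  km <- tibble::tibble(
    tertile = rep(sub("^tertile=", "", names(sf$strata)),
                  times = sf$strata),
    time = sf$time, surv = sf$surv, n_risk = sf$n.risk,
    n_event = sf$n.event)
  structure(list(relative_hazards = dplyr::bind_rows(rh), fits = fits,
                 km = km),
            class = "lrs_tertile_hazards")
}

#' Event fraction by a given time from a Kaplan-Meier curve
#'
#' @param km The `km` tibble of [tertile_hazards()].
#' @param at Time (years) at which to read off the cumulative event
#'   fraction `1 - S(t)`.
#' @return Tibble with one row per tertile.
#' @export
km_event_fraction <- function(km, at) {
  km |>
    dplyr::group_by(.data$tertile) |>
    dplyr::summarise(event_fraction = {
      s <- c(1, .data$surv)[findInterval(at, c(0, .data$time))]
      1 - s
    }, .groups = "drop")
}

#' Predicted event risk at a horizon from a Cox fit
#'
#' Breslow baseline cumulative hazard evaluated at the horizon, combined
#' with the subject's fixed-effect linear predictor:
#' `risk = 1 - exp(-H0(tau) * exp(lp))`. Only unstratified fits are
#' supported.
#'
#' @param fit A `frailty_cox` fit.
#' @param newdata Data frame on which to predict (defaults to the training
#'   data linear predictor).
#' @param horizon Prediction horizon in years.
#' @return Numeric vector of event probabilities by `horizon`.
#' @export
predict_risk <- function(fit, newdata = NULL, horizon) {
  if (!is.null(fit$strata)) {
    stop("risk prediction is only supported for unstratified fits",
         call. = FALSE)
  }
  lp <- if (is.null(newdata)) fit$lp else {
    X <- design_matrix(newdata, fit$covariates)
    drop(X %*% fit$coefficients[colnames(X)])
  }
  # Breslow baseline on the training data
  r <- exp(fit$lp - mean(fit$lp))
  o <- order(fit$y_time)
  ts <- fit$y_time[o]; st <- fit$y_event[o]; rs <- r[o]
  revcum <- rev(cumsum(rev(rs)))
  ev <- which(st == 1 & ts <= horizon)
  if (length(ev) == 0L) return(rep(0, length(lp)))
  tk <- unique(ts[ev])
  H0 <- sum(vapply(tk, function(t0) {
    first <- match(TRUE, ts >= t0)
    sum(ts == t0 & st == 1) / revcum[first]
  }, numeric(1)))
  1 - exp(-H0 * exp(lp - mean(fit$lp)))
}
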