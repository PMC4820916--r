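# Liability-threshold modeling and the kinship-adjusted ROC.
#
# A binary trait y is modeled as the indicator that a latent liability
# L = mu + X beta + g + e exceeds zero, with polygenic effect
# g ~ N(0, h2 * K) (K the relationship matrix, unit diagonal) and residual
# e ~ N(0, 1 - h2), so the total latent variance is 1 and the marginal
# prevalence at covariates x is Phi(mu + x beta).

# Own Newton probit (used when there is no polygenic component, and as the
# inner step of the Laplace fit).
probit_newton <- function(X, y, tol = 1e-10, max_iter = 50) {
  q <- 2 * y - 1
  beta <- numeric(ncol(X))
  for (it in seq_len(max_iter)) {
    z <- q * drop(X %*% beta)
    lam <- exp(stats::dnorm(z, log = TRUE) - stats::pnorm(z, log.p = TRUE))
    v <- q * lam
    w <- lam * (lam + z)
    H <- crossprod(X, w * X)
    step <- tryCatch(solve(H, drop(crossprod(X, v))),
                     error = function(e) rep(0, ncol(X)))
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  z <- q * drop(X %*% beta)
  list(beta = beta,
       loglik = sum(stats::pnorm(z, log.p = TRUE)),
       converged = max(abs(step)) < 1e-6)
}

# Laplace-approximate marginal likelihood of the polygenic probit at a
# fixed heritability; joint Newton over (beta, g).
liability_laplace <- function(X, y, Kinv, logdetK, h2, tol = 1e-8,
                              max_iter = 50) {
  n <- length(y)
  q <- 2 * y - 1
  s <- sqrt(1 - h2)
  Ginv <- Kinv / h2
  beta <- numeric(ncol(X))
  g <- numeric(n)
  p <- ncol(X)
  for (it in seq_len(max_iter)) {
    a <- drop(X %*% beta) + g
    z <- q * a / s
    lam <- exp(stats::dnorm(z, log = TRUE) - stats::pnorm(z, log.p = TRUE))
    v <- q * lam / s
    w <- lam * (lam + z) / s^2
    Hbb <- Ginv
    diag(Hbb) <- diag(Hbb) + w
    H <- rbind(cbind(crossprod(X, w * X), t(w * X)),
               cbind(w * X, Hbb))
    grad <- c(drop(crossprod(X, v)), v - drop(Ginv %*% g))
    step <- tryCatch(solve(H, grad), error = function(e) rep(0, n + p))
    beta <- beta + step[seq_len(p)]
    g <- g + step[-seq_len(p)]
    if (max(abs(step)) < tol) break
  }
  a <- drop(X %*% beta) + g
  z <- q * a / s
  lam <- exp(stats::dnorm(z, log = TRUE) - stats::pnorm(z, log.p = TRUE))
  w <- lam * (lam + z) / s^2
  pen <- sum(stats::pnorm(z, log.p = TRUE)) - sum(g * (Ginv %*% g)) / 2
  Hbb <- Ginv
  diag(Hbb) <- diag(Hbb) + w
  lmarg <- pen - 0.5 * (n * log(h2) + logdetK +
                          as.numeric(determinant(Hbb)$modulus))
  list(beta = beta, g = g, loglik = lmarg)
}

#' Liability-threshold prevalence model for family data
#'
#' Fits a probit liability model with an optional polygenic random effect
#' whose covariance is `h2 * K` (`K` the relationship matrix), by Laplace
#' approximation of the marginal likelihood; the heritability is profiled
#' by golden-section search unless fixed. The implied prevalence is the
#' standard-normal upper-tail mass beyond the fitted threshold, averaged
#' over the sample covariate values (the total latent variance is 1 by
#' construction, so the marginal prevalence at covariates `x` is
#' `Phi(mu + x beta)`).
#'
#' With no kinship matrix the model is an ordinary probit; with no
#' covariates its prevalence equals the sample case fraction. An all-case
#' or all-control sample has no interior maximum: the prevalence is clamped
#' to `0.5/n` from the boundary, with a warning.
#'
#' @param data Data frame.
#' @param outcome Column name of the binary outcome (0/1 or logical).
#' @param covariates Optional character vector of fixed-effect terms.
#' @param kinship Optional relationship matrix (self = 1 scale).
#' @param h2 Heritability: `NULL` to estimate (when `kinship` is given), or
#'   a fixed value in `[0, 1)`.
#' @param warn Warn when the prevalence is clamped.
#' @return Object of class `liability_fit`: `mu` (threshold/mean on the
#'   liability scale), `beta`, `h2`, `prevalence`, `loglik`, `n`, `n_case`.
#' @export
estimate_prevalence <- function(data, outcome, covariates = NULL,
                                kinship = NULL, h2 = NULL, warn = TRUE) {
  assert_columns(data, c(outcome, covariates))
  y <- as.integer(data[[outcome]])
  if (!all(y %in% c(0L, 1L))) stop("outcome must be binary", call. = FALSE)
  n <- length(y)
  if (n < 2L) stop("need at least 2 subjects", call. = FALSE)
  Xc <- design_matrix(data, covariates)
  X <- cbind(`(Intercept)` = 1, Xc)
  if (sum(y) == 0L || sum(y) == n) {
    if (warn) warning("all-case or all-control sample: prevalence clamped",
                      call. = FALSE)
    prev <- if (sum(y) == 0L) 0.5 / n else 1 - 0.5 / n
    return(structure(list(mu = stats::qnorm(prev),
                          beta = stats::setNames(numeric(ncol(Xc)),
                                                 colnames(Xc)),
                          h2 = 0, prevalence = prev, loglik = NA_real_,
                          n = n, n_case = sum(y), clamped = TRUE),
                     class = "liability_fit"))
  }
  kinship <- align_kinship(kinship, data)
  use_poly <- !is.null(kinship) && (is.null(h2) || h2 > 0)
  if (!use_poly) {
    fit <- probit_newton(X, y)
    coefs <- fit$beta
    h2_hat <- 0
    ll <- fit$loglik
  } else {
    ki <- kinship_inverse(kinship)
    fit_h2 <- function(h) liability_laplace(X, y, ki$Kinv, ki$logdet, h)
    if (is.null(h2)) {
      opt <- stats::optimize(function(h) fit_h2(h)$loglik,
                             interval = c(1e-3, 0.9), maximum = TRUE,
                             tol = 1e-3)
      plain <- probit_newton(X, y)
      if (plain$loglik >= opt$objective) {
        coefs <- plain$beta; h2_hat <- 0; ll <- plain$loglik
      } else {
        h2_hat <- opt$maximum
        fit <- fit_h2(h2_hat)
        coefs <- fit$beta; ll <- fit$loglik
      }
    } else {
      h2_hat <- h2
      fit <- fit_h2(h2)
      coefs <- fit$beta; ll <- fit$loglik
    }
  }
  mu <- coefs[1]
  beta <- stats::setNames(coefs[-1], colnames(Xc))
  prev <- mean(stats::pnorm(drop(X %*% coefs)))
  prev <- min(max(prev, 0.5 / n), 1 - 0.5 / n)
  structure(list(mu = unname(mu), beta = beta, h2 = h2_hat,
                 prevalence = prev, loglik = ll, n = n, n_case = sum(y),
                 clamped = FALSE),
            class = "liability_fit")
}

#' @export
print.liability_fit <- function(x, ...) {
  cat(sprintf(
    "Liability-threshold fit: mu = %.4f, h2 = %.3f, prevalence = %.4f (n = %d, cases = %d)\n",
    x$mu, x$h2, x$prevalence, x$n, x$n_case))
  invisible(x)
}

#' Bayesian sensitivity and specificity from cutoff prevalences
#'
#' Given the proportion of subjects above a cutoff (`p`) and the outcome
#' prevalence among subjects above (`p1`) and below (`p0`) the cutoff,
#' returns
#' `sensitivity = p*p1 / (p*p1 + (1-p)*p0)` and
#' `specificity = (1-p)*(1-p0) / ((1-p)*(1-p0) + p*(1-p1))`.
#'
#' @param p,p1,p0 Probabilities in `[0, 1]` (vectorized).
#' @return Tibble with columns `sensitivity` and `specificity`.
#' @examples
#' bayes_sens_spec(0.3, 0.4, 0.1) # 0.6316, 0.7778
#' @export
bayes_sens_spec <- function(p, p1, p0) {
  vals <- c(p, p1, p0)
  if (any(!is.finite(vals)) || any(vals < 0 | vals > 1)) {
    stop("all inputs must be probabilities in [0, 1]", call. = FALSE)
  }
  den_sens <- p * p1 + (1 - p) * p0
  den_spec <- (1 - p) * (1 - p0) + p * (1 - p1)
  if (any(den_sens == 0) || any(den_spec == 0)) {
    stop("undefined sensitivity/specificity: zero denominators",
         call. = FALSE)
  }
  tibble::tibble(sensitivity = p * p1 / den_sens,
                 specificity = (1 - p) * (1 - p0) / den_spec)
}

#' Kinship-adjusted ROC curve via liability-threshold prevalences
#'
#' For each cutoff of a continuous predictor, estimates (i) the proportion
#' of subjects above the cutoff, (ii) the outcome prevalence among subjects
#' above, and (iii) below the cutoff -- each through the
#' [estimate_prevalence()] liability machinery so kinship enters as a
#' polygenic random effect -- and transforms them into Bayesian sensitivity
#' and specificity with [bayes_sens_spec()]. The points are assembled into
#' a monotone curve with endpoints (0,0) and (1,1), and the area under the
#' curve carries a Hanley-McNeil standard error.
#'
#' With `kinship = NULL` and no covariates every prevalence reduces to an
#' empirical proportion and the curve equals the classical empirical ROC.
#' When a kinship matrix is supplied the heritability is estimated once on
#' the full-sample outcome model and held fixed across cutoffs.
#'
#' @inheritParams estimate_prevalence
#' @param predictor Column name of the continuous predictor (>= 10 distinct
#'   values required).
#' @param max_cutoffs Cutoff grid size: all distinct observed values if
#'   fewer, else this many quantile-spaced cutoffs.
#' @return Object of class `lrs_roc`: `points` (cutoff, sensitivity,
#'   specificity), `auc`, `auc_se`, `n_pos`, `n_neg`, `h2`.
#' @export
family_roc <- function(data, predictor, outcome, covariates = NULL,
                       kinship = NULL, h2 = NULL, max_cutoffs = 200) {
  assert_columns(data, c(predictor, outcome))
  x <- data[[predictor]]
  y <- as.integer(data[[outcome]])
  if (length(unique(x)) < 10L) {
    stop("predictor must have at least 10 distinct values", call. = FALSE)
  }
  kinship <- align_kinship(kinship, data)
  if (!is.null(kinship) && is.null(h2)) {
    h2 <- estimate_prevalence(data, outcome, covariates, kinship,
                              warn = FALSE)$h2
  }
  vals <- sort(unique(x))
  cutoffs <- if (length(vals) - 1L <= max_cutoffs) {
    # midpoints between consecutive observed values
    (vals[-1] + vals[-length(vals)]) / 2
  } else {
    stats::quantile(x, probs = seq_len(max_cutoffs) / (max_cutoffs + 1),
                    names = FALSE)
  }
  cutoffs <- unique(cutoffs)
  if (length(cutoffs) < 3L) stop("fewer than 3 valid cutoffs", call. = FALSE)
  d <- tibble::as_tibble(data)
  rows <- purrr::map(cutoffs, function(cc) {
    above <- x > cc
    d$.above <- as.integer(above)
    p <- estimate_prevalence(d, ".above", covariates = NULL,
                             kinship = kinship, h2 = h2,
                             warn = FALSE)$prevalence
    sub_a <- d[above, , drop = FALSE]
    sub_b <- d[!above, , drop = FALSE]
    k_a <- if (is.null(kinship)) NULL else kinship[above, above, drop = FALSE]
    k_b <- if (is.null(kinship)) NULL else kinship[!above, !above, drop = FALSE]
    p1 <- estimate_prevalence(sub_a, outcome, covariates, k_a, h2 = h2,
                              warn = FALSE)$prevalence
    p0 <- estimate_prevalence(sub_b, outcome, covariates, k_b, h2 = h2,
                              warn = FALSE)$prevalence
    ss <- bayes_sens_spec(p, p1, p0)
    tibble::tibble(cutoff = cc, sensitivity = ss$sensitivity,
                   specificity = ss$specificity)
  })
  pts <- dplyr::bind_rows(rows) |>
    dplyr::arrange(dplyr::desc(.data$cutoff))
  curve <- dplyr::bind_rows(
    tibble::tibble(cutoff = Inf, sensitivity = 0, specificity = 1),
    pts,
    tibble::tibble(cutoff = -Inf, sensitivity = 1, specificity = 0))
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  a <- auc_hanley(curve, n_pos, n_neg)
  structure(list(points = curve, auc = a$auc, auc_se = a$se,
                 n_pos = n_pos, n_neg = n_neg, h2 = h2 %||% 0),
            class = "lrs_roc")
}

#' @export
print.lrs_roc <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, AUC = %.4f (SE %.4f)\n",
              nrow(x$points), x$auc, x$auc_se))
  invisible(x)
}

#' Hanley-McNeil area under an ROC curve
#'
#' Trapezoidal AUC over (1-specificity, sensitivity), with the
#' Hanley-McNeil standard error
#' `sqrt((A(1-A) + (n_pos-1)(Q1 - A^2) + (n_neg-1)(Q2 - A^2)) /
#' (n_pos * n_neg))`, `Q1 = A/(2-A)`, `Q2 = 2A^2/(1+A)`.
#'
#' @param curve Either an `lrs_roc` object or a data frame with
#'   `sensitivity` and `specificity` columns.
#' @param n_pos,n_neg Numbers of cases and non-cases.
#' @return Tibble with `auc` and `se`.
#' @export
auc_hanley <- function(curve, n_pos, n_neg) {
  if (inherits(curve, "lrs_roc")) curve <- curve$points
  stopifnot(n_pos >= 1, n_neg >= 1)
  fpr <- 1 - curve$specificity
  tpr <- curve$sensitivity
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
                (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
  tibble::tibble(auc = auc, se = se)
}

#' Chi-square comparison of two AUCs
#'
#' `z = (A1 - A2) / sqrt(se1^2 + se2^2 - 2 r se1 se2)`; the statistic `z^2`
#' is referred to a chi-square distribution with 1 degree of freedom.
#'
#' @param auc1,auc2 AUC estimates (or `lrs_roc` objects, from which AUC and
#'   SE are taken).
#' @param se1,se2 Standard errors (ignored when ROC objects are supplied).
#' @param correlation Correlation `r` between the two AUC estimates
#'   (e.g. from bootstrapping paired curves); 0 for independent samples.
#' @return Tibble with `statistic` (chi-square, 1 df), `z` and `p.value`.
#' @export
compare_aucs <- function(auc1, auc2, se1 = NULL, se2 = NULL,
                         correlation = 0) {
  if (inherits(auc1, "lrs_roc")) { se1 <- auc1$auc_se; auc1 <- auc1$auc }
  if (inherits(auc2, "lrs_roc")) { se2 <- auc2$auc_se; auc2 <- auc2$auc }
  if (is.null(se1) || is.null(se2) || se1 <= 0 || se2 <= 0) {
    stop("positive standard errors are required", call. = FALSE)
  }
  v <- se1^2 + se2^2 - 2 * correlation * se1 * se2
  z <- (auc1 - auc2) / sqrt(v)
  tibble::tibble(statistic = z^2, z = z,
                 p.value = stats::pchisq(z^2, df = 1, lower.tail = FALSE))
}

#' Youden-optimal cutoff of an ROC curve
#'
#' The cutoff maximizing sensitivity + specificity - 1; used to define the
#' high-score group when a score feeds a screening strategy.
#'
#' @param roc An `lrs_roc` object.
#' @return A one-row tibble: `cutoff`, `sensitivity`, `specificity`,
#'   `youden`.
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "lrs_roc"))
  pts <- roc$points[is.finite(roc$points$cutoff), , drop = FALSE]
  j <- pts$sensitivity + pts$specificity - 1
  i <- which.max(j)
  tibble::tibble(cutoff = pts$cutoff[i], sensitivity = pts$sensitivity[i],
                 specificity = pts$specificity[i], youden = j[i])
}
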