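# Decision-analytic cost-effectiveness of screening-and-intervention
# strategies: mechanical tree construction from strategy specs, rollback by
# backward induction, ICER / net monetary benefit, tornado and
# one-way microsimulation sensitivity analyses. Costs and outcomes are
# undiscounted over a 5-year horizon, from a single-payer perspective.

#' Default cost, utility and probability inputs for the screening analyses
#'
#' `cea_costs()`: 2015 US$ screening and 5-year intervention/medical costs.
#' The per-assay score cost is assembled from its printed components
#' (three lipid species at ~$1 each, ~$4 mass spectrometry, $4 manpower =
#' $11), with a $29 sample preparation and a $50 primary-care visit charged
#' once per screening strategy, never duplicated across assays.
#' `cea_utilities()`: 5-year quality-adjusted life years by diabetes status
#' and intervention, and intervention efficacies (lifestyle 0.58,
#' metformin 0.31).
#'
#' Intervention costs, medical costs and QALYs are *reconstructed*,
#' Diabetes-Prevention-Program-flavoured synthetic defaults (the primary
#' sources report them only in supplementary tables); every value is
#' overridable.
#'
#' @return Named lists of numeric inputs.
#' @export
cea_costs <- function() {
  lrs_components <- c(lipid_species = 3 * 1, mass_spec = 4, manpower = 4)
  list(
    lrs_assay_components = lrs_components,
    lrs_assay = sum(lrs_components), sample_prep = 29, visit = 50,
    fpg_test = 21, rf_questionnaire = 16,
    intervention_5y = c(none = 0, lifestyle = 4600, metformin = 1200),
    medical_5y = c(no_t2d = 4100, t2d = 21000)
  )
}

#' @rdname cea_costs
#' @export
cea_utilities <- function() {
  list(
    qaly_5y = list(
      no_t2d = c(none = 4.50, lifestyle = 4.55, metformin = 4.48),
      t2d = c(none = 4.10, lifestyle = 4.16, metformin = 4.09)
    ),
    efficacy = c(none = 0, lifestyle = 0.58, metformin = 0.31)
  )
}

#' Bundle cost-effectiveness inputs
#'
#' @param p_t2d Named 5-year T2D probabilities per risk group (`HR`, `MR`,
#'   `LR`) plus the unscreened population (`ALL`). The defaults are
#'   synthetic placeholders for cohort-derived estimates.
#' @param costs See [cea_costs()].
#' @param utilities See [cea_utilities()].
#' @param wtp Willingness to pay (2015 US$) per QALY over the 5-year
#'   program (default 4450.12).
#' @return List of class `cea_inputs`.
#' @export
cea_inputs <- function(p_t2d = c(HR = 0.35, MR = 0.15, LR = 0.05,
                                 ALL = 0.14),
                       costs = cea_costs(), utilities = cea_utilities(),
                       wtp = 4450.12) {
  stopifnot(all(p_t2d >= 0 & p_t2d <= 1), wtp > 0)
  stopifnot(all(utilities$efficacy >= 0 & utilities$efficacy <= 1))
  structure(list(p_t2d = p_t2d, costs = costs, utilities = utilities,
                 wtp = wtp),
            class = "cea_inputs")
}

#' Screening-and-intervention strategy specification
#'
#' A strategy names its screening tests, how the screened population splits
#' into risk groups, and which intervention each group receives. The
#' screening cost per person is the sum of the per-test assay costs plus --
#' charged once per strategy, however many assays it uses -- sample
#' preparation (for strategies with at least one blood assay) and a
#' primary-care visit (for any screening at all).
#'
#' @param name Strategy label.
#' @param tests Character subset of `c("fpg", "lrs", "rf")`; empty for no
#'   screening.
#' @param groups Tibble with columns `group` (e.g. HR/MR/LR/ALL), `prob`
#'   (must sum to 1) and `intervention`
#'   (`"none"`, `"lifestyle"` or `"metformin"`).
#' @param costs Cost list used to price the screen.
#' @return List of class `strategy_spec` with a computed `screen_cost`.
#' @export
strategy_spec <- function(name, tests, groups, costs = cea_costs()) {
  stopifnot(all(tests %in% c("fpg", "lrs", "rf")))
  groups <- tibble::as_tibble(groups)
  assert_columns(groups, c("group", "prob", "intervention"), "groups")
  if (abs(sum(groups$prob) - 1) > 1e-8) {
    stop("risk-group probabilities must sum to 1", call. = FALSE)
  }
  stopifnot(all(groups$intervention %in% c("none", "lifestyle", "metformin")))
  assay <- sum(c(fpg = costs$fpg_test, lrs = costs$lrs_assay,
                 rf = costs$rf_questionnaire)[tests])
  blood <- any(tests %in% c("fpg", "lrs"))
  screen_cost <- if (length(tests) == 0L) 0 else {
    assay + (if (blood) costs$sample_prep else 0) + costs$visit
  }
  structure(list(name = name, tests = tests, groups = groups,
                 screen_cost = unname(screen_cost)),
            class = "strategy_spec")
}

#' The seven default screening strategies
#'
#' No screening; fasting plasma glucose (FPG) followed by lifestyle
#' intervention or by metformin for the impaired-fasting-glucose group;
#' lipidomic risk score (LRS) followed by metformin or by lifestyle for the
#' high-score group; FPG and LRS combined; and risk-factor assessment (RF)
#' combined with the LRS. High/moderate/low-risk group frequencies are
#' cohort-dependent; the presets for `"familial"` and `"population"`
#' emulate a younger family cohort and an older population cohort and are
#' synthetic placeholders -- supply your own `group_probs` for real use
#' (e.g. from the score's ROC-derived cutoff, see [youden_cutoff()]).
#'
#' @param costs Cost list ([cea_costs()]).
#' @param cohort Which group-frequency preset to use.
#' @param group_probs Optional named list overriding the preset: one
#'   numeric vector of group probabilities per strategy name.
#' @return Named list of [strategy_spec()] objects, length 7.
#' @export
build_default_strategies <- function(costs = cea_costs(),
                                     cohort = c("familial", "population"),
                                     group_probs = NULL) {
  cohort <- match.arg(cohort)
  gp <- list(
    familial = list(
      no_screening = c(ALL = 1),
      fpg_lifestyle = c(HR = 0.26, LR = 0.74),
      lrs_metformin = c(HR = 0.33, LR = 0.67),
      lrs_lifestyle = c(HR = 0.33, LR = 0.67),
      fpg_metformin = c(HR = 0.26, LR = 0.74),
      fpg_lrs_combined = c(HR = 0.14, MR = 0.31, LR = 0.55),
      rf_lrs = c(HR = 0.20, MR = 0.27, LR = 0.53)),
    population = list(
      no_screening = c(ALL = 1),
      fpg_lifestyle = c(HR = 0.38, LR = 0.62),
      lrs_metformin = c(HR = 0.33, LR = 0.67),
      lrs_lifestyle = c(HR = 0.33, LR = 0.67),
      fpg_metformin = c(HR = 0.38, LR = 0.62),
      fpg_lrs_combined = c(HR = 0.19, MR = 0.33, LR = 0.48),
      rf_lrs = c(HR = 0.24, MR = 0.30, LR = 0.46))
  )[[cohort]]
  if (!is.null(group_probs)) gp[names(group_probs)] <- group_probs
  grp <- function(probs, interventions) {
    tibble::tibble(group = names(probs), prob = unname(probs),
                   intervention = interventions)
  }
  list(
    no_screening = strategy_spec("no_screening", character(0),
                                 grp(gp$no_screening, "none"), costs),
    fpg_lifestyle = strategy_spec("fpg_lifestyle", "fpg",
                                  grp(gp$fpg_lifestyle,
                                      c("lifestyle", "none")), costs),
    lrs_metformin = strategy_spec("lrs_metformin", "lrs",
                                  grp(gp$lrs_metformin,
                                      c("metformin", "none")), costs),
    lrs_lifestyle = strategy_spec("lrs_lifestyle", "lrs",
                                  grp(gp$lrs_lifestyle,
                                      c("lifestyle", "none")), costs),
    fpg_metformin = strategy_spec("fpg_metformin", "fpg",
                                  grp(gp$fpg_metformin,
                                      c("metformin", "none")), costs),
    fpg_lrs_combined = strategy_spec("fpg_lrs_combined", c("fpg", "lrs"),
                                     grp(gp$fpg_lrs_combined,
                                         c("lifestyle", "metformin",
                                           "none")), costs),
    rf_lrs = strategy_spec("rf_lrs", c("rf", "lrs"),
                           grp(gp$rf_lrs,
                               c("lifestyle", "metformin", "none")), costs)
  )
}

#' Decision tree of a strategy
#'
#' Mechanical construction: screen -> chance node over risk groups ->
#' intervention -> chance node over 5-year diabetes status -> cost/QALY
#' leaf. The treated 5-year diabetes probability is
#' `p_group * (1 - efficacy)`.
#'
#' @param strategy A [strategy_spec()].
#' @param inputs A [cea_inputs()].
#' @return Nested list of `chance` nodes (`branches` of `(prob, node)`)
#'   and `leaf` nodes (payoff `cost`, `qaly`, `t2d`).
#' @export
build_tree <- function(strategy, inputs) {
  stopifnot(inherits(strategy, "strategy_spec"),
            inherits(inputs, "cea_inputs"))
  leaf <- function(cost, qaly, t2d) {
    list(type = "leaf", cost = cost, qaly = qaly, t2d = t2d)
  }
  branches <- purrr::pmap(strategy$groups, function(group, prob,
                                                    intervention) {
    if (!group %in% names(inputs$p_t2d)) {
      stop("no 5-year probability for group ", group, call. = FALSE)
    }
    p0 <- inputs$p_t2d[[group]]
    eff <- inputs$utilities$efficacy[[intervention]]
    p <- p0 * (1 - eff)
    base_cost <- strategy$screen_cost +
      inputs$costs$intervention_5y[[intervention]]
    t2d_node <- list(
      type = "chance",
      branches = list(
        list(prob = p,
             node = leaf(base_cost + inputs$costs$medical_5y[["t2d"]],
                         inputs$utilities$qaly_5y$t2d[[intervention]], 1)),
        list(prob = 1 - p,
             node = leaf(base_cost + inputs$costs$medical_5y[["no_t2d"]],
                         inputs$utilities$qaly_5y$no_t2d[[intervention]],
                         0))))
    list(prob = prob, node = t2d_node)
  })
  list(type = "chance", branches = branches)
}

#' Roll back a decision tree
#'
#' Expected cost, QALYs and diabetes probability by backward induction.
#' Chance-node probabilities must sum to 1.
#'
#' @param node A tree from [build_tree()] (or any nested chance/leaf
#'   structure with `cost`, `qaly`, `t2d` payoffs).
#' @return Named numeric vector `c(cost, qaly, t2d)`.
#' @export
rollback <- function(node) {
  if (identical(node$type, "leaf")) {
    return(c(cost = node$cost, qaly = node$qaly, t2d = node$t2d))
  }
  probs <- vapply(node$branches, `[[`, numeric(1), "prob")
  if (abs(sum(probs) - 1) > 1e-8) {
    stop("chance node probabilities must sum to 1", call. = FALSE)
  }
  vals <- vapply(node$branches, function(b) rollback(b$node), numeric(3))
  drop(vals %*% probs)
}

#' Expected cost and effectiveness of a set of strategies
#'
#' Rolls back every strategy's tree and reports expected cost, expected
#' QALYs, expected 5-year diabetes probability and the expected risk
#' reduction relative to the same groups untreated
#' (`sum_g prob_g * p_g * efficacy_g`).
#'
#' @param strategies Named list of [strategy_spec()]s.
#' @param inputs A [cea_inputs()].
#' @return Tibble of class `cea_result` with one row per strategy.
#' @export
cea_rollback <- function(strategies, inputs) {
  rows <- purrr::map(strategies, function(s) {
    ev <- rollback(build_tree(s, inputs))
    rr <- sum(purrr::pmap_dbl(s$groups, function(group, prob, intervention) {
      prob * inputs$p_t2d[[group]] *
        inputs$utilities$efficacy[[intervention]]
    }))
    tibble::tibble(strategy = s$name, cost = ev[["cost"]],
                   qaly = ev[["qaly"]], p_t2d = ev[["t2d"]],
                   risk_reduction = rr)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cea_result", class(out))
  attr(out, "wtp") <- inputs$wtp
  out
}

#' Incremental cost-effectiveness ratios and net monetary benefit
#'
#' ICER is incremental cost per incremental QALY versus the reference
#' strategy; strategies with non-positive incremental QALYs do not have a
#' meaningful ICER and are flagged (`dominated` when they also cost at
#' least as much as the reference). Net monetary benefit is
#' `WTP * QALY - cost`.
#'
#' @param results A [cea_rollback()] tibble.
#' @param reference Reference strategy name (conventionally the most
#'   cost-effective one).
#' @param wtp Willingness to pay per QALY over the program.
#' @return The results tibble with `icer`, `nmb`, `icer_defined` and
#'   `dominated` columns.
#' @export
icer_nmb <- function(results, reference, wtp = attr(results, "wtp")) {
  if (nrow(results) < 2L) stop("need at least 2 strategies", call. = FALSE)
  if (!reference %in% results$strategy) {
    stop("unknown reference strategy", call. = FALSE)
  }
  ref <- results[results$strategy == reference, ]
  d_cost <- results$cost - ref$cost
  d_qaly <- results$qaly - ref$qaly
  out <- results
  out$icer <- ifelse(d_qaly > 0, d_cost / d_qaly, NA_real_)
  out$icer_defined <- d_qaly > 0
  out$dominated <- d_qaly <= 0 & d_cost >= 0 &
    results$strategy != reference
  out$nmb <- wtp * results$qaly - results$cost
  out$reference <- results$strategy == reference
  class(out) <- class(results)
  attr(out, "wtp") <- wtp
  out
}

# Set a nested input parameter addressed as "p_t2d.HR",
# "costs.intervention_5y.lifestyle", "utilities.efficacy.metformin", ...
set_cea_param <- function(inputs, parameter, value) {
  parts <- strsplit(parameter, ".", fixed = TRUE)[[1]]
  x <- unclass(inputs)
  if (length(parts) == 1L) {
    x[[parts]] <- value
  } else if (length(parts) == 2L) {
    x[[parts[1]]][[parts[2]]] <- value
  } else if (length(parts) == 3L) {
    x[[parts[1]]][[parts[2]]][[parts[3]]] <- value
  } else {
    stop("parameter paths deeper than 3 are not supported", call. = FALSE)
  }
  class(x) <- "cea_inputs"
  x
}

get_cea_param <- function(inputs, parameter) {
  parts <- strsplit(parameter, ".", fixed = TRUE)[[1]]
  out <- unclass(inputs)
  for (p in parts) out <- out[[p]]
  out
}

#' Default one-way sensitivity ranges
#'
#' Brackets each major input around its base case. Cohort-derived
#' probabilities are the least certain inputs and get wide (plus/minus 50%
#' relative) ranges; trial-reported costs and efficacies are bracketed more
#' tightly (plus/minus 10-20%).
#'
#' @param inputs A [cea_inputs()].
#' @return Tibble with `parameter`, `low`, `high`.
#' @export
default_tornado_ranges <- function(inputs) {
  p <- inputs$p_t2d
  half <- function(x) c(max(0.5 * x, 0.001), min(1.5 * x, 0.99))
  rows <- list(
    list("p_t2d.HR", half(p[["HR"]])),
    list("p_t2d.MR", half(p[["MR"]])),
    list("p_t2d.LR", half(p[["LR"]])),
    list("costs.intervention_5y.lifestyle",
         c(0.8, 1.2) * inputs$costs$intervention_5y[["lifestyle"]]),
    list("costs.intervention_5y.metformin",
         c(0.8, 1.2) * inputs$costs$intervention_5y[["metformin"]]),
    list("costs.medical_5y.t2d",
         c(0.9, 1.1) * inputs$costs$medical_5y[["t2d"]]),
    list("utilities.efficacy.lifestyle", c(0.48, 0.68)),
    list("utilities.efficacy.metformin", c(0.21, 0.41))
  )
  tibble::tibble(parameter = vapply(rows, `[[`, character(1), 1),
                 low = vapply(rows, function(r) r[[2]][1], numeric(1)),
                 high = vapply(rows, function(r) r[[2]][2], numeric(1)))
}

#' Tornado (one-way) sensitivity analysis
#'
#' Evaluates the expected value at each end of every parameter range (all
#' other inputs at base case) and sorts parameters by the absolute swing.
#' The expected value is the net monetary benefit of a chosen strategy, or
#' of the per-scenario best strategy (`strategy = NULL`, the decision-level
#' expected value).
#'
#' @param strategies Named list of [strategy_spec()]s.
#' @param inputs Base-case [cea_inputs()].
#' @param ranges Tibble `parameter`/`low`/`high` (default
#'   [default_tornado_ranges()]); ranges must bracket the base case.
#' @param strategy Strategy whose net monetary benefit is tracked, or
#'   `NULL` for the best strategy per scenario.
#' @return Tibble of class `cea_tornado`, sorted by decreasing `|swing|`.
#' @export
tornado <- function(strategies, inputs, ranges = default_tornado_ranges(inputs),
                    strategy = NULL) {
  ev <- function(inp) {
    res <- cea_rollback(strategies, inp)
    nmb <- inp$wtp * res$qaly - res$cost
    if (is.null(strategy)) max(nmb) else nmb[res$strategy == strategy]
  }
  base_ev <- ev(inputs)
  rows <- purrr::pmap(ranges, function(parameter, low, high) {
    base_val <- get_cea_param(inputs, parameter)
    if (low > base_val || high < base_val) {
      stop("range for ", parameter, " does not bracket the base case",
           call. = FALSE)
    }
    ev_lo <- ev(set_cea_param(inputs, parameter, low))
    ev_hi <- ev(set_cea_param(inputs, parameter, high))
    tibble::tibble(parameter = parameter, low = low, high = high,
                   ev_low = ev_lo, ev_high = ev_hi,
                   swing = abs(ev_hi - ev_lo))
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::arrange(dplyr::desc(.data$swing))
  attr(out, "base_ev") <- base_ev
  class(out) <- c("cea_tornado", class(out))
  out
}

#' One-way microsimulation sensitivity analysis
#'
#' Samples the chosen parameter uniformly across its range, rolls back
#' every strategy per run, and smooths each strategy's expected value
#' against the parameter with a fourth-order polynomial least-squares fit
#' (to capture non-linearity). The summary value per strategy is the mean
#' cost/QALY ratio over runs.
#'
#' @param strategies Named list of [strategy_spec()]s.
#' @param inputs Base-case [cea_inputs()].
#' @param parameter Parameter path (e.g. `"p_t2d.HR"`).
#' @param range Length-2 numeric range to sample.
#' @param n_runs Number of runs (>= 10; 1000 recommended).
#' @param value Which expected value to smooth: cost/QALY ratio, net
#'   monetary benefit, cost or QALYs.
#' @param seed Optional seed; fixed seed reproduces the curves exactly.
#' @return Object of class `cea_microsim`: per-run values, fitted degree-4
#'   polynomial coefficients and smoothed curves per strategy, and mean
#'   cost/QALY ratios.
#' @export
one_way_microsim <- function(strategies, inputs, parameter, range,
                             n_runs = 1000,
                             value = c("cost_per_qaly", "nmb", "cost",
                                       "qaly"),
                             seed = NULL) {
  value <- match.arg(value)
  if (n_runs < 10) stop("n_runs must be at least 10", call. = FALSE)
  stopifnot(length(range) == 2L, range[1] < range[2])
  with_seed(seed, {
    x <- stats::runif(n_runs, range[1], range[2])
    runs <- purrr::map_dfr(seq_len(n_runs), function(i) {
      res <- cea_rollback(strategies,
                          set_cea_param(inputs, parameter, x[i]))
      res$run <- i
      res$param_value <- x[i]
      res
    })
    runs$nmb <- inputs$wtp * runs$qaly - runs$cost
    runs$cost_per_qaly <- runs$cost / runs$qaly
    fits <- runs |>
      dplyr::group_by(.data$strategy) |>
      dplyr::group_map(function(g, key) {
        fit <- stats::lm(g[[value]] ~ stats::poly(g$param_value, 4,
                                                  raw = TRUE))
        grid <- seq(range[1], range[2], length.out = 101)
        co <- stats::coef(fit)
        co[is.na(co)] <- 0
        smooth <- drop(cbind(1, stats::poly(grid, 4, raw = TRUE)) %*% co)
        ss_res <- sum(stats::resid(fit)^2)
        ss_tot <- sum((g[[value]] - mean(g[[value]]))^2)
        list(strategy = key$strategy, coefficients = unname(co),
             curve = tibble::tibble(param_value = grid, fitted = smooth),
             r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1)
      })
    curves <- purrr::map_dfr(fits, function(f) {
      dplyr::mutate(f$curve, strategy = f$strategy)
    })
    means <- runs |>
      dplyr::group_by(.data$strategy) |>
      dplyr::summarise(mean_cost_per_qaly = mean(.data$cost_per_qaly),
                       mean_cost = mean(.data$cost),
                       mean_qaly = mean(.data$qaly), .groups = "drop")
    structure(list(runs = runs, curves = curves, fits = fits,
                   means = means, parameter = parameter, value = value,
                   range = range, n_runs = n_runs),
              class = "cea_microsim")
  })
}
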