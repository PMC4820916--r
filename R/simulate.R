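#' Simulation configuration for synthetic cohorts
#'
#' Bundles and validates every knob of the synthetic-cohort generator:
#' a multigenerational pedigree cohort (three-generation families) with
#' exact incident-diabetes follow-up, and an unrelated cohort with
#' person-time follow-up only. Lipid species are log-normal marginally,
#' carry a polygenic (kinship-proportional) variance component and a
#' block-correlation structure across species, and a small set of candidate
#' species carries planted proportional-hazards effects on the
#' inverse-normal scale.
#'
#' @param n_families Number of three-generation families.
#' @param family_size List with `mean_children` (expected sibship of the
#'   founder couple, min 1) and `mean_grandchildren` (expected children per
#'   second-generation couple).
#' @param n_unrelated Size of the unrelated validation cohort.
#' @param n_lipid_species Number of lipid species columns (`lipid_001`...).
#' @param n_candidate_species Number of candidate species (the first
#'   columns); planted species must be among these.
#' @param planted_species Named numeric vector of per-SD log hazard ratios,
#'   names in `lipid_001 ... lipid_<n_candidate>`.
#' @param lipid_heritability Fraction of each species' variance attributable
#'   to the polygenic component, in `[0, 1]`.
#' @param lipid_block_correlation Within-block correlation across species,
#'   in `[0, 1)`; `lipid_block_size` sets the block width.
#' @param lipid_block_size Species per correlation block.
#' @param baseline_hazard Baseline event rate per person-year.
#' @param weibull_shape Shape of the baseline event-time law (1 =
#'   exponential).
#' @param covariate_hazard Named log-hazard effects for `age` (per year,
#'   centered), `male`, `bmi` (per unit, centered) and `prediabetes`.
#' @param visit_interval_years Spacing of follow-up visits.
#' @param max_followup_years Administrative censoring horizon for the
#'   pedigree cohort.
#' @param dropout_rate Exponential dropout rate per person-year.
#' @param event_time_convention How the pedigree cohort records event
#'   times: `"exact"` (true time), `"interval_midpoint"` or `"visit_date"`.
#' @param unrelated_followup_years Maximum follow-up of the unrelated
#'   cohort; individual follow-up is uniform on 60-100% of it.
#' @param person_time_convention Exposure recorded for the unrelated
#'   cohort: `"at_risk"` (time to event or end of follow-up) or
#'   `"full_followup"` (whole follow-up length regardless of events).
#' @param prediabetes_model List of logistic coefficients (`intercept`,
#'   `age` per year over 45, `bmi` per unit over 29) for baseline
#'   prediabetes.
#' @param seed Integer seed; together with the config it fully determines
#'   every generated table.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_families = 40,
                       family_size = list(mean_children = 3.5,
                                          mean_grandchildren = 2.8),
                       n_unrelated = 644,
                       n_lipid_species = 319,
                       n_candidate_species = min(10, n_lipid_species),
                       planted_species = c(lipid_001 = 0.42,
                                           lipid_002 = -0.34,
                                           lipid_003 = 0.54),
                       lipid_heritability = 0.3,
                       lipid_block_correlation = 0.3,
                       lipid_block_size = 10,
                       baseline_hazard = 0.013,
                       weibull_shape = 1,
                       covariate_hazard = c(age = 0.035, male = 0.25,
                                            bmi = 0.04, prediabetes = 0.8),
                       visit_interval_years = 5,
                       max_followup_years = 23,
                       dropout_rate = 0.015,
                       event_time_convention = c("exact", "interval_midpoint",
                                                 "visit_date"),
                       unrelated_followup_years = 13,
                       person_time_convention = c("at_risk", "full_followup"),
                       prediabetes_model = list(intercept = -1.6, age = 0.035,
                                                bmi = 0.09),
                       seed = 1L) {
  event_time_convention <- match.arg(event_time_convention)
  person_time_convention <- match.arg(person_time_convention)
  stopifnot(n_families >= 0, n_unrelated >= 0, n_lipid_species >= 1,
            n_candidate_species >= 1,
            n_candidate_species <= n_lipid_species,
            baseline_hazard > 0, weibull_shape > 0,
            visit_interval_years > 0, max_followup_years > 0,
            dropout_rate >= 0, unrelated_followup_years > 0,
            lipid_block_size >= 1)
  assert_fraction(lipid_heritability, "lipid_heritability")
  assert_fraction(lipid_block_correlation, "lipid_block_correlation",
                  upper = 1, upper_open = TRUE)
  candidates <- species_names(n_candidate_species)
  if (length(planted_species) > 0) {
    if (is.null(names(planted_species)) ||
        !all(names(planted_species) %in% candidates)) {
      stop("planted_species must be named and lie within the candidate set",
           call. = FALSE)
    }
  }
  structure(
    list(n_families = as.integer(n_families), family_size = family_size,
         n_unrelated = as.integer(n_unrelated),
         n_lipid_species = as.integer(n_lipid_species),
         n_candidate_species = as.integer(n_candidate_species),
         planted_species = planted_species,
         lipid_heritability = lipid_heritability,
         lipid_block_correlation = lipid_block_correlation,
         lipid_block_size = as.integer(lipid_block_size),
         baseline_hazard = baseline_hazard, weibull_shape = weibull_shape,
         covariate_hazard = covariate_hazard,
         visit_interval_years = visit_interval_years,
         max_followup_years = max_followup_years,
         dropout_rate = dropout_rate,
         event_time_convention = event_time_convention,
         unrelated_followup_years = unrelated_followup_years,
         person_time_convention = person_time_convention,
         prediabetes_model = prediabetes_model,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

species_names <- function(n) sprintf("lipid_%03d", seq_len(n))

# Log-normal location/scale per species, drawn from a seed-derived stream so
# both cohorts share the same species-level parameters.
species_params <- function(config) {
  with_seed(config$seed, {
    n <- config$n_lipid_species
    tibble::tibble(species = species_names(n),
                   meanlog = stats::runif(n, -1, 2),
                   sdlog = stats::runif(n, 0.35, 0.7))
  })
}

# Upper Cholesky factor of the block-correlation species covariance.
species_chol <- function(config) {
  n <- config$n_lipid_species
  bs <- config$lipid_block_size
  rho <- config$lipid_block_correlation
  sig <- matrix(0, n, n)
  blocks <- split(seq_len(n), ceiling(seq_len(n) / bs))
  for (b in blocks) sig[b, b] <- rho
  diag(sig) <- 1
  chol(sig)
}

# One three-generation family: founder couple, their children with
# married-in spouses, and grandchildren.
simulate_family <- function(fam, fs) {
  id <- function(k) sprintf("fam%03d_i%03d", fam, k)
  k <- 0L
  nxt <- function() { k <<- k + 1L; id(k) }
  rows <- list()
  add <- function(i, f, m, sex, gen) {
    rows[[length(rows) + 1L]] <<- list(id = i, father = f, mother = m,
                                       sex = sex, generation = gen)
  }
  g1f <- nxt(); add(g1f, NA, NA, 1L, 1L)
  g1m <- nxt(); add(g1m, NA, NA, 2L, 1L)
  n_child <- 1L + stats::rpois(1, max(fs$mean_children - 1, 0))
  for (j in seq_len(n_child)) {
    child <- nxt()
    sex_c <- sample(1:2, 1)
    add(child, g1f, g1m, sex_c, 2L)
    spouse <- nxt()
    add(spouse, NA, NA, 3L - sex_c, 2L)
    n_gc <- stats::rpois(1, fs$mean_grandchildren)
    for (g in seq_len(n_gc)) {
      gc_id <- nxt()
      if (sex_c == 1L) add(gc_id, child, spouse, sample(1:2, 1), 3L)
      else add(gc_id, spouse, child, sample(1:2, 1), 3L)
    }
  }
  df <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  df$family <- sprintf("fam%03d", fam)
  df
}

# Covariate block shared by both cohorts; ages supplied by the caller.
simulate_covariates <- function(n, age, sex, prediabetes_model) {
  bmi <- pmin(pmax(stats::rnorm(n, 29, 4.5), 18), 45)
  waist <- 15 + 2.4 * bmi + stats::rnorm(n, 0, 5)
  sbp <- 105 + 0.5 * (age - 45) + stats::rnorm(n, 0, 12)
  dbp <- 68 + 0.2 * (age - 45) + stats::rnorm(n, 0, 8)
  total_chol <- pmax(stats::rnorm(n, 5.1, 0.9), 2.5)
  hdl_chol <- pmax(stats::rnorm(n, 1.3, 0.3), 0.5)
  triglycerides <- stats::rlnorm(n, log(1.4), 0.45)
  lipid_drug <- stats::rbinom(n, 1, stats::plogis(-3 + 0.04 * (age - 45)))
  bp_drug <- stats::rbinom(n, 1, stats::plogis(-2.6 + 0.05 * (age - 45)))
  family_history <- stats::rbinom(n, 1, 0.3)
  pm <- prediabetes_model
  p_pre <- stats::plogis(pm$intercept + pm$age * (age - 45) +
                           pm$bmi * (bmi - 29))
  glycemic_class <- ifelse(stats::runif(n) < p_pre, "prediabetes", "NGT")
  fpg <- ifelse(glycemic_class == "NGT",
                stats::runif(n, 80, 99.5), stats::runif(n, 100, 125))
  tibble::tibble(
    sex = sex, age = age, bmi = bmi, waist = waist, sbp = sbp, dbp = dbp,
    total_chol = total_chol, hdl_chol = hdl_chol,
    triglycerides = triglycerides, lipid_drug = lipid_drug,
    bp_drug = bp_drug, family_history = family_history,
    glycemic_class = glycemic_class, fpg = fpg,
    fpi = stats::rlnorm(n, log(9), 0.4),
    leptin = stats::rlnorm(n, log(12), 0.5),
    adiponectin = stats::rlnorm(n, log(8), 0.4)
  )
}

# Planted + covariate log-hazard linear predictor (centered).
hazard_lp <- function(cohort, config) {
  lp <- numeric(nrow(cohort))
  for (s in names(config$planted_species)) {
    lp <- lp + config$planted_species[[s]] * inverse_normalize(cohort[[s]])
  }
  ch <- config$covariate_hazard
  lp <- lp + ch[["age"]] * (cohort$age - mean(cohort$age)) +
    ch[["male"]] * (cohort$sex == 1L) +
    ch[["bmi"]] * (cohort$bmi - mean(cohort$bmi)) +
    ch[["prediabetes"]] * (cohort$glycemic_class == "prediabetes")
  lp - mean(lp)
}

# Proportional-hazards event times: H(t) = h0 * t^shape * exp(lp).
draw_event_times <- function(n, lp, config) {
  e <- stats::rexp(n)
  (e / (config$baseline_hazard * exp(lp)))^(1 / config$weibull_shape)
}

#' Simulate a pedigree-structured cohort with incident-diabetes follow-up
#'
#' Builds `n_families` three-generation pedigrees, draws lipid species with
#' polygenic covariance `h2 * R + (1 - h2) * I` per species (`R` the
#' family relationship matrix), assigns covariates and baseline glycemic
#' class, and draws event times from a proportional-hazards model whose
#' linear predictor carries the planted per-SD log hazard ratios on the
#' inverse-normal scale of the planted species plus modest covariate
#' effects. Follow-up is censored at `max_followup_years` or at an
#' exponential dropout time; no subject has diabetes at baseline.
#'
#' @param config A [sim_config()].
#' @return A list with `cohort` (tibble: one row per subject with
#'   covariates, `lipid_*` concentrations, `glycemic_class`, `event`,
#'   `time` in years) and `pedigree` (a [as_pedigree()] tibble with a
#'   `family` column).
#' @export
simulate_pedigree_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_families < 1L) stop("n_families must be >= 1", call. = FALSE)
  sp <- species_params(config)
  chol_s <- species_chol(config)
  with_seed(config$seed + 1L, {
    peds <- lapply(seq_len(config$n_families), simulate_family,
                   fs = config$family_size)
    ped_all <- dplyr::bind_rows(peds)
    h2 <- config$lipid_heritability
    lip_rows <- vector("list", length(peds))
    for (f in seq_along(peds)) {
      pf <- peds[[f]]
      K <- build_relationship_matrix(
        pf[, c("id", "father", "mother", "sex")])
      A <- h2 * K + (1 - h2) * diag(nrow(K))
      Z <- matrix(stats::rnorm(nrow(K) * config$n_lipid_species), nrow(K))
      lip_rows[[f]] <- t(chol(A)) %*% Z %*% chol_s
    }
    X <- do.call(rbind, lip_rows)
    conc <- sweep(sweep(X, 2, sp$sdlog, `*`), 2, sp$meanlog, `+`)
    conc <- exp(conc)
    colnames(conc) <- sp$species
    n <- nrow(ped_all)
    age <- ifelse(ped_all$generation == 1L, stats::runif(n, 58, 75),
                  ifelse(ped_all$generation == 2L, stats::runif(n, 35, 55),
                         stats::runif(n, 18, 34)))
    cov <- simulate_covariates(n, age, ped_all$sex, config$prediabetes_model)
    cohort <- dplyr::bind_cols(
      tibble::tibble(id = ped_all$id, family = ped_all$family), cov,
      tibble::as_tibble(conc))
    lp <- hazard_lp(cohort, config)
    t_event <- draw_event_times(n, lp, config)
    cens <- pmin(config$max_followup_years,
                 if (config$dropout_rate > 0)
                   stats::rexp(n, config$dropout_rate) else Inf)
    obs <- observe_events(t_event, cens, config)
    cohort$event <- obs$event
    cohort$time <- obs$time
    pedigree <- as_pedigree(ped_all[, c("id", "father", "mother", "sex")])
    pedigree$family <- ped_all$family
    list(cohort = cohort, pedigree = pedigree)
  })
}

# Apply the event-time recording convention of the pedigree cohort.
observe_events <- function(t_event, cens, config) {
  event <- t_event <= cens
  time <- pmin(t_event, cens)
  if (config$event_time_convention != "exact") {
    iv <- config$visit_interval_years
    visit <- iv * ceiling(t_event / iv)
    seen <- event & visit <= cens & visit <= config$max_followup_years
    time[event & !seen] <- cens[event & !seen]
    event <- seen
    if (config$event_time_convention == "visit_date") {
      time[event] <- visit[event]
    } else {
      time[event] <- visit[event] - iv / 2
    }
  }
  list(event = as.integer(event), time = pmax(time, 1e-6))
}

#' Simulate an unrelated cohort with person-time follow-up
#'
#' Same lipid and covariate model as [simulate_pedigree_cohort()] but with
#' no family structure (identity relationship matrix) and an older age
#' range. The outcome is recorded the way interval-surveyed cohorts record
#' it: an event indicator by end of follow-up plus person-years exposure,
#' with no exact event date column.
#'
#' @inheritParams simulate_pedigree_cohort
#' @return A cohort tibble with `events` (0/1 by end of follow-up) and
#'   `person_years` exposure.
#' @export
simulate_unrelated_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_unrelated
  sp <- species_params(config)
  if (n == 0L) {
    empty <- tibble::tibble(id = character(0))
    return(empty)
  }
  chol_s <- species_chol(config)
  with_seed(config$seed + 2L, {
    Z <- matrix(stats::rnorm(n * config$n_lipid_species), n)
    conc <- exp(sweep(sweep(Z %*% chol_s, 2, sp$sdlog, `*`),
                      2, sp$meanlog, `+`))
    colnames(conc) <- sp$species
    age <- stats::runif(n, 45, 75)
    sex <- sample(1:2, n, replace = TRUE)
    cov <- simulate_covariates(n, age, sex, config$prediabetes_model)
    cohort <- dplyr::bind_cols(
      tibble::tibble(id = sprintf("unrel_%04d", seq_len(n))), cov,
      tibble::as_tibble(conc))
    lp <- hazard_lp(cohort, config)
    t_event <- draw_event_times(n, lp, config)
    fu <- config$unrelated_followup_years * stats::runif(n, 0.6, 1)
    cohort$events <- as.integer(t_event <= fu)
    cohort$person_years <- if (config$person_time_convention == "at_risk") {
      pmax(pmin(t_event, fu), 1e-6)
    } else {
      fu
    }
    cohort
  })
}

#' Couple insulin-resistance measures to the planted lipid signal
#'
#' Regenerates fasting plasma glucose and insulin, leptin and adiponectin
#' with a monotone dependence of strength `coupling` on the planted-species
#' linear predictor (the same weighted sum of inverse-normalized planted
#' species that drives the simulated hazard). Glucose stays inside the
#' range consistent with each subject's baseline glycemic class, so the
#' class/FPG invariant is preserved.
#'
#' @param cohort A cohort tibble carrying the planted species columns.
#' @param coupling Dependence strength in `[-1, 1]`; 0 leaves the measures
#'   independent of the lipid signal.
#' @param planted Named per-SD weights defining the lipid signal
#'   (defaults to the [sim_config()] planted set).
#' @param seed Optional seed for reproducibility.
#' @return The cohort with `fpg`, `fpi`, `leptin`, `adiponectin` replaced.
#' @export
simulate_ir_measures <- function(cohort, coupling,
                                 planted = sim_config()$planted_species,
                                 seed = NULL) {
  assert_fraction(coupling, "coupling", lower = -1, upper = 1)
  assert_columns(cohort, c(names(planted), "glycemic_class"))
  n <- nrow(cohort)
  lp <- numeric(n)
  for (s in names(planted)) {
    lp <- lp + planted[[s]] * inverse_normalize(cohort[[s]])
  }
  z <- as.numeric(scale(lp))
  with_seed(seed, {
    mix <- function() coupling * z +
      sqrt(1 - coupling^2) * stats::rnorm(n)
    u_fpi <- mix(); u_fpg <- mix(); u_lep <- mix(); u_adi <- mix()
    out <- tibble::as_tibble(cohort)
    out$fpi <- exp(log(9) + 0.45 * u_fpi)
    pre <- out$glycemic_class == "prediabetes"
    lo <- ifelse(pre, 100, 80)
    hi <- ifelse(pre, 125, 99.5)
    out$fpg <- lo + (hi - lo) * stats::pnorm(u_fpg)
    out$leptin <- exp(log(12) + 0.4 * u_lep)
    out$adiponectin <- exp(log(8) - 0.35 * u_adi)
    out
  })
}

#' Write a simulated cohort and its pedigree to disk
#'
#' Cohort as tab-separated values, pedigree as a PED-style file, config as
#' JSON.
#'
#' @param sim Result of [simulate_pedigree_cohort()].
#' @param dir Output directory (created if needed).
#' @param config Optional [sim_config()] to store alongside.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir, config = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(sim$cohort, file.path(dir, "cohort.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(sim$pedigree)) write_ped(sim$pedigree, file.path(dir, "pedigree.ped"))
  if (!is.null(config)) {
    jsonlite::write_json(unclass(config), file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
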