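test_that("with no frailty the fit matches the partial-likelihood oracle", {
  d <- toy_survival(n = 120, beta = 0.6, cens = 0.03, seed = 3)
  # inject tied event times to exercise the Efron correction
  d$time <- round(d$time * 4) / 4 + 0.01
  fit <- fit_frailty_cox(d, c("x", "z"))
  oracle <- survival::coxph(survival::Surv(time, event) ~ x + z, data = d,
                            ties = "efron")
  expect_lt(max(abs(fit$coefficients - coef(oracle))), 1e-4)
  expect_lt(max(abs(fit$se - sqrt(diag(vcov(oracle))))), 1e-4)
  expect_equal(fit$loglik, oracle$loglik[2], tolerance = 1e-8)
  expect_equal(fit$AIC, -2 * oracle$loglik[2] + 2 * 2, tolerance = 1e-6)
  # identity kinship with sigma2 fixed at zero takes the same path
  K <- diag(nrow(d))
  fit0 <- fit_frailty_cox(d, c("x", "z"), kinship = K, sigma2 = 0)
  expect_equal(fit0$coefficients, fit$coefficients, tolerance = 1e-10)
})

test_that("stratified fits match the stratified partial-likelihood oracle", {
  d <- toy_survival(n = 150, beta = 0.5, cens = 0.04, seed = 8)
  d$grp <- rep(c("a", "b"), length.out = nrow(d))
  fit <- fit_frailty_cox(d, "x", strata = "grp")
  oracle <- survival::coxph(
    survival::Surv(time, event) ~ x + strata(grp), data = d, ties = "efron")
  expect_lt(abs(fit$coefficients[["x"]] - coef(oracle)[["x"]]), 1e-5)
  expect_equal(fit$loglik, oracle$loglik[2], tolerance = 1e-8)
})

test_that("degenerate inputs are rejected", {
  d <- toy_survival(n = 60, seed = 2)
  d$const <- 1
  expect_error(fit_frailty_cox(d, c("x", "const")), "singular|constant")
  d0 <- d; d0$event <- 0L
  expect_error(fit_frailty_cox(d0, "x"), "event")
  dneg <- d; dneg$time[1] <- 0
  expect_error(fit_frailty_cox(dneg, "x"), "positive")
})

test_that("the frailty variance is recovered and the fit stays coherent", {
  # strong familial clustering: shared sibship random effect
  set.seed(42)
  cfg <- sim_config(n_families = 30, n_unrelated = 0, n_lipid_species = 4,
                    planted_species = c(lipid_001 = 0),
                    baseline_hazard = 0.02, seed = 42)
  sim <- simulate_pedigree_cohort(cfg)
  K <- build_relationship_matrix(sim$pedigree)
  d <- sim$cohort
  # overlay a polygenic log-frailty with variance 1 on new event times
  b <- drop(t(chol(K + 1e-8 * diag(nrow(K)))) %*% rnorm(nrow(K)))
  d$time <- rexp(nrow(d), 0.02 * exp(b))
  d$event <- as.integer(d$time <= 23)
  d$time <- pmin(d$time, 23)
  fit <- fit_frailty_cox(d, c("age", "bmi"), kinship = K)
  expect_true(fit$converged)
  expect_gt(fit$sigma2, 0.2) # planted variance 1; profile is imprecise
  # null data: profiled variance collapses toward zero and the fit
  # reduces to the plain Cox solution
  d2 <- sim$cohort
  fit_fr <- fit_frailty_cox(d2, c("age", "bmi"), kinship = K)
  fit_pl <- fit_frailty_cox(d2, c("age", "bmi"))
  if (fit_fr$sigma2 < 1e-3) {
    expect_equal(fit_fr$coefficients, fit_pl$coefficients,
                 tolerance = 1e-6)
  } else {
    expect_lt(max(abs(fit_fr$coefficients - fit_pl$coefficients)), 0.15)
  }
})

test_that("likelihood-ratio statistics for nested fits are non-negative", {
  d <- toy_survival(n = 130, beta = 0.5, cens = 0.05, seed = 12)
  base <- fit_frailty_cox(d, "z")
  aug <- fit_frailty_cox(d, c("z", "x"))
  lt <- lr_test(base, aug)
  expect_gte(lt$statistic, 0)
  expect_equal(aug$AIC - base$AIC, -lt$statistic + 2 * 1,
               tolerance = 1e-10)
  # null model works and the global LR equals the nested chain
  null <- fit_frailty_cox(d, character(0))
  expect_equal(lr_test(null, aug)$statistic,
               lr_test(null, base)$statistic + lt$statistic,
               tolerance = 1e-8)
})

test_that("lipidome screening ranks planted species first and flags by FDR", {
  cfg <- sim_config(n_families = 18, n_unrelated = 0, n_lipid_species = 25,
                    planted_species = c(lipid_001 = 0.8, lipid_002 = -0.7),
                    baseline_hazard = 0.02, seed = 31)
  sim <- simulate_pedigree_cohort(cfg)
  K <- build_relationship_matrix(sim$pedigree)
  scr <- screen_lipidome(sim$cohort, species_names(25), kinship = K)
  expect_s3_class(scr, "lrs_screen")
  expect_setequal(scr$species, species_names(25))
  expect_true(all(c("lipid_001", "lipid_002") %in% scr$species[1:4]))
  expect_equal(sign(scr$beta[scr$species == "lipid_001"]), 1)
  expect_equal(sign(scr$beta[scr$species == "lipid_002"]), -1)
  # BH column equals the definitional oracle on the same p-values
  expect_equal(scr$p_adj, bh_oracle(scr$p), tolerance = 1e-12)
  # fdr_threshold = 1 flags every convergent species
  scr_all <- screen_lipidome(sim$cohort, species_names(25),
                             fdr_threshold = 1, sigma2 = 0)
  expect_true(all(scr_all$significant[!is.na(scr_all$p)]))
})

test_that("backward elimination keeps strong candidates, drops noise, and is order invariant", {
  cfg <- sim_config(n_families = 20, n_unrelated = 0, n_lipid_species = 10,
                    planted_species = c(lipid_001 = 0.9),
                    baseline_hazard = 0.025, seed = 55)
  sim <- simulate_pedigree_cohort(cfg)
  cands <- species_names(6)
  el <- backward_eliminate(sim$cohort, cands, sigma2 = 0)
  expect_true("lipid_001" %in% el$retained)
  shuffled <- backward_eliminate(sim$cohort, rev(cands), sigma2 = 0)
  expect_setequal(el$retained, shuffled$retained)
  # single strong candidate is retained
  single <- backward_eliminate(sim$cohort, "lipid_001", sigma2 = 0)
  expect_equal(single$retained, "lipid_001")
  # pure-noise candidates are mostly eliminated at the alpha level
  retained_frac <- vapply(1:30, function(i) {
    cfg_i <- sim_config(n_families = 2, n_unrelated = 150,
                        n_lipid_species = 5,
                        planted_species = c(lipid_001 = 0),
                        unrelated_followup_years = 20, seed = 100 + i)
    u <- simulate_unrelated_cohort(cfg_i)
    u$time <- u$person_years
    u$event <- u$events
    el_i <- suppressWarnings(
      backward_eliminate(u, species_names(5), covariates = c("age", "bmi"),
                         alpha_stay = 0.05))
    length(el_i$retained) / 5
  }, numeric(1))
  expect_lt(mean(retained_frac), 0.2)
})

test_that("the score is the weighted sum of inverse-normalized species", {
  w <- c(0.4176, -0.3443, 0.5361)
  sp <- c("cer_d18_0_18_0", "lpc_o_22_1", "tg_16_0_18_0_18_1")
  m <- lrs_model(sp, w, training = "published")
  set.seed(1)
  d <- tibble::as_tibble(setNames(as.data.frame(matrix(rlnorm(300), 100)),
                                  sp))
  s <- score_lrs(m, d)
  manual <- w[1] * inverse_normalize(d[[sp[1]]]) +
    w[2] * inverse_normalize(d[[sp[2]]]) +
    w[3] * inverse_normalize(d[[sp[3]]])
  expect_equal(s, manual, tolerance = 1e-12)
  # all-equal inverse-normal values of zero give a zero score
  expect_equal(sum(w * rep(0, 3)), 0)
  # serialization round trip preserves scores exactly
  path <- withr::local_tempfile(fileext = ".json")
  write_lrs(m, path)
  expect_equal(score_lrs(read_lrs(path), d), s, tolerance = 1e-12)
  expect_error(lrs_model(c("a", "a"), c(1, 2)), "distinct")
  expect_error(lrs_model("a", Inf), "finite")
})

test_that("tertile hazards are monotone under a planted score effect", {
  cfg <- sim_config(n_families = 22, n_unrelated = 0, n_lipid_species = 8,
                    planted_species = c(lipid_001 = 0.7, lipid_003 = 0.7),
                    baseline_hazard = 0.02, seed = 77)
  sim <- simulate_pedigree_cohort(cfg)
  score <- inverse_normalize(sim$cohort$lipid_001) +
    inverse_normalize(sim$cohort$lipid_003)
  th <- tertile_hazards(sim$cohort, score, sigma2 = 0)
  rh <- th$relative_hazards
  for (dg in unique(rh$design)) {
    sub <- rh[rh$design == dg, ]
    up <- sub$rh[grepl("upper", sub$term)]
    mid <- sub$rh[grepl("middle", sub$term)]
    expect_gt(up, mid)
    expect_gt(up, 1)
  }
  # Kaplan-Meier curves start at survival 1 and are non-increasing
  expect_equal(km_event_fraction(th$km, 0)$event_fraction, rep(0, 3))
  for (g in unique(th$km$tertile)) {
    expect_true(all(diff(th$km$surv[th$km$tertile == g]) <= 1e-12))
  }
})

test_that("null scores give tertile hazards compatible with 1", {
  covered <- vapply(1:25, function(i) {
    cfg <- sim_config(n_families = 2, n_unrelated = 250,
                      n_lipid_species = 4,
                      planted_species = c(lipid_001 = 0),
                      unrelated_followup_years = 20, seed = 200 + i)
    u <- simulate_unrelated_cohort(cfg)
    u$time <- u$person_years
    u$event <- u$events
    score <- inverse_normalize(u$lipid_001)
    th <- tertile_hazards(u, score, covariates = c("age", "bmi"),
                          designs = "stratified")
    sub <- th$relative_hazards
    all(sub$conf.low <= 1 & sub$conf.high >= 1)
  }, logical(1))
  expect_gte(mean(covered), 0.8)
})
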