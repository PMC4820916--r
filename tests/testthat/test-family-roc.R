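test_that("Bayesian sensitivity/specificity evaluate the printed formulas", {
  expect_equal(bayes_sens_spec(0.5, 1, 0),
               tibble::tibble(sensitivity = 1, specificity = 1))
  # uninformative marker: p1 = p0 gives sens = spec = p by symmetry
  ss <- bayes_sens_spec(0.5, 0.3, 0.3)
  expect_equal(ss$sensitivity, 0.5)
  expect_equal(ss$specificity, 0.5)
  ss2 <- bayes_sens_spec(0.3, 0.4, 0.1)
  expect_equal(ss2$sensitivity, 0.12 / 0.19, tolerance = 1e-10)
  expect_equal(ss2$specificity, 0.63 / 0.81, tolerance = 1e-10)
  expect_equal(round(ss2$sensitivity, 4), 0.6316)
  expect_equal(round(ss2$specificity, 4), 0.7778)
  expect_error(bayes_sens_spec(0.5, 1.2, 0), "\\[0, 1\\]")
  expect_error(bayes_sens_spec(0, 1, 0), "denominators")
})

test_that("bayes formulas reconstruct the 2x2 table from exact prevalences", {
  set.seed(40)
  x <- rnorm(400)
  y <- as.integer(plogis(x) > runif(400))
  for (cc in quantile(x, c(0.25, 0.5, 0.75))) {
    above <- x > cc
    p <- mean(above)
    p1 <- mean(y[above]); p0 <- mean(y[!above])
    ss <- bayes_sens_spec(p, p1, p0)
    expect_equal(ss$sensitivity, mean(x[y == 1] > cc), tolerance = 1e-12)
    expect_equal(ss$specificity, mean(x[y == 0] <= cc), tolerance = 1e-12)
  }
})

test_that("liability prevalence equals the case fraction without covariates", {
  set.seed(11)
  d <- tibble::tibble(y = rbinom(1200, 1, 0.22))
  f <- estimate_prevalence(d, "y")
  expect_lt(abs(f$prevalence - mean(d$y)), 0.01)
  expect_equal(f$h2, 0)
  # case fraction one half puts the threshold at zero
  d2 <- tibble::tibble(y = rep(0:1, 250))
  expect_lt(abs(estimate_prevalence(d2, "y")$mu), 1e-6)
  # degenerate subsets clamp with a warning
  expect_warning(f0 <- estimate_prevalence(tibble::tibble(y = rep(0, 20)),
                                           "y"), "clamped")
  expect_equal(f0$prevalence, 0.025)
})

test_that("zero heritability reduces to the plain probit oracle", {
  set.seed(12)
  n <- 800
  d <- tibble::tibble(x = rnorm(n))
  d$y <- rbinom(n, 1, pnorm(-0.4 + 0.7 * d$x))
  f <- estimate_prevalence(d, "y", covariates = "x")
  oracle <- glm(y ~ x, family = binomial("probit"), data = d)
  expect_lt(abs(f$mu - coef(oracle)[1]), 1e-5)
  expect_lt(abs(f$beta[["x"]] - coef(oracle)[2]), 1e-5)
  # identity kinship with h2 forced to zero matches as well
  f2 <- estimate_prevalence(d, "y", covariates = "x",
                            kinship = diag(n), h2 = 0)
  expect_lt(abs(f2$beta[["x"]] - coef(oracle)[2]), 1e-5)
})

test_that("polygenic liability fit runs on pedigree data and is sane", {
  cfg <- sim_config(n_families = 12, n_unrelated = 0, n_lipid_species = 4,
                    seed = 19)
  sim <- simulate_pedigree_cohort(cfg)
  K <- build_relationship_matrix(sim$pedigree)
  d <- sim$cohort
  d$y <- d$event
  f <- estimate_prevalence(d, "y", kinship = K)
  expect_gte(f$h2, 0)
  expect_lt(f$h2, 1)
  expect_lt(abs(f$prevalence - mean(d$y)), 0.08)
})

test_that("with unrelated subjects the family ROC equals the empirical ROC", {
  set.seed(23)
  n <- 2000
  d <- tibble::tibble(score = rnorm(n))
  d$y <- rbinom(n, 1, plogis(-1.4 + 1.1 * d$score))
  roc <- family_roc(d, "score", "y")
  pts <- roc$points[is.finite(roc$points$cutoff), ]
  emp_sens <- vapply(pts$cutoff,
                     function(cc) mean(d$score[d$y == 1] > cc), numeric(1))
  emp_spec <- vapply(pts$cutoff,
                     function(cc) mean(d$score[d$y == 0] <= cc), numeric(1))
  expect_lt(max(abs(pts$sensitivity - emp_sens)), 0.02)
  expect_lt(max(abs(pts$specificity - emp_spec)), 0.02)
  # empirical AUC oracle (probability of correct ordering)
  emp_auc <- mean(outer(d$score[d$y == 1], d$score[d$y == 0], `>`) +
                    0.5 * outer(d$score[d$y == 1], d$score[d$y == 0],
                                `==`))
  expect_lt(abs(roc$auc - emp_auc), 0.01)
  # curve endpoints after augmentation
  expect_equal(range(pts$sensitivity) %in% c(0, 1), c(FALSE, FALSE))
  expect_equal(roc$points$sensitivity[1], 0)
  expect_equal(roc$points$sensitivity[nrow(roc$points)], 1)
})

test_that("a predictor independent of the outcome gives AUC near 0.5", {
  set.seed(31)
  d <- tibble::tibble(score = rnorm(500), y = rbinom(500, 1, 0.3))
  roc <- family_roc(d, "score", "y")
  expect_lt(abs(roc$auc - 0.5), 3 * roc$auc_se)
})

test_that("a strong predictor yields a high AUC", {
  set.seed(32)
  n <- 600
  liab <- rnorm(n)
  d <- tibble::tibble(score = liab, y = as.integer(liab + 0.3 * rnorm(n) > 1))
  roc <- family_roc(d, "score", "y")
  expect_gt(roc$auc, 0.9)
})

test_that("Hanley-McNeil area and standard error match the closed form", {
  # perfectly separating predictor
  curve <- tibble::tibble(sensitivity = c(0, 1, 1),
                          specificity = c(1, 1, 0))
  expect_equal(auc_hanley(curve, 10, 10)$auc, 1)
  # chance diagonal at A = 0.5, n = 50/50: the closed form reduces to 0.01
  diagonal <- tibble::tibble(sensitivity = seq(0, 1, 0.25),
                             specificity = seq(1, 0, -0.25))
  hm <- auc_hanley(diagonal, 50, 50)
  expect_equal(hm$auc, 0.5, tolerance = 1e-12)
  a <- 0.5; q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
  se_manual <- sqrt((a * (1 - a) + 49 * (q1 - a^2) + 49 * (q2 - a^2)) /
                      2500)
  expect_equal(hm$se, se_manual, tolerance = 1e-12)
  # SE decreases with sample size at fixed A
  expect_lt(auc_hanley(diagonal, 200, 200)$se, hm$se)
})

test_that("AUC comparison is a 1-df chi-square and symmetric", {
  same <- compare_aucs(0.7, 0.7, 0.05, 0.05)
  expect_equal(same$p.value, 1)
  cmp <- compare_aucs(0.75, 0.60, 0.03, 0.03)
  expect_equal(cmp$z, 0.15 / sqrt(2 * 0.03^2), tolerance = 1e-10)
  expect_equal(round(cmp$z, 3), 3.536)
  expect_equal(cmp$p.value, 4.06e-4, tolerance = 0.01)
  flipped <- compare_aucs(0.60, 0.75, 0.03, 0.03)
  expect_equal(cmp$p.value, flipped$p.value)
  expect_error(compare_aucs(0.7, 0.6, 0, 0.03), "positive")
  # correlated comparison shrinks the variance
  expect_lt(compare_aucs(0.75, 0.7, 0.03, 0.03, correlation = 0.5)$p.value,
            compare_aucs(0.75, 0.7, 0.03, 0.03)$p.value)
})

test_that("kinship-adjusted ROC stays close to empirical on family data", {
  cfg <- sim_config(n_families = 10, n_unrelated = 0, n_lipid_species = 4,
                    planted_species = c(lipid_001 = 0.9),
                    baseline_hazard = 0.03, seed = 61)
  sim <- simulate_pedigree_cohort(cfg)
  K <- build_relationship_matrix(sim$pedigree)
  d <- sim$cohort
  d$y <- d$event
  d$score <- inverse_normalize(d$lipid_001)
  roc <- family_roc(d, "score", "y", kinship = K, h2 = 0.3,
                    max_cutoffs = 20)
  emp_auc <- mean(outer(d$score[d$y == 1], d$score[d$y == 0], `>`))
  expect_lt(abs(roc$auc - emp_auc), 0.08)
  yd <- youden_cutoff(roc)
  expect_true(is.finite(yd$cutoff))
  expect_gt(yd$youden, 0)
})
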