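test_that("simulation is fully reproducible under a fixed seed", {
  cfg <- small_config(seed = 1)
  s1 <- simulate_pedigree_cohort(cfg)
  s2 <- simulate_pedigree_cohort(cfg)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$pedigree, s2$pedigree)
  u1 <- simulate_unrelated_cohort(cfg)
  u2 <- simulate_unrelated_cohort(cfg)
  expect_identical(u1, u2)
  ir1 <- simulate_ir_measures(u1, 0.5, seed = 9)
  ir2 <- simulate_ir_measures(u1, 0.5, seed = 9)
  expect_identical(ir1, ir2)
  # the global RNG stream is untouched
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(simulate_pedigree_cohort(cfg))
  expect_identical(rnorm(1), before)
})

test_that("cohort tables satisfy their structural invariants", {
  cfg <- small_config(seed = 4)
  sim <- simulate_pedigree_cohort(cfg)
  co <- sim$cohort
  expect_true(all(co$time > 0))
  expect_true(all(co$event %in% 0:1))
  expect_true(all(co[, grep("^lipid_\\d", names(co))] > 0))
  # glycemic class consistent with fasting-glucose thresholds
  expect_true(all(co$fpg[co$glycemic_class == "NGT"] < 100))
  expect_true(all(co$fpg[co$glycemic_class == "prediabetes"] >= 100 &
                    co$fpg[co$glycemic_class == "prediabetes"] < 126))
  expect_setequal(co$id, sim$pedigree$id)
  u <- simulate_unrelated_cohort(cfg)
  expect_equal(nrow(u), cfg$n_unrelated)
  expect_true(all(u$person_years > 0))
  # empty unrelated cohort is allowed
  expect_equal(nrow(simulate_unrelated_cohort(small_config(n_unrelated = 0))),
               0)
  # invalid configs are rejected
  expect_error(sim_config(lipid_heritability = 1.4), "lipid_heritability")
  expect_error(sim_config(planted_species = c(lipid_099 = 1)), "candidate")
  expect_error(simulate_pedigree_cohort(small_config(n_families = 0)),
               "n_families")
})

test_that("sibling lipid correlation increases with heritability", {
  sib_cor <- function(h2) {
    cfg <- sim_config(n_families = 150, n_unrelated = 0,
                      n_lipid_species = 6, lipid_heritability = h2,
                      planted_species = c(lipid_001 = 0), seed = 10)
    sim <- simulate_pedigree_cohort(cfg)
    ped <- sim$pedigree
    key <- paste(ped$father, ped$mother)
    sibs <- split(ped$id, key)
    sibs <- sibs[!grepl("NA", names(sibs), fixed = TRUE)]
    pairs <- do.call(rbind, lapply(sibs, function(ids) {
      if (length(ids) < 2) return(NULL)
      t(combn(ids, 2))
    }))
    y <- log(sim$cohort$lipid_002)
    names(y) <- sim$cohort$id
    cor(y[pairs[, 1]], y[pairs[, 2]])
  }
  r <- vapply(c(0, 0.4, 0.8), sib_cor, numeric(1))
  expect_lt(abs(r[1]), 0.05)       # no polygenic component
  expect_true(r[1] < r[2] && r[2] < r[3])
  # expected sibling correlation is h2 * K_sib = h2 / 2
  expect_lt(abs(r[3] - 0.4), 0.12)
})

test_that("an oracle Cox fit recovers the planted log hazard ratios", {
  cfg <- sim_config(n_families = 2, n_unrelated = 2500,
                    n_lipid_species = 12, dropout_rate = 0,
                    unrelated_followup_years = 13, seed = 21)
  u <- simulate_unrelated_cohort(cfg)
  d <- data.frame(time = u$person_years, event = u$events,
                  i1 = inverse_normalize(u$lipid_001),
                  i2 = inverse_normalize(u$lipid_002),
                  i3 = inverse_normalize(u$lipid_003),
                  age = u$age, male = as.integer(u$sex == 1), bmi = u$bmi,
                  prediab = as.integer(u$glycemic_class == "prediabetes"))
  fit <- survival::coxph(
    survival::Surv(time, event) ~ i1 + i2 + i3 + age + male + bmi + prediab,
    data = d)
  b <- coef(fit)[1:3]
  se <- sqrt(diag(vcov(fit)))[1:3]
  planted <- unname(cfg$planted_species)
  expect_true(all(abs(b - planted) < 3 * se))
})

test_that("null planted rate matches a Poisson count oracle", {
  rate <- 0.02
  cfg <- sim_config(n_families = 2, n_unrelated = 3000,
                    n_lipid_species = 8,
                    planted_species = c(lipid_001 = 0),
                    covariate_hazard = c(age = 0, male = 0, bmi = 0,
                                         prediabetes = 0),
                    baseline_hazard = rate, dropout_rate = 0, seed = 5)
  u <- simulate_unrelated_cohort(cfg)
  ev <- sum(u$events); py <- sum(u$person_years)
  se <- sqrt(ev) / py
  expect_lt(abs(ev / py - rate), 3 * se)
})

test_that("null planted effects give equal event fractions across tertiles", {
  cfg <- sim_config(n_families = 25, n_unrelated = 0, n_lipid_species = 8,
                    planted_species = c(lipid_001 = 0),
                    baseline_hazard = 0.02, seed = 14)
  sim <- simulate_pedigree_cohort(cfg)
  score <- inverse_normalize(sim$cohort$lipid_001)
  g <- tertile_groups(score)
  frac <- tapply(sim$cohort$event, g, mean)
  p <- mean(sim$cohort$event)
  n_g <- as.vector(table(g))
  # each tertile fraction within 3 binomial SEs of the pooled fraction
  expect_true(all(abs(frac - p) < 3 * sqrt(p * (1 - p) / n_g)))
})

test_that("interval conventions coarsen times without inventing events", {
  for (conv in c("interval_midpoint", "visit_date")) {
    cfg <- small_config(event_time_convention = conv, seed = 8)
    sim <- simulate_pedigree_cohort(cfg)
    exact <- simulate_pedigree_cohort(small_config(seed = 8))
    # interval detection can only lose events relative to exact recording
    expect_lte(sum(sim$cohort$event), sum(exact$cohort$event))
    iv <- cfg$visit_interval_years
    obs <- sim$cohort$time[sim$cohort$event == 1]
    off <- if (conv == "visit_date") 0 else iv / 2
    expect_true(all(abs(((obs + off) / iv) - round((obs + off) / iv)) < 1e-8))
  }
})

test_that("insulin-resistance coupling is monotone and null when zero", {
  cfg <- sim_config(n_families = 2, n_unrelated = 800, n_lipid_species = 8,
                    seed = 17)
  u <- simulate_unrelated_cohort(cfg)
  planted <- cfg$planted_species
  lp <- numeric(nrow(u))
  for (s in names(planted)) {
    lp <- lp + planted[[s]] * inverse_normalize(u[[s]])
  }
  g <- tertile_groups(lp)
  strong <- compute_ir_panel(simulate_ir_measures(u, 0.8, planted, seed = 3))
  med <- tapply(strong$homa_ir, g, median)
  expect_true(med[1] < med[2] && med[2] < med[3])
  # coupling = 0: Kruskal-Wallis across tertiles behaves as a null test
  base <- u[seq_len(150), , drop = FALSE]
  g0 <- tertile_groups(lp[seq_len(150)])
  reject <- vapply(1:100, function(i) {
    ir <- compute_ir_panel(simulate_ir_measures(base, 0, planted, seed = i))
    stats::kruskal.test(ir$homa_ir, g0)$p.value < 0.05
  }, logical(1))
  expect_gte(mean(!reject), 0.9)
  expect_error(simulate_ir_measures(u, 1.3), "coupling")
})

test_that("cohort export writes readable plain-text files", {
  cfg <- small_config(n_families = 3, n_unrelated = 0, seed = 2)
  sim <- simulate_pedigree_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(sim, dir, config = cfg)
  back <- read.delim(file.path(dir, "cohort.tsv"))
  expect_equal(nrow(back), nrow(sim$cohort))
  ped <- read_ped(file.path(dir, "pedigree.ped"), family = TRUE)
  expect_setequal(ped$id, sim$pedigree$id)
  cfg_back <- jsonlite::read_json(file.path(dir, "config.json"),
                                  simplifyVector = TRUE)
  expect_equal(cfg_back$n_families, cfg$n_families)
})
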