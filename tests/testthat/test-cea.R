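test_that("screening costs assemble from the printed components", {
  strats <- build_default_strategies()
  expect_length(strats, 7)
  # LRS-only: 11 (assay) + 29 (prep) + 50 (visit)
  expect_equal(strats$lrs_metformin$screen_cost, 90)
  expect_equal(strats$lrs_lifestyle$screen_cost, 90)
  # combined FPG + LRS charges prep and visit once, not per assay
  expect_equal(strats$fpg_lrs_combined$screen_cost,
               cea_costs()$fpg_test + 11 + 29 + 50)
  expect_equal(strats$no_screening$screen_cost, 0)
  # efficacies as reported by the prevention trial
  eff <- cea_utilities()$efficacy
  expect_equal(unname(eff[c("lifestyle", "metformin")]), c(0.58, 0.31))
  # group probabilities sum to one in every strategy
  for (s in strats) expect_equal(sum(s$groups$prob), 1)
  expect_error(strategy_spec("bad", "lrs",
                             tibble::tibble(group = c("HR", "LR"),
                                            prob = c(0.6, 0.5),
                                            intervention = "none")),
               "sum to 1")
})

test_that("rollback equals the path-enumeration oracle", {
  # toy two-branch node
  toy <- list(type = "chance", branches = list(
    list(prob = 0.2, node = list(type = "leaf", cost = 0, qaly = 4,
                                 t2d = 0)),
    list(prob = 0.8, node = list(type = "leaf", cost = 0, qaly = 5,
                                 t2d = 0))))
  expect_equal(rollback(toy)[["qaly"]], 4.8)
  # deterministic tree: EV equals the single live path's payoff
  det <- list(type = "chance", branches = list(
    list(prob = 1, node = list(type = "leaf", cost = 7, qaly = 4.2,
                               t2d = 1)),
    list(prob = 0, node = list(type = "leaf", cost = 99, qaly = 1,
                               t2d = 0))))
  expect_equal(rollback(det), c(cost = 7, qaly = 4.2, t2d = 1))
  # random trees up to ~100 leaves
  set.seed(31)
  for (i in 1:25) {
    tr <- random_tree(4)
    expect_equal(rollback(tr), enumeration_ev(tr), tolerance = 1e-12)
  }
  # strategy trees match the oracle too
  strats <- build_default_strategies()
  inp <- cea_inputs()
  for (s in strats) {
    tr <- build_tree(s, inp)
    expect_equal(rollback(tr), enumeration_ev(tr), tolerance = 1e-12)
  }
  # unnormalized chance nodes are rejected
  bad <- toy; bad$branches[[1]]$prob <- 0.4
  expect_error(rollback(bad), "sum to 1")
})

test_that("zero efficacy means zero risk reduction", {
  inp <- cea_inputs()
  inp$utilities$efficacy[] <- 0
  res <- cea_rollback(build_default_strategies(), inp)
  expect_equal(res$risk_reduction, rep(0, 7))
  # with no intervention effect every strategy keeps its group-weighted
  # baseline risk
  strats <- build_default_strategies()
  for (i in seq_along(strats)) {
    g <- strats[[i]]$groups
    expect_equal(res$p_t2d[i],
                 sum(g$prob * inp$p_t2d[g$group]), tolerance = 1e-12)
  }
})

test_that("ICER and net monetary benefit identities hold", {
  strats <- build_default_strategies()
  inp <- cea_inputs()
  res <- cea_rollback(strats, inp)
  out <- icer_nmb(res, "lrs_metformin")
  expect_equal(out$icer[out$strategy == "fpg_lifestyle"],
               (out$cost[out$strategy == "fpg_lifestyle"] -
                  out$cost[out$strategy == "lrs_metformin"]) /
                 (out$qaly[out$strategy == "fpg_lifestyle"] -
                    out$qaly[out$strategy == "lrs_metformin"]))
  # the reference against itself is flagged, not given a ratio
  expect_true(is.na(out$icer[out$reference]))
  # direct arithmetic: dCost 1000 over dQALY 0.5 is 2000 per QALY
  toy <- tibble::tibble(strategy = c("a", "b"), cost = c(0, 1000),
                        qaly = c(4, 4.5), p_t2d = 0, risk_reduction = 0)
  class(toy) <- c("cea_result", class(toy))
  expect_equal(icer_nmb(toy, "a", wtp = 4450.12)$icer[2], 2000)
  # NMB ordering is invariant to a constant cost added to all strategies
  shifted <- res
  shifted$cost <- shifted$cost + 500
  o1 <- icer_nmb(res, "lrs_metformin", wtp = inp$wtp)
  o2 <- icer_nmb(shifted, "lrs_metformin", wtp = inp$wtp)
  expect_equal(order(o1$nmb), order(o2$nmb))
  # sign(NMB difference) flips as WTP crosses the ICER
  pick <- function(w, s) icer_nmb(res, "lrs_metformin", wtp = w)
  icer_ab <- out$icer[out$strategy == "fpg_lifestyle"]
  low <- icer_nmb(res, "lrs_metformin", wtp = icer_ab * 0.5)
  high <- icer_nmb(res, "lrs_metformin", wtp = icer_ab * 1.5)
  d_low <- low$nmb[low$strategy == "fpg_lifestyle"] -
    low$nmb[low$strategy == "lrs_metformin"]
  d_high <- high$nmb[high$strategy == "fpg_lifestyle"] -
    high$nmb[high$strategy == "lrs_metformin"]
  expect_lt(d_low * d_high, 0)
})

test_that("tornado sorts by swing and is widest for the high-risk probability", {
  strats <- build_default_strategies()
  inp <- cea_inputs()
  tor <- tornado(strats, inp)
  expect_true(all(diff(tor$swing) <= 1e-12))
  expect_equal(tor$parameter[1], "p_t2d.HR")
  # zero-width range gives zero swing
  zr <- tornado(strats, inp,
                ranges = tibble::tibble(parameter = "p_t2d.HR",
                                        low = inp$p_t2d[["HR"]],
                                        high = inp$p_t2d[["HR"]]))
  expect_equal(zr$swing, 0)
  # swings grow with range width for monotone parameters
  narrow <- tornado(strats, inp,
                    ranges = tibble::tibble(parameter = "p_t2d.HR",
                                            low = 0.3, high = 0.4),
                    strategy = "lrs_metformin")
  wide <- tornado(strats, inp,
                  ranges = tibble::tibble(parameter = "p_t2d.HR",
                                          low = 0.2, high = 0.5),
                  strategy = "lrs_metformin")
  expect_gt(wide$swing, narrow$swing)
  expect_error(tornado(strats, inp,
                       ranges = tibble::tibble(parameter = "p_t2d.HR",
                                               low = 0.5, high = 0.6)),
               "bracket")
})

test_that("microsimulation is reproducible and captures linear truth", {
  strats <- build_default_strategies()
  inp <- cea_inputs()
  m1 <- one_way_microsim(strats, inp, "p_t2d.HR", c(0.2, 0.5),
                         n_runs = 40, seed = 6)
  m2 <- one_way_microsim(strats, inp, "p_t2d.HR", c(0.2, 0.5),
                         n_runs = 40, seed = 6)
  expect_equal(m1$curves, m2$curves)
  expect_equal(m1$means, m2$means)
  # rollback is linear in a probability input: degree-4 fit reproduces it
  m3 <- one_way_microsim(strats, inp, "p_t2d.HR", c(0.2, 0.5),
                         n_runs = 60, value = "cost", seed = 2)
  r2 <- vapply(m3$fits, `[[`, numeric(1), "r_squared")
  affected <- vapply(strats,
                     function(s) "HR" %in% s$groups$group, logical(1))
  expect_true(all(r2[affected[m3$means$strategy]] > 0.99))
  # constant payoffs: flat fitted polynomial
  inp_flat <- inp
  inp_flat$p_t2d[] <- 0.1
  m4 <- one_way_microsim(strats["no_screening"], inp_flat, "p_t2d.HR",
                         c(0.05, 0.3), n_runs = 30, value = "cost",
                         seed = 3)
  expect_lt(max(abs(m4$fits[[1]]$coefficients[-1])), 1e-6)
  expect_error(one_way_microsim(strats, inp, "p_t2d.HR", c(0.2, 0.5),
                                n_runs = 5), "n_runs")
})

test_that("plot methods return ggplot objects", {
  strats <- build_default_strategies()
  inp <- cea_inputs()
  res <- cea_rollback(strats, inp)
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(autoplot(tornado(strats, inp)), "ggplot")
  set.seed(2)
  d <- tibble::tibble(score = rnorm(300))
  d$y <- rbinom(300, 1, plogis(-1 + d$score))
  expect_s3_class(autoplot(family_roc(d, "score", "y")), "ggplot")
})
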