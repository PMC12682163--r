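test_that("ICER dominance classification covers every quadrant", {
  expect_identical(icer(-114.959, 0.022)$class, "dominant")
  expect_identical(icer(500, -0.1)$class, "dominated")
  ne <- icer(100, 0.01)
  expect_identical(ne$class, "north_east")
  expect_equal(ne$value, 10000)
  # saving per QALY lost, as printed for the As-Treated scenario
  sw <- icer(-435.792, -0.35044)
  expect_identical(sw$class, "south_west")
  expect_equal(sw$value, 1243.56, tolerance = 1e-4)
  expect_gt(sw$value, 0)
  expect_identical(icer(5, 0)$class, "undefined")
  # exhaustive and mutually exclusive over random sign patterns
  set.seed(2)
  for (i in 1:200) {
    dc <- sample(c(-1, 0, 1), 1) * runif(1)
    dq <- sample(c(-1, 0, 1), 1) * runif(1)
    r <- icer(dc, dq)
    expect_true(r$class %in% c("dominant", "dominated", "north_east",
                               "south_west", "undefined"))
    if (dq == 0) expect_identical(r$class, "undefined")
    if (dc < 0 && dq > 0) expect_identical(r$class, "dominant")
    if (dc > 0 && dq < 0) expect_identical(r$class, "dominated")
  }
})

test_that("net monetary benefit is exactly linear in willingness to pay", {
  # published base-case identity: 20000 * 0.02244375 + 114.959
  expect_equal(inmb(-114.959, 0.02244375, 20000), 563.834, tolerance = 1e-9)
  expect_equal(inmb(-83.125, 0.0361299, 30000), 1167.022, tolerance = 1e-3)
  expect_equal(inmb(3, 0.5, 0), -3)
  dc <- runif(1, -100, 100); dq <- runif(1, -1, 1)
  l1 <- inmb(dc, dq, 10000); l2 <- inmb(dc, dq, 20000)
  expect_equal(inmb(dc, dq, 15000), (l1 + l2) / 2, tolerance = 1e-12)
  expect_equal(inmb(dc, dq, 0), -dc)
})

test_that("deterministic comparison flags identical strategies", {
  p <- fixed_params(prob_list(0.5, 0.1, 0, 0.9, 0.05, 0.1, 0.08, 0.1),
                    payoff_list(runif(8, 100, 500)), payoff_list(runif(8)))
  cea <- deterministic_cea(p, cost_regression(baseline = 100,
                                              baseline_sd = 0,
                                              delabel_sd = 0, tf_sd = 0))
  expect_equal(cea$delta_cost, 0, tolerance = 1e-12)
  expect_equal(cea$delta_qaly, 0, tolerance = 1e-12)
  expect_identical(cea$icer$class, "undefined")
})

test_that("parameter sampling honours each family and the seed", {
  params <- base_params()
  reg <- cost_regression()
  th1 <- sample_parameters(params, reg, 500, seed = 5)
  th2 <- sample_parameters(params, reg, 500, seed = 5)
  expect_identical(th1, th2)
  # fixed parameters are constant
  expect_true(all(th1$paap.p_delabel_pos == 0))
  expect_true(all(th1$usual_care.p_delabel_neg == 1))
  expect_true(all(th1$paap.cost.pos_pal_tf == 510.23))
  set.seed(1)
  big <- sample_parameters(params, reg, 1e5, seed = 9)
  x <- big$paap.p_test
  expect_lt(abs(mean(x) - 0.910), 4 * 0.082 / sqrt(1e5))
  y <- big$paap.cost.pos_pal_notf
  expect_lt(abs(mean(y) - 1176.55), 4 * 1587.10 / sqrt(1e5))
  expect_lt(abs(sd(y) - 1587.10), 30 * 1587.10 / sqrt(1e5))
  # all-fixed parameter set: identical rows
  pf <- fixed_params(prob_list(0.9, 0.1, 0, 0.95, 0.03, 0.1, 0.09, 0.08),
                     payoff_list(rep(100, 8)), payoff_list(rep(0.9, 8)))
  thf <- sample_parameters(pf, cost_regression(baseline_sd = 0,
                                               delabel_sd = 0, tf_sd = 0),
                           10, seed = 1)
  expect_identical(nrow(unique(thf)), 1L)
})

test_that("PSA with zero variances reproduces the deterministic result", {
  params <- base_params()
  # zero out every uncertainty SD
  for (arm in c("paap", "usual_care"))
    for (kind in c("probs", "costs", "qalys"))
      for (nm in names(params[[arm]][[kind]])) {
        d <- params[[arm]][[kind]][[nm]]
        params[[arm]][[kind]][[nm]] <- dist_spec(d$family, d$mean, 0)
      }
  reg <- cost_regression(baseline_sd = 0, delabel_sd = 0, tf_sd = 0)
  cfg <- econ_config(psa_draws = 25)
  det <- deterministic_cea(params, reg, cfg)
  psa <- run_psa(params, reg, cfg)
  expect_equal(psa$summary$mean_delta_cost, det$delta_cost,
               tolerance = 1e-10)
  expect_equal(psa$summary$mean_delta_qaly, det$delta_qaly,
               tolerance = 1e-10)
  expect_equal(max(abs(psa$draws$delta_cost - det$delta_cost)), 0,
               tolerance = 1e-10)
  expect_identical(psa$summary$failed_draws, 0L)
})

test_that("PSA summaries are internally consistent", {
  m <- paap_model()
  psa <- simulate(m, nsim = 2000, seed = 4)
  d <- psa$draws
  expect_identical(nrow(d), 2000L)
  expect_equal(d$delta_cost, d$cost_paap - d$cost_usual_care,
               tolerance = 1e-12)
  expect_equal(psa$summary$p_ce_20000,
               mean(20000 * d$delta_qaly - d$delta_cost > 0))
  # Monte-Carlo error follows the square-root law: across independent
  # replicates, quadrupling the draws halves the spread of the estimated
  # mean incremental QALYs (QALY draws are bounded, so replicate means
  # are well behaved at this size)
  reps <- function(n) vapply(1:24, function(s)
    simulate(m, nsim = n, seed = 1000 + s)$summary$mean_delta_qaly, 0)
  ratio <- sd(reps(500)) / sd(reps(2000))
  expect_gt(ratio, 1.3)
  expect_lt(ratio, 3)
})

test_that("the acceptability curve is a draw count at each threshold", {
  # hand-set draws: signs known
  psa <- manual_psa(delta_cost = c(-10, -10, 10, 10),
                    delta_qaly = c(0.01, -0.01, 0.01, -0.01))
  cv <- ceac(psa, c(0, 2000, 1e9))
  # at 0: P(dC < 0) = 0.5; at 2000: INMB = 20+10, -20+10, 20-10, -20-10
  expect_equal(cv$p_cost_effective, c(0.5, 0.5, 0.5))
  expect_equal(attr(cv, "p_cost_saving"), 0.5)
  # large-threshold limit equals P(dQ > 0)
  psa2 <- manual_psa(delta_cost = rnorm(200),
                     delta_qaly = rnorm(200, 0.01, 0.02))
  cv2 <- ceac(psa2, c(0, 1e9))
  expect_equal(cv2$p_cost_effective[1], mean(psa2$draws$delta_cost < 0))
  expect_equal(cv2$p_cost_effective[2], mean(psa2$draws$delta_qaly > 0))
  # all dominant draws: curve identically one
  psa3 <- manual_psa(delta_cost = rep(-5, 10), delta_qaly = rep(0.1, 10))
  expect_true(all(ceac(psa3, c(0, 20000))$p_cost_effective == 1))
  expect_true(all(cv$p_cost_effective >= 0 & cv$p_cost_effective <= 1))
  expect_error(ceac(manual_psa(numeric(0), numeric(0))), "no draws")
})

test_that("subgroup pipelines recover built-in effect heterogeneity", {
  # a single all-in stratum reproduces the whole-sample analysis
  tab <- generate_trial(generator_config(
    n_per_arm = c(paap = 4000, usual_care = 4000), seed = 60L))
  cfg <- econ_config(psa_draws = 200)
  whole <- subgroup_cea(tab, splits = list(all = function(p) rep("all", nrow(p))),
                        config = cfg, n_draws = 200)
  pars <- resolve_missing_branches(estimate_params(tab))
  reg <- fit_post_year1_cost_model(tab)
  det <- deterministic_cea(pars, reg, cfg)
  expect_equal(whole$delta_cost, det$delta_cost, tolerance = 1e-9)
  expect_equal(whole$delta_qaly, det$delta_qaly, tolerance = 1e-9)
  expect_identical(whole$n, 8000L)

  # built-in age-by-intervention utility effect: the older stratum shows
  # the larger QALY gain
  gen <- generator_config(n_per_arm = c(paap = 15000, usual_care = 15000),
                          covariate_effects = list(age65_qaly = 0.08),
                          seed = 61L)
  tab2 <- generate_trial(gen)
  res <- subgroup_cea(tab2,
                      splits = list(age = function(p)
                        ifelse(p$age < 65, "young", "old")),
                      config = cfg, n_draws = 200)
  dq_old <- res$delta_qaly[res$stratum == "old"]
  dq_young <- res$delta_qaly[res$stratum == "young"]
  expect_gt(dq_old, dq_young)
  expect_false(any(res$small_stratum))
})
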