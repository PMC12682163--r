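test_that("path probabilities multiply along edges and conserve mass", {
  tree <- tree_spec()
  params <- base_params()
  paths <- enumerate_paths(tree, params, "paap")
  expect_equal(sum(paths$probability), 1, tolerance = 1e-12)
  pr <- function(b) paths$probability[paths$branch == b]
  # hand products from the base-case probabilities
  expect_equal(pr("neg_nopal_notf"), 0.910 * 0.918 * 0.973 * 0.911,
               tolerance = 1e-12)
  ucp <- enumerate_paths(tree, params, "usual_care")
  pu <- function(b) ucp$probability[ucp$branch == b]
  expect_equal(pu("notest_tf") + pu("notest_notf"), 0.988, tolerance = 1e-12)
  expect_equal(pu("notest_tf"), 0.988 * 0.114, tolerance = 1e-12)
  # degenerate tree: a single path with probability one
  deg <- fixed_params(prob_list(1, 1, 0, 0, 1, 0, 0, 0),
                      payoff_list(rep(10, 8)), payoff_list(rep(0.5, 8)))
  dp <- enumerate_paths(tree, deg, "paap")
  expect_equal(dp$probability[dp$branch == "pos_pal_tf"], 1)
  expect_equal(sum(dp$probability), 1, tolerance = 1e-15)
})

test_that("conservation and payoff agreement hold over random parameter sets", {
  tree <- tree_spec()
  set.seed(1234)
  cfg <- econ_config()
  worst_mass <- worst_path <- worst_payoff <- 0
  for (i in 1:1000) {
    params <- random_fixed_params()
    for (arm in c("paap", "usual_care")) {
      paths <- enumerate_paths(tree, params, arm)
      worst_mass <- max(worst_mass, abs(sum(paths$probability) - 1))
      # brute-force oracle agreement
      probs <- lapply(params[[arm]]$probs, function(d) d$mean)
      op <- oracle_paths(probs)
      worst_path <- max(worst_path,
                        abs(paths$probability[match(names(op), paths$branch)] -
                              unname(op)))
      y1 <- expected_year1_payoffs(tree, params, arm, cfg)
      oc <- oracle_expected_payoff(probs,
              lapply(params[[arm]]$costs, function(d) d$mean))
      oq <- oracle_expected_payoff(probs,
              lapply(params[[arm]]$qalys, function(d) d$mean))
      worst_payoff <- max(worst_payoff, abs(y1[["cost"]] - oc) / max(oc, 1),
                          abs(y1[["qaly"]] - oq))
    }
  }
  expect_lt(worst_mass, 1e-12)
  expect_lt(worst_path, 1e-14)
  expect_lt(worst_payoff, 1e-12)
})

test_that("expected first-year payoffs match the enumeration oracle", {
  tree <- tree_spec()
  params <- base_params()
  cfg <- econ_config()
  y1p <- expected_year1_payoffs(tree, params, "paap", cfg)
  expect_equal(y1p[["cost"]], 1390.112, tolerance = 1e-4)
  expect_equal(y1p[["qaly"]], 0.870414, tolerance = 1e-5)
  y1u <- expected_year1_payoffs(tree, params, "usual_care", cfg)
  expect_equal(y1u[["cost"]], 1297.777, tolerance = 1e-4)
  expect_equal(y1u[["qaly"]], 0.839977, tolerance = 1e-5)
  # payoff bounded by branch extremes
  cm <- vapply(params$paap$costs, function(d) d$mean, 0)
  expect_gte(y1p[["cost"]], min(cm)); expect_lte(y1p[["cost"]], max(cm))
  # the exposure fraction scales linearly
  half <- expected_year1_payoffs(tree, params, "paap",
                                 econ_config(year1_exposure_fraction = 0.5))
  expect_equal(unname(half), unname(y1p) / 2, tolerance = 1e-12)
  # degenerate tree returns the single branch payoff
  deg <- fixed_params(prob_list(0, 0, 0, 0, 0, 0, 0, 1),
                      payoff_list(1:8 * 100), payoff_list(1:8 / 10))
  yd <- expected_year1_payoffs(tree, deg, "paap", cfg)
  expect_equal(yd[["cost"]], 700)  # notest_tf is the 7th payoff branch
  expect_equal(yd[["qaly"]], 0.7)
})

test_that("end-of-year-1 states aggregate label and failure status", {
  tree <- tree_spec()
  params <- base_params()
  st <- end_of_year1_states(tree, params, "paap")
  nolabel <- sum(st$probability[st$state %in% c("nopal_tf", "nopal_notf")])
  expect_equal(nolabel, 0.910 * 0.918 * 0.973, tolerance = 1e-12)
  stu <- end_of_year1_states(tree, params, "usual_care")
  expect_equal(sum(stu$probability[grepl("^nopal", stu$state)]),
               0.012 * 0.8 * 1.0, tolerance = 1e-12)
  expect_equal(sum(st$probability), 1, tolerance = 1e-12)
  # all de-labelled without failure: all mass on nopal_notf
  deg <- fixed_params(prob_list(1, 0, 0, 1, 0, 0, 0, 0),
                      payoff_list(rep(1, 8)), payoff_list(rep(0.9, 8)))
  std <- end_of_year1_states(tree, deg, "paap")
  expect_equal(std$probability[std$state == "nopal_notf"], 1)
})

test_that("annuity factors sum discrete discount weights", {
  expect_equal(annuity_factor(0, 2, 5), 4)
  # direct summation oracle
  expect_equal(annuity_factor(0.035, 2, 5),
               1.035^-1 + 1.035^-2 + 1.035^-3 + 1.035^-4, tolerance = 1e-15)
  expect_equal(annuity_factor(0.035, 2, 5), 3.673080, tolerance = 1e-6)
  expect_equal(annuity_factor(0.035, 2, 2), 0.966184, tolerance = 1e-6)
  expect_error(annuity_factor(0.035, 1, 5))
  expect_error(annuity_factor(0.035, 3, 2))
})

test_that("extrapolation holds QALYs constant and discounts later years", {
  tree <- tree_spec()
  params <- base_params()
  cfg <- econ_config()
  st <- end_of_year1_states(tree, params, "paap")
  # constant annual QALY times the years 2-5 annuity; the published
  # usual-care figure 1.549 comes from the rounded annual value 0.422
  tr <- extrapolate(st, c(cost = 500, qaly = 0.422), cost_regression(), cfg)
  expect_equal(sum(tr$disc_qaly[-1]), 0.422 * annuity_factor(0.035, 2, 5),
               tolerance = 1e-12)
  expect_equal(sum(tr$disc_qaly[-1]), 1.549, tolerance = 2e-3)
  # zero discount, unit multipliers: years 2-5 cost is 4x the baseline
  cfg0 <- econ_config(discount_rate = 0)
  reg1 <- cost_regression(baseline = 321, delabel_mult = 1, tf_mult = 1)
  tr0 <- extrapolate(st, c(cost = 0, qaly = 0.5), reg1, cfg0)
  expect_equal(sum(tr0$disc_cost[-1]), 4 * 321, tolerance = 1e-10)
  # with discounting, unit multipliers give baseline times the annuity
  tr1 <- extrapolate(st, c(cost = 0, qaly = 0.5), reg1, cfg)
  expect_equal(sum(tr1$disc_cost[-1]), 321 * annuity_factor(0.035, 2, 5),
               tolerance = 1e-10)
  # the trajectory identity
  expect_equal(attr(tr, "total_cost"),
               tr$cost[1] + sum(tr$cost[-1] * 1.035^-(2:5 - 1)),
               tolerance = 1e-12)
  expect_true(all(tr$qaly >= 0 & tr$qaly <= 1))
})

test_that("relabelling Markov chain reduces to extrapolation at rate zero", {
  tree <- tree_spec()
  params <- base_params()
  cfg <- econ_config()
  reg <- cost_regression()
  for (arm in c("paap", "usual_care")) {
    y1 <- expected_year1_payoffs(tree, params, arm, cfg)
    st <- end_of_year1_states(tree, params, arm)
    a <- extrapolate(st, y1, reg, cfg)
    b <- markov_relabel(st, y1, reg, 0, cfg)
    expect_equal(attr(a, "total_cost"), attr(b, "total_cost"),
                 tolerance = 1e-10)
    expect_equal(a$qaly, b$qaly, tolerance = 1e-10)
  }
  expect_error(markov_relabel(end_of_year1_states(tree, params, "paap"),
                              c(cost = 1, qaly = 0.5), reg, 1.2, cfg),
               "relabelling rate")
})

test_that("full relabelling matches a hand-run two-state chain", {
  tree <- tree_spec()
  params <- base_params()
  cfg <- econ_config()
  reg <- cost_regression()
  y1 <- expected_year1_payoffs(tree, params, "paap", cfg)
  st <- end_of_year1_states(tree, params, "paap")
  tr <- markov_relabel(st, y1, reg, 1, cfg)
  # hand chain: from year 2 every de-labelled patient is relabelled
  p <- setNames(st$probability, st$state)
  q <- setNames(st$qaly, st$state)
  qr <- attr(st, "relabel_qaly")
  cost_hand <- (p[["pal_tf"]] + p[["nopal_tf"]]) * reg$baseline * reg$tf_mult +
    (p[["pal_notf"]] + p[["nopal_notf"]]) * reg$baseline
  qaly_hand <- p[["pal_tf"]] * q[["pal_tf"]] + p[["pal_notf"]] * q[["pal_notf"]] +
    p[["nopal_tf"]] * qr[["tf"]] + p[["nopal_notf"]] * qr[["notf"]]
  expect_equal(tr$cost[2:5], rep(unname(cost_hand), 4), tolerance = 1e-12)
  expect_equal(tr$qaly[2:5], rep(unname(qaly_hand), 4), tolerance = 1e-12)
  # the published 6-month relabelling scenario rate conversion
  expect_equal(annualise_rate(0.066, 0.5), 1 - (1 - 0.066)^2,
               tolerance = 1e-12)
  expect_equal(annualise_rate(0.066, 0.5), 0.127644, tolerance = 1e-6)
})

test_that("relabelling monotonically erodes the intervention's advantage", {
  params <- base_params()
  reg <- cost_regression()
  cfg <- econ_config()
  rates <- c(0, 0.1, 0.3, 0.6, 1)
  dcs <- vapply(rates, function(r)
    deterministic_cea(params, reg, cfg, relabel_rate = r)$delta_cost, 0)
  dqs <- vapply(rates, function(r)
    deterministic_cea(params, reg, cfg, relabel_rate = r)$delta_qaly, 0)
  expect_true(all(diff(dcs) > 0))  # costs rise with relabelling
  expect_true(all(diff(dqs) < 0))  # QALY gains shrink
})

test_that("relabelling-rate thresholds are located by bisection", {
  # fixture where relabelling harms only the intervention arm: dominant at
  # rate 0, dominated at rate 1, so both thresholds exist in (0,1)
  paap_q <- payoff_list(rep(0.8, 8)); paap_q$neg_nopal_notf <- 0.9
  fix <- fixed_params(prob_list(1, 0, 0, 0.9, 0, 0, 0, 0),
                      payoff_list(rep(150, 8)), paap_q,
                      prob_list(0, 0, 0, 0, 0, 0, 0, 0),
                      payoff_list(rep(120, 8)), payoff_list(rep(0.85, 8)))
  reg <- cost_regression(baseline = 100, delabel_mult = 0.5, tf_mult = 1,
                         baseline_sd = 0, delabel_sd = 0, tf_sd = 0)
  m <- paap_model(fix, reg)
  cea0 <- deterministic_cea(fix, reg, m$config, relabel_rate = 0)
  cea1 <- deterministic_cea(fix, reg, m$config, relabel_rate = 1)
  expect_identical(cea0$icer$class, "dominant")
  expect_identical(cea1$icer$class, "dominated")
  th <- relabel_thresholds(m, wtp = 20000)
  expect_identical(th$cost_saving$status, "ok")
  expect_identical(th$inmb_zero$status, "ok")
  expect_gt(th$cost_saving$rate, 0); expect_lt(th$cost_saving$rate, 1)
  # independent root check against uniroot on the same functions
  dc_at <- function(r) deterministic_cea(fix, reg, m$config,
                                         relabel_rate = r)$delta_cost
  expect_equal(th$cost_saving$rate, uniroot(dc_at, c(0, 1), tol = 1e-9)$root,
               tolerance = 1e-5)
  inmb_at <- function(r) {
    cea <- deterministic_cea(fix, reg, m$config, relabel_rate = r)
    inmb(cea$delta_cost, cea$delta_qaly, 20000)
  }
  expect_equal(th$inmb_zero$rate, uniroot(inmb_at, c(0, 1), tol = 1e-9)$root,
               tolerance = 1e-5)
  # ICER (where defined) does not improve as relabelling increases
  expect_lt(inmb_at(0.8), inmb_at(0.2))
  # a model with no crossing reports so rather than erroring
  flat <- fixed_params(prob_list(0, 0, 0, 0, 0, 0, 0, 0.1),
                       payoff_list(rep(100, 8)), payoff_list(rep(0.9, 8)))
  m2 <- paap_model(flat, cost_regression(baseline = 100, delabel_mult = 1,
                                         tf_mult = 1, baseline_sd = 0,
                                         delabel_sd = 0, tf_sd = 0))
  th2 <- relabel_thresholds(m2)
  expect_identical(th2$cost_saving$status, "no crossing in [0,1]")
  expect_true(is.na(th2$cost_saving$rate))
})
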