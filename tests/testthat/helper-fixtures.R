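# Shared fixtures and independent oracles. Large generated tables are
# memoised so several test files can reuse them.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

base_params <- function() memo("base_params",
                               resolve_missing_branches(table2_params()))

# Large trials generated at the published truths, reused across files.
big_table_100k <- function() memo("big100k", {
  generate_trial(generator_config(
    n_per_arm = c(paap = 100000, usual_care = 100000), seed = 424241L))
})
big_table_50k <- function() memo("big50k", {
  generate_trial(generator_config(
    n_per_arm = c(paap = 50000, usual_care = 50000), seed = 424242L))
})

# Fully deterministic parameter set: every probability/payoff fixed.
fixed_spec <- function(m) dist_spec("fixed", m, 0)

make_arm <- function(probs, costs, qalys, n = NA_integer_) {
  arm_params(probs = probs, costs = costs, qalys = qalys, n = n)
}

# A parameter set with arbitrary fixed values; probability list and payoff
# vectors given per arm. Used for hand-checkable tree fixtures.
fixed_params <- function(paap_probs, paap_costs, paap_qalys,
                         uc_probs = paap_probs, uc_costs = paap_costs,
                         uc_qalys = paap_qalys) {
  mk <- function(pr, co, qa) {
    arm_params(probs = lapply(pr, fixed_spec),
               costs = lapply(co, fixed_spec),
               qalys = lapply(qa, fixed_spec))
  }
  branch_params(mk(paap_probs, paap_costs, paap_qalys),
                mk(uc_probs, uc_costs, uc_qalys))
}

payoff_list <- function(values) {
  stats::setNames(as.list(values), paapcea:::PAYOFF_BRANCHES)
}

prob_list <- function(p_test, p_positive, p_delabel_pos, p_delabel_neg,
                      tf_pos_pal, tf_neg_pal, tf_neg_nopal, tf_notest) {
  list(p_test = p_test, p_positive = p_positive,
       p_delabel_pos = p_delabel_pos, p_delabel_neg = p_delabel_neg,
       tf_pos_pal = tf_pos_pal, tf_neg_pal = tf_neg_pal,
       tf_neg_nopal = tf_neg_nopal, tf_notest = tf_notest)
}

# Random feasible fixed parameter set (structural zero kept for
# p_delabel_pos so payoffs exist for every reachable terminal).
random_fixed_params <- function() {
  rp <- function() prob_list(runif(1), runif(1), 0, runif(1), runif(1),
                             runif(1), runif(1), runif(1))
  fixed_params(rp(), payoff_list(runif(8, 0, 3000)), payoff_list(runif(8)),
               rp(), payoff_list(runif(8, 0, 3000)), payoff_list(runif(8)))
}

# Independent brute-force tree walk: enumerate every terminal by explicit
# nested conditioning, no shared code with the implementation.
oracle_paths <- function(probs) {
  out <- list()
  add <- function(branch, p) out[[branch]] <<- p
  pt <- probs$p_test
  # tested, positive
  for (delab in c(TRUE, FALSE)) {
    pd <- if (delab) probs$p_delabel_pos else 1 - probs$p_delabel_pos
    tfp <- if (delab) probs$tf_neg_nopal else probs$tf_pos_pal
    base <- pt * probs$p_positive * pd
    lab <- if (delab) "pos_nopal" else "pos_pal"
    add(paste0(lab, "_tf"), base * tfp)
    add(paste0(lab, "_notf"), base * (1 - tfp))
  }
  # tested, negative
  for (delab in c(TRUE, FALSE)) {
    pd <- if (delab) probs$p_delabel_neg else 1 - probs$p_delabel_neg
    tfp <- if (delab) probs$tf_neg_nopal else probs$tf_neg_pal
    base <- pt * (1 - probs$p_positive) * pd
    lab <- if (delab) "neg_nopal" else "neg_pal"
    add(paste0(lab, "_tf"), base * tfp)
    add(paste0(lab, "_notf"), base * (1 - tfp))
  }
  # not tested
  add("notest_tf", (1 - pt) * probs$tf_notest)
  add("notest_notf", (1 - pt) * (1 - probs$tf_notest))
  unlist(out)
}

oracle_expected_payoff <- function(probs, payoffs) {
  p <- oracle_paths(probs)
  sum(vapply(names(payoffs), function(b) p[[b]] * payoffs[[b]], 0))
}

# Hand-built minimal participant table.
manual_table <- function(participants, years) {
  structure(list(participants = participants, years = years,
                 meta = list(seed = 0L, config_hash = "manual")),
            class = "participant_table")
}

year_row <- function(id, year, cost, utility, exposure = 365,
                     test = 0) {
  rest <- cost - test
  data.frame(id = id, year = as.integer(year), exposure_days = exposure,
             cost_test = test, primary_care = rest, medications = 0,
             admissions = 0, outpatient = 0, emergency = 0,
             cost_total = cost, utility = utility)
}

participant_row <- function(id, arm, tested, result, delab, tf,
                            age = 50, gender = "female", qof = 1, abx = 1) {
  data.frame(id = id, arm = arm, tested = tested,
             test_result = if (tested) result else "not_applicable",
             delabelled = delab, treatment_failure = tf,
             branch = NA_character_, age = age, gender = gender,
             qof_count = qof, abx_count = abx, stringsAsFactors = FALSE)
}

# Minimal psa_result wrapper for hand-set draws.
manual_psa <- function(delta_cost, delta_qaly, params = NULL,
                       extra = list()) {
  n <- length(delta_cost)
  draws <- data.frame(draw = seq_len(n),
                      cost_paap = rep(0, n), qaly_paap = rep(0, n),
                      cost_usual_care = rep(0, n),
                      qaly_usual_care = rep(0, n),
                      delta_cost = delta_cost, delta_qaly = delta_qaly,
                      p_tf_paap = rep(0.08, n),
                      p_tf_usual_care = rep(0.11, n))
  for (nm in names(extra)) draws[[nm]] <- extra[[nm]]
  structure(list(draws = draws,
                 params = if (is.null(params)) data.frame(dummy = rep(1, n))
                          else params,
                 summary = list(), n_draws = n, seed = 0L,
                 relabel_rate = 0, config = econ_config()),
            class = "psa_result")
}
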