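test_that("empty trial returns a valid empty table", {
  gen <- generator_config(n_per_arm = c(paap = 0, usual_care = 0))
  tab <- generate_trial(gen)
  expect_s3_class(tab, "participant_table")
  expect_identical(nrow(tab$participants), 0L)
  expect_identical(nrow(tab$years), 0L)
  expect_identical(tab$meta$seed, gen$seed)
  expect_match(tab$meta$config_hash, "^[0-9a-f]+$")
})

test_that("degenerate probabilities send every participant down one path", {
  # all tested, all negative, all de-labelled, no failures
  p1 <- fixed_params(prob_list(1, 0, 0, 1, 0, 0, 0, 0),
                     payoff_list(rep(100, 8)), payoff_list(rep(0.9, 8)))
  gen <- generator_config(params = p1, n_per_arm = c(paap = 3, usual_care = 3))
  tab <- generate_trial(gen)
  expect_true(all(tab$participants$branch == "neg_nopal_notf"))
  # nobody tested, everyone fails treatment
  p2 <- fixed_params(prob_list(0, 0, 0, 0, 0, 0, 0, 1),
                     payoff_list(rep(100, 8)), payoff_list(rep(0.9, 8)))
  tab2 <- generate_trial(generator_config(params = p2,
                                          n_per_arm = c(paap = 3,
                                                        usual_care = 3)))
  expect_true(all(tab2$participants$branch == "notest_tf"))
  expect_true(all(tab2$participants$test_result == "not_applicable"))
})

test_that("default test uptake matches the configured truth", {
  tab <- generate_trial(generator_config(seed = 20260929L))
  paap <- tab$participants[tab$participants$arm == "paap", ]
  expect_identical(nrow(paap), 401L)
  x <- sum(paap$tested)
  # exact binomial 99% interval around 0.910 at n=401
  expect_gte(x, qbinom(0.005, 401, 0.910))
  expect_lte(x, qbinom(0.995, 401, 0.910))
  # usual care rarely tested
  uc <- tab$participants[tab$participants$arm == "usual_care", ]
  expect_lte(sum(uc$tested), qbinom(0.995, 410, 0.012))
})

test_that("participant tables obey their structural invariants", {
  tab <- generate_trial(generator_config(seed = 5L))
  p <- tab$participants
  expect_false(any(duplicated(p$id)))
  expect_identical(p$test_result == "not_applicable", !p$tested)
  # de-labelling implies testing except the structural usual-care path
  expect_true(all(p$tested[p$delabelled & p$arm == "paap"]))
  y <- tab$years
  expect_true(all(y$exposure_days > 0 & y$exposure_days <= 366))
  expect_true(all(y$utility >= 0 & y$utility <= 1))
  comp <- y$cost_test + y$primary_care + y$medications + y$admissions +
    y$outpatient + y$emergency
  expect_equal(comp, y$cost_total, tolerance = 1e-10)
})

test_that("branch proportions converge to the configured path probabilities", {
  tab <- big_table_100k()
  params <- base_params()
  for (arm in c("paap", "usual_care")) {
    probs <- lapply(params[[arm]]$probs, function(d) d$mean)
    truth <- oracle_paths(probs)
    p <- tab$participants[tab$participants$arm == arm, ]
    n <- nrow(p)
    for (b in names(truth)) {
      obs <- mean(p$branch == b)
      se <- sqrt(truth[[b]] * (1 - truth[[b]]) / n)
      expect_lt(abs(obs - truth[[b]]), 3 * se + 1e-12)
    }
  }
})

test_that("generation is reproducible and serialization round-trips", {
  gen <- generator_config(n_per_arm = c(paap = 40, usual_care = 40),
                          seed = 77L)
  t1 <- generate_trial(gen)
  t2 <- generate_trial(gen)
  expect_identical(t1, t2)
  dir <- withr::local_tempdir()
  write_participant_table(t1, dir)
  t3 <- read_participant_table(dir)
  expect_equal(t3$participants, t1$participants)
  expect_equal(t3$years, t1$years, tolerance = 0)
  expect_identical(t3$meta$seed, t1$meta$seed)
  # byte-for-byte determinism of the canonical serialization
  dir2 <- withr::local_tempdir()
  write_participant_table(t2, dir2)
  for (f in list.files(dir))
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)))
})

test_that("as-treated reassignment moves exactly the untested PAAP patients", {
  tab <- generate_trial(generator_config(seed = 3L))
  at <- as_treated_reassign(tab)
  expect_identical(nrow(at$participants), nrow(tab$participants))
  # brute-force row scan oracle
  n_paap <- 0L; n_uc <- 0L
  for (i in seq_len(nrow(tab$participants))) {
    r <- tab$participants[i, ]
    if (r$arm == "paap" && !r$tested) n_uc <- n_uc + 1L
    else if (r$arm == "paap") n_paap <- n_paap + 1L
    else n_uc <- n_uc + 1L
  }
  expect_identical(sum(at$participants$arm == "paap"), n_paap)
  expect_identical(sum(at$participants$arm == "usual_care"), n_uc)
  # every non-arm field unchanged
  expect_identical(at$participants[setdiff(names(at$participants), "arm")],
                   tab$participants[setdiff(names(tab$participants), "arm")])
  expect_identical(at$years, tab$years)
  # all-tested table is unchanged
  all_tested <- tab
  keep <- all_tested$participants$tested | all_tested$participants$arm != "paap"
  all_tested <- paapcea:::subset_table(all_tested,
                                       all_tested$participants$id[keep])
  expect_identical(as_treated_reassign(all_tested)$participants$arm,
                   all_tested$participants$arm)
})

test_that("censoring scales observed costs to the exposed window", {
  gen <- generator_config(n_per_arm = c(paap = 20, usual_care = 20),
                          censor_fraction = 0, seed = 8L)
  tab <- generate_trial(gen)
  expect_identical(apply_censoring(tab, gen), tab)

  # one participant, uniform daily cost c: censoring at day 100 leaves 100c
  daily <- 2.5
  tab1 <- manual_table(participant_row(1L, "paap", TRUE, "negative", TRUE,
                                       FALSE),
                       do.call(rbind, lapply(1:5, function(t)
                         year_row(1L, t, 365 * daily, 0.9))))
  gen1 <- generator_config(n_per_arm = c(paap = 1, usual_care = 0),
                           censor_fraction = 1,
                           censor_window_days = c(100, 100))
  cens <- apply_censoring(tab1, gen1)
  expect_identical(nrow(cens$years), 1L)
  expect_equal(cens$years$exposure_days, 100)
  expect_equal(cens$years$cost_total, 100 * daily)

  # binomial check on the censored fraction within year 2
  gen2 <- generator_config(n_per_arm = c(paap = 2000, usual_care = 2000),
                           censor_fraction = 0.3,
                           censor_window_days = c(366, 730), seed = 12L)
  cens2 <- apply_censoring(generate_trial(gen2), gen2)
  y2 <- cens2$years[cens2$years$year == 2, ]
  x <- sum(y2$exposure_days < 365)
  expect_gte(x, qbinom(0.005, nrow(y2), 0.3))
  expect_lte(x, qbinom(0.995, nrow(y2), 0.3))
  # years after the censoring year carry no records
  expect_identical(nrow(cens2$years[cens2$years$year > 2 &
                                      cens2$years$id %in%
                                        y2$id[y2$exposure_days < 365], ]), 0L)
})

test_that("arm summaries report annualised means and SDs", {
  tab <- manual_table(participant_row(1L, "paap", TRUE, "negative", TRUE,
                                      FALSE),
                      year_row(1L, 1, 500, 0.8))
  s <- summarize_arm(tab, "paap")
  expect_false(attr(s, "empty"))
  expect_equal(s$mean[s$quantity == "cost_total"], 500)
  expect_equal(s$mean[s$quantity == "utility"], 0.8)
  expect_true(all(s$sd == 0))
  empty <- summarize_arm(tab, "usual_care")
  expect_true(attr(empty, "empty"))
  expect_identical(nrow(empty), 0L)

  # Monte-Carlo check: first-year mean total cost near configured truth
  tab2 <- big_table_50k()
  s2 <- summarize_arm(tab2, "paap")
  m <- s2$mean[s2$year == 1 & s2$quantity == "cost_total"]
  params <- base_params()
  probs <- lapply(params$paap$probs, function(d) d$mean)
  truth <- oracle_expected_payoff(
    probs, lapply(params$paap$costs, function(d) d$mean))
  se <- s2$sd[s2$year == 1 & s2$quantity == "cost_total"] / sqrt(50000)
  expect_lt(abs(m - truth), 3 * se)
})
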