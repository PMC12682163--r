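#' Incremental cost-effectiveness ratio with dominance classification
#'
#' A strategy that saves costs and gains QALYs is dominant (no ratio is
#' reported); one that adds costs and loses QALYs is dominated. Same-sign
#' pairs yield the ratio with its quadrant: in the south-west quadrant
#' (cost saving, QALYs lost) the positive ratio is interpreted as the
#' saving per QALY lost. A zero QALY difference gives an undefined ratio.
#'
#' @param delta_cost incremental cost (intervention minus comparator).
#' @param delta_qaly incremental QALYs.
#' @return list with \code{value} (the ratio, or \code{NA} when dominant,
#'   dominated or undefined) and \code{class} in \code{"dominant"},
#'   \code{"dominated"}, \code{"north_east"}, \code{"south_west"},
#'   \code{"undefined"}.
#' @export
icer <- function(delta_cost, delta_qaly) {
  stopifnot(is.finite(delta_cost), is.finite(delta_qaly))
  if (delta_qaly == 0)
    return(list(value = NA_real_, class = "undefined"))
  if (delta_cost < 0 && delta_qaly > 0)
    return(list(value = NA_real_, class = "dominant"))
  if (delta_cost > 0 && delta_qaly < 0)
    return(list(value = NA_real_, class = "dominated"))
  cls <- if (delta_qaly > 0) "north_east" else "south_west"
  list(value = delta_cost / delta_qaly, class = cls)
}

#' Incremental net monetary benefit
#'
#' \eqn{INMB(\lambda) = \lambda \Delta Q - \Delta C}; exactly linear in
#' the willingness to pay.
#'
#' @param delta_cost,delta_qaly incremental cost and QALYs (vectorised).
#' @param wtp willingness to pay per QALY, >= 0.
#' @return currency value(s).
#' @export
inmb <- function(delta_cost, delta_qaly, wtp) {
  stopifnot(all(wtp >= 0))
  wtp * delta_qaly - delta_cost
}

#' Deterministic cost-effectiveness comparison at the parameter means
#'
#' Runs the decision tree and extrapolation for both arms at the parameter
#' means and assembles the incremental results.
#'
#' @param params resolved \code{\link{branch_params}}.
#' @param reg a \code{\link{cost_regression}}.
#' @param config an \code{\link{econ_config}}.
#' @param relabel_rate annual relabelling rate for the Markov scenario
#'   (0 = base-case extrapolation).
#' @return object of class \code{"cea_result"}: incremental cost and
#'   QALYs, ICER with dominance class, INMB over the configured
#'   willingness-to-pay grid, and the per-arm trajectories.
#' @export
deterministic_cea <- function(params, reg = cost_regression(),
                              config = econ_config(), relabel_rate = 0) {
  tree <- tree_spec()
  traj <- lapply(ARMS, function(a) {
    y1 <- expected_year1_payoffs(tree, params, a, config)
    st <- end_of_year1_states(tree, params, a)
    markov_relabel(st, y1, reg, relabel_rate, config)
  })
  names(traj) <- ARMS
  tc <- vapply(traj, attr, 0, "total_cost")
  tq <- vapply(traj, attr, 0, "total_qaly")
  dc <- tc[["paap"]] - tc[["usual_care"]]
  dq <- tq[["paap"]] - tq[["usual_care"]]
  structure(list(delta_cost = dc, delta_qaly = dq,
                 icer = icer(dc, dq),
                 inmb = stats::setNames(inmb(dc, dq, config$wtp_grid),
                                        config$wtp_grid),
                 totals = list(cost = tc, qaly = tq),
                 trajectories = traj,
                 relabel_rate = relabel_rate),
            class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat("Cost-effectiveness comparison (intervention vs usual care)\n")
  cat(sprintf("  incremental cost:  %10.3f\n", x$delta_cost))
  cat(sprintf("  incremental QALYs: %10.4f\n", x$delta_qaly))
  lab <- switch(x$icer$class,
                dominant = "Dominant (saves costs, gains QALYs)",
                dominated = "Dominated (adds costs, loses QALYs)",
                undefined = "Undefined (zero QALY difference)",
                south_west = sprintf("%.3f per QALY lost (cost saving)",
                                     x$icer$value),
                sprintf("%.3f per QALY", x$icer$value))
  cat(sprintf("  ICER: %s\n", lab))
  for (w in c(20000, 30000))
    if (as.character(w) %in% names(x$inmb))
      cat(sprintf("  INMB at %d: %.3f\n", w, x$inmb[[as.character(w)]]))
  invisible(x)
}

param_columns <- function(params, reg) {
  cols <- list()
  for (arm in ARMS) {
    a <- params[[arm]]
    for (nm in names(a$probs)) cols[[paste(arm, nm, sep = ".")]] <- a$probs[[nm]]
    for (nm in names(a$costs)) cols[[paste(arm, "cost", nm, sep = ".")]] <- a$costs[[nm]]
    for (nm in names(a$qalys)) cols[[paste(arm, "qaly", nm, sep = ".")]] <- a$qalys[[nm]]
  }
  cols[["reg.baseline"]] <- dist_spec(if (reg$baseline_sd > 0) "lognormal" else "fixed",
                                      reg$baseline, reg$baseline_sd)
  cols[["reg.delabel_mult"]] <- dist_spec(if (reg$delabel_sd > 0) "lognormal" else "fixed",
                                          reg$delabel_mult, reg$delabel_sd)
  cols[["reg.tf_mult"]] <- dist_spec(if (reg$tf_sd > 0) "lognormal" else "fixed",
                                     reg$tf_mult, reg$tf_sd)
  cols
}

#' Sample parameter vectors for probabilistic sensitivity analysis
#'
#' Independent draws of every model parameter from its configured family
#' (Beta and lognormal by moment matching; fixed parameters constant),
#' including the post-year-1 cost-model components.
#'
#' @param params resolved \code{\link{branch_params}}.
#' @param reg a \code{\link{cost_regression}}.
#' @param n_draws number of draws.
#' @param seed RNG seed.
#' @return data frame, one row per draw, one named column per parameter.
#' @export
sample_parameters <- function(params, reg = cost_regression(),
                              n_draws = 10000, seed = 1L) {
  stopifnot(inherits(params, "branch_params"), n_draws >= 1)
  if (!params_resolved(params))
    stop("parameter set has unresolved empty branches")
  set.seed(seed)
  cols <- param_columns(params, reg)
  out <- as.data.frame(lapply(cols, sample_dist, n = n_draws))
  names(out) <- names(cols) # preserve dots
  out
}

# Vectorised model evaluation over sampled parameter rows. Returns
# per-draw per-arm discounted totals plus first-year summaries.
eval_draws <- function(theta, config, relabel_rate = 0) {
  H <- config$horizon_years
  f <- config$year1_exposure_fraction
  d <- config$discount_rate
  g <- function(nm) theta[[nm]]
  res <- list()
  for (arm in ARMS) {
    pr <- lapply(stats::setNames(PROB_NAMES, PROB_NAMES),
                 function(nm) g(paste(arm, nm, sep = ".")))
    P <- path_prob_matrix(pr)
    if (any(P[, STRUCTURAL_BRANCHES] > 1e-12))
      stop("positive-and-delabelled branches have positive probability but no payoff")
    C <- sapply(PAYOFF_BRANCHES,
                function(b) g(paste(arm, "cost", b, sep = ".")))
    Q <- sapply(PAYOFF_BRANCHES,
                function(b) g(paste(arm, "qaly", b, sep = ".")))
    if (is.null(dim(C))) { C <- matrix(C, nrow = 1); Q <- matrix(Q, nrow = 1)
                           colnames(C) <- colnames(Q) <- PAYOFF_BRANCHES }
    Pp <- P[, PAYOFF_BRANCHES, drop = FALSE]
    if (is.null(dim(Pp))) Pp <- matrix(Pp, nrow = 1,
                                       dimnames = list(NULL, PAYOFF_BRANCHES))
    y1c <- f * rowSums(Pp * C)
    y1q <- f * rowSums(Pp * Q)
    p_pal_tf <- Pp[, "pos_pal_tf"] + Pp[, "neg_pal_tf"] + Pp[, "notest_tf"]
    p_pal_notf <- Pp[, "pos_pal_notf"] + Pp[, "neg_pal_notf"] +
      Pp[, "notest_notf"]
    p_nopal_tf <- Pp[, "neg_nopal_tf"]
    p_nopal_notf <- Pp[, "neg_nopal_notf"]
    b0 <- g("reg.baseline"); dm <- g("reg.delabel_mult"); tm <- g("reg.tf_mult")
    # relabelling reversion targets: labelled-state mean utilities
    q_rel_tf <- ifelse(p_pal_tf > 0,
                       (Pp[, "pos_pal_tf"] * Q[, "pos_pal_tf"] +
                          Pp[, "neg_pal_tf"] * Q[, "neg_pal_tf"] +
                          Pp[, "notest_tf"] * Q[, "notest_tf"]) / p_pal_tf,
                       Q[, "notest_tf"])
    q_rel_notf <- ifelse(p_pal_notf > 0,
                         (Pp[, "pos_pal_notf"] * Q[, "pos_pal_notf"] +
                            Pp[, "neg_pal_notf"] * Q[, "neg_pal_notf"] +
                            Pp[, "notest_notf"] * Q[, "notest_notf"]) /
                           p_pal_notf,
                         Q[, "notest_notf"])
    cost_tot <- y1c; qaly_tot <- y1q
    for (t in 2:H) {
      kept <- (1 - relabel_rate)^(t - 1)
      m_tf <- p_nopal_tf * (1 - kept)
      m_notf <- p_nopal_notf * (1 - kept)
      cost_t <- b0 * ((p_pal_tf + m_tf) * tm + (p_pal_notf + m_notf) +
                      (p_nopal_tf - m_tf) * dm * tm +
                      (p_nopal_notf - m_notf) * dm)
      qaly_t <- y1q - f * (m_tf * (Q[, "neg_nopal_tf"] - q_rel_tf) +
                           m_notf * (Q[, "neg_nopal_notf"] - q_rel_notf))
      disc <- (1 + d)^-(t - 1)
      cost_tot <- cost_tot + cost_t * disc
      qaly_tot <- qaly_tot + qaly_t * disc
    }
    res[[arm]] <- list(cost = cost_tot, qaly = qaly_tot,
                       y1_cost = y1c, y1_qaly = y1q,
                       p_tf = p_pal_tf + p_nopal_tf)
  }
  res
}

#' Run the probabilistic sensitivity analysis
#'
#' Propagates every parameter's uncertainty through the full model: for
#' each sampled parameter vector the decision tree and extrapolation are
#' evaluated for both arms, giving per-draw costs and QALYs.
#'
#' @inheritParams deterministic_cea
#' @param n_draws number of draws (default from \code{config}).
#' @param seed RNG seed (default from \code{config}).
#' @return object of class \code{"psa_result"}: \code{draws} (per-draw
#'   strategy costs/QALYs, increments and arm treatment-failure
#'   probabilities), \code{params} (the sampled parameter matrix),
#'   \code{summary} (mean increments, INMB and probability cost-effective
#'   at 20,000 and 30,000 per QALY, probability of cost saving, failed
#'   draw count) and metadata.
#' @export
run_psa <- function(params, reg = cost_regression(), config = econ_config(),
                    relabel_rate = 0, n_draws = config$psa_draws,
                    seed = config$seed) {
  theta <- sample_parameters(params, reg, n_draws, seed)
  ev <- eval_draws(theta, config, relabel_rate)
  draws <- data.frame(
    draw = seq_len(n_draws),
    cost_paap = ev$paap$cost, qaly_paap = ev$paap$qaly,
    cost_usual_care = ev$usual_care$cost, qaly_usual_care = ev$usual_care$qaly,
    delta_cost = ev$paap$cost - ev$usual_care$cost,
    delta_qaly = ev$paap$qaly - ev$usual_care$qaly,
    p_tf_paap = ev$paap$p_tf, p_tf_usual_care = ev$usual_care$p_tf)
  ok <- is.finite(draws$delta_cost) & is.finite(draws$delta_qaly)
  failed <- sum(!ok)
  dc <- draws$delta_cost[ok]; dq <- draws$delta_qaly[ok]
  summ <- list(
    mean_delta_cost = mean(dc), mean_delta_qaly = mean(dq),
    inmb_20000 = inmb(mean(dc), mean(dq), 20000),
    inmb_30000 = inmb(mean(dc), mean(dq), 30000),
    p_ce_20000 = mean(inmb(dc, dq, 20000) > 0),
    p_ce_30000 = mean(inmb(dc, dq, 30000) > 0),
    p_cost_saving = mean(dc < 0),
    p_qaly_gain = mean(dq > 0),
    failed_draws = failed)
  structure(list(draws = draws, params = theta, summary = summ,
                 n_draws = n_draws, seed = seed,
                 relabel_rate = relabel_rate, config = config),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("PSA (%d draws, seed %d%s)\n", x$n_draws, x$seed,
              if (x$relabel_rate > 0)
                sprintf(", relabel rate %.4f", x$relabel_rate) else ""))
  cat(sprintf("  mean incremental cost  %10.3f  (P(cost saving) %.1f%%)\n",
              s$mean_delta_cost, 100 * s$p_cost_saving))
  cat(sprintf("  mean incremental QALYs %10.4f  (P(QALY gain) %.1f%%)\n",
              s$mean_delta_qaly, 100 * s$p_qaly_gain))
  cat(sprintf("  INMB at 20,000: %9.3f  (P(CE) %.0f%%)\n",
              s$inmb_20000, 100 * s$p_ce_20000))
  cat(sprintf("  INMB at 30,000: %9.3f  (P(CE) %.0f%%)\n",
              s$inmb_30000, 100 * s$p_ce_30000))
  if (s$failed_draws > 0)
    cat(sprintf("  %d failed draw(s) excluded from summaries\n",
                s$failed_draws))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws with
#' strictly positive incremental net monetary benefit; ties count as not
#' cost-effective. At a threshold of zero the curve equals the probability
#' of cost saving.
#'
#' @param psa a \code{"psa_result"} or a data frame with
#'   \code{delta_cost}/\code{delta_qaly} columns.
#' @param wtp_grid ascending willingness-to-pay grid.
#' @return object of class \code{"ceac_curve"}: data frame \code{wtp},
#'   \code{p_cost_effective}; attribute \code{p_cost_saving}.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 50000, by = 1000)) {
  draws <- if (inherits(psa, "psa_result")) psa$draws else psa
  if (nrow(draws) == 0) stop("no draws to summarise")
  dc <- draws$delta_cost; dq <- draws$delta_qaly
  p <- vapply(wtp_grid, function(w) mean(inmb(dc, dq, w) > 0), 0)
  out <- data.frame(wtp = wtp_grid, p_cost_effective = p)
  attr(out, "p_cost_saving") <- mean(dc < 0)
  class(out) <- c("ceac_curve", "data.frame")
  out
}

subset_table <- function(table, keep_ids) {
  structure(list(
    participants = table$participants[table$participants$id %in% keep_ids, ],
    years = table$years[table$years$id %in% keep_ids, ],
    meta = table$meta), class = "participant_table")
}

default_splits <- function() list(
  gender = function(p) ifelse(p$gender == "female", "female", "male"),
  age = function(p) ifelse(p$age < 65, "age_under_65", "age_65_plus"),
  qof = function(p) ifelse(p$qof_count < 2, "qof_under_2", "qof_2_plus"),
  abx = function(p) ifelse(p$abx_count < 2, "abx_under_2", "abx_2_plus"))

#' Subgroup cost-effectiveness analysis
#'
#' Re-runs the whole pipeline (parameter estimation, substitution,
#' post-year-1 cost fit, decision model, deterministic comparison and PSA)
#' within each stratum of each split.
#'
#' @param table a \code{"participant_table"}.
#' @param splits named list of functions mapping the participant frame to
#'   a stratum label per participant; default splits by gender, age 65,
#'   two QOF-registered conditions, and two baseline antibiotic courses.
#' @param config an \code{\link{econ_config}}.
#' @param n_draws PSA draws per stratum.
#' @param min_n strata below this size are flagged (still reported).
#' @param sd_mode uncertainty-SD convention for estimation.
#' @return data frame: one row per stratum with n, incremental cost and
#'   QALYs, ICER class/value, INMB and probability cost-effective at
#'   20,000 and 30,000 per QALY, and a small-stratum flag.
#' @export
subgroup_cea <- function(table, splits = default_splits(),
                         config = econ_config(), n_draws = 2000,
                         min_n = 50, sd_mode = "sample") {
  stopifnot(inherits(table, "participant_table"))
  rows <- list()
  for (sp in names(splits)) {
    lab <- splits[[sp]](table$participants)
    for (st in sort(unique(lab))) {
      ids <- table$participants$id[lab == st]
      sub <- subset_table(table, ids)
      n <- nrow(sub$participants)
      res <- tryCatch({
        pars <- resolve_missing_branches(estimate_params(sub, sd_mode))
        reg <- fit_post_year1_cost_model(sub)
        det <- deterministic_cea(pars, reg, config)
        psa <- run_psa(pars, reg, config, n_draws = n_draws,
                       seed = config$seed)
        data.frame(split = sp, stratum = st, n = n,
                   delta_cost = det$delta_cost, delta_qaly = det$delta_qaly,
                   icer_class = det$icer$class,
                   icer_value = if (is.na(det$icer$value)) NA_real_ else det$icer$value,
                   inmb_20000 = inmb(det$delta_cost, det$delta_qaly, 20000),
                   inmb_30000 = inmb(det$delta_cost, det$delta_qaly, 30000),
                   p_ce_20000 = psa$summary$p_ce_20000,
                   p_ce_30000 = psa$summary$p_ce_30000,
                   small_stratum = n < min_n,
                   error = NA_character_, stringsAsFactors = FALSE)
      }, error = function(e)
        data.frame(split = sp, stratum = st, n = n,
                   delta_cost = NA_real_, delta_qaly = NA_real_,
                   icer_class = NA_character_, icer_value = NA_real_,
                   inmb_20000 = NA_real_, inmb_30000 = NA_real_,
                   p_ce_20000 = NA_real_, p_ce_30000 = NA_real_,
                   small_stratum = n < min_n,
                   error = conditionMessage(e), stringsAsFactors = FALSE))
      rows[[length(rows) + 1]] <- res
    }
  }
  do.call(rbind, rows)
}

#' Probability that a relabelling rate is below the model's thresholds
#'
#' For a candidate annual relabelling rate (for example a rate reported in
#' the literature), the probability across PSA draws that it lies below
#' the rate at which the intervention's net monetary benefit turns
#' negative, and below the rate at which the intervention becomes cost
#' increasing. Because both quantities are monotone in the relabelling
#' rate, the event "the candidate rate is below the threshold" is
#' evaluated draw-by-draw as the sign of the quantity at the candidate
#' rate itself.
#'
#' @inheritParams deterministic_cea
#' @param rate candidate annual relabelling rate.
#' @param wtp willingness to pay for the net-benefit threshold.
#' @param n_draws,seed PSA settings.
#' @return list: \code{p_below_inmb_zero}, \code{p_below_cost_saving}.
#' @export
relabel_threshold_probability <- function(params, reg = cost_regression(),
                                          config = econ_config(),
                                          rate = 0.032, wtp = 20000,
                                          n_draws = config$psa_draws,
                                          seed = config$seed) {
  psa <- run_psa(params, reg, config, relabel_rate = rate,
                 n_draws = n_draws, seed = seed)
  dc <- psa$draws$delta_cost; dq <- psa$draws$delta_qaly
  list(p_below_inmb_zero = mean(inmb(dc, dq, wtp) > 0),
       p_below_cost_saving = mean(dc < 0))
}
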