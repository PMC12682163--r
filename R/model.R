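#' Fit the five-year cost-effectiveness model
#'
#' The package's central object: a two-arm decision-tree model of a
#' penicillin allergy assessment pathway versus usual care, with
#' regression-based cost extrapolation to the model horizon. The model
#' can be fitted either from a parameter set (defaulting to the published
#' base-case table) or from individual-level trial data, in which case
#' every parameter is re-estimated: branch probabilities and payoffs via
#' \code{\link{estimate_params}} (with missing-branch substitution) and
#' the post-year-1 cost model via \code{\link{fit_post_year1_cost_model}}.
#'
#' @param params a \code{\link{branch_params}}; ignored when \code{data}
#'   is supplied. Defaults to the published base-case table.
#' @param reg a \code{\link{cost_regression}}; ignored when \code{data} is
#'   supplied.
#' @param config an \code{\link{econ_config}}.
#' @param data optional \code{"participant_table"} of individual-level
#'   trial records to estimate all parameters from.
#' @param sd_mode uncertainty-SD convention when estimating from data
#'   (\code{"sample"} or \code{"se"}).
#' @return an object of class \code{"paap_model"} with components
#'   \code{params}, \code{reg}, \code{config} and the fitted
#'   deterministic comparison \code{cea}.
#' @seealso \code{\link{summary.paap_model}},
#'   \code{\link{simulate.paap_model}}, \code{\link{predict.paap_model}},
#'   \code{\link{relabel_thresholds}}
#' @examples
#' m <- paap_model()
#' m
#' coef(m)[1:5]
#' @export
paap_model <- function(params = NULL, reg = NULL, config = econ_config(),
                       data = NULL, sd_mode = "sample") {
  if (!is.null(data)) {
    stopifnot(inherits(data, "participant_table"))
    params <- resolve_missing_branches(estimate_params(data, sd_mode))
    reg <- fit_post_year1_cost_model(data)
  } else {
    if (is.null(params)) params <- resolve_missing_branches(table2_params())
    if (is.null(reg)) reg <- cost_regression()
  }
  stopifnot(inherits(params, "branch_params"),
            inherits(reg, "cost_regression"),
            inherits(config, "econ_config"))
  if (!params_resolved(params))
    params <- resolve_missing_branches(params)
  structure(list(params = params, reg = reg, config = config,
                 cea = deterministic_cea(params, reg, config),
                 fitted_from_data = !is.null(data)),
            class = "paap_model")
}

#' @export
print.paap_model <- function(x, ...) {
  cat("Five-year decision-tree cost-effectiveness model",
      if (x$fitted_from_data) "(parameters estimated from data)" else
        "(published base-case parameters)", "\n")
  cat(sprintf("  horizon %d years, discount %.1f%%, year-1 exposure fraction %g\n",
              x$config$horizon_years, 100 * x$config$discount_rate,
              x$config$year1_exposure_fraction))
  print(x$cea)
  invisible(x)
}

#' Model parameter means
#'
#' @param object a \code{"paap_model"}.
#' @param ... unused.
#' @return named numeric vector of every parameter's mean (branch
#'   probabilities, payoffs and cost-model components).
#' @export
coef.paap_model <- function(object, ...) {
  cols <- param_columns(object$params, object$reg)
  vapply(cols, function(d) d$mean, 0)
}

#' Per-arm trajectories under the fitted model
#'
#' @param object a \code{"paap_model"}.
#' @param arm \code{"paap"}, \code{"usual_care"} or \code{"both"}.
#' @param relabel_rate annual relabelling rate for the Markov scenario.
#' @param ... unused.
#' @return an \code{"arm_trajectory"} (or a named list of two).
#' @export
predict.paap_model <- function(object, arm = c("both", "paap", "usual_care"),
                               relabel_rate = 0, ...) {
  arm <- match.arg(arm)
  tree <- tree_spec()
  one <- function(a) {
    y1 <- expected_year1_payoffs(tree, object$params, a, object$config)
    st <- end_of_year1_states(tree, object$params, a)
    markov_relabel(st, y1, object$reg, relabel_rate, object$config)
  }
  if (arm != "both") return(one(arm))
  stats::setNames(lapply(ARMS, one), ARMS)
}

#' Summary of the fitted model: per-period totals and incremental results
#'
#' @param object a \code{"paap_model"}.
#' @param ... unused.
#' @return object of class \code{"summary.paap_model"} with a per-period
#'   table (year-1 and discounted years 2+ costs and QALYs per arm with
#'   differences) and the deterministic comparison.
#' @export
summary.paap_model <- function(object, ...) {
  traj <- object$cea$trajectories
  per_period <- do.call(rbind, lapply(c("cost", "qaly"), function(q) {
    y1 <- vapply(traj, function(tr) tr[[paste0("disc_", q)]][1], 0)
    later <- vapply(traj, function(tr) sum(tr[[paste0("disc_", q)]][-1]), 0)
    data.frame(quantity = paste0(q, c("_year1", "_year2plus_discounted")),
               paap = c(y1[["paap"]], later[["paap"]]),
               usual_care = c(y1[["usual_care"]], later[["usual_care"]]))
  }))
  per_period$difference <- per_period$paap - per_period$usual_care
  structure(list(per_period = per_period, cea = object$cea,
                 config = object$config), class = "summary.paap_model")
}

#' @export
print.summary.paap_model <- function(x, ...) {
  cat("Per-period totals (discounted):\n")
  print(x$per_period, row.names = FALSE, digits = 6)
  cat("\n")
  print(x$cea)
  invisible(x)
}

#' Probabilistic sensitivity analysis of a fitted model
#'
#' @param object a \code{"paap_model"}.
#' @param nsim number of parameter draws.
#' @param seed RNG seed (default the model configuration's).
#' @param relabel_rate annual relabelling rate for the Markov scenario.
#' @param ... unused.
#' @return a \code{"psa_result"}; see \code{\link{run_psa}}.
#' @export
simulate.paap_model <- function(object, nsim = object$config$psa_draws,
                                seed = object$config$seed,
                                relabel_rate = 0, ...) {
  run_psa(object$params, object$reg, object$config,
          relabel_rate = relabel_rate, n_draws = nsim, seed = seed)
}

#' Plot a fitted model's probabilistic results
#'
#' \code{type = "ce_plane"} draws the cost-effectiveness plane (per-draw
#' incremental QALYs against incremental costs, with the willingness-to-
#' pay line); \code{type = "ceac"} draws the cost-effectiveness
#' acceptability curve.
#'
#' @param x a \code{"paap_model"}.
#' @param type plot type.
#' @param psa an optional pre-computed \code{"psa_result"} (simulated at
#'   the model defaults otherwise).
#' @param wtp willingness to pay drawn on the plane.
#' @param ... passed to the underlying plotting function.
#' @return the \code{"psa_result"} used, invisibly.
#' @export
plot.paap_model <- function(x, type = c("ce_plane", "ceac"), psa = NULL,
                            wtp = 20000, ...) {
  type <- match.arg(type)
  if (is.null(psa)) psa <- simulate(x)
  d <- psa$draws
  if (type == "ce_plane") {
    graphics::plot(d$delta_qaly, d$delta_cost, pch = 16, cex = 0.3,
                   col = grDevices::adjustcolor("steelblue", 0.4),
                   xlab = "Incremental QALYs",
                   ylab = "Incremental cost (GBP)",
                   main = "Cost-effectiveness plane", ...)
    graphics::abline(h = 0, v = 0, col = "grey40")
    graphics::abline(a = 0, b = wtp, lty = 2, col = "firebrick")
    graphics::points(mean(d$delta_qaly), mean(d$delta_cost), pch = 3,
                     cex = 1.5, lwd = 2, col = "black")
  } else {
    cv <- ceac(psa, x$config$wtp_grid)
    graphics::plot(cv$wtp, cv$p_cost_effective, type = "l", lwd = 2,
                   ylim = c(0, 1),
                   xlab = "Willingness to pay (GBP per QALY)",
                   ylab = "Probability cost-effective",
                   main = "Cost-effectiveness acceptability curve", ...)
    graphics::abline(h = 0.5, lty = 3, col = "grey50")
  }
  invisible(psa)
}

#' Adjust branch cost payoffs for an alternative testing unit cost
#'
#' Sensitivity-analysis helper: shifts the mean first-year cost payoff of
#' every tested branch by the difference between an alternative unit cost
#' of the testing episode (for example a day-case tariff, or centre-
#' specific micro-costs) and the baseline unit cost embedded in the
#' payoffs. Uncertainty SDs are unchanged.
#'
#' @param params a \code{\link{branch_params}}.
#' @param test_cost alternative unit cost per tested participant.
#' @param baseline_test_cost unit cost embedded in the current payoffs.
#' @param arm arm(s) to adjust; testing is rare under usual care, so the
#'   default adjusts the intervention arm only.
#' @return a \code{\link{branch_params}} with shifted cost means.
#' @export
apply_unit_cost_scenario <- function(params, test_cost,
                                     baseline_test_cost = 186.29,
                                     arm = "paap") {
  stopifnot(inherits(params, "branch_params"), test_cost >= 0)
  delta <- test_cost - baseline_test_cost
  tested_branches <- grep("^(pos|neg)_", PAYOFF_BRANCHES, value = TRUE)
  out <- params
  for (a in arm) {
    for (b in tested_branches) {
      d <- out[[a]]$costs[[b]]
      out[[a]]$costs[[b]] <- dist_spec(d$family, max(d$mean + delta, 0.01),
                                       d$sd)
    }
  }
  out
}
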