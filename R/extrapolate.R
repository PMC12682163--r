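#' Economic evaluation configuration
#'
#' @param discount_rate annual discount rate applied to costs and QALYs
#'   from year 2 (year 1 is undiscounted; year t is weighted
#'   \eqn{(1+d)^{-(t-1)}}).
#' @param horizon_years modelled horizon, in years.
#' @param wtp_grid ascending willingness-to-pay grid (currency per QALY)
#'   for acceptability curves.
#' @param year1_exposure_fraction scaling applied to the tree's expected
#'   year-1 cost and QALY (and hence to the constant annual QALY carried
#'   into later years); 1 uses the branch payoffs as-is.
#' @param psa_draws default number of probabilistic sensitivity analysis
#'   draws.
#' @param seed RNG seed recorded with probabilistic output.
#' @return object of class \code{"econ_config"}.
#' @export
econ_config <- function(discount_rate = 0.035, horizon_years = 5,
                        wtp_grid = seq(0, 50000, by = 1000),
                        year1_exposure_fraction = 1,
                        psa_draws = 10000, seed = 1L) {
  stopifnot(discount_rate >= 0, horizon_years >= 1,
            length(wtp_grid) >= 1, !is.unsorted(wtp_grid),
            year1_exposure_fraction > 0, year1_exposure_fraction <= 1,
            psa_draws >= 1)
  structure(list(discount_rate = discount_rate,
                 horizon_years = as.integer(horizon_years),
                 wtp_grid = wtp_grid,
                 year1_exposure_fraction = year1_exposure_fraction,
                 psa_draws = as.integer(psa_draws),
                 seed = as.integer(seed)),
            class = "econ_config")
}

#' Post-year-1 annual cost model
#'
#' Multiplicative model of annual healthcare cost in years 2 and beyond as
#' a function of 12-month allergy-label status and year-1 treatment
#' failure: \code{cost = baseline * delabel_mult^[no label] *
#' tf_mult^[TF] * drift^(year-2)}. The reference category (baseline) is a
#' labelled participant without treatment failure. Each component carries
#' an uncertainty SD for probabilistic analysis (sampled lognormal).
#'
#' @param baseline annual cost (currency/year) for the labelled, no-failure
#'   reference, > 0.
#' @param delabel_mult multiplicative effect of having had the allergy
#'   label removed at 12 months (< 1 means de-labelled patients cost less).
#' @param tf_mult multiplicative effect of year-1 treatment failure.
#' @param drift optional multiplicative year-on-year drift (1 = none).
#' @param baseline_sd,delabel_sd,tf_sd uncertainty SDs; 0 fixes the
#'   component in probabilistic analysis.
#' @return object of class \code{"cost_regression"}.
#' @export
cost_regression <- function(baseline = 1500, delabel_mult = 0.92,
                            tf_mult = 1.42, drift = 1,
                            baseline_sd = 150, delabel_sd = 0.0125,
                            tf_sd = 0.018) {
  stopifnot(baseline > 0, delabel_mult > 0, tf_mult > 0, drift > 0,
            baseline_sd >= 0, delabel_sd >= 0, tf_sd >= 0)
  structure(list(baseline = baseline, delabel_mult = delabel_mult,
                 tf_mult = tf_mult, drift = drift,
                 baseline_sd = baseline_sd, delabel_sd = delabel_sd,
                 tf_sd = tf_sd),
            class = "cost_regression")
}

#' @export
print.cost_regression <- function(x, ...) {
  cat(sprintf(paste0("Post-year-1 annual cost model:\n",
                     "  baseline (labelled, no TF): %.2f /year\n",
                     "  de-labelled multiplier:     %.3f\n",
                     "  treatment-failure multiplier: %.3f\n",
                     "  annual drift: %.3f\n"),
              x$baseline, x$delabel_mult, x$tf_mult, x$drift))
  invisible(x)
}

#' Predicted annual cost for a label/treatment-failure state
#'
#' @param object a \code{\link{cost_regression}}.
#' @param label logical, allergy label present at 12 months.
#' @param tf logical, treatment failure during year 1.
#' @param year model year (>= 2), used only by the drift term.
#' @param ... unused.
#' @return predicted annual cost (currency/year).
#' @export
predict.cost_regression <- function(object, label = TRUE, tf = FALSE,
                                    year = 2, ...) {
  object$baseline * ifelse(label, 1, object$delabel_mult) *
    ifelse(tf, object$tf_mult, 1) * object$drift^(year - 2)
}

#' Discount annuity factor over a run of model years
#'
#' \eqn{\sum_{t=first}^{last} (1+r)^{-(t-1)}}, under the convention that
#' year 1 is undiscounted.
#'
#' @param rate annual discount rate, >= 0.
#' @param first_year,last_year inclusive year range, with
#'   \code{last_year >= first_year >= 2}.
#' @return dimensionless factor.
#' @examples
#' annuity_factor(0.035, 2, 5) # 3.673080
#' @export
annuity_factor <- function(rate, first_year, last_year) {
  stopifnot(rate >= 0, first_year >= 2, last_year >= first_year)
  sum((1 + rate)^-(seq(first_year, last_year) - 1))
}

make_trajectory <- function(years, cost, qaly, rate) {
  disc <- c(1, (1 + rate)^-(years[-1] - 1))
  out <- data.frame(year = years, cost = cost, qaly = qaly,
                    discount = disc,
                    disc_cost = cost * disc, disc_qaly = qaly * disc)
  attr(out, "total_cost") <- sum(out$disc_cost)
  attr(out, "total_qaly") <- sum(out$disc_qaly)
  class(out) <- c("arm_trajectory", "data.frame")
  out
}

#' @export
print.arm_trajectory <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, ...)
  cat(sprintf("Discounted totals: cost %.3f, QALYs %.4f\n",
              attr(x, "total_cost"), attr(x, "total_qaly")))
  invisible(x)
}

#' Extrapolate one arm's costs and QALYs over the model horizon
#'
#' Year-1 values come from the decision tree; annual costs in years 2+
#' are predicted from the post-year-1 cost model applied to the end-of-
#' year-1 state distribution, and annual QALYs are held constant at their
#' year-1 value. Years 2+ are discounted at the configured rate.
#'
#' @param states a \code{\link{end_of_year1_states}} result.
#' @param year1 named vector \code{c(cost=, qaly=)} from
#'   \code{\link{expected_year1_payoffs}}.
#' @param reg a \code{\link{cost_regression}}.
#' @param config an \code{\link{econ_config}}.
#' @return an \code{"arm_trajectory"} data frame (year, undiscounted and
#'   discounted cost and QALY) with discounted totals as attributes.
#' @export
extrapolate <- function(states, year1, reg, config = econ_config()) {
  markov_relabel(states, year1, reg, annual_relabel_rate = 0, config = config)
}

#' Extrapolation with annual relabelling as a two-state Markov chain
#'
#' De-labelled participants are relabelled during years 2+ at a constant
#' annual rate (label state absorbing). On relabelling, annual cost
#' reverts to the labelled prediction of the cost model and annual utility
#' reverts to the arm's labelled-state mean utility matched on
#' treatment-failure status. Treatment-failure status is fixed at its
#' year-1 value throughout. A rate of zero reproduces
#' \code{\link{extrapolate}}.
#'
#' @inheritParams extrapolate
#' @param annual_relabel_rate annual probability of relabelling in \[0,1\].
#' @return an \code{"arm_trajectory"}; see \code{\link{extrapolate}}.
#' @export
markov_relabel <- function(states, year1, reg, annual_relabel_rate,
                           config = econ_config()) {
  stopifnot(inherits(states, "state_distribution"),
            inherits(reg, "cost_regression"),
            is.numeric(annual_relabel_rate), length(annual_relabel_rate) == 1)
  if (annual_relabel_rate < 0 || annual_relabel_rate > 1)
    stop("annual relabelling rate must lie in [0,1]")
  H <- config$horizon_years
  f <- config$year1_exposure_fraction
  p <- stats::setNames(states$probability, states$state)
  q <- stats::setNames(states$qaly, states$state)
  qr <- attr(states, "relabel_qaly")
  yrs <- seq_len(H)
  cost <- qaly <- numeric(H)
  cost[1] <- year1[["cost"]]; qaly[1] <- year1[["qaly"]]
  for (t in yrs[-1]) {
    kept <- (1 - annual_relabel_rate)^(t - 1) # still de-labelled at year t
    m_tf <- p[["nopal_tf"]] * (1 - kept)
    m_notf <- p[["nopal_notf"]] * (1 - kept)
    cost[t] <-
      (p[["pal_tf"]] + m_tf) * predict(reg, TRUE, TRUE, t) +
      (p[["pal_notf"]] + m_notf) * predict(reg, TRUE, FALSE, t) +
      (p[["nopal_tf"]] - m_tf) * predict(reg, FALSE, TRUE, t) +
      (p[["nopal_notf"]] - m_notf) * predict(reg, FALSE, FALSE, t)
    qaly[t] <- year1[["qaly"]] -
      f * (m_tf * (q[["nopal_tf"]] - qr[["tf"]]) +
           m_notf * (q[["nopal_notf"]] - qr[["notf"]]))
  }
  make_trajectory(yrs, cost, qaly, config$discount_rate)
}

#' Relabelling-rate thresholds for cost saving and positive net benefit
#'
#' Finds, by bisection on the annual relabelling rate in \[0,1\], the rate
#' at which the intervention's incremental cost crosses zero and the rate
#' at which its incremental net monetary benefit at the given threshold
#' crosses zero.
#'
#' @param model a \code{\link{paap_model}}.
#' @param wtp willingness to pay per QALY for the net-benefit threshold.
#' @param tol bisection tolerance on the rate.
#' @return list with elements \code{cost_saving} and \code{inmb_zero},
#'   each either the threshold rate or \code{NA} with
#'   \code{status = "no crossing in [0,1]"}.
#' @export
relabel_thresholds <- function(model, wtp = 20000, tol = 1e-6) {
  stopifnot(inherits(model, "paap_model"))
  eval_at <- function(rate) {
    cea <- deterministic_cea(model$params, model$reg, model$config,
                             relabel_rate = rate)
    c(dc = cea$delta_cost, inmb = inmb(cea$delta_cost, cea$delta_qaly, wtp))
  }
  root <- function(fun) {
    lo <- 0; hi <- 1
    flo <- fun(lo); fhi <- fun(hi)
    if (sign(flo) == sign(fhi))
      return(list(rate = NA_real_, status = "no crossing in [0,1]"))
    for (i in seq_len(100)) {
      mid <- (lo + hi) / 2
      fm <- fun(mid)
      if (fm == 0) { lo <- hi <- mid; break }
      if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
      if (hi - lo < tol) break
    }
    list(rate = (lo + hi) / 2, status = "ok")
  }
  list(cost_saving = root(function(r) eval_at(r)[["dc"]]),
       inmb_zero = root(function(r) eval_at(r)[["inmb"]]))
}
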