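nmb_increment <- function(psa, wtp) {
  stopifnot(inherits(psa, "psa_result"))
  d <- psa$draws
  ok <- is.finite(d$delta_cost) & is.finite(d$delta_qaly)
  inmb(d$delta_cost[ok], d$delta_qaly[ok], wtp)
}

#' Expected value of perfect information per patient
#'
#' The expected gain from resolving all parameter uncertainty before
#' choosing between the two strategies: the mean over PSA draws of the
#' best achievable net benefit minus the net benefit of the strategy that
#' is best on average. For a two-strategy comparison with incremental net
#' benefit \eqn{b}, this is \eqn{E[\max(0,b)] - \max(0, E[b])}.
#'
#' @param psa a \code{"psa_result"}.
#' @param wtp willingness to pay per QALY.
#' @return currency per patient (>= 0 up to Monte-Carlo error).
#' @export
evpi <- function(psa, wtp = 20000) {
  b <- nmb_increment(psa, wtp)
  if (length(b) == 0) stop("no usable PSA draws")
  mean(pmax(b, 0)) - max(0, mean(b))
}

# Positive-part regression estimator shared by EVPPI and EVSI: flexible
# regression of the per-draw incremental net benefit on conditioning
# statistics, then E[max(0, E[b | stats])] - max(0, E[b]).
evppi_on_stats <- function(b, stats_df, order = 3) {
  terms <- character()
  for (nm in names(stats_df)) {
    k <- min(order, length(unique(stats_df[[nm]])) - 1)
    if (k >= 1)
      terms <- c(terms, sprintf("poly(%s, %d)", nm, k))
  }
  if (length(terms) == 0) return(0)
  dat <- cbind(b = b, stats_df)
  fit <- stats::lm(stats::as.formula(paste("b ~", paste(terms, collapse = " + "))),
                   data = dat)
  max(0, mean(pmax(stats::fitted(fit), 0)) - max(0, mean(b)))
}

#' Expected value of perfect information on a single parameter
#'
#' Regression-based estimator: the per-draw incremental net benefit is
#' regressed on the parameter with a polynomial basis (default cubic) and
#' the positive-part identity is applied to the fitted conditional means.
#' Clipped to \[0, EVPI\].
#'
#' @param psa a \code{"psa_result"}.
#' @param parameter_id a column name of \code{psa$params}.
#' @param wtp willingness to pay per QALY.
#' @param order polynomial basis order.
#' @return list: \code{evppi} (currency per patient) and
#'   \code{degenerate} (\code{TRUE} when the parameter does not vary, in
#'   which case the value is 0).
#' @export
evppi_single <- function(psa, parameter_id, wtp = 20000, order = 3) {
  stopifnot(inherits(psa, "psa_result"),
            parameter_id %in% names(psa$params))
  x <- psa$params[[parameter_id]]
  b <- nmb_increment(psa, wtp)
  if (length(unique(x)) <= 1)
    return(list(evppi = 0, degenerate = TRUE))
  v <- evppi_on_stats(b, data.frame(x = x), order)
  list(evppi = min(v, evpi(psa, wtp)), degenerate = FALSE)
}

#' Rank all varying parameters by their partial EVPI
#'
#' @inheritParams evppi_single
#' @return data frame \code{parameter}, \code{evppi}, sorted decreasing;
#'   fixed parameters are omitted.
#' @export
evppi_rank <- function(psa, wtp = 20000, order = 3) {
  vary <- names(psa$params)[vapply(psa$params,
                                   function(x) length(unique(x)) > 1, TRUE)]
  vals <- vapply(vary, function(nm)
    evppi_single(psa, nm, wtp, order)$evppi, 0)
  out <- data.frame(parameter = vary, evppi = unname(vals),
                    stringsAsFactors = FALSE)
  out <- out[sort.list(out$evppi, decreasing = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Follow-on trial design
#'
#' Linear cost and duration models for a hypothetical two-arm follow-on
#' trial, with the per-participant sampling dispersions used when
#' simulating its summary statistics. The default cost and duration
#' coefficients are calibrated to pass through the published
#' (769 participants, 1.76M, 30 months) and (1267, 2.37M, 46 months)
#' points.
#'
#' @param n_participants planned total enrolment.
#' @param allocation two-element allocation ratio (default 1:1).
#' @param endpoints \code{"clinical"} (treatment-failure outcomes only) or
#'   \code{"full"} (clinical plus cost and HRQoL data).
#' @param fixed_cost,cost_per_participant trial cost model (currency).
#' @param fixed_months,months_per_participant trial duration model.
#' @param cost_sd,qaly_sd per-participant SDs of the (discounted total)
#'   cost and QALY endpoints used to simulate trial summary statistics.
#' @return object of class \code{"trial_design"}.
#' @export
trial_design <- function(n_participants = 1267, allocation = c(1, 1),
                         endpoints = c("clinical", "full"),
                         fixed_cost = 818052.21,
                         cost_per_participant = 1224.8996,
                         fixed_months = 5.293173,
                         months_per_participant = 0.03212851,
                         cost_sd = 3000, qaly_sd = 0.7) {
  endpoints <- match.arg(endpoints)
  stopifnot(n_participants >= 0, length(allocation) == 2, all(allocation > 0),
            fixed_cost >= 0, cost_per_participant >= 0,
            fixed_months >= 0, months_per_participant >= 0)
  structure(list(n_participants = n_participants, allocation = allocation,
                 endpoints = endpoints, fixed_cost = fixed_cost,
                 cost_per_participant = cost_per_participant,
                 fixed_months = fixed_months,
                 months_per_participant = months_per_participant,
                 cost_sd = cost_sd, qaly_sd = qaly_sd),
            class = "trial_design")
}

#' Cost of a follow-on trial of a given size
#'
#' @param design a \code{\link{trial_design}}.
#' @param n total enrolment (default the design's).
#' @return currency.
#' @export
trial_cost <- function(design, n = design$n_participants) {
  stopifnot(inherits(design, "trial_design"), all(n >= 0))
  design$fixed_cost + design$cost_per_participant * n
}

#' Duration of a follow-on trial of a given size
#'
#' @inheritParams trial_cost
#' @return months.
#' @export
trial_duration <- function(design, n = design$n_participants) {
  stopifnot(inherits(design, "trial_design"), all(n >= 0))
  design$fixed_months + design$months_per_participant * n
}

evsi_stats <- function(psa, design, n) {
  w <- design$allocation / sum(design$allocation)
  n1 <- max(1, round(n * w[1])) # intervention arm
  n2 <- max(1, n - round(n * w[1]))
  d <- psa$draws
  m <- nrow(d)
  s <- data.frame(tf_diff = stats::rbinom(m, n2, d$p_tf_usual_care) / n2 -
                    stats::rbinom(m, n1, d$p_tf_paap) / n1)
  if (design$endpoints == "full") {
    se_c <- design$cost_sd * sqrt(1 / n1 + 1 / n2)
    se_q <- design$qaly_sd * sqrt(1 / n1 + 1 / n2)
    s$cost_diff <- stats::rnorm(m, d$cost_usual_care - d$cost_paap, se_c)
    s$qaly_diff <- stats::rnorm(m, d$qaly_paap - d$qaly_usual_care, se_q)
  }
  s
}

#' Expected value of sample information for a follow-on trial
#'
#' Simulates, conditional on each PSA draw, the summary statistics the
#' follow-on trial would report (the difference in per-arm
#' treatment-failure proportions; with full endpoints also the mean cost
#' and mean QALY differences), regresses the per-draw incremental net
#' benefit on those statistics, and applies the positive-part identity.
#' Tends to the partial EVPI of the informed parameter set as the trial
#' size grows; zero by definition for an empty trial.
#'
#' @param psa a \code{"psa_result"}.
#' @param design a \code{\link{trial_design}}.
#' @param wtp willingness to pay per QALY.
#' @param seed RNG seed for the simulated trial statistics.
#' @param order polynomial basis order for the regression.
#' @return currency per patient, clipped to \[0, EVPI\].
#' @export
evsi <- function(psa, design, wtp = 20000, seed = 1L, order = 3) {
  stopifnot(inherits(psa, "psa_result"), inherits(design, "trial_design"))
  n <- design$n_participants
  if (n == 0) return(0)
  set.seed(seed)
  s <- evsi_stats(psa, design, n)
  b <- nmb_increment(psa, wtp)
  min(evppi_on_stats(b, s, order), evpi(psa, wtp))
}

#' Partial EVPI of the parameter set a follow-on trial would inform
#'
#' The large-sample limit of \code{\link{evsi}}: the positive-part
#' regression estimator applied to the exact per-draw values of the
#' quantities the trial estimates (treatment-failure probability
#' difference; with full endpoints also the true mean cost and QALY
#' differences).
#'
#' @inheritParams evsi
#' @param endpoints \code{"clinical"} or \code{"full"}.
#' @return currency per patient.
#' @export
evppi_informed <- function(psa, endpoints = c("clinical", "full"),
                           wtp = 20000, order = 3) {
  endpoints <- match.arg(endpoints)
  d <- psa$draws
  s <- data.frame(tf_diff = d$p_tf_usual_care - d$p_tf_paap)
  if (endpoints == "full") {
    s$cost_diff <- d$cost_usual_care - d$cost_paap
    s$qaly_diff <- d$qaly_paap - d$qaly_usual_care
  }
  b <- nmb_increment(psa, wtp)
  min(evppi_on_stats(b, s, order), evpi(psa, wtp))
}

#' Eligible population model for scaling per-patient value
#'
#' @param total eligible prevalent and incident population over the
#'   horizon.
#' @param horizon_years scaling horizon.
#' @param discount_rate annual discount rate.
#' @param accrual \code{"uniform"} (equal annual cohorts, discounted with
#'   year 1 undiscounted) or \code{"immediate"} (whole population at
#'   decision time, no discounting).
#' @return object of class \code{"population_model"}.
#' @export
population_model <- function(total = 79877, horizon_years = 10,
                             discount_rate = 0.035,
                             accrual = c("uniform", "immediate")) {
  accrual <- match.arg(accrual)
  stopifnot(total >= 0, horizon_years >= 1, discount_rate >= 0)
  structure(list(total = total, horizon_years = as.integer(horizon_years),
                 discount_rate = discount_rate, accrual = accrual),
            class = "population_model")
}

#' Scale a per-patient value to the eligible population
#'
#' Linear in the per-patient value: uniform annual cohorts of
#' \code{total/horizon} patients, each year's cohort discounted by
#' \eqn{(1+d)^{-(t-1)}}.
#'
#' @param per_patient currency per patient.
#' @param pop a \code{\link{population_model}}.
#' @return currency.
#' @export
population_value <- function(per_patient, pop = population_model()) {
  stopifnot(inherits(pop, "population_model"))
  if (pop$accrual == "immediate") return(per_patient * pop$total)
  cohort <- pop$total / pop$horizon_years
  per_patient * cohort *
    sum((1 + pop$discount_rate)^-(seq_len(pop$horizon_years) - 1))
}

#' Optimise the expected net benefit of sampling over trial size
#'
#' ENBS(n) = population-scaled EVSI(n) minus the trial cost at n,
#' evaluated over a grid of enrolments (concavity is not assumed).
#'
#' @param psa a \code{"psa_result"}.
#' @param design a \code{\link{trial_design}} template (its cost/duration
#'   models and endpoints are reused at each grid size).
#' @param pop a \code{\link{population_model}}.
#' @param wtp willingness to pay per QALY.
#' @param n_grid enrolments to evaluate.
#' @param seed RNG seed for the EVSI simulations.
#' @param evsi_fn optional replacement for the EVSI computation, a
#'   function of the enrolment \code{n} returning currency per patient
#'   (used to optimise a known sampling-value curve).
#' @return list: \code{optimal_n} (0 with \code{all_negative = TRUE} when
#'   no size has positive ENBS), \code{curve} (data frame n, evsi,
#'   population_value, trial_cost, enbs).
#' @export
enbs_optimize <- function(psa, design = trial_design(),
                          pop = population_model(), wtp = 20000,
                          n_grid = seq(50, 2000, by = 50), seed = 1L,
                          evsi_fn = NULL) {
  rows <- lapply(seq_along(n_grid), function(i) {
    n <- n_grid[i]
    des <- design; des$n_participants <- n
    ev <- if (is.null(evsi_fn)) evsi(psa, des, wtp, seed = seed + i)
          else evsi_fn(n)
    pv <- population_value(ev, pop)
    data.frame(n = n, evsi = ev, population_value = pv,
               trial_cost = trial_cost(design, n),
               enbs = pv - trial_cost(design, n))
  })
  curve <- do.call(rbind, rows)
  all_neg <- all(curve$enbs <= 0)
  list(optimal_n = if (all_neg) 0 else curve$n[which.max(curve$enbs)],
       all_negative = all_neg, curve = curve)
}

#' Sample size for comparing two proportions
#'
#' Standard normal-approximation formula for a two-sided two-sample test
#' of proportions, rounded up.
#'
#' @param p1,p2 the two proportions (must differ).
#' @param power target power in (0,1).
#' @param alpha two-sided significance level in (0,1).
#' @return required n per arm.
#' @export
sample_size_two_proportions <- function(p1, p2, power = 0.9, alpha = 0.05) {
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1,
            power > 0, power < 1, alpha > 0, alpha < 1)
  if (p1 == p2) stop("proportions are equal; sample size is infeasible")
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  ceiling(z^2 * (p1 * (1 - p1) + p2 * (1 - p2)) / (p1 - p2)^2)
}
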