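#' Annualise a cost observed over a partial exposure window
#'
#' Observed values are multiplied by 365 and divided by the exposure time
#' in days during the annual observation period, adjusting for
#' administrative censoring. Linear in the value and inverse-linear in the
#' exposure.
#'
#' @param value cost observed over the window (vectorised).
#' @param exposure_days exposure time in days, in (0, 366].
#' @return annualised value (currency per year).
#' @examples
#' annualize(100, 365)   # 100
#' annualize(50, 182.5)  # 100
#' @export
annualize <- function(value, exposure_days) {
  stopifnot(is.numeric(value), is.numeric(exposure_days))
  if (any(exposure_days <= 0)) stop("exposure_days must be > 0")
  if (any(exposure_days > 366)) stop("exposure_days must be <= 366")
  value * 365 / exposure_days
}

prop_spec <- function(x, sd_mode) {
  # x: logical membership vector over the parent set. Returns a list with
  # the dist_spec, a boundary flag and an empty flag.
  n <- length(x)
  if (n == 0)
    return(list(spec = dist_spec("fixed", 0, 0), boundary = FALSE,
                empty = TRUE))
  p <- mean(x)
  if (p == 0 || p == 1)
    return(list(spec = dist_spec("fixed", p, 0), boundary = TRUE,
                empty = FALSE))
  s <- sqrt(p * (1 - p))
  if (sd_mode == "se") s <- s / sqrt(n)
  list(spec = dist_spec("beta", p, min(s, 0.999 * sqrt(p * (1 - p)))),
       boundary = FALSE, empty = FALSE)
}

#' Estimate the decision-tree event probabilities from trial data
#'
#' Each probability is the conditional sample proportion on its parent set
#' (test uptake among all; positivity among tested; label removal among
#' each test result; treatment failure within each result-by-label
#' context). The uncertainty SD recorded with each estimate is, by
#' default, the Bernoulli sample SD \eqn{\sqrt{p(1-p)}} (\code{sd_mode =
#' "sample"}), shrunk by 0.1 percent because the raw value sits exactly
#' on the Beta feasibility boundary \eqn{sd^2 < p(1-p)}; \code{sd_mode =
#' "se"} records the standard error instead. Boundary proportions (0 or
#' 1) are stored as fixed values and excluded from probabilistic
#' analysis; empty parent sets are flagged.
#'
#' @param table a \code{"participant_table"}.
#' @param sd_mode \code{"sample"} or \code{"se"}.
#' @return list per arm: \code{probs} (named \code{dist_spec} list),
#'   \code{boundary} and \code{empty} (character vectors), \code{n}.
#' @export
estimate_branch_probabilities <- function(table, sd_mode = c("sample", "se")) {
  sd_mode <- match.arg(sd_mode)
  stopifnot(inherits(table, "participant_table"))
  out <- list()
  for (arm in ARMS) {
    d <- table$participants[table$participants$arm == arm, ]
    if (nrow(d) == 0) stop(sprintf("no participants in arm '%s'", arm))
    pos <- d$tested & d$test_result == "positive"
    neg <- d$tested & d$test_result == "negative"
    sets <- list(
      p_test = d$tested,
      p_positive = pos[d$tested],
      p_delabel_pos = d$delabelled[pos],
      p_delabel_neg = d$delabelled[neg],
      tf_pos_pal = d$treatment_failure[pos & !d$delabelled],
      tf_neg_pal = d$treatment_failure[neg & !d$delabelled],
      tf_neg_nopal = d$treatment_failure[neg & d$delabelled],
      tf_notest = d$treatment_failure[!d$tested])
    est <- lapply(sets, prop_spec, sd_mode = sd_mode)
    out[[arm]] <- list(
      probs = lapply(est, `[[`, "spec"),
      boundary = names(est)[vapply(est, `[[`, TRUE, "boundary")],
      empty = names(est)[vapply(est, `[[`, TRUE, "empty")],
      n = nrow(d))
  }
  out
}

payoff_spec <- function(v, family, sd_mode) {
  n <- length(v)
  if (n == 0)
    return(list(spec = dist_spec("fixed", 0, 0), empty = TRUE,
                degenerate = FALSE))
  m <- mean(v)
  s <- if (n > 1) stats::sd(v) else 0
  if (sd_mode == "se" && n > 1) s <- s / sqrt(n)
  if (m <= 0) return(list(spec = dist_spec("fixed", max(m, 0), 0),
                          empty = FALSE, degenerate = n == 1))
  if (family == "beta") {
    m <- min(m, 1)
    s <- min(s, 0.999 * sqrt(m * (1 - m))) # cap at feasible Beta moments
    if (m >= 1) s <- 0
  }
  list(spec = dist_spec(if (s > 0) family else "fixed", m, s),
       empty = FALSE, degenerate = n == 1)
}

#' Estimate per-branch first-year cost and QALY payoffs
#'
#' For each terminal branch of the tree, the mean and SD of the members'
#' censoring-annualised first-year total cost (lognormal family) and of
#' their first-year utility (beta family, capped at feasible moments).
#' Branches without members receive a fixed-0 placeholder and are flagged
#' empty for \code{\link{resolve_missing_branches}}; single-member
#' branches are flagged degenerate and carry SD 0.
#'
#' @inheritParams estimate_branch_probabilities
#' @return list per arm: \code{costs}, \code{qalys} (named
#'   \code{dist_spec} lists), \code{empty} and \code{degenerate} flags.
#' @export
estimate_branch_payoffs <- function(table, sd_mode = c("sample", "se")) {
  sd_mode <- match.arg(sd_mode)
  stopifnot(inherits(table, "participant_table"))
  y1 <- table$years[table$years$year == 1, ]
  acost <- annualize(y1$cost_total, y1$exposure_days)
  names(acost) <- as.character(y1$id)
  util <- stats::setNames(y1$utility, as.character(y1$id))
  out <- list()
  for (arm in ARMS) {
    d <- table$participants[table$participants$arm == arm, ]
    if (nrow(d) == 0) stop(sprintf("no participants in arm '%s'", arm))
    br <- branch_of(d$tested, d$test_result, d$delabelled,
                    d$treatment_failure)
    costs <- qalys <- stats::setNames(vector("list", length(PAYOFF_BRANCHES)),
                                      PAYOFF_BRANCHES)
    empty <- list(costs = character(), qalys = character())
    degen <- character()
    for (b in PAYOFF_BRANCHES) {
      ids <- as.character(d$id[br == b])
      ce <- payoff_spec(unname(acost[ids]), "lognormal", sd_mode)
      qe <- payoff_spec(unname(util[ids]), "beta", sd_mode)
      costs[[b]] <- ce$spec; qalys[[b]] <- qe$spec
      if (ce$empty) empty$costs <- c(empty$costs, b)
      if (qe$empty) empty$qalys <- c(empty$qalys, b)
      if (ce$degenerate) degen <- c(degen, b)
    }
    out[[arm]] <- list(costs = costs, qalys = qalys, empty = empty,
                       degenerate = degen, n = nrow(d))
  }
  out
}

#' Estimate the full two-arm parameter set from trial data
#'
#' Combines \code{\link{estimate_branch_probabilities}} and
#' \code{\link{estimate_branch_payoffs}} into a \code{\link{branch_params}}
#' object (with empty branches flagged, not yet substituted).
#'
#' @inheritParams estimate_branch_probabilities
#' @param substitution substitution rule passed to
#'   \code{\link{branch_params}}.
#' @return a \code{\link{branch_params}}.
#' @export
estimate_params <- function(table, sd_mode = c("sample", "se"),
                            substitution = list(qaly_source = "other_arm",
                                                cost_source = "same_arm_no_test")) {
  sd_mode <- match.arg(sd_mode)
  pr <- estimate_branch_probabilities(table, sd_mode)
  po <- estimate_branch_payoffs(table, sd_mode)
  mk <- function(arm) {
    a <- arm_params(probs = pr[[arm]]$probs, costs = po[[arm]]$costs,
                    qalys = po[[arm]]$qalys, n = pr[[arm]]$n,
                    empty = list(probs = pr[[arm]]$empty,
                                 costs = po[[arm]]$empty$costs,
                                 qalys = po[[arm]]$empty$qalys))
    attr(a, "boundary") <- pr[[arm]]$boundary
    attr(a, "degenerate") <- po[[arm]]$degenerate
    a
  }
  branch_params(paap = mk("paap"), usual_care = mk("usual_care"),
                substitution = substitution)
}

#' Fit the post-year-1 annual cost model to trial data
#'
#' Gamma generalised linear model with log link of censoring-annualised
#' annual costs in years 2 and beyond on 12-month allergy-label status and
#' year-1 treatment failure. Zero-cost records are offset by half the
#' smallest positive observed cost (standard handling for skewed cost data
#' with zeros). The reference category is a labelled participant without
#' treatment failure.
#'
#' @param table a \code{"participant_table"} with year >= 2 records.
#' @return a \code{\link{cost_regression}} with fitted multipliers and
#'   delta-method SDs; the underlying \code{glm} fit is attached as
#'   attribute \code{"fit"}.
#' @export
fit_post_year1_cost_model <- function(table) {
  stopifnot(inherits(table, "participant_table"))
  y <- table$years[table$years$year >= 2, ]
  if (nrow(y) == 0) stop("no post-year-1 cost records to fit")
  p <- table$participants
  idx <- match(y$id, p$id)
  dat <- data.frame(
    cost = annualize(y$cost_total, y$exposure_days),
    nolabel = as.numeric(p$delabelled[idx]),
    tf = as.numeric(p$treatment_failure[idx]))
  pos <- dat$cost[dat$cost > 0]
  if (length(pos) == 0) stop("all post-year-1 costs are zero; cannot fit")
  dat$cost[dat$cost == 0] <- min(pos) * 0.5
  if (stats::var(dat$cost) == 0) {
    # Degenerate data: constant costs imply unit multipliers.
    return(cost_regression(baseline = dat$cost[1], delabel_mult = 1,
                           tf_mult = 1, baseline_sd = 0, delabel_sd = 0,
                           tf_sd = 0))
  }
  fit <- stats::glm(cost ~ nolabel + tf, data = dat,
                    family = stats::Gamma(link = "log"))
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  val <- function(nm) if (nm %in% names(cf) && !is.na(cf[nm])) cf[[nm]] else 0
  sev <- function(nm) if (nm %in% names(se) && !is.na(cf[nm])) se[[nm]] else 0
  out <- cost_regression(
    baseline = exp(val("(Intercept)")),
    delabel_mult = exp(val("nolabel")),
    tf_mult = exp(val("tf")),
    baseline_sd = exp(val("(Intercept)")) * sev("(Intercept)"),
    delabel_sd = exp(val("nolabel")) * sev("nolabel"),
    tf_sd = exp(val("tf")) * sev("tf"))
  attr(out, "fit") <- fit
  out
}
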