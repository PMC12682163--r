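#' First-year decision tree structure
#'
#' The chance-node sequence of the first-year pathway: receive allergy test
#' -> test result -> allergy-label removal (conditional on the result) ->
#' treatment failure (conditional on result and label context). A
#' "positive" result indicates the patient is penicillin allergic; a
#' positive test never removes the label, so the positive-and-delabelled
#' pair of terminals is structurally zero probability and carries no
#' payoff.
#'
#' @return object of class \code{"tree_spec"}: one row per terminal branch
#'   with its node path, 12-month label status, treatment-failure status
#'   and the treatment-failure probability context.
#' @export
tree_spec <- function() {
  tb <- data.frame(
    branch = ALL_BRANCHES,
    tested = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE),
    result = c("positive", "positive", "negative", "negative", "negative",
               "negative", NA, NA, "positive", "positive"),
    delabelled = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE,
                   TRUE, TRUE),
    tf = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
    tf_context = c("tf_pos_pal", "tf_pos_pal", "tf_neg_pal", "tf_neg_pal",
                   "tf_neg_nopal", "tf_neg_nopal", "tf_notest", "tf_notest",
                   "tf_neg_nopal", "tf_neg_nopal"),
    stringsAsFactors = FALSE)
  tb$label_12m <- !tb$delabelled
  structure(tb, class = c("tree_spec", "data.frame"))
}

#' @export
print.tree_spec <- function(x, ...) {
  cat("Decision tree (per arm):\n")
  cat("  receive test?\n")
  fmt <- function(rows, indent) {
    for (i in rows) cat(strrep(" ", indent),
                        sprintf("%s: label=%s TF=%s [%s]\n",
                                x$branch[i], x$label_12m[i], x$tf[i],
                                x$tf_context[i]))
  }
  cat("    yes -> result positive -> label kept/removed -> TF?\n")
  fmt(which(x$tested & x$result == "positive"), 6)
  cat("    yes -> result negative -> label kept/removed -> TF?\n")
  fmt(which(x$tested & x$result == "negative"), 6)
  cat("    no  -> label kept -> TF?\n")
  fmt(which(!x$tested), 6)
  invisible(x)
}

# Vectorised path probabilities. `pr` is a named list of equal-length
# numeric vectors (one element per draw) for the eight event probabilities.
# Returns a draws x 10 matrix with branch names as columns; rows sum to 1.
path_prob_matrix <- function(pr) {
  pt <- pr$p_test; pp <- pr$p_positive
  dp <- pr$p_delabel_pos; dn <- pr$p_delabel_neg
  cbind(
    pos_pal_tf     = pt * pp * (1 - dp) * pr$tf_pos_pal,
    pos_pal_notf   = pt * pp * (1 - dp) * (1 - pr$tf_pos_pal),
    neg_pal_tf     = pt * (1 - pp) * (1 - dn) * pr$tf_neg_pal,
    neg_pal_notf   = pt * (1 - pp) * (1 - dn) * (1 - pr$tf_neg_pal),
    neg_nopal_tf   = pt * (1 - pp) * dn * pr$tf_neg_nopal,
    neg_nopal_notf = pt * (1 - pp) * dn * (1 - pr$tf_neg_nopal),
    notest_tf      = (1 - pt) * pr$tf_notest,
    notest_notf    = (1 - pt) * (1 - pr$tf_notest),
    pos_nopal_tf   = pt * pp * dp * pr$tf_neg_nopal,
    pos_nopal_notf = pt * pp * dp * (1 - pr$tf_neg_nopal))
}

prob_means <- function(params, arm)
  lapply(params[[arm]]$probs, function(d) d$mean)

#' Enumerate terminal branches and their path probabilities
#'
#' Multiplies conditional probabilities along each root-to-leaf path of the
#' first-year tree at the parameter means.
#'
#' @param tree a \code{\link{tree_spec}}.
#' @param params a resolved \code{\link{branch_params}}.
#' @param arm \code{"paap"} or \code{"usual_care"}.
#' @return data frame with one row per terminal branch: \code{branch},
#'   \code{probability}, \code{label_12m}, \code{tf}. Probabilities sum to
#'   one to within 1e-12.
#' @export
enumerate_paths <- function(tree, params, arm = c("paap", "usual_care")) {
  arm <- match.arg(arm)
  stopifnot(inherits(tree, "tree_spec"), inherits(params, "branch_params"))
  if (!params_resolved(params))
    stop("parameter set has unresolved empty branches; run resolve_missing_branches()")
  p <- drop(path_prob_matrix(prob_means(params, arm)))
  out <- data.frame(branch = tree$branch, probability = p[tree$branch],
                    label_12m = tree$label_12m, tf = tree$tf,
                    stringsAsFactors = FALSE)
  stopifnot(abs(sum(out$probability) - 1) < 1e-12)
  out
}

#' Expected first-year cost and QALY of one arm
#'
#' Probability-weighted sum of the terminal-branch payoffs, multiplied by
#' the configured year-1 exposure fraction.
#'
#' @inheritParams enumerate_paths
#' @param config an \code{\link{econ_config}}.
#' @return named numeric vector \code{c(cost=, qaly=)}.
#' @export
expected_year1_payoffs <- function(tree, params, arm = c("paap", "usual_care"),
                                   config = econ_config()) {
  arm <- match.arg(arm)
  paths <- enumerate_paths(tree, params, arm)
  if (any(paths$probability[paths$branch %in% STRUCTURAL_BRANCHES] > 0))
    stop("positive-and-delabelled branches have positive probability but no payoff")
  keep <- match(PAYOFF_BRANCHES, paths$branch)
  pb <- paths$probability[keep]
  cost <- vapply(params[[arm]]$costs, function(d) d$mean, 0)[PAYOFF_BRANCHES]
  qaly <- vapply(params[[arm]]$qalys, function(d) d$mean, 0)[PAYOFF_BRANCHES]
  f <- config$year1_exposure_fraction
  c(cost = f * sum(pb * cost), qaly = f * sum(pb * qaly))
}

#' End-of-year-1 state distribution
#'
#' Aggregates the terminal-branch probabilities into the four 12-month
#' states used for extrapolation: allergy label kept or removed, crossed
#' with treatment failure during year 1. Untested participants keep their
#' label. Each state also carries its probability-weighted mean annual
#' utility; the labelled states' mean utilities (falling back to the
#' no-test branch when a labelled state is empty) are attached as the
#' reversion targets used by the relabelling scenario.
#'
#' @inheritParams enumerate_paths
#' @return object of class \code{"state_distribution"}: data frame with
#'   columns \code{state}, \code{probability}, \code{qaly}; attribute
#'   \code{relabel_qaly} (named vector \code{tf}/\code{notf}).
#' @export
end_of_year1_states <- function(tree, params, arm = c("paap", "usual_care")) {
  arm <- match.arg(arm)
  paths <- enumerate_paths(tree, params, arm)
  qaly <- vapply(params[[arm]]$qalys, function(d) d$mean, 0)
  qaly <- c(qaly, pos_nopal_tf = 0, pos_nopal_notf = 0) # structural, prob 0
  key <- paste0(ifelse(paths$label_12m, "pal", "nopal"),
                ifelse(paths$tf, "_tf", "_notf"))
  states <- c("pal_tf", "pal_notf", "nopal_tf", "nopal_notf")
  pr <- vapply(states, function(s) sum(paths$probability[key == s]), 0)
  qw <- vapply(states, function(s) {
    i <- key == s
    if (pr[s] > 0) sum(paths$probability[i] * qaly[paths$branch[i]]) / pr[s] else 0
  }, 0)
  stopifnot(abs(sum(pr) - 1) < 1e-12, all(pr >= -1e-15))
  out <- data.frame(state = states, probability = unname(pr),
                    qaly = unname(qw), stringsAsFactors = FALSE)
  attr(out, "relabel_qaly") <- c(
    tf = if (pr[["pal_tf"]] > 0) qw[["pal_tf"]] else
      params[[arm]]$qalys$notest_tf$mean,
    notf = if (pr[["pal_notf"]] > 0) qw[["pal_notf"]] else
      params[[arm]]$qalys$notest_notf$mean)
  class(out) <- c("state_distribution", "data.frame")
  out
}
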