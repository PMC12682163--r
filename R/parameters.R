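# Terminal branches of the first-year decision tree. The first eight carry
# cost and QALY payoffs; the positive-and-delabelled pair is structurally
# zero probability (a positive test never removes the allergy label) and
# carries no payoff.
PAYOFF_BRANCHES <- c("pos_pal_tf", "pos_pal_notf",
                     "neg_pal_tf", "neg_pal_notf",
                     "neg_nopal_tf", "neg_nopal_notf",
                     "notest_tf", "notest_notf")
STRUCTURAL_BRANCHES <- c("pos_nopal_tf", "pos_nopal_notf")
ALL_BRANCHES <- c(PAYOFF_BRANCHES, STRUCTURAL_BRANCHES)

PROB_NAMES <- c("p_test", "p_positive", "p_delabel_pos", "p_delabel_neg",
                "tf_pos_pal", "tf_neg_pal", "tf_neg_nopal", "tf_notest")

ARMS <- c("paap", "usual_care")

#' Parameter set for one trial arm
#'
#' Bundles the event probabilities of the first-year decision tree with the
#' per-branch first-year cost payoffs and annual QALY payoffs, each as a
#' \code{\link{dist_spec}}.
#'
#' @param probs named list of \code{dist_spec}s for \code{p_test},
#'   \code{p_positive}, \code{p_delabel_pos}, \code{p_delabel_neg} and the
#'   four treatment-failure probabilities \code{tf_pos_pal},
#'   \code{tf_neg_pal}, \code{tf_neg_nopal}, \code{tf_notest}.
#' @param costs,qalys named lists of \code{dist_spec}s keyed by the eight
#'   payoff branches.
#' @param n number of participants behind the estimates (informational).
#' @param empty character vectors naming branches with no observed members,
#'   as \code{list(costs =, qalys =)}; such payoffs await substitution via
#'   \code{\link{resolve_missing_branches}}.
#' @param substituted bookkeeping of branches whose payoff was filled from a
#'   donor, same shape as \code{empty}.
#' @return object of class \code{"arm_params"}.
#' @export
arm_params <- function(probs, costs, qalys, n = NA_integer_,
                       empty = list(probs = character(), costs = character(),
                                    qalys = character()),
                       substituted = list(costs = character(), qalys = character())) {
  if (is.null(empty$probs)) empty$probs <- character()
  if (is.null(empty$costs)) empty$costs <- character()
  if (is.null(empty$qalys)) empty$qalys <- character()
  stopifnot(setequal(names(probs), PROB_NAMES),
            setequal(names(costs), PAYOFF_BRANCHES),
            setequal(names(qalys), PAYOFF_BRANCHES))
  for (p in probs) {
    stopifnot(inherits(p, "dist_spec"))
    if (p$mean < 0 || p$mean > 1) stop("probability mean outside [0,1]")
  }
  for (q in qalys) {
    stopifnot(inherits(q, "dist_spec"))
    if (!is.na(q$mean) && (q$mean < 0 || q$mean > 1))
      stop("QALY payoff mean outside [0,1]")
  }
  for (cc in costs) {
    stopifnot(inherits(cc, "dist_spec"))
    if (!is.na(cc$mean) && cc$mean < 0) stop("negative cost payoff mean")
  }
  structure(list(probs = probs[PROB_NAMES], costs = costs[PAYOFF_BRANCHES],
                 qalys = qalys[PAYOFF_BRANCHES], n = n,
                 empty = empty, substituted = substituted),
            class = "arm_params")
}

#' Two-arm model parameter set
#'
#' @param paap,usual_care \code{\link{arm_params}} for the intervention
#'   (allergy assessment pathway) and usual-care arms.
#' @param substitution rule used by \code{\link{resolve_missing_branches}}:
#'   \code{qaly_source} is \code{"other_arm"} or \code{"pooled"};
#'   \code{cost_source} is \code{"same_arm_no_test"}, \code{"other_arm"} or
#'   \code{"pooled"}.
#' @return object of class \code{"branch_params"}.
#' @export
branch_params <- function(paap, usual_care,
                          substitution = list(qaly_source = "other_arm",
                                              cost_source = "same_arm_no_test")) {
  stopifnot(inherits(paap, "arm_params"), inherits(usual_care, "arm_params"))
  structure(list(paap = paap, usual_care = usual_care,
                 substitution = substitution),
            class = "branch_params")
}

#' @export
print.branch_params <- function(x, ...) {
  cat("Two-arm decision-tree parameter set\n")
  for (a in ARMS) {
    arm <- x[[a]]
    cat(sprintf("  %s (n=%s): p_test=%.3f, p_positive=%.3f, p_delabel_neg=%.3f\n",
                a, format(arm$n), arm$probs$p_test$mean,
                arm$probs$p_positive$mean, arm$probs$p_delabel_neg$mean))
    ne <- length(arm$empty$costs) + length(arm$empty$qalys)
    if (ne > 0) cat(sprintf("    %d unresolved empty branch payoff(s)\n", ne))
  }
  invisible(x)
}

#' Base-case model parameters
#'
#' The published base-case parameter set of the ALABAMA cost-effectiveness
#' model (event probabilities, first-year branch cost payoffs in GBP at
#' 2022-23 prices, annual QALY payoffs, each with its sampling family),
#' read from the structured text file bundled with the package.
#'
#' @return a \code{\link{branch_params}} object.
#' @export
table2_params <- function() {
  path <- system.file("extdata", "alabama_base_case_parameters.json",
                      package = "paapcea", mustWork = TRUE)
  read_branch_params(path)
}

#' Published summary results bundled for validation
#'
#' Printed summary tables of the published ALABAMA cost-effectiveness
#' analysis (observed first-year cost composition, per-period totals,
#' deterministic and probabilistic headline results, subgroup rows, and the
#' value-of-information anchors), used by the validation checks.
#'
#' @return nested list mirroring the published tables.
#' @export
published_tables <- function() {
  path <- system.file("extdata", "alabama_published_results.json",
                      package = "paapcea", mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

dist_to_list <- function(d) list(family = d$family, mean = d$mean, sd = d$sd)
dist_from_list <- function(l) dist_spec(l$family, l$mean, l$sd)

#' Write a parameter set to a structured text file
#'
#' JSON serialization whose field names mirror the rows of the model's
#' parameter table; \code{\link{read_branch_params}} round-trips exactly.
#'
#' @param params a \code{\link{branch_params}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_branch_params <- function(params, path) {
  stopifnot(inherits(params, "branch_params"))
  ser_arm <- function(a) list(
    n = a$n,
    event_probabilities = lapply(a$probs, dist_to_list),
    first_year_costs = lapply(a$costs, dist_to_list),
    annual_qalys = lapply(a$qalys, dist_to_list),
    empty = a$empty, substituted = a$substituted)
  obj <- list(currency = "GBP 2022-23",
              arms = list(paap = ser_arm(params$paap),
                          usual_care = ser_arm(params$usual_care)),
              substitution = params$substitution)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a parameter set written by \code{write_branch_params}
#'
#' @param path file path.
#' @return a \code{\link{branch_params}}.
#' @export
read_branch_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  de_arm <- function(a) {
    emp <- lapply(a$empty, function(e) as.character(unlist(e)))
    sub <- lapply(a$substituted, function(e) as.character(unlist(e)))
    if (length(emp) == 0) emp <- list(costs = character(), qalys = character())
    if (length(sub) == 0) sub <- list(costs = character(), qalys = character())
    arm_params(probs = lapply(a$event_probabilities, dist_from_list),
               costs = lapply(a$first_year_costs, dist_from_list),
               qalys = lapply(a$annual_qalys, dist_from_list),
               n = if (is.null(a$n)) NA_integer_ else a$n,
               empty = emp, substituted = sub)
  }
  branch_params(paap = de_arm(obj$arms$paap),
                usual_care = de_arm(obj$arms$usual_care),
                substitution = lapply(obj$substitution, as.character))
}

other_arm <- function(arm) if (arm == "paap") "usual_care" else "paap"

#' Fill empty branch payoffs from their substitution source
#'
#' Decision-tree branches with no observed trial members still need a payoff
#' for the tree to evaluate. QALY payoffs default to the corresponding
#' branch of the other arm (the published table's convention); cost payoffs
#' default to the same arm's no-test branch with matching treatment-failure
#' status. Substituted payoffs are recorded with provenance and enter the
#' probabilistic analysis as fixed values (SD 0).
#'
#' @param params a \code{\link{branch_params}} with \code{empty} flags set.
#' @return a \code{\link{branch_params}} with every payoff populated.
#' @export
resolve_missing_branches <- function(params) {
  stopifnot(inherits(params, "branch_params"))
  qsrc <- params$substitution$qaly_source
  csrc <- params$substitution$cost_source
  donor <- function(kind, arm, branch, source) {
    get_spec <- function(a, b) params[[a]][[kind]][[b]]
    is_empty <- function(a, b) b %in% params[[a]]$empty[[kind]]
    oa <- other_arm(arm)
    nb <- if (grepl("_notf$", branch)) "notest_notf" else "notest_tf"
    primary <- if (source == "same_arm_no_test") list(c(arm, nb))
               else list(c(oa, branch))
    # fallback chain: other arm's branch, same-arm no-test, other-arm
    # no-test, then the pooled mean over every populated branch
    candidates <- c(primary, list(c(oa, branch), c(arm, nb), c(oa, nb)))
    pick <- NULL
    for (cand in candidates) {
      if (!is_empty(cand[1], cand[2])) { pick <- get_spec(cand[1], cand[2]); break }
    }
    if (is.null(pick)) {
      vals <- unlist(lapply(ARMS, function(a)
        vapply(setdiff(PAYOFF_BRANCHES, params[[a]]$empty[[kind]]),
               function(b) get_spec(a, b)$mean, 0)))
      if (length(vals) == 0)
        stop(sprintf("branch '%s' (%s, %s) empty with no usable donor: unresolvable",
                     branch, arm, kind))
      return(dist_spec("fixed", mean(vals), 0))
    }
    dist_spec(pick$family, pick$mean, 0) # substituted payoffs are fixed
  }
  out <- params
  for (arm in ARMS) {
    for (kind in c("costs", "qalys")) {
      src <- if (kind == "qalys") qsrc else csrc
      for (b in params[[arm]]$empty[[kind]]) {
        out[[arm]][[kind]][[b]] <- donor(kind, arm, b, src)
        out[[arm]]$substituted[[kind]] <-
          union(out[[arm]]$substituted[[kind]], b)
      }
      out[[arm]]$empty[[kind]] <- character()
    }
  }
  out
}

# TRUE when every payoff of both arms is populated (no pending substitution).
params_resolved <- function(params) {
  all(vapply(ARMS, function(a) {
    length(params[[a]]$empty$costs) + length(params[[a]]$empty$qalys) == 0 &&
      !anyNA(vapply(params[[a]]$costs, function(d) d$mean, 0)) &&
      !anyNA(vapply(params[[a]]$qalys, function(d) d$mean, 0))
  }, TRUE))
}
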