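# Observed composition of annual costs used to split simulated totals into
# components (shares of the non-test total, from the trial's printed
# resource-use summary).
.component_names <- c("primary_care", "medications", "admissions",
                      "outpatient", "emergency")
.default_shares <- list(
  paap = list(year1 = c(38.74, 6.07, 643.54, 462.59, 74.25),
              later = c(39.59, 8.30, 848.79, 581.54, 59.11)),
  usual_care = list(year1 = c(47.25, 8.87, 748.12, 475.51, 89.72),
                    later = c(42.02, 7.29, 888.58, 507.67, 73.18)))

#' Synthetic-trial generator configuration
#'
#' Defines the data-generating truth for a two-arm allergy-testing trial
#' with the structure the decision model assumes. Defaults reproduce the
#' ALABAMA base-case parameter table: arm sizes 401/410, test uptake
#' 0.910 vs 0.012, and the published branch probabilities, first-year cost
#' payoffs and annual utilities as truths. Component costs are drawn as a
#' right-skewed (Gamma) total split by the observed cost composition;
#' utilities are Beta draws in \[0,1\].
#'
#' @param params a \code{\link{branch_params}} giving the branch
#'   probability / cost / QALY truths.
#' @param post_year1 a \code{\link{cost_regression}}: the truth for annual
#'   costs in years 2+.
#' @param n_per_arm named integer vector \code{c(paap=, usual_care=)}.
#' @param post_year1_cv coefficient of variation of annual cost draws in
#'   years 2+ (observed later-year cost data are strongly right-skewed,
#'   SD roughly twice the mean).
#' @param test_unit_cost named vector: cost of the testing episode per
#'   tested participant, per arm (enters the test cost component).
#' @param censor_fraction fraction of participants administratively
#'   censored.
#' @param censor_window_days two-element vector: censoring times are drawn
#'   uniformly over this window of study days (default spans years 2-5 up
#'   to the trial's maximum observed follow-up of ~4.3 years, so year-1
#'   data are complete).
#' @param covariates list: \code{age_mean}, \code{age_sd} (normal,
#'   truncated to 18-95 years), \code{p_female}, \code{qof_lambda} and
#'   \code{abx_lambda} (Poisson counts).
#' @param covariate_effects list: \code{age65_qaly}, an additive annual
#'   utility effect of the intervention for participants aged 65+ (0 =
#'   covariates independent of outcomes, the default).
#' @param seed RNG seed.
#' @return object of class \code{"generator_config"}.
#' @export
generator_config <- function(params = resolve_missing_branches(table2_params()),
                             post_year1 = cost_regression(),
                             n_per_arm = c(paap = 401L, usual_care = 410L),
                             post_year1_cv = 2,
                             test_unit_cost = c(paap = 186.29, usual_care = 126.67),
                             censor_fraction = 0.32,
                             censor_window_days = c(366, 1570),
                             covariates = list(age_mean = 54, age_sd = 16,
                                               p_female = 0.71,
                                               qof_lambda = 1.8,
                                               abx_lambda = 1.9),
                             covariate_effects = list(age65_qaly = 0),
                             seed = 1L) {
  stopifnot(inherits(params, "branch_params"),
            inherits(post_year1, "cost_regression"),
            all(n_per_arm >= 0), length(n_per_arm) == 2,
            all(ARMS %in% names(n_per_arm)),
            post_year1_cv > 0, all(test_unit_cost >= 0),
            censor_fraction >= 0, censor_fraction <= 1,
            length(censor_window_days) == 2,
            censor_window_days[1] > 0,
            censor_window_days[2] >= censor_window_days[1])
  if (!params_resolved(params))
    stop("generator truth parameters must be resolved (no empty branches)")
  structure(list(params = params, post_year1 = post_year1,
                 n_per_arm = stats::setNames(as.integer(round(n_per_arm[ARMS])),
                                             ARMS),
                 post_year1_cv = post_year1_cv,
                 test_unit_cost = test_unit_cost,
                 censor_fraction = censor_fraction,
                 censor_window_days = censor_window_days,
                 covariates = covariates,
                 covariate_effects = covariate_effects,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# Small stable FNV-1a hash of a configuration's deparsed form.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 216613626
  for (b in bytes) h <- (bitwXor(h, b) * 16777619) %% 2147483647
  sprintf("%08x", h)
}

rgamma_ms <- function(n, mean, sd) {
  # Gamma draws matched to mean/sd; sd 0 degenerates to the mean.
  out <- rep(mean, length.out = n)
  ok <- sd > 0 & mean > 0
  if (any(ok)) {
    shape <- (mean / sd)^2
    out[ok] <- stats::rgamma(sum(ok), shape = shape[ok],
                             scale = (sd^2 / mean)[ok])
  }
  out
}

rbeta_ms <- function(n, mean, sd) {
  out <- rep(mean, length.out = n)
  ok <- sd > 0
  if (any(ok)) {
    nu <- mean[ok] * (1 - mean[ok]) / sd[ok]^2 - 1
    out[ok] <- stats::rbeta(sum(ok), mean[ok] * nu, (1 - mean[ok]) * nu)
  }
  out
}

branch_of <- function(tested, result, delabelled, tf) {
  ifelse(!tested,
         ifelse(tf, "notest_tf", "notest_notf"),
  ifelse(result == "positive",
         ifelse(delabelled,
                ifelse(tf, "pos_nopal_tf", "pos_nopal_notf"),
                ifelse(tf, "pos_pal_tf", "pos_pal_notf")),
         ifelse(delabelled,
                ifelse(tf, "neg_nopal_tf", "neg_nopal_notf"),
                ifelse(tf, "neg_pal_tf", "neg_pal_notf"))))
}

#' Generate a synthetic two-arm trial
#'
#' Draws individual participants through the first-year decision tree at
#' the configured branch probabilities, assigns per-branch first-year
#' costs (Gamma) and annual utilities (Beta), extends annual costs through
#' year 5 from the post-year-1 cost model with Gamma noise (utilities held
#' at their year-1 value), and attaches covariates. All participants are
#' initially uncensored (365 exposure days each year); apply
#' \code{\link{apply_censoring}} for administrative censoring.
#'
#' @param config a \code{\link{generator_config}}.
#' @return object of class \code{"participant_table"}: list with
#'   \code{participants} (one row per participant), \code{years} (one row
#'   per participant-year: exposure days, component costs, total cost,
#'   utility) and \code{meta} (seed, config hash).
#' @export
generate_trial <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  horizon <- 5L
  parts <- vector("list", 2)
  years <- vector("list", 2)
  offset <- 0L
  for (ai in seq_along(ARMS)) {
    arm <- ARMS[ai]
    n <- config$n_per_arm[[arm]]
    if (n == 0L) {
      parts[[ai]] <- NULL
      next
    }
    ap <- config$params[[arm]]
    pm <- lapply(ap$probs, function(d) d$mean)
    id <- offset + seq_len(n)
    offset <- offset + n
    tested <- stats::runif(n) < pm$p_test
    result <- rep(NA_character_, n)
    result[tested] <- ifelse(stats::runif(sum(tested)) < pm$p_positive,
                             "positive", "negative")
    delab <- rep(FALSE, n)
    pos <- tested & result == "positive"
    neg <- tested & result == "negative"
    delab[pos] <- stats::runif(sum(pos)) < pm$p_delabel_pos
    delab[neg] <- stats::runif(sum(neg)) < pm$p_delabel_neg
    p_tf <- rep(pm$tf_notest, n)
    p_tf[pos & !delab] <- pm$tf_pos_pal
    p_tf[neg & !delab] <- pm$tf_neg_pal
    p_tf[neg & delab] <- pm$tf_neg_nopal
    p_tf[tested & delab & result == "positive"] <- pm$tf_neg_nopal
    tf <- stats::runif(n) < p_tf
    branch <- branch_of(tested, result, delab, tf)

    cov <- config$covariates
    age <- pmin(95, pmax(18, round(stats::rnorm(n, cov$age_mean, cov$age_sd))))
    gender <- ifelse(stats::runif(n) < cov$p_female, "female", "male")
    qof <- stats::rpois(n, cov$qof_lambda)
    abx <- stats::rpois(n, cov$abx_lambda)

    # First-year totals and utilities by branch truth (structural branches
    # with zero probability never occur; guard with no-test values).
    cmean <- vapply(ap$costs, function(d) d$mean, 0)
    csd <- vapply(ap$costs, function(d) d$sd, 0)
    qmean <- vapply(ap$qalys, function(d) d$mean, 0)
    qsd <- vapply(ap$qalys, function(d) d$sd, 0)
    bidx <- match(branch, PAYOFF_BRANCHES)
    if (anyNA(bidx)) stop("structural branch drawn; p_delabel_pos must be 0")
    cost1 <- rgamma_ms(n, cmean[bidx], csd[bidx])
    util1 <- rbeta_ms(n, qmean[bidx], qsd[bidx])
    if (arm == "paap" && config$covariate_effects$age65_qaly != 0)
      util1 <- pmin(1, pmax(0, util1 +
                              config$covariate_effects$age65_qaly * (age >= 65)))

    # Later-year annual costs from the post-year-1 model truth.
    label <- !delab
    reg <- config$post_year1
    ylist <- vector("list", horizon)
    sh1 <- .default_shares[[arm]]$year1
    shL <- .default_shares[[arm]]$later
    split_components <- function(total, test_cost, shares) {
      rest <- pmax(total - test_cost, 0)
      comp <- outer(rest, shares / sum(shares))
      colnames(comp) <- .component_names
      comp
    }
    tc1 <- ifelse(tested, pmin(config$test_unit_cost[[arm]], cost1), 0)
    comp1 <- split_components(cost1, tc1, sh1)
    ylist[[1]] <- data.frame(id = id, year = 1L, exposure_days = 365,
                             cost_test = tc1, comp1,
                             cost_total = tc1 + rowSums(comp1),
                             utility = util1)
    for (t in 2:horizon) {
      mu <- predict(reg, label, tf, t)
      ct <- rgamma_ms(n, mu, config$post_year1_cv * mu)
      compt <- split_components(ct, 0, shL)
      ylist[[t]] <- data.frame(id = id, year = as.integer(t),
                               exposure_days = 365,
                               cost_test = 0, compt,
                               cost_total = rowSums(compt),
                               utility = util1)
    }
    parts[[ai]] <- data.frame(
      id = id, arm = arm, tested = tested,
      test_result = ifelse(tested, result, "not_applicable"),
      delabelled = delab, treatment_failure = tf, branch = branch,
      age = age, gender = gender, qof_count = qof, abx_count = abx,
      stringsAsFactors = FALSE)
    years[[ai]] <- do.call(rbind, ylist)
  }
  participants <- do.call(rbind, parts)
  yrs <- do.call(rbind, years)
  if (is.null(participants)) {
    participants <- data.frame(id = integer(), arm = character(),
                               tested = logical(), test_result = character(),
                               delabelled = logical(),
                               treatment_failure = logical(),
                               branch = character(), age = numeric(),
                               gender = character(), qof_count = integer(),
                               abx_count = integer())
    yrs <- data.frame(id = integer(), year = integer(),
                      exposure_days = numeric(), cost_test = numeric(),
                      primary_care = numeric(), medications = numeric(),
                      admissions = numeric(), outpatient = numeric(),
                      emergency = numeric(), cost_total = numeric(),
                      utility = numeric())
  } else {
    yrs <- yrs[order(yrs$id, yrs$year), ]
    rownames(yrs) <- NULL
  }
  structure(list(participants = participants, years = yrs,
                 meta = list(seed = config$seed,
                             config_hash = config_hash(config))),
            class = "participant_table")
}

#' @export
print.participant_table <- function(x, ...) {
  np <- nrow(x$participants)
  cat(sprintf("Participant table: %d participants (%s), %d participant-years\n",
              np,
              paste(sprintf("%s=%d", ARMS,
                            vapply(ARMS, function(a) sum(x$participants$arm == a),
                                   0L)), collapse = ", "),
              nrow(x$years)))
  cat(sprintf("  seed %s, config %s\n", format(x$meta$seed), x$meta$config_hash))
  invisible(x)
}

#' Apply administrative censoring to a generated trial
#'
#' A configured fraction of participants is censored at a time drawn
#' uniformly over the censoring window. Years entirely after the censoring
#' time are removed; the censoring year's exposure days are reduced and
#' its observed costs scaled proportionally (uniform daily cost within the
#' year). Utilities are annual averages and are left unchanged.
#'
#' @param table a \code{\link{generate_trial}} result.
#' @param config the \code{\link{generator_config}}.
#' @return a censored \code{"participant_table"}.
#' @export
apply_censoring <- function(table, config) {
  stopifnot(inherits(table, "participant_table"),
            inherits(config, "generator_config"))
  if (config$censor_fraction == 0 || nrow(table$participants) == 0)
    return(table)
  set.seed(config$seed + 104729L) # distinct stream from generation
  n <- nrow(table$participants)
  cens <- stats::runif(n) < config$censor_fraction
  day <- rep(Inf, n)
  day[cens] <- stats::runif(sum(cens), config$censor_window_days[1],
                            config$censor_window_days[2])
  names(day) <- as.character(table$participants$id)
  y <- table$years
  cd <- day[as.character(y$id)]
  start <- (y$year - 1) * 365
  keep <- start < cd
  y <- y[keep, ]
  cd <- cd[keep]; start <- start[keep]
  partial <- cd < start + 365
  expo <- ifelse(partial, cd - start, y$exposure_days)
  scale <- expo / 365
  costcols <- c("cost_test", .component_names, "cost_total")
  y[partial, costcols] <- y[partial, costcols] * scale[partial]
  y$exposure_days <- expo
  rownames(y) <- NULL
  out <- table
  out$years <- y
  out$meta$censored <- TRUE
  out
}

#' Reassign untested intervention participants to usual care
#'
#' The "As Treated" scenario: every intervention-arm participant who did
#' not undergo testing is moved to the usual-care arm; all other fields
#' are unchanged and the table size is preserved.
#'
#' @param table a \code{"participant_table"}.
#' @return a \code{"participant_table"} with reassigned arms.
#' @export
as_treated_reassign <- function(table) {
  stopifnot(inherits(table, "participant_table"))
  out <- table
  move <- out$participants$arm == "paap" & !out$participants$tested
  out$participants$arm[move] <- "usual_care"
  out$meta$as_treated <- TRUE
  out
}

#' Per-year summary of one arm's costs and utilities
#'
#' Means and SDs of each censoring-annualised cost component, the total
#' cost and the utility, by year, mirroring the layout of the trial's
#' resource-use summary table.
#'
#' @param table a \code{"participant_table"}.
#' @param arm \code{"paap"} or \code{"usual_care"}.
#' @return data frame (year x quantity x mean/sd/n); zero rows with
#'   attribute \code{empty = TRUE} when the arm has no participants.
#' @export
summarize_arm <- function(table, arm = c("paap", "usual_care")) {
  arm <- match.arg(arm)
  stopifnot(inherits(table, "participant_table"))
  ids <- table$participants$id[table$participants$arm == arm]
  y <- table$years[table$years$id %in% ids, ]
  cols <- c("cost_test", .component_names, "cost_total", "utility")
  if (nrow(y) == 0) {
    out <- data.frame(year = integer(), quantity = character(),
                      n = integer(), mean = numeric(), sd = numeric())
    attr(out, "empty") <- TRUE
    return(out)
  }
  res <- list()
  for (t in sort(unique(y$year))) {
    yt <- y[y$year == t, ]
    for (cl in cols) {
      v <- yt[[cl]]
      if (cl != "utility") v <- annualize(v, yt$exposure_days)
      res[[length(res) + 1]] <- data.frame(
        year = t, quantity = cl, n = nrow(yt), mean = mean(v),
        sd = if (nrow(yt) > 1) stats::sd(v) else 0)
    }
  }
  out <- do.call(rbind, res)
  attr(out, "empty") <- FALSE
  out
}

num_to_chr <- function(df) {
  for (cl in names(df)) if (is.double(df[[cl]]))
    df[[cl]] <- sprintf("%.17g", df[[cl]])
  df
}

#' Write a participant table to CSV files with a JSON sidecar
#'
#' Writes \code{<prefix>_participants.csv} (one row per participant),
#' \code{<prefix>_years.csv} (one row per participant-year) and
#' \code{<prefix>_meta.json} (seed, config hash). Doubles are written with
#' 17 significant digits so that \code{\link{read_participant_table}}
#' round-trips exactly.
#'
#' @param table a \code{"participant_table"}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return the directory, invisibly.
#' @export
write_participant_table <- function(table, dir, prefix = "trial") {
  stopifnot(inherits(table, "participant_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(num_to_chr(table$participants),
                   file.path(dir, paste0(prefix, "_participants.csv")),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(num_to_chr(table$years),
                   file.path(dir, paste0(prefix, "_years.csv")),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(table$meta,
                       file.path(dir, paste0(prefix, "_meta.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a participant table written by \code{write_participant_table}
#'
#' @param dir directory containing the files.
#' @param prefix file-name prefix used when writing.
#' @return a \code{"participant_table"}.
#' @export
read_participant_table <- function(dir, prefix = "trial") {
  p <- utils::read.csv(file.path(dir, paste0(prefix, "_participants.csv")),
                       stringsAsFactors = FALSE)
  y <- utils::read.csv(file.path(dir, paste0(prefix, "_years.csv")),
                       stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(file.path(dir, paste0(prefix, "_meta.json")),
                              simplifyVector = TRUE)
  structure(list(participants = p, years = y, meta = meta),
            class = "participant_table")
}
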