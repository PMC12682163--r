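#' Convert a per-period relabelling rate to an annual rate
#'
#' Constant-hazard conversion: a probability \code{rate} of relabelling
#' over \code{period_years} corresponds to an annual probability
#' \eqn{1-(1-rate)^{1/period}}. A 6-month rate of 0.066 gives an annual
#' rate of 0.12764.
#'
#' @param rate per-period relabelling probability in \[0,1).
#' @param period_years period length in years.
#' @return annual probability.
#' @export
annualise_rate <- function(rate, period_years) {
  stopifnot(rate >= 0, rate < 1, period_years > 0)
  1 - (1 - rate)^(1 / period_years)
}

#' End-to-end run configuration
#'
#' @param mode \code{"from_table2"} (published parameter table),
#'   \code{"from_synthetic"} (generate a trial, then estimate every
#'   parameter from it) or \code{"from_csv"} (load a participant table
#'   written by \code{\link{write_participant_table}}).
#' @param out_dir output directory for run artifacts.
#' @param econ an \code{\link{econ_config}}.
#' @param generator a \code{\link{generator_config}} (synthetic mode).
#' @param data_dir,data_prefix location of CSV data (csv mode).
#' @param params_file optional parameter file overriding the bundled one
#'   (table mode).
#' @param scenarios list of scenario switches: \code{relabel_rate}
#'   (annual rate for a Markov relabelling row), \code{as_treated}
#'   (logical; data modes only), \code{test_unit_cost} (named numeric
#'   vector of alternative testing unit costs, e.g.
#'   \code{c(day_case = 368)}).
#' @param psa_draws PSA draws for the run.
#' @param subgroups run subgroup analyses (data modes only).
#' @param voi run value-of-information analyses.
#' @param voi_n_grid enrolment grid for the sampling-benefit curve.
#' @param seed run seed.
#' @return object of class \code{"run_config"}. Unknown scenario keys are
#'   an error.
#' @export
run_config <- function(mode = c("from_table2", "from_synthetic", "from_csv"),
                       out_dir, econ = econ_config(),
                       generator = generator_config(),
                       data_dir = NULL, data_prefix = "trial",
                       params_file = NULL,
                       scenarios = list(), psa_draws = 5000,
                       subgroups = FALSE, voi = FALSE,
                       voi_n_grid = seq(100, 2000, by = 100),
                       seed = 1L) {
  mode <- match.arg(mode)
  known <- c("relabel_rate", "as_treated", "test_unit_cost")
  bad <- setdiff(names(scenarios), known)
  if (length(bad) > 0)
    stop("unknown scenario key(s): ", paste(bad, collapse = ", "))
  if (mode == "from_csv" && is.null(data_dir))
    stop("mode 'from_csv' requires data_dir")
  structure(list(mode = mode, out_dir = out_dir, econ = econ,
                 generator = generator, data_dir = data_dir,
                 data_prefix = data_prefix, params_file = params_file,
                 scenarios = scenarios, psa_draws = psa_draws,
                 subgroups = subgroups, voi = voi,
                 voi_n_grid = voi_n_grid, seed = as.integer(seed)),
            class = "run_config")
}

write_num_csv <- function(df, path) {
  utils::write.csv(num_to_chr(df), path, row.names = FALSE, quote = TRUE)
}

cea_row <- function(label, det, psa = NULL) {
  data.frame(
    scenario = label,
    delta_cost = det$delta_cost, delta_qaly = det$delta_qaly,
    icer_class = det$icer$class,
    icer_value = if (is.na(det$icer$value)) NA_real_ else det$icer$value,
    inmb_20000 = inmb(det$delta_cost, det$delta_qaly, 20000),
    inmb_30000 = inmb(det$delta_cost, det$delta_qaly, 30000),
    p_ce_20000 = if (is.null(psa)) NA_real_ else psa$summary$p_ce_20000,
    p_ce_30000 = if (is.null(psa)) NA_real_ else psa$summary$p_ce_30000,
    p_cost_saving = if (is.null(psa)) NA_real_ else psa$summary$p_cost_saving,
    stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: parameter acquisition (published table, synthetic
#' generation + estimation, or CSV load + estimation), the deterministic
#' comparison, the probabilistic sensitivity analysis with its
#' acceptability curve, the configured scenario rows, optional subgroup
#' analyses and optional value-of-information analyses; writes every
#' result as a CSV/JSON artifact in the output directory, stamped with
#' the run seed and configuration hash, and renders a markdown report.
#'
#' @param config a \code{\link{run_config}}.
#' @return (invisibly) a list of the in-memory results, with
#'   \code{artifacts} naming the files written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- "setup"
  result <- tryCatch({
    econ <- config$econ
    econ$seed <- config$seed
    econ$psa_draws <- as.integer(config$psa_draws)
    data <- NULL
    stage <- "parameters"
    if (config$mode == "from_table2") {
      params <- if (is.null(config$params_file)) table2_params()
                else read_branch_params(config$params_file)
      params <- resolve_missing_branches(params)
      reg <- cost_regression()
    } else {
      if (config$mode == "from_synthetic") {
        gen <- config$generator
        gen$seed <- config$seed
        data <- apply_censoring(generate_trial(gen), gen)
      } else {
        data <- read_participant_table(config$data_dir, config$data_prefix)
      }
      params <- resolve_missing_branches(estimate_params(data))
      reg <- fit_post_year1_cost_model(data)
    }
    write_branch_params(params, file.path(out, "parameters.json"))
    # hash the scientific configuration only, not filesystem locations
    hash_cfg <- config[setdiff(names(config), c("out_dir", "data_dir"))]
    meta <- list(seed = config$seed, mode = config$mode,
                 config_hash = config_hash(hash_cfg))
    jsonlite::write_json(meta, file.path(out, "run_meta.json"),
                         auto_unbox = TRUE, digits = NA)

    stage <- "deterministic"
    model <- paap_model(params, reg, econ)
    det <- model$cea
    s <- summary(model)
    write_num_csv(s$per_period, file.path(out, "per_period.csv"))

    stage <- "psa"
    psa <- simulate(model)
    write_num_csv(psa$draws, file.path(out, "psa_draws.csv"))
    jsonlite::write_json(c(psa$summary, list(seed = psa$seed,
                                             n_draws = psa$n_draws)),
                         file.path(out, "psa_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    cv <- ceac(psa, econ$wtp_grid)
    write_num_csv(as.data.frame(cv), file.path(out, "ceac.csv"))
    write_num_csv(cea_row("base_case", det, psa),
                  file.path(out, "cea_deterministic.csv"))

    stage <- "scenarios"
    sens <- list()
    sc <- config$scenarios
    if (!is.null(sc$relabel_rate)) {
      r <- sc$relabel_rate
      det_r <- deterministic_cea(params, reg, econ, relabel_rate = r)
      psa_r <- run_psa(params, reg, econ, relabel_rate = r)
      sens[[length(sens) + 1]] <-
        cea_row(sprintf("relabelling_annual_%.4f", r), det_r, psa_r)
    }
    if (isTRUE(sc$as_treated)) {
      if (is.null(data))
        stop("'as_treated' scenario requires individual-level data")
      at <- as_treated_reassign(data)
      p_at <- resolve_missing_branches(estimate_params(at))
      r_at <- fit_post_year1_cost_model(at)
      det_at <- deterministic_cea(p_at, r_at, econ)
      psa_at <- run_psa(p_at, r_at, econ)
      sens[[length(sens) + 1]] <- cea_row("as_treated", det_at, psa_at)
    }
    for (nm in names(sc$test_unit_cost)) {
      p_uc <- apply_unit_cost_scenario(params, sc$test_unit_cost[[nm]])
      det_uc <- deterministic_cea(p_uc, reg, econ)
      psa_uc <- run_psa(p_uc, reg, econ)
      sens[[length(sens) + 1]] <-
        cea_row(paste0("unit_cost_", nm), det_uc, psa_uc)
    }
    if (length(sens) > 0)
      write_num_csv(do.call(rbind, sens), file.path(out, "sensitivity.csv"))

    stage <- "subgroups"
    sub <- NULL
    if (isTRUE(config$subgroups)) {
      if (is.null(data))
        stop("subgroup analysis requires individual-level data")
      sub <- subgroup_cea(data, config = econ,
                          n_draws = min(2000, econ$psa_draws))
      write_num_csv(sub, file.path(out, "subgroups.csv"))
    }

    stage <- "voi"
    voi <- NULL
    if (isTRUE(config$voi)) {
      ev <- evpi(psa, 20000)
      rank <- evppi_rank(psa, 20000)
      design_c <- trial_design(endpoints = "clinical")
      design_f <- trial_design(endpoints = "full")
      evsi_c <- evsi(psa, design_c, 20000, seed = config$seed)
      evsi_f <- evsi(psa, design_f, 20000, seed = config$seed)
      pop <- population_model()
      enbs <- enbs_optimize(psa, design_c, pop, 20000,
                            n_grid = config$voi_n_grid, seed = config$seed)
      voi <- list(evpi = ev,
                  evsi_clinical = evsi_c, evsi_full = evsi_f,
                  trial_cost = trial_cost(design_c),
                  trial_duration = trial_duration(design_c),
                  net_value_clinical =
                    population_value(evsi_c, pop) - trial_cost(design_c),
                  net_value_full =
                    population_value(evsi_f, pop) - trial_cost(design_f),
                  optimal_n = enbs$optimal_n)
      jsonlite::write_json(voi, file.path(out, "voi.json"),
                           auto_unbox = TRUE, digits = NA)
      write_num_csv(rank, file.path(out, "evppi.csv"))
      write_num_csv(enbs$curve, file.path(out, "enbs.csv"))
    }

    stage <- "report"
    write_report(out)
    list(model = model, psa = psa, sensitivity = sens, subgroups = sub,
         voi = voi, artifacts = list.files(out))
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}

fmt_or_absent <- function(path, fn) {
  if (file.exists(path)) fn(path) else "(absent)\n"
}

md_table <- function(df) {
  fmt <- function(v) {
    if (is.numeric(v)) formatC(v, format = "g", digits = 6) else as.character(v)
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  if (is.null(dim(cells))) cells <- matrix(cells, nrow = 1)
  paste0("| ", paste(names(df), collapse = " | "), " |\n",
         "|", paste(rep("---", ncol(df)), collapse = "|"), "|\n",
         paste(apply(cells, 1, function(r)
           paste0("| ", paste(r, collapse = " | "), " |")), collapse = "\n"),
         "\n")
}

#' Render a markdown report from a run's artifacts
#'
#' Produces a single human-readable summary reproducing the layouts of
#' the per-period, headline, sensitivity and subgroup tables from the
#' run's own numbers, labelled with the run seed and configuration hash.
#' Missing artifacts are listed as absent; the report is still produced.
#'
#' @param dir the run's output directory.
#' @return path of the written \code{report.md}, invisibly.
#' @export
write_report <- function(dir) {
  rd_csv <- function(p) utils::read.csv(p, stringsAsFactors = FALSE)
  parts <- c("# Cost-effectiveness analysis report\n")
  meta_p <- file.path(dir, "run_meta.json")
  if (file.exists(meta_p)) {
    meta <- jsonlite::read_json(meta_p, simplifyVector = TRUE)
    parts <- c(parts, sprintf("Mode: %s; seed: %s; config: %s\n",
                              meta$mode, meta$seed, meta$config_hash))
  } else parts <- c(parts, "Run metadata: (absent)\n")
  section <- function(title, file, render = md_table) {
    p <- file.path(dir, file)
    body <- fmt_or_absent(p, function(pp) render(rd_csv(pp)))
    paste0("\n## ", title, "\n\n", body)
  }
  parts <- c(parts,
             section("Per-period totals", "per_period.csv"),
             section("Deterministic comparison", "cea_deterministic.csv"),
             {
               p <- file.path(dir, "psa_summary.json")
               paste0("\n## Probabilistic sensitivity analysis\n\n",
                      fmt_or_absent(p, function(pp) {
                        s <- jsonlite::read_json(pp, simplifyVector = TRUE)
                        paste0(sprintf("- mean incremental cost: %.3f (P(cost saving) %.1f%%)\n",
                                       s$mean_delta_cost, 100 * s$p_cost_saving),
                               sprintf("- mean incremental QALYs: %.4f\n",
                                       s$mean_delta_qaly),
                               sprintf("- INMB 20,000: %.3f (P(CE) %.0f%%); INMB 30,000: %.3f (P(CE) %.0f%%)\n",
                                       s$inmb_20000, 100 * s$p_ce_20000,
                                       s$inmb_30000, 100 * s$p_ce_30000),
                               sprintf("- draws: %d (failed: %d)\n",
                                       s$n_draws, s$failed_draws))
                      }))
             },
             section("Sensitivity analyses", "sensitivity.csv"),
             section("Subgroup analyses", "subgroups.csv"),
             {
               p <- file.path(dir, "voi.json")
               paste0("\n## Value of information\n\n",
                      fmt_or_absent(p, function(pp) {
                        v <- jsonlite::read_json(pp, simplifyVector = TRUE)
                        paste0(sprintf("- EVPI per patient: %.2f\n", v$evpi),
                               sprintf("- EVSI per patient (clinical / full): %.2f / %.2f\n",
                                       v$evsi_clinical, v$evsi_full),
                               sprintf("- follow-on trial cost: %.0f; duration: %.1f months\n",
                                       v$trial_cost, v$trial_duration),
                               sprintf("- net population value (clinical / full): %.0f / %.0f\n",
                                       v$net_value_clinical, v$net_value_full),
                               sprintf("- sampling-optimal enrolment: %d\n",
                                       v$optimal_n))
                      }))
             })
  path <- file.path(dir, "report.md")
  writeLines(paste(parts, collapse = ""), path)
  invisible(path)
}
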