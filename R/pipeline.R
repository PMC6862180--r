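#' Profile presets for the pipeline
#'
#' `desk` (20 replications per cell, 3-day horizon) keeps the full
#' workflow interactive on one CPU; `paper` (1000 replications, 7-day
#' horizon) reproduces the study scale.
#'
#' @param profile `"desk"` or `"paper"`.
#' @return list with `replications`, `horizon_days`.
#' @export
pipeline_profile <- function(profile = c("desk", "paper")) {
  profile <- match.arg(profile)
  if (profile == "desk") list(replications = 20L, horizon_days = 3L)
  else list(replications = 1000L, horizon_days = 7L)
}

stage_seed <- function(master_seed, stage) {
  # documented counter scheme: independent per-stage substreams
  as.integer((as.numeric(master_seed) * 131 + stage * 7919) %%
               .Machine$integer.max)
}

#' Run the full simulation-optimization workflow
#'
#' Executes the four study steps in order: (1) simulate the 36-cell
#' dynamic Taguchi plan, (2) fit per-row ideal functions and SN ratios and
#' select SN-optimal levels per response, (3) map cell means to
#' desirabilities and train the neural-network surrogate (architecture
#' search over hidden widths), (4) maximize TP = d1 * d2^2 by the genetic
#' algorithm, then sweep each factor one-at-a-time around the optimum.
#' Fully deterministic for a given `seed` (stages use independent derived
#' substreams).
#'
#' @param base_config a [scenario_config()]; its `horizon_days` is
#'   overridden by the profile.
#' @param profile `"desk"` or `"paper"`; see [pipeline_profile()].
#' @param seed master seed.
#' @param hidden_range hidden-layer widths searched (default 2:8).
#' @param nn_iterations training iterations per candidate network.
#' @param ga ga settings (a [ga_config()]; its seed is overridden by the
#'   derived stage seed).
#' @param out_dir optional directory; when given, [write_report()] is
#'   called on the result.
#' @return a `pipeline_report`: list with `plan`, `responses`, `cells`,
#'   `sn` (per-response SN tables, main effects, Taguchi optima),
#'   `bounds`, `surrogate` (comparison + best model), `optimum`,
#'   `sensitivity`, `seeds`, `profile`.
#' @export
run_pipeline <- function(base_config = scenario_config(),
                         profile = c("desk", "paper"),
                         seed = 1L,
                         hidden_range = 2:8,
                         nn_iterations = 10000L,
                         ga = ga_config(),
                         out_dir = NULL) {
  profile <- match.arg(profile)
  prof <- pipeline_profile(profile)
  cfg <- base_config
  cfg$horizon_days <- prof$horizon_days
  cfg <- validate_scenario_config(cfg)
  seeds <- list(simulate = stage_seed(seed, 1L), split = stage_seed(seed, 2L),
                nn = stage_seed(seed, 3L), ga = stage_seed(seed, 4L))

  # STEP 1: simulate the crossed plan
  plan <- build_plan(replications = prof$replications, base_config = cfg)
  responses <- simulate_plan(plan, seed = seeds$simulate)
  cells <- cell_means(responses)

  # STEP 2: dynamic SN analysis per response
  sn <- lapply(c(EDWINC = "mean_EDWINC", ST = "mean_ST"), function(rv) {
    tab <- sn_table(responses, response = rv)
    eff <- main_effects(tab)
    list(table = tab, effects = eff, optimum = select_optimal_levels(eff))
  })

  # STEP 3: desirabilities + NN surrogate
  cells <- add_desirabilities(cells)
  bounds <- attr(cells, "bounds")
  ttab <- build_training_table(cells, seed = seeds$split)
  search <- architecture_search(ttab, hidden_range = hidden_range,
                                iterations = nn_iterations, seed = seeds$nn)

  # STEP 4: GA optimization + OFAT sensitivity
  ga$seed <- seeds$ga
  optimum <- optimize_factors(search$best, config = ga)
  sens <- ofat_sweep(search$best, optimum)

  report <- list(plan = plan, responses = responses, cells = cells,
                 sn = sn, bounds = bounds,
                 surrogate = search, optimum = optimum, sensitivity = sens,
                 seeds = c(master = seed, unlist(seeds)),
                 profile = list(name = profile, replications =
                                  prof$replications,
                                horizon_days = prof$horizon_days))
  class(report) <- "pipeline_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("EMS simulation-optimization report (", x$profile$name, " profile, ",
      x$profile$replications, " reps x ", x$profile$horizon_days,
      "-day horizon)\n", sep = "")
  cat("  Taguchi SN optima: EDWINC ",
      paste(x$sn$EDWINC$optimum$levels, collapse = ""),
      sprintf(" (%.2f dB), ST ", x$sn$EDWINC$optimum$predicted_sn_db),
      paste(x$sn$ST$optimum$levels, collapse = ""),
      sprintf(" (%.2f dB)\n", x$sn$ST$optimum$predicted_sn_db), sep = "")
  cat("  surrogate: ", with(x$surrogate$comparison,
                            structure[which.min(rmse_test)]), "\n", sep = "")
  print(x$optimum)
  invisible(x)
}

#' Write every pipeline artifact as delimited/structured text files
#'
#' Emits the design plan, per-replication responses, cell means with
#' desirabilities, SN and main-effect tables, surrogate comparison table
#' and serialized best model, GA optimum with its convergence trace,
#' sensitivity tables and a plain-text summary report.
#'
#' @param report a `pipeline_report`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(d, f) utils::write.csv(d, file.path(dir, f), row.names = FALSE)
  w(report$plan$cells, "design_plan.csv")
  w(report$responses, "responses.csv")
  w(report$cells, "cell_means.csv")
  for (rv in names(report$sn)) {
    w(report$sn[[rv]]$table, paste0("sn_table_", rv, ".csv"))
    w(report$sn[[rv]]$effects, paste0("main_effects_", rv, ".csv"))
  }
  w(report$surrogate$comparison, "surrogate_comparison.csv")
  write_surrogate(report$surrogate$best, file.path(dir, "surrogate_best.json"))
  w(data.frame(generation = seq_along(report$optimum$history),
               best_tp = report$optimum$history), "ga_history.csv")
  for (f in names(report$sensitivity))
    w(report$sensitivity[[f]], paste0("sensitivity_", f, ".csv"))
  jsonlite::write_json(
    list(profile = report$profile, seeds = as.list(report$seeds),
         bounds = report$bounds,
         taguchi_optima = lapply(report$sn, function(s)
           list(levels = as.list(s$optimum$levels),
                predicted_sn_db = s$optimum$predicted_sn_db)),
         ga_optimum = list(setting = report$optimum$setting,
                           tp = report$optimum$tp)),
    file.path(dir, "report.json"), digits = NA, auto_unbox = TRUE)
  summary_lines <- c(
    "EMS simulation-optimization summary",
    sprintf("profile: %s (%d replications, %d-day horizon)",
            report$profile$name, report$profile$replications,
            report$profile$horizon_days),
    sprintf("master seed: %s", report$seeds[["master"]]),
    sprintf("Taguchi optimum (EDWINC): %s, predicted %.2f dB",
            paste(report$sn$EDWINC$optimum$levels, collapse = ","),
            report$sn$EDWINC$optimum$predicted_sn_db),
    sprintf("Taguchi optimum (ST): %s, predicted %.2f dB",
            paste(report$sn$ST$optimum$levels, collapse = ","),
            report$sn$ST$optimum$predicted_sn_db),
    sprintf("best NN structure: %s",
            report$surrogate$comparison$structure[
              which.min(report$surrogate$comparison$rmse_test)]),
    sprintf("GA optimum: A = %.2f, B = %d, C = %d, D = %d, TP = %.3f",
            report$optimum$setting$A, report$optimum$setting$B,
            report$optimum$setting$C, report$optimum$setting$D,
            report$optimum$tp))
  writeLines(summary_lines, file.path(dir, "report.txt"))
  invisible(dir)
}
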