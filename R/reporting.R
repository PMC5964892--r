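#' Pipeline runners
#'
#' High-level entry points wiring simulation, index computation,
#' analysis and design into file-based reports. Each runner writes its
#' outputs under `out_dir` together with a JSON manifest recording the
#' configuration, seed and package version, so any run can be replayed.
#' A thin command-line dispatcher over these functions ships in
#' `inst/cli/fluidroc.R`.
#'
#' @name runners
NULL

#' @describeIn runners Simulate a cohort (and optionally a beat series)
#'   and write them as CSV.
#' @param out_dir Output directory (created if needed).
#' @param n_patients Cohort size.
#' @param seed Run seed; all stage seeds derive from it.
#' @param beat_series Also write a simulated beat series CSV.
#' @return `run_simulate()`: the cohort file path, invisibly.
#' @export
run_simulate <- function(out_dir, n_patients = 30, seed = 1,
                         beat_series = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  coh <- simulate_cohort(cohort_config(n_patients = n_patients),
                         seed = derive_seed(seed, 1))
  path <- file.path(out_dir, "cohort.csv")
  write_cohort(coh, path)
  if (beat_series) {
    bs <- simulate_beat_series(beat_config(noise_sd = 0.02),
                               seed = derive_seed(seed, 2))
    write_beat_series(bs, file.path(out_dir, "beat_series.csv"))
  }
  write_manifest(out_dir, list(command = "simulate", seed = seed,
                               n_patients = n_patients,
                               beat_series = beat_series))
  message(sprintf("simulate: wrote %d patients to %s", n_patients, path))
  invisible(path)
}

#' @describeIn runners Analyze a cohort CSV and write the summary,
#'   accuracy and comparison tables.
#' @param cohort_csv Path of a cohort CSV (see [read_cohort()]).
#' @param threshold Responder cutoff, percent.
#' @param boot_reps,tolerance Passed to [roc_grayzone()].
#' @return `run_analyze()`: the [fluid_response_analysis()] object,
#'   invisibly.
#' @export
run_analyze <- function(cohort_csv, out_dir, threshold = 15,
                        boot_reps = 2000, tolerance = 0.10, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- read_cohort(cohort_csv)
  ana <- fluid_response_analysis(cohort, threshold = threshold,
                                 boot_reps = boot_reps,
                                 tolerance = tolerance, seed = seed)
  s <- ana$summary
  utils::write.csv(as.data.frame(s), file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(accuracy_table(ana),
                   file.path(out_dir, "accuracy.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(unclass(ana$comparison)),
                   file.path(out_dir, "auc_comparison.csv"))
  write_manifest(out_dir, list(command = "analyze",
                               cohort_csv = cohort_csv, seed = seed,
                               threshold = threshold,
                               boot_reps = boot_reps,
                               tolerance = tolerance))
  message(sprintf("analyze: %d/%d responders (%.0f%%)",
                  attr(s, "responder_n"), attr(s, "n"),
                  100 * attr(s, "responder_fraction")))
  invisible(ana)
}

#' @describeIn runners Compute per-window indices from a beat-series
#'   CSV under a device preset.
#' @param beat_csv Path of a beat-series CSV (see [read_beat_series()]).
#' @param device Device preset name (see [device_policy()]).
#' @param step Window-end spacing, seconds.
#' @return `run_indices()`: the indices file path, invisibly.
#' @export
run_indices <- function(beat_csv, out_dir, device = "picco", step = 5) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  series <- read_beat_series(beat_csv)
  idx <- windowed_indices(series, device_policy(device), step = step)
  path <- file.path(out_dir, "indices.csv")
  utils::write.csv(idx, path, row.names = FALSE)
  write_manifest(out_dir, list(command = "indices", beat_csv = beat_csv,
                               device = device, step = step))
  invisible(path)
}

#' @describeIn runners Sample-size design report with a Monte-Carlo
#'   power check.
#' @param alpha,power,sd_pct,effect_pct,dropouts See
#'   [required_sample_size()].
#' @param reps Monte-Carlo replicates for the power check.
#' @return `run_design()`: a list with the design inputs, `n_evaluable`,
#'   `n_total`, and closed-form and simulated power, invisibly.
#' @export
run_design <- function(out_dir, alpha = 0.05, power = 0.8, sd_pct = 20,
                       effect_pct = 15, dropouts = 2, reps = 50000,
                       seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n <- required_sample_size(alpha, power, sd_pct, effect_pct, dropouts)
  report <- list(alpha = alpha, power = power, sd_pct = sd_pct,
                 effect_pct = effect_pct, dropouts = dropouts,
                 n_evaluable = n$n_evaluable, n_total = n$n_total,
                 closed_form_power = closed_form_power(n$n_evaluable,
                                                       alpha, sd_pct,
                                                       effect_pct),
                 simulated_power = simulated_power(n$n_evaluable, alpha,
                                                   sd_pct, effect_pct,
                                                   reps = reps,
                                                   seed = derive_seed(
                                                     seed, 4)))
  jsonlite::write_json(report, file.path(out_dir, "design.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(out_dir, list(command = "design", seed = seed,
                               reps = reps))
  message(sprintf("design: %d evaluable + %d dropouts = %d total",
                  n$n_evaluable, dropouts, n$n_total))
  invisible(report)
}
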