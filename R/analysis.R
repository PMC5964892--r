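#' End-to-end analysis of a fluid-challenge cohort
#'
#' Runs the complete evaluation on a paired cohort table: before/after
#' summary with paired t-tests, responder classification by relative
#' stroke volume increase, one gray-zone ROC fit per dynamic preload
#' index (baseline values as predictor), and the pairwise AUC
#' comparison.
#'
#' @param cohort A cohort table ([simulate_cohort()], [read_cohort()]).
#' @param threshold Responder cutoff on the relative stroke volume
#'   change, percent.
#' @param indices Index columns to analyze (default all seven).
#' @param boot_reps,tolerance,conf Passed to [roc_grayzone()].
#' @param seed Integer seed; per-index bootstrap seeds are derived from
#'   it deterministically.
#' @return An object of class `fluid_response_analysis`: list with
#'   `summary` ([summarize_cohort()]), `responders`
#'   ([classify_responders()]), `fits` (named list of [roc_grayzone()]),
#'   and `comparison` ([pairwise_auc_matrix()]).
#' @examples
#' coh <- simulate_cohort(cohort_config(), seed = 1)
#' ana <- fluid_response_analysis(coh, boot_reps = 200, seed = 1)
#' ana
#' @export
fluid_response_analysis <- function(cohort, threshold = 15,
                                    indices = index_names(),
                                    boot_reps = 2000, tolerance = 0.10,
                                    conf = 0.95, seed = NULL) {
  validate_cohort(cohort)
  missing <- setdiff(indices, names(cohort))
  if (length(missing))
    stop("cohort lacks index column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  resp <- classify_responders(cohort, threshold)
  if (!any(resp$responder) || all(resp$responder))
    stop("cohort has a single responder class; ROC analysis undefined",
         call. = FALSE)
  before <- cohort[cohort$phase == "before", ]
  before <- before[match(resp$patient_id, before$patient_id), ]
  fits <- lapply(seq_along(indices), function(i) {
    roc_grayzone(before[[indices[i]]], resp$responder,
                 index_name = indices[i], boot_reps = boot_reps,
                 tolerance = tolerance, conf = conf,
                 seed = derive_seed(seed, i))
  })
  names(fits) <- indices
  structure(list(summary = summarize_cohort(cohort, threshold),
                 responders = resp, fits = fits,
                 comparison = if (length(fits) >= 2)
                   pairwise_auc_matrix(fits) else NULL,
                 threshold = threshold, call = match.call()),
            class = "fluid_response_analysis")
}

#' Accuracy table of a fitted analysis
#'
#' The per-index accuracy summary in the conventional reporting layout:
#' AUC with confidence interval and p-value, the Youden threshold
#' (threshold A) with its bootstrap interval, the center of the
#' diagnosis-tolerance band (threshold B) with its bounds, and the final
#' gray zone.
#'
#' @param x A [fluid_response_analysis()] object or a list of
#'   [roc_grayzone()] fits.
#' @return A `data.frame` with columns `index_name`, `auc`, `ci_low`,
#'   `ci_high`, `p`, `threshold_a`, `a_low`, `a_high`, `threshold_b`,
#'   `b_low`, `b_high`, `final_low`, `final_high`.
#' @export
accuracy_table <- function(x) {
  fits <- if (inherits(x, "fluid_response_analysis")) x$fits else x
  rows <- lapply(fits, function(f) {
    data.frame(index_name = f$index_name, auc = f$auc,
               ci_low = f$auc_ci[1L], ci_high = f$auc_ci[2L], p = f$p,
               threshold_a = f$youden$threshold,
               a_low = f$zone_boot[["low"]],
               a_high = f$zone_boot[["high"]],
               threshold_b = mean(f$zone_tol),
               b_low = f$zone_tol[["low"]],
               b_high = f$zone_tol[["high"]],
               final_low = f$final_zone[["low"]],
               final_high = f$final_zone[["high"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.fluid_response_analysis <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Fluid responsiveness analysis (n = %d, dSV > %g%%)\n",
              attr(s, "n"), x$threshold))
  cat(sprintf("Responders: %d/%d (%.0f%%); dSV %.1f +/- %.1f %%\n\n",
              attr(s, "responder_n"), attr(s, "n"),
              100 * attr(s, "responder_fraction"),
              attr(s, "delta_sv_mean"), attr(s, "delta_sv_sd")))
  tab <- accuracy_table(x)
  show <- data.frame(index = tab$index_name,
                     AUC = sprintf("%.2f (%.2f-%.2f)", tab$auc,
                                   tab$ci_low, tab$ci_high),
                     p = ifelse(tab$p < 0.001, "<0.001",
                                sprintf("%.3f", tab$p)),
                     threshold = sprintf("%.1f", tab$threshold_a),
                     gray_zone = sprintf("%.1f-%.1f", tab$final_low,
                                         tab$final_high))
  print(show, row.names = FALSE)
  invisible(x)
}
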