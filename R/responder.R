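#' Relative stroke volume change and responder classification
#'
#' A patient is a fluid responder when the stroke volume rises by
#' strictly more than `threshold` percent after the bolus:
#' `delta_sv_pct = 100 * (after - before) / before`. The inequality is
#' strict, so a change of exactly 15% is a non-responder at the default
#' cutoff. Classification is invariant to a common rescaling of the
#' stroke volume units.
#'
#' @param before_sv,after_sv Paired stroke volumes (mL); `before_sv`
#'   must be positive. Vectorized.
#' @param threshold Responder cutoff in percent (default 15).
#' @return A `data.frame` with columns `delta_sv_pct` and `responder`.
#' @examples
#' delta_sv_and_classify(59, 73)   # +23.7%, responder
#' @export
delta_sv_and_classify <- function(before_sv, after_sv, threshold = 15) {
  stop_if_not_finite(before_sv, "before_sv")
  stop_if_not_finite(after_sv, "after_sv")
  if (length(before_sv) != length(after_sv))
    stop("before_sv and after_sv must have equal length", call. = FALSE)
  if (any(before_sv <= 0))
    stop("before_sv must be positive", call. = FALSE)
  d <- 100 * (after_sv - before_sv) / before_sv
  data.frame(delta_sv_pct = d, responder = d > threshold)
}

#' Responder status for a cohort
#'
#' Derives the relative stroke volume change and responder flag for each
#' patient of a long patient-phase cohort table.
#'
#' @param cohort A cohort `data.frame` as produced by
#'   [simulate_cohort()] or [read_cohort()].
#' @param threshold Responder cutoff in percent.
#' @return A `data.frame` with one row per patient: `patient_id`,
#'   `sv_before`, `sv_after`, `delta_sv_pct`, `responder`.
#' @export
classify_responders <- function(cohort, threshold = 15) {
  validate_cohort(cohort)
  before <- cohort[cohort$phase == "before", ]
  after <- cohort[cohort$phase == "after", ]
  after <- after[match(before$patient_id, after$patient_id), ]
  cls <- delta_sv_and_classify(before$sv_ml, after$sv_ml, threshold)
  data.frame(patient_id = before$patient_id,
             sv_before = before$sv_ml, sv_after = after$sv_ml, cls)
}

#' Paired t-test on before/after measurements
#'
#' Standard paired t-test on the differences (df = n - 1, two-sided).
#' Zero-variance differences cannot support the test; they are reported
#' as degenerate (`t` and `p` set to `NA`) rather than as a spurious
#' p-value.
#'
#' @param before,after Paired numeric vectors of equal length, n >= 3.
#' @return A list with `t`, `df`, `p`, `mean_diff` and logical
#'   `degenerate`.
#' @export
paired_t_test <- function(before, after) {
  stop_if_not_finite(before, "before")
  stop_if_not_finite(after, "after")
  n <- length(before)
  if (length(after) != n) stop("unequal lengths", call. = FALSE)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  d <- after - before
  if (stats::sd(d) == 0)
    return(list(t = NA_real_, df = n - 1, p = NA_real_,
                mean_diff = mean(d), degenerate = TRUE))
  ht <- stats::t.test(after, before, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = mean(d), degenerate = FALSE)
}

#' Before/after cohort summary
#'
#' Per-channel mean and SD before and after the fluid bolus with the
#' paired t-test p-value, plus the responder count and the moments of
#' the relative stroke volume change — the standard summary table of a
#' fluid-challenge study.
#'
#' @param cohort A cohort table (see [simulate_cohort()]).
#' @param threshold Responder cutoff in percent.
#' @return An object of class `cohort_summary`: a `data.frame` with
#'   columns `parameter`, `before_mean`, `before_sd`, `after_mean`,
#'   `after_sd`, `p`, carrying attributes `n`, `responder_n`,
#'   `responder_fraction`, `delta_sv_mean`, `delta_sv_sd`.
#' @export
summarize_cohort <- function(cohort, threshold = 15) {
  validate_cohort(cohort)
  before <- cohort[cohort$phase == "before", ]
  after <- cohort[cohort$phase == "after", ]
  after <- after[match(before$patient_id, after$patient_id), ]
  if (nrow(before) < 3) stop("need at least 3 patients", call. = FALSE)
  chans <- setdiff(cohort_columns(), c("patient_id", "phase"))
  rows <- lapply(chans, function(ch) {
    tt <- paired_t_test(before[[ch]], after[[ch]])
    data.frame(parameter = ch,
               before_mean = mean(before[[ch]]),
               before_sd = stats::sd(before[[ch]]),
               after_mean = mean(after[[ch]]),
               after_sd = stats::sd(after[[ch]]),
               p = tt$p)
  })
  out <- do.call(rbind, rows)
  resp <- classify_responders(cohort, threshold)
  attr(out, "n") <- nrow(before)
  attr(out, "responder_n") <- sum(resp$responder)
  attr(out, "responder_fraction") <- mean(resp$responder)
  attr(out, "delta_sv_mean") <- mean(resp$delta_sv_pct)
  attr(out, "delta_sv_sd") <- stats::sd(resp$delta_sv_pct)
  attr(out, "threshold") <- threshold
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' @export
print.cohort_summary <- function(x, digits = 3, ...) {
  cat(sprintf("Fluid-challenge cohort: n = %d patients\n", attr(x, "n")))
  cat(sprintf("Stroke volume change: %.1f +/- %.1f %%\n",
              attr(x, "delta_sv_mean"), attr(x, "delta_sv_sd")))
  cat(sprintf("Responders (dSV > %g%%): %d (%.0f%%)\n\n",
              attr(x, "threshold"), attr(x, "responder_n"),
              100 * attr(x, "responder_fraction")))
  fmt <- function(m, s) sprintf("%6.1f +/- %4.1f", m, s)
  tab <- data.frame(parameter = x$parameter,
                    before = fmt(x$before_mean, x$before_sd),
                    after = fmt(x$after_mean, x$after_sd),
                    p = ifelse(is.na(x$p), "-",
                               ifelse(x$p < 0.001, "<0.001",
                                      sprintf("%.3f", x$p))))
  print(tab, row.names = FALSE)
  invisible(x)
}
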