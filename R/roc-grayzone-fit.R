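#' Fit a gray-zone ROC analysis for one index
#'
#' The central fit of the package: given one dynamic preload index
#' measured at baseline and the responder status observed after the
#' fluid bolus, estimate how well the index predicts fluid
#' responsiveness. The fit combines
#'
#' * the empirical ROC curve and its AUC with Hanley-McNeil standard
#'   error, confidence interval and test against chance
#'   ([roc_auc()]),
#' * the Youden-optimal threshold ([youden_threshold()]),
#' * gray-zone candidate A: the stratified-bootstrap percentile interval
#'   of the optimal threshold ([bootstrap_threshold_zone()]),
#' * gray-zone candidate B: the diagnosis-tolerance band of the
#'   two-graph ROC, on both the empirical and the smooth binormal curve
#'   ([tolerance_zone()], [binormal_fit()]),
#' * the final gray zone as the wider of the two candidates
#'   ([final_gray_zone()]).
#'
#' Higher index values are assumed to predict responders (all dynamic
#' preload indices fall after volume loading); no automatic direction
#' detection is performed.
#'
#' @param scores Baseline index values (%), one per patient.
#' @param labels Logical responder flags.
#' @param index_name Label used in printing and tables.
#' @param boot_reps Bootstrap replicates for gray-zone candidate A.
#' @param tolerance Diagnosis tolerance for candidate B.
#' @param conf Confidence level for the AUC interval and the bootstrap
#'   percentile interval.
#' @param seed Integer seed making the bootstrap reproducible.
#' @return An object of class `roc_grayzone`; see [print.roc_grayzone()],
#'   [summary.roc_grayzone()], [coef.roc_grayzone()],
#'   [plot.roc_grayzone()].
#' @examples
#' set.seed(42)
#' scores <- c(rnorm(15, 18, 6), rnorm(15, 12, 6))
#' labels <- rep(c(TRUE, FALSE), each = 15)
#' fit <- roc_grayzone(scores, labels, index_name = "svv", seed = 1)
#' fit
#' coef(fit)
#' @export
roc_grayzone <- function(scores, labels,
                         index_name = deparse(substitute(scores)),
                         boot_reps = 2000, tolerance = 0.10,
                         conf = 0.95, seed = NULL) {
  labels <- check_two_classes(scores, labels)
  roc <- empirical_roc(scores, labels)
  a <- roc_auc(scores, labels, conf = conf)
  yj <- youden_threshold(scores, labels)
  zone_a <- bootstrap_threshold_zone(scores, labels, reps = boot_reps,
                                     conf = conf, seed = seed)
  zone_b <- tolerance_zone(scores, labels, tolerance = tolerance)
  bin <- tryCatch(binormal_fit(scores, labels), error = function(e) NULL)
  structure(list(index_name = index_name,
                 n = length(scores), n_pos = a$n_pos, n_neg = a$n_neg,
                 scores = scores, labels = labels, roc = roc,
                 auc = a$auc, auc_se = a$se, auc_ci = a$ci, p = a$p,
                 youden = yj, zone_boot = zone_a, zone_tol = zone_b,
                 binormal = bin,
                 final_zone = final_gray_zone(zone_a, zone_b),
                 boot_reps = boot_reps, tolerance = tolerance,
                 conf = conf, call = match.call()),
            class = "roc_grayzone")
}

#' @describeIn roc_grayzone Compact display: AUC with CI and p, the
#'   optimal threshold, both gray-zone candidates and the final zone.
#' @param x,object A `roc_grayzone` fit.
#' @param ... Unused.
#' @export
print.roc_grayzone <- function(x, ...) {
  cat(sprintf("Gray-zone ROC analysis: %s\n", x$index_name))
  cat(sprintf("  n = %d (%d responders / %d non-responders)\n",
              x$n, x$n_pos, x$n_neg))
  cat(sprintf("  AUC = %.2f  %.0f%% CI %.2f-%.2f  p %s\n",
              x$auc, 100 * x$conf, x$auc_ci[1L], x$auc_ci[2L],
              if (x$p < 0.001) "< 0.001" else sprintf("= %.3f", x$p)))
  cat(sprintf("  Youden threshold = %.1f%% (Se %.2f, Sp %.2f, J %.2f)\n",
              x$youden$threshold, x$youden$se, x$youden$sp, x$youden$j))
  cat(sprintf("  zone A (bootstrap %d): [%.1f, %.1f]\n",
              x$boot_reps, x$zone_boot[["low"]], x$zone_boot[["high"]]))
  cat(sprintf("  zone B (tolerance %.0f%%): [%.1f, %.1f]\n",
              100 * x$tolerance, x$zone_tol[["low"]],
              x$zone_tol[["high"]]))
  cat(sprintf("  final gray zone: [%.1f, %.1f] (width %.1f)\n",
              x$final_zone[["low"]], x$final_zone[["high"]],
              zone_width(x$final_zone)))
  invisible(x)
}

#' @describeIn roc_grayzone Adds the binormal parameters and the spread
#'   of the bootstrap thresholds to the display.
#' @export
summary.roc_grayzone <- function(object, ...) {
  th <- attr(object$zone_boot, "thresholds")
  structure(list(fit = object,
                 boot_quartiles = stats::quantile(th,
                                                  c(0.25, 0.5, 0.75)),
                 binormal = object$binormal),
            class = "summary.roc_grayzone")
}

#' @export
print.summary.roc_grayzone <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  bootstrap threshold quartiles: %.1f / %.1f / %.1f\n",
              x$boot_quartiles[1L], x$boot_quartiles[2L],
              x$boot_quartiles[3L]))
  if (!is.null(x$binormal))
    cat(sprintf("  binormal: a = %.2f, b = %.2f, smooth AUC = %.2f\n",
                x$binormal$a, x$binormal$b, x$binormal$auc))
  invisible(x)
}

#' @describeIn roc_grayzone Named vector of the headline quantities:
#'   `auc`, `threshold`, `j`, and the final zone bounds.
#' @export
coef.roc_grayzone <- function(object, ...) {
  c(auc = object$auc, threshold = object$youden$threshold,
    j = object$youden$j, zone_low = object$final_zone[["low"]],
    zone_high = object$final_zone[["high"]])
}

#' @describeIn roc_grayzone Two-graph ROC plot (`type = "tgroc"`):
#'   sensitivity and specificity against the decision threshold with the
#'   final gray zone hatched; or the ROC curve in the unit square
#'   (`type = "roc"`) with the smooth binormal curve overlaid when
#'   available.
#' @param type `"tgroc"` or `"roc"`.
#' @export
plot.roc_grayzone <- function(x, type = c("tgroc", "roc"), ...) {
  type <- match.arg(type)
  if (type == "tgroc") {
    roc <- x$roc
    graphics::plot(roc$threshold, roc$se, type = "s", ylim = c(0, 1),
                   xlab = sprintf("%s threshold (%%)", x$index_name),
                   ylab = "Se / Sp",
                   main = sprintf("Two-graph ROC: %s", x$index_name),
                   ...)
    graphics::lines(roc$threshold, roc$sp, type = "s", lty = 2)
    graphics::rect(x$final_zone[["low"]], 0, x$final_zone[["high"]], 1,
                   density = 15, angle = 45,
                   col = grDevices::grey(0.4), border = NA)
    graphics::abline(h = 1 - x$tolerance, lty = 3)
    graphics::legend("right", lty = c(1, 2), bty = "n",
                     legend = c("Sensitivity", "Specificity"))
  } else {
    roc <- x$roc
    o <- order(1 - roc$sp, roc$se)
    graphics::plot(1 - roc$sp[o], roc$se[o], type = "s",
                   xlab = "1 - Specificity", ylab = "Sensitivity",
                   main = sprintf("ROC: %s (AUC %.2f)", x$index_name,
                                  x$auc), ...)
    graphics::abline(0, 1, lty = 3)
    if (!is.null(x$binormal)) {
      fp <- seq(0.001, 0.999, length.out = 200)
      se <- stats::pnorm(x$binormal$a + x$binormal$b *
                           stats::qnorm(fp))
      graphics::lines(fp, se, lty = 2)
    }
  }
  invisible(x)
}
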