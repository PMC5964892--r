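#' Gray zone (inconclusive interval) of index values
#'
#' A closed interval of index values (%) within which a test result does
#' not reliably predict fluid responsiveness.
#'
#' @param low,high Interval bounds, `low <= high`.
#' @param method Optional label of the estimator that produced the zone.
#' @return An object of class `gray_zone`: numeric vector
#'   `c(low, high)`.
#' @export
gray_zone <- function(low, high, method = NULL) {
  stop_if_not_finite(c(low, high), "gray zone bounds")
  if (low > high) stop("gray zone requires low <= high", call. = FALSE)
  structure(c(low = low, high = high), class = "gray_zone",
            method = method)
}

#' @export
print.gray_zone <- function(x, ...) {
  cat(sprintf("gray zone [%.2f, %.2f] (width %.2f%s)\n",
              x[["low"]], x[["high"]], zone_width(x),
              if (!is.null(attr(x, "method")))
                paste0(", ", attr(x, "method")) else ""))
  invisible(x)
}

#' Width of a gray zone
#' @param zone A [gray_zone()].
#' @return `high - low` (>= 0).
#' @export
zone_width <- function(zone) {
  unname(zone[["high"]] - zone[["low"]])
}

check_two_classes <- function(scores, labels) {
  stop_if_not_finite(scores, "scores")
  labels <- as.logical(labels)
  if (length(labels) != length(scores))
    stop("scores and labels must have equal length", call. = FALSE)
  if (anyNA(labels)) stop("labels must be TRUE/FALSE", call. = FALSE)
  if (!any(labels) || all(labels))
    stop("both classes (responders and non-responders) must be present",
         call. = FALSE)
  labels
}

# Candidate decision thresholds: midpoints between consecutive distinct
# scores, flanked by sentinels half the minimal gap outside the observed
# range (so the grid always contains an all-positive and an all-negative
# rule, and every reported threshold stays within the observed range
# extended by half the minimal gap). A single distinct value uses gap 1.
threshold_grid <- function(scores) {
  v <- sort(unique(scores))
  g <- if (length(v) > 1L) min(diff(v)) else 1
  c(v[1L] - g / 2,
    if (length(v) > 1L) (v[-length(v)] + v[-1L]) / 2,
    v[length(v)] + g / 2)
}

#' Empirical ROC points
#'
#' Sensitivity and specificity of the rule "predict responder when the
#' index exceeds the threshold", evaluated at every candidate threshold
#' (midpoints between consecutive distinct scores plus one sentinel on
#' each side of the observed range). Higher index values are taken to
#' predict responders. Sensitivity is nonincreasing and specificity
#' nondecreasing as the threshold rises.
#'
#' @param scores Index values.
#' @param labels Logical responder flags (or coercible).
#' @return A `data.frame` with columns `threshold`, `se`, `sp`.
#' @export
empirical_roc <- function(scores, labels) {
  labels <- check_two_classes(scores, labels)
  th <- threshold_grid(scores)
  pos <- scores[labels]
  neg <- scores[!labels]
  data.frame(threshold = th,
             se = vapply(th, function(x) mean(pos > x), numeric(1)),
             sp = vapply(th, function(x) mean(neg <= x), numeric(1)))
}

#' Area under the ROC curve with Hanley-McNeil inference
#'
#' AUC by midrank pair counting (ties count one half), equal to the
#' normalized Mann-Whitney statistic. The standard error follows Hanley
#' and McNeil's formula, the 95% interval is `auc +/- z * se` clipped to
#' \[0, 1\], and the p-value tests AUC = 0.5 by a normal approximation.
#' With perfect separation the Hanley-McNeil SE collapses to zero and
#' the p-value is reported as 0 (or 1 when AUC is exactly 0.5).
#'
#' @inheritParams empirical_roc
#' @param conf Confidence level (default 0.95).
#' @return A list with `auc`, `se`, `ci` (length-2 vector), `p`,
#'   `n_pos`, `n_neg`.
#' @examples
#' roc_auc(c(3, 4, 5, 1, 2, 3), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
#' @export
roc_auc <- function(scores, labels, conf = 0.95) {
  labels <- check_two_classes(scores, labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  r <- rank(scores)                       # midranks handle ties
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- pmin(pmax(auc + c(-1, 1) * z * se, 0), 1)
  p <- if (se > 0) 2 * stats::pnorm(-abs(auc - 0.5) / se) else
    if (auc == 0.5) 1 else 0
  list(auc = auc, se = se, ci = ci, p = p, n_pos = n1, n_neg = n0)
}

#' Youden-optimal threshold
#'
#' The threshold maximizing the Youden index J = Se + Sp - 1, searched
#' over the midpoints between adjacent distinct scores (a decision cut
#' outside the observed values carries no information, so the sentinel
#' endpoints of the ROC grid are not candidates); ties are broken by the
#' smallest such threshold. When the scores hold a single distinct value
#' no cut can discriminate and that value is returned with J = 0.
#'
#' @inheritParams empirical_roc
#' @return A list with `threshold`, `j`, `se`, `sp`.
#' @export
youden_threshold <- function(scores, labels) {
  roc <- empirical_roc(scores, labels)
  if (nrow(roc) == 2L) {                  # single distinct score
    v <- unique(scores)
    return(list(threshold = v, j = 0,
                se = mean(scores[labels] > v),
                sp = mean(scores[!labels] <= v)))
  }
  roc <- roc[-c(1L, nrow(roc)), , drop = FALSE]
  j <- roc$se + roc$sp - 1
  i <- which(j == max(j))[1L]             # grid sorted: smallest wins
  list(threshold = roc$threshold[i], j = j[i],
       se = roc$se[i], sp = roc$sp[i])
}

#' Bootstrap gray zone of the optimal threshold
#'
#' Resamples patients with replacement, stratified by responder status
#' (class sizes preserved), recomputes the Youden-optimal threshold in
#' each replicate, and returns the percentile interval of the replicate
#' thresholds as the gray zone. Degenerate replicates (a class collapsing
#' onto one value) keep their defined threshold so that all replicates
#' contribute.
#'
#' @inheritParams empirical_roc
#' @param reps Number of bootstrap replicates (default 2000).
#' @param conf Coverage of the percentile interval (default 0.95).
#' @param seed Integer seed; fixed seed gives an identical zone.
#' @return A [gray_zone()] with attribute `thresholds` holding the
#'   replicate thresholds.
#' @export
bootstrap_threshold_zone <- function(scores, labels, reps = 2000,
                                     conf = 0.95, seed = NULL) {
  labels <- check_two_classes(scores, labels)
  if (sum(labels) < 2 || sum(!labels) < 2)
    stop("need at least 2 patients per class", call. = FALSE)
  pos <- scores[labels]
  neg <- scores[!labels]
  th <- with_seed(seed, {
    vapply(seq_len(reps), function(i) {
      s <- c(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
      l <- rep(c(TRUE, FALSE), c(length(pos), length(neg)))
      youden_threshold(s, l)$threshold
    }, numeric(1))
  })
  q <- stats::quantile(th, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                       names = FALSE)
  structure(gray_zone(q[1L], q[2L], method = "bootstrap"),
            thresholds = th)
}

#' Binormal ROC model
#'
#' Fits the classical binormal ROC model by class-wise moments: scores
#' are normal within each class, `N(mu0, sd0)` for non-responders and
#' `N(mu1, sd1)` for responders. The smooth curve is parameterized by
#' `a = (mu1 - mu0) / sd1` and `b = sd0 / sd1`, with
#' `AUC = pnorm(a / sqrt(1 + b^2))`.
#'
#' @inheritParams empirical_roc
#' @return An object of class `binormal_roc`: list with `a`, `b`,
#'   `mu0`, `sd0`, `mu1`, `sd1`, `auc`, and functions `se_fun(th)`,
#'   `sp_fun(th)` giving the smooth sensitivity/specificity at a
#'   threshold.
#' @export
binormal_fit <- function(scores, labels) {
  labels <- check_two_classes(scores, labels)
  if (sum(labels) < 3 || sum(!labels) < 3)
    stop("need at least 3 patients per class", call. = FALSE)
  mu0 <- mean(scores[!labels]); sd0 <- stats::sd(scores[!labels])
  mu1 <- mean(scores[labels]);  sd1 <- stats::sd(scores[labels])
  if (sd0 == 0 || sd1 == 0)
    stop("zero within-class variance; binormal model undefined",
         call. = FALSE)
  a <- (mu1 - mu0) / sd1
  b <- sd0 / sd1
  structure(list(a = a, b = b, mu0 = mu0, sd0 = sd0, mu1 = mu1,
                 sd1 = sd1,
                 auc = stats::pnorm(a / sqrt(1 + b^2)),
                 se_fun = function(th) 1 - stats::pnorm((th - mu1) / sd1),
                 sp_fun = function(th) stats::pnorm((th - mu0) / sd0)),
            class = "binormal_roc")
}

#' @export
print.binormal_roc <- function(x, ...) {
  cat(sprintf("binormal ROC: a = %.3f, b = %.3f, AUC = %.3f\n",
              x$a, x$b, x$auc))
  invisible(x)
}

# tolerance zone bounds on an (se, sp) curve sampled at thresholds `th`
.tol_bounds <- function(th, se, sp, tolerance) {
  ok_se <- th[se >= 1 - tolerance]
  ok_sp <- th[sp >= 1 - tolerance]
  low <- if (length(ok_se)) max(ok_se) else min(th)
  high <- if (length(ok_sp)) min(ok_sp) else max(th)
  c(low, high)
}

.zone_from_bounds <- function(b, clamp, method) {
  b <- pmin(pmax(b, clamp[1L]), clamp[2L])
  if (b[1L] > b[2L]) {                    # conclusive everywhere
    mid <- mean(b)
    gray_zone(mid, mid, method = method)
  } else gray_zone(b[1L], b[2L], method = method)
}

#' Diagnosis-tolerance (two-graph ROC) gray zone
#'
#' The inconclusive band of the two-graph ROC: with a diagnosis
#' tolerance of 10%, index values whose sensitivity and specificity both
#' fall below 90% are inconclusive. The lower bound is the largest
#' threshold keeping `Se >= 1 - tolerance`, the upper bound the smallest
#' threshold reaching `Sp >= 1 - tolerance`. The band is computed on
#' both the empirical (non-parametric) and the smooth binormal curve;
#' the method's zone covers the values inconclusive on either curve
#' (the interval hull of the two bands — it always contains the wider
#' band and shrinks monotonically as the tolerance grows). When a curve
#' is conclusive everywhere (lower bound above upper bound) its band
#' degenerates to a zero-width interval at their midpoint. Bounds are
#' clamped to the observed score range extended by half the minimal
#' score gap.
#'
#' @inheritParams empirical_roc
#' @param tolerance Diagnosis tolerance in (0, 0.5); default 0.10.
#' @param binormal `TRUE` to also evaluate the binormal curve (skipped
#'   automatically when the model is undefined, e.g. zero within-class
#'   variance).
#' @return A [gray_zone()]; attributes `empirical` and `binormal` hold
#'   the per-curve bands.
#' @export
tolerance_zone <- function(scores, labels, tolerance = 0.10,
                           binormal = TRUE) {
  if (tolerance <= 0 || tolerance >= 0.5)
    stop("tolerance must be in (0, 0.5)", call. = FALSE)
  labels <- check_two_classes(scores, labels)
  roc <- empirical_roc(scores, labels)
  clamp <- range(roc$threshold)
  z_emp <- .zone_from_bounds(
    .tol_bounds(roc$threshold, roc$se, roc$sp, tolerance),
    clamp, "tolerance (empirical)")
  z_bin <- NULL
  if (binormal && sum(labels) >= 3 && sum(!labels) >= 3 &&
      stats::sd(scores[labels]) > 0 && stats::sd(scores[!labels]) > 0) {
    fit <- binormal_fit(scores, labels)
    b <- c(fit$mu1 + fit$sd1 * stats::qnorm(tolerance),
           fit$mu0 + fit$sd0 * stats::qnorm(1 - tolerance))
    z_bin <- .zone_from_bounds(b, clamp, "tolerance (binormal)")
  }
  out <- if (is.null(z_bin)) {
    gray_zone(z_emp[["low"]], z_emp[["high"]], method = "tolerance")
  } else {
    gray_zone(min(z_emp[["low"]], z_bin[["low"]]),
              max(z_emp[["high"]], z_bin[["high"]]),
              method = "tolerance")
  }
  attr(out, "empirical") <- z_emp
  attr(out, "binormal") <- z_bin
  out
}

#' Final gray zone: the widest-zone rule
#'
#' Of the two gray-zone candidates — the bootstrap confidence interval
#' of the optimal threshold and the diagnosis-tolerance band — the wider
#' one is retained as the final gray zone; ties keep the first.
#'
#' @param zone_a,zone_b Two [gray_zone()] objects.
#' @return The wider of the two zones.
#' @export
final_gray_zone <- function(zone_a, zone_b) {
  stopifnot(inherits(zone_a, "gray_zone"), inherits(zone_b, "gray_zone"))
  if (zone_width(zone_a) >= zone_width(zone_b)) zone_a else zone_b
}
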