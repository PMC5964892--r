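#' Compare two AUCs by a z-test
#'
#' Tests equality of two areas under the ROC curve with the z-statistic
#' `(auc1 - auc2) / sqrt(se1^2 + se2^2)` on Hanley-McNeil standard
#' errors and a two-sided normal p-value. The statistic treats the two
#' curves as independent; for curves estimated on the same patients this
#' ignores their positive correlation and is therefore conservative.
#'
#' @param auc1,auc2 Areas under the curve, in \[0, 1\].
#' @param se1,se2 Their standard errors (> 0).
#' @return A list with `z` and `p`.
#' @examples
#' fisher_z_compare(0.92, 0.05, 0.68, 0.10)   # z = 2.15, p = 0.032
#' @export
fisher_z_compare <- function(auc1, se1, auc2, se2) {
  stop_if_not_finite(c(auc1, se1, auc2, se2), "fisher_z_compare inputs")
  if (auc1 < 0 || auc1 > 1 || auc2 < 0 || auc2 > 1)
    stop("AUCs must lie in [0, 1]", call. = FALSE)
  if (se1 <= 0 || se2 <= 0) stop("standard errors must be > 0",
                                 call. = FALSE)
  z <- (auc1 - auc2) / sqrt(se1^2 + se2^2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Pairwise AUC comparison matrix
#'
#' Compares every unordered pair of per-index ROC fits with
#' [fisher_z_compare()]. P-values are reported raw, without multiplicity
#' adjustment. A perfectly separating index has a degenerate
#' Hanley-McNeil standard error of zero; pairs whose combined standard
#' error vanishes are reported as p = 1 when the AUCs agree and p = 0
#' otherwise.
#'
#' @param fits A named list of [roc_grayzone()] fits (>= 2), or any list
#'   of lists each carrying `auc` and `auc_se` (or `se`) elements.
#' @return An object of class `auc_comparison`: a symmetric matrix of
#'   p-values with `NA` on the diagonal; printed as the conventional
#'   lower-triangular table.
#' @export
pairwise_auc_matrix <- function(fits) {
  if (length(fits) < 2) stop("need at least two indices", call. = FALSE)
  nm <- names(fits) %||% paste0("index", seq_along(fits))
  if (is.null(names(fits)) && all(vapply(fits, function(f)
    !is.null(f$index_name), logical(1))))
    nm <- vapply(fits, function(f) f$index_name, character(1))
  auc <- vapply(fits, function(f) f$auc, numeric(1))
  se <- vapply(fits, function(f) f$auc_se %||% f$se, numeric(1))
  k <- length(fits)
  p <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    pij <- if (se[i]^2 + se[j]^2 == 0) {
      if (auc[i] == auc[j]) 1 else 0
    } else {
      s <- pmax(se, .Machine$double.xmin)
      fisher_z_compare(auc[i], s[i], auc[j], s[j])$p
    }
    p[i, j] <- p[j, i] <- pij
  }
  structure(p, class = c("auc_comparison", class(p)), auc = auc)
}

#' @export
print.auc_comparison <- function(x, digits = 3, ...) {
  cat("Pairwise AUC comparison (two-sided p-values)\n")
  m <- unclass(x)
  m[upper.tri(m, diag = TRUE)] <- NA
  m <- m[-1, -ncol(m), drop = FALSE]
  print(round(m, digits), na.print = "")
  invisible(x)
}

#' Required sample size for the fluid-challenge design
#'
#' Normal-approximation sample size for detecting a relative stroke
#' volume change of `effect_pct` against a standard deviation of
#' `sd_pct` at two-sided level `alpha` and the given power:
#' `n = ceiling(2 * (z_{1-alpha/2} + z_{power})^2 * (sd/effect)^2)`
#' evaluable patients, plus the planned dropouts. At the conventional
#' design (alpha 0.05, power 0.8, SD 20%, effect 15%, 2 dropouts) this
#' gives 28 evaluable and 30 total patients. A paired one-sample variant
#' (without the factor 2, treating `sd_pct` as the SD of the paired
#' differences) is available behind `paired = TRUE`.
#'
#' @param alpha Two-sided type-I error (default 0.05).
#' @param power Target power (default 0.8).
#' @param sd_pct Standard deviation of the relative stroke volume
#'   change, percent (default 20).
#' @param effect_pct Clinically relevant change, percent (default 15).
#' @param dropouts Additional patients budgeted for dropout (default 2).
#' @param paired Use the paired one-sample formula instead of the
#'   two-group one.
#' @return A list with `n_evaluable` and `n_total`.
#' @examples
#' required_sample_size()   # 28 evaluable, 30 total
#' @export
required_sample_size <- function(alpha = 0.05, power = 0.8, sd_pct = 20,
                                 effect_pct = 15, dropouts = 2,
                                 paired = FALSE) {
  stop_if_not_finite(c(alpha, power, sd_pct, effect_pct, dropouts),
                     "design parameters")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("alpha and power must lie in (0, 1)", call. = FALSE)
  if (sd_pct <= 0 || effect_pct <= 0)
    stop("sd_pct and effect_pct must be > 0", call. = FALSE)
  if (dropouts < 0) stop("dropouts must be >= 0", call. = FALSE)
  zsum <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  mult <- if (paired) 1 else 2
  n <- ceiling(mult * zsum^2 * (sd_pct / effect_pct)^2)
  list(n_evaluable = as.integer(n),
       n_total = as.integer(n + dropouts))
}

#' Closed-form power of the design's normal test
#'
#' Two-sided power of the two-group z-test at effect `effect_pct`,
#' standard deviation `sd_pct` and `n` evaluable patients per group:
#' `pnorm(lambda - z) + pnorm(-lambda - z)` with
#' `lambda = sqrt(n / 2) * effect / sd` and `z = z_{1-alpha/2}`.
#'
#' @inheritParams required_sample_size
#' @param n Evaluable sample size.
#' @return Power in \[0, 1\].
#' @export
closed_form_power <- function(n, alpha = 0.05, sd_pct = 20,
                              effect_pct = 15) {
  lam <- sqrt(n / 2) * effect_pct / sd_pct
  z <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(lam - z) + stats::pnorm(-lam - z)
}

#' Monte-Carlo power of the design's normal test
#'
#' Simulates the two-group comparison under the design assumptions —
#' normally distributed relative stroke volume changes with known
#' standard deviation — and returns the rejection rate of the two-sided
#' z-test at level `alpha`. With `effect_pct = 0` the estimate recovers
#' the test's size.
#'
#' @inheritParams required_sample_size
#' @param n Evaluable sample size (per group).
#' @param reps Monte-Carlo replicates (>= 1000).
#' @param seed Integer seed; fixed seed gives a deterministic estimate.
#' @return Estimated power in \[0, 1\].
#' @examples
#' simulated_power(28, reps = 10000, seed = 1)   # about 0.80
#' @export
simulated_power <- function(n, alpha = 0.05, sd_pct = 20,
                            effect_pct = 15, reps = 50000,
                            seed = NULL) {
  if (reps < 1000) stop("reps must be >= 1000", call. = FALSE)
  if (effect_pct < 0) stop("effect_pct must be >= 0", call. = FALSE)
  with_seed(seed, {
    se_diff <- sd_pct * sqrt(2 / n)
    dhat <- stats::rnorm(reps, mean = effect_pct, sd = se_diff)
    mean(abs(dhat / se_diff) > stats::qnorm(1 - alpha / 2))
  })
}
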