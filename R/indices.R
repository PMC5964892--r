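#' Window policy for dynamic index computation
#'
#' The monitoring systems differ in the time window over which the
#' extreme values entering a variation index are taken. Calibrated
#' pulse-contour analysis averages four extreme readings over a 30 s
#' window, while the uncalibrated pulse-contour systems use a single
#' 20 s window.
#'
#' @param window_length Window length in seconds (> 0).
#' @param extremes_mode Either `"single_extreme"` — one (max - min) / mean
#'   ratio over the whole window — or `"four_cycle_average"` — the window
#'   is split into four equal sub-windows whose ratios are averaged.
#' @return An object of class `window_policy`.
#' @seealso [device_policy()] for the named device presets.
#' @export
window_policy <- function(window_length,
                          extremes_mode = c("single_extreme",
                                            "four_cycle_average")) {
  extremes_mode <- match.arg(extremes_mode)
  stop_if_not_finite(window_length, "window_length")
  if (window_length <= 0) stop("window_length must be > 0", call. = FALSE)
  structure(list(window_length = window_length,
                 extremes_mode = extremes_mode),
            class = "window_policy")
}

#' Device presets for index windows
#'
#' @param device `"picco"` (30 s, four-sub-window average), `"lidco"` or
#'   `"flotrac"` (20 s, single extreme pair).
#' @return A [window_policy()].
#' @export
device_policy <- function(device = c("picco", "lidco", "flotrac")) {
  device <- match.arg(device)
  switch(device,
         picco   = window_policy(30, "four_cycle_average"),
         lidco   = window_policy(20, "single_extreme"),
         flotrac = window_policy(20, "single_extreme"))
}

#' Variation index of a per-beat quantity
#'
#' The respiratory variation of a beat-level quantity, in percent:
#' `100 * (max - min) / mean` over the window. In
#' `"four_cycle_average"` mode the window is partitioned into four equal
#' sub-windows (by time when beat times are supplied, else by beat
#' count), the ratio is computed in each, and the four ratios are
#' averaged.
#'
#' @param values Per-beat quantity (>= 2 values, positive mean).
#' @param mode `"single_extreme"` or `"four_cycle_average"`.
#' @param t Optional beat times, used to form time-based sub-windows.
#' @return Variation in percent (>= 0).
#' @examples
#' variation_index(c(55, 60, 65, 60))   # 16.67
#' @export
variation_index <- function(values,
                            mode = c("single_extreme",
                                     "four_cycle_average"),
                            t = NULL) {
  mode <- match.arg(mode)
  stop_if_not_finite(values, "values")
  if (length(values) < 2L) stop("need at least 2 beats", call. = FALSE)
  one <- function(v) {
    m <- mean(v)
    if (m <= 0) stop("window mean must be > 0", call. = FALSE)
    100 * (max(v) - min(v)) / m
  }
  if (mode == "single_extreme") return(one(values))
  if (is.null(t)) {
    grp <- ceiling(seq_along(values) / (length(values) / 4))
  } else {
    if (length(t) != length(values))
      stop("t and values must have equal length", call. = FALSE)
    edges <- seq(min(t), max(t), length.out = 5)
    grp <- pmin(findInterval(t, edges, rightmost.closed = TRUE), 4L)
  }
  vals <- vapply(1:4, function(g) {
    v <- values[grp == g]
    if (length(v) < 2L)
      stop("sub-window with fewer than 2 beats; window too short ",
           "for four_cycle_average", call. = FALSE)
    one(v)
  }, numeric(1))
  mean(vals)
}

# beats in the trailing window of `length` seconds (closed on both ends)
trailing_window <- function(series, length) {
  span <- max(series$t) - min(series$t)
  if (span < length)
    stop(sprintf("series spans %.1f s, shorter than the %.1f s window",
                 span, length), call. = FALSE)
  series[series$t >= max(series$t) - length, , drop = FALSE]
}

index_over_window <- function(series, channel, policy) {
  stopifnot(inherits(policy, "window_policy"))
  if (is.null(series[[channel]]))
    stop(sprintf("series has no '%s' channel", channel), call. = FALSE)
  win <- trailing_window(series, policy$window_length)
  variation_index(win[[channel]], policy$extremes_mode, t = win$t)
}

#' Stroke volume variation (SVV)
#'
#' `100 * (SVmax - SVmin) / SVmean` over the trailing device window of
#' the series, with the policy's extremes mode.
#'
#' @param series A [beat_series()].
#' @param policy A [window_policy()]; defaults to the calibrated
#'   pulse-contour preset (30 s, four-sub-window average).
#' @return SVV in percent.
#' @export
svv <- function(series, policy = device_policy("picco")) {
  index_over_window(series, "sv", policy)
}

#' Pulse pressure variation (PPV)
#'
#' `100 * (PPmax - PPmin) / PPmean` over the trailing device window.
#'
#' @inheritParams svv
#' @return PPV in percent.
#' @export
ppv <- function(series, policy = device_policy("picco")) {
  index_over_window(series, "pp", policy)
}

#' Pleth variability index (PVI)
#'
#' Respiratory variation of the pulse-oximeter pulse index:
#' `100 * (PImax - PImin) / PImax` over the window (note the maximum,
#' not the mean, in the denominator, following the manufacturer's
#' definition). Scale-invariant in the pulse index.
#'
#' @param series A [beat_series()] with a `pi` channel.
#' @param window_length Trailing window in seconds, or `NULL` to use the
#'   whole series. Must cover at least one respiratory cycle.
#' @return PVI in percent.
#' @export
pvi <- function(series, window_length = NULL) {
  if (is.null(series$pi))
    stop("series has no pulse-index ('pi') channel", call. = FALSE)
  win <- if (is.null(window_length)) series else
    trailing_window(series, window_length)
  v <- win$pi
  if (length(v) < 2L) stop("need at least 2 beats", call. = FALSE)
  if (any(v <= 0)) stop("pulse index must be positive", call. = FALSE)
  100 * (max(v) - min(v)) / max(v)
}

#' Per-window index values over a beat series
#'
#' Slides the device window over the series and reports SVV, PPV and
#' (when the pulse-index channel is present) PVI at each window end, in
#' the long format used by the reporting layer.
#'
#' @param series A [beat_series()].
#' @param policy A [window_policy()].
#' @param step Minimum spacing of successive window ends in seconds;
#'   window ends fall on beat times.
#' @return A `data.frame` with columns `window_end_s`, `index_name`,
#'   `value_pct`.
#' @export
windowed_indices <- function(series, policy = device_policy("picco"),
                             step = 5) {
  stopifnot(inherits(policy, "window_policy"))
  t0 <- min(series$t)
  cand <- series$t[series$t >= t0 + policy$window_length]
  if (!length(cand))
    stop("series shorter than one window", call. = FALSE)
  ends <- cand[1L]
  for (e in cand[-1L])
    if (e >= ends[length(ends)] + step) ends <- c(ends, e)
  rows <- lapply(ends, function(e) {
    sub <- series[series$t <= e, , drop = FALSE]
    out <- data.frame(window_end_s = e,
                      index_name = c("svv", "ppv"),
                      value_pct = c(svv(sub, policy), ppv(sub, policy)))
    if (!is.null(series$pi))
      out <- rbind(out, data.frame(window_end_s = e, index_name = "pvi",
                                   value_pct = pvi(sub,
                                                   policy$window_length)))
    out
  })
  do.call(rbind, rows)
}
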