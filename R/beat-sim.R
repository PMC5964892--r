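#' Configuration for a simulated beat-by-beat series
#'
#' Parameters of the respiratory-modulation beat model. Under controlled
#' positive-pressure ventilation the cyclic change in preload modulates
#' stroke volume, pulse pressure and the pulse-oximeter pulse index at
#' the respiratory frequency; the simulator represents each channel as a
#' sinusoid about its mean plus white noise, sampled once per heart beat.
#'
#' `modulation_fraction` is half the peak-to-trough relative amplitude:
#' a noiseless channel oscillates between `mean * (1 - m)` and
#' `mean * (1 + m)`, so the ideal variation index (max - min) / mean
#' equals `200 * m` percent.
#'
#' @param heart_rate Heart rate in beats per minute (default 86).
#' @param resp_rate Ventilator respiratory rate in breaths per minute
#'   (default 12); must be below `heart_rate`.
#' @param sv_mean Mean stroke volume, mL.
#' @param pp_mean Mean pulse pressure, mmHg.
#' @param pi_mean Mean pulse-oximeter pulse index, %.
#' @param modulation_fraction Relative modulation amplitude m >= 0.
#' @param noise_sd Additive white-noise SD, as a fraction of each
#'   channel's mean (0 gives a clean sinusoid).
#' @param duration Series duration in seconds; must cover at least one
#'   full respiratory cycle.
#' @return An object of class `beat_config`.
#' @seealso [simulate_beat_series()]
#' @export
beat_config <- function(heart_rate = 86, resp_rate = 12,
                        sv_mean = 59, pp_mean = 50, pi_mean = 4,
                        modulation_fraction = 0.08, noise_sd = 0,
                        duration = 60) {
  cfg <- list(heart_rate = heart_rate, resp_rate = resp_rate,
              sv_mean = sv_mean, pp_mean = pp_mean, pi_mean = pi_mean,
              modulation_fraction = modulation_fraction,
              noise_sd = noise_sd, duration = duration)
  stop_if_not_finite(unlist(cfg), "beat_config values")
  if (resp_rate <= 0 || heart_rate <= resp_rate)
    stop("need heart_rate > resp_rate > 0", call. = FALSE)
  if (modulation_fraction < 0) stop("modulation_fraction must be >= 0",
                                    call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (duration < 60 / resp_rate)
    stop("duration must cover at least one respiratory cycle (",
         round(60 / resp_rate, 2), " s)", call. = FALSE)
  if (sv_mean <= 0 || pp_mean <= 0 || pi_mean <= 0)
    stop("channel means must be > 0", call. = FALSE)
  structure(cfg, class = "beat_config")
}

#' Construct a beat-by-beat series
#'
#' A beat series holds one sample per heart beat of stroke volume, pulse
#' pressure and (optionally) the pulse-oximeter pulse index, at strictly
#' increasing beat times.
#'
#' @param t Beat times in seconds, strictly increasing.
#' @param sv Stroke volume per beat, mL (> 0).
#' @param pp Pulse pressure per beat, mmHg (> 0).
#' @param pi Optional pulse index per beat, % (> 0).
#' @return A `data.frame` of class `beat_series` with columns `t`, `sv`,
#'   `pp` and, if supplied, `pi`.
#' @export
beat_series <- function(t, sv, pp, pi = NULL) {
  lens <- c(length(t), length(sv), length(pp),
            if (!is.null(pi)) length(pi))
  if (length(unique(lens)) != 1L)
    stop("t, sv, pp (and pi) must have equal length", call. = FALSE)
  stop_if_not_finite(t, "t"); stop_if_not_finite(sv, "sv")
  stop_if_not_finite(pp, "pp")
  if (any(diff(t) <= 0)) stop("beat times must be strictly increasing",
                              call. = FALSE)
  if (any(sv <= 0) || any(pp <= 0))
    stop("sv and pp must be positive", call. = FALSE)
  out <- data.frame(t = t, sv = sv, pp = pp)
  if (!is.null(pi)) {
    stop_if_not_finite(pi, "pi")
    if (any(pi <= 0)) stop("pi must be positive", call. = FALSE)
    out$pi <- pi
  }
  class(out) <- c("beat_series", "data.frame")
  out
}

#' Simulate a respiratory-modulated beat series
#'
#' Generates beats at a fixed interval of `60 / heart_rate` seconds
#' starting at time 0. Each channel follows
#' `mean * (1 + m * sin(2 * pi * f_resp * t))` plus independent Gaussian
#' noise with SD `noise_sd * mean`, where `f_resp` is the respiratory
#' frequency in Hz and `m` the modulation fraction.
#'
#' @param config A [beat_config()] object.
#' @param seed Integer seed; identical seed and config reproduce the
#'   series exactly. `NULL` uses the current RNG stream.
#' @return A [beat_series()] with `t`, `sv`, `pp`, `pi`.
#' @examples
#' bs <- simulate_beat_series(beat_config(modulation_fraction = 0.05))
#' svv(bs, device_policy("picco"))   # about 10%
#' @export
simulate_beat_series <- function(config = beat_config(), seed = NULL) {
  stopifnot(inherits(config, "beat_config"))
  with_seed(seed, {
    t <- seq(0, config$duration, by = 60 / config$heart_rate)
    mod <- 1 + config$modulation_fraction *
      sin(2 * pi * config$resp_rate / 60 * t)
    n <- length(t)
    ch <- function(mean) {
      pmax(mean * mod + stats::rnorm(n, sd = config$noise_sd * mean),
           .Machine$double.eps)
    }
    beat_series(t, sv = ch(config$sv_mean), pp = ch(config$pp_mean),
                pi = ch(config$pi_mean))
  })
}
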