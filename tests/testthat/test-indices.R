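test_that("variation index follows the (max - min) / mean formula", {
  expect_equal(variation_index(c(55, 60, 65, 60)), 100 * 10 / 60)
  expect_equal(variation_index(rep(42, 10)), 0)
  expect_error(variation_index(60), "at least 2")
  expect_error(variation_index(c(-1, 1)), "mean")
})

test_that("variation index is scale invariant and matches a scan oracle", {
  set.seed(31)
  for (i in 1:25) {
    v <- stats::runif(sample(5:40, 1), min = 30, max = 90)
    vi <- variation_index(v)
    expect_gte(vi, 0)
    expect_equal(vi, 100 * (max(v) - min(v)) / mean(v))  # brute scan
    expect_equal(variation_index(3.7 * v), vi)           # positive scaling
  }
})

test_that("four-sub-window averaging smooths but agrees on stationary input", {
  bs <- simulate_beat_series(beat_config(modulation_fraction = 0.08,
                                         noise_sd = 0))
  s_single <- svv(bs, window_policy(30, "single_extreme"))
  s_four <- svv(bs, window_policy(30, "four_cycle_average"))
  # both estimate 2 m = 16% on a stationary noiseless sinusoid
  expect_equal(s_single, 16, tolerance = 0.02)
  expect_equal(s_four, 16, tolerance = 0.05)
  # smoothing: with one spike, the averaged mode is less affected
  sv <- rep(60, 40); sv[20] <- 90
  t <- seq_len(40)
  spike <- beat_series(t, sv, sv)
  pol1 <- window_policy(39, "single_extreme")
  pol4 <- window_policy(39, "four_cycle_average")
  expect_lt(svv(spike, pol4), svv(spike, pol1))
})

test_that("device presets carry the device time windows", {
  expect_equal(device_policy("picco")$window_length, 30)
  expect_equal(device_policy("picco")$extremes_mode, "four_cycle_average")
  expect_equal(device_policy("lidco")$window_length, 20)
  expect_equal(device_policy("flotrac")$window_length, 20)
  expect_equal(device_policy("lidco")$extremes_mode, "single_extreme")
})

test_that("windows shorter than the series are rejected", {
  bs <- simulate_beat_series(beat_config(duration = 15))
  expect_error(svv(bs, device_policy("picco")), "shorter")
  expect_silent(svv(bs, window_policy(10, "single_extreme")))
})

test_that("pvi uses the max-normalized pulse index formula", {
  t <- 1:10
  s <- beat_series(t, rep(60, 10), rep(50, 10),
                   pi = c(rep(5, 5), rep(4, 5)))
  expect_equal(pvi(s), 100 * (5 - 4) / 5)
  s2 <- beat_series(t, rep(60, 10), rep(50, 10),
                    pi = 3 * c(rep(5, 5), rep(4, 5)))
  expect_equal(pvi(s2), pvi(s))   # scale invariance
  const <- beat_series(t, rep(60, 10), rep(50, 10), pi = rep(4, 10))
  expect_equal(pvi(const), 0)
  no_pi <- beat_series(t, rep(60, 10), rep(50, 10))
  expect_error(pvi(no_pi), "channel")
})

test_that("windowed indices report per-window values in long form", {
  bs <- simulate_beat_series(beat_config(modulation_fraction = 0.05,
                                         noise_sd = 0, duration = 45))
  out <- windowed_indices(bs, device_policy("lidco"), step = 5)
  expect_named(out, c("window_end_s", "index_name", "value_pct"))
  expect_setequal(unique(out$index_name), c("svv", "ppv", "pvi"))
  svv_rows <- out[out$index_name == "svv", ]
  expect_true(all(abs(svv_rows$value_pct - 10) < 0.5))
})
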