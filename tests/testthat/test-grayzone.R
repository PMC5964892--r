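test_that("gray zone objects enforce ordering and report width", {
  z <- gray_zone(13.5, 18.9)
  expect_equal(zone_width(z), 5.4)
  expect_error(gray_zone(5, 3), "low <= high")
  expect_equal(zone_width(gray_zone(4, 4)), 0)
})

test_that("the widest-zone rule keeps the wider candidate, ties keep A", {
  a <- gray_zone(13.5, 18.9)
  b <- gray_zone(15, 17)
  expect_equal(final_gray_zone(a, b), a)
  expect_equal(final_gray_zone(gray_zone(0, 0), gray_zone(10, 15)),
               gray_zone(10, 15))
  tie_a <- gray_zone(1, 3)
  expect_identical(final_gray_zone(tie_a, gray_zone(11, 13)), tie_a)
})

test_that("bootstrap zone is deterministic and collapses when unambiguous", {
  f <- separable_fixture()
  z1 <- bootstrap_threshold_zone(f$scores, f$labels, reps = 400, seed = 5)
  z2 <- bootstrap_threshold_zone(f$scores, f$labels, reps = 400, seed = 5)
  expect_identical(z1, z2)
  # constant scores within each class: every resample gives the same cut
  z0 <- bootstrap_threshold_zone(c(20, 20, 20, 10, 10, 10),
                                 rep(c(TRUE, FALSE), each = 3),
                                 reps = 200, seed = 1)
  expect_equal(zone_width(z0), 0)
  expect_equal(unname(z0[["low"]]), 15)
})

test_that("bootstrap zone brackets the full-sample threshold when separated", {
  set.seed(43)
  hits <- replicate(60, {
    scores <- c(stats::rnorm(12, 20, 2), stats::rnorm(12, 10, 2))
    labels <- rep(c(TRUE, FALSE), each = 12)
    th <- youden_threshold(scores, labels)$threshold
    z <- bootstrap_threshold_zone(scores, labels, reps = 300,
                                  seed = sample.int(1e6, 1))
    th >= z[["low"]] && th <= z[["high"]]
  })
  expect_gte(mean(hits), 0.95)
})

test_that("zones stay within the extended observed score range", {
  set.seed(47)
  for (i in 1:20) {
    inst <- random_instance()
    v <- sort(unique(inst$scores))
    g <- if (length(v) > 1) min(diff(v)) else 1
    lo <- min(v) - g / 2
    hi <- max(v) + g / 2
    zb <- bootstrap_threshold_zone(inst$scores, inst$labels, reps = 100,
                                   seed = i)
    zt <- tolerance_zone(inst$scores, inst$labels)
    for (z in list(zb, zt)) {
      expect_gte(z[["low"]], lo)
      expect_lte(z[["high"]], hi)
      expect_lte(z[["low"]], z[["high"]])
    }
  }
})

test_that("tolerance zone collapses under perfect separation", {
  f <- separable_fixture()
  z <- tolerance_zone(f$scores, f$labels)
  expect_equal(zone_width(attr(z, "empirical")), 0)
  expect_equal(unname(attr(z, "empirical")[["low"]]), 15)
})

test_that("tolerance zone widens with stricter tolerance and overlap", {
  set.seed(53)
  scores <- c(stats::rnorm(20, 16, 5), stats::rnorm(20, 13, 5))
  labels <- rep(c(TRUE, FALSE), each = 20)
  z10 <- tolerance_zone(scores, labels, tolerance = 0.10)
  z05 <- tolerance_zone(scores, labels, tolerance = 0.05)
  expect_lte(z05[["low"]], z10[["low"]])     # 5% zone contains 10% zone
  expect_gte(z05[["high"]], z10[["high"]])
  # heavy overlap: the zone spans most of the observed range
  expect_gt(zone_width(z10),
            0.5 * diff(range(scores)) * 0.5)
  expect_error(tolerance_zone(scores, labels, tolerance = 0.7),
               "tolerance")
})

test_that("the fitted analysis object is coherent", {
  set.seed(59)
  f <- binormal_fixture(n1 = 15, n0 = 15, a = 2)
  fit <- roc_grayzone(f$scores, f$labels, index_name = "svv",
                      boot_reps = 300, seed = 7)
  expect_s3_class(fit, "roc_grayzone")
  expect_lte(fit$auc_ci[1], fit$auc)
  expect_gte(fit$auc_ci[2], fit$auc)
  expect_equal(zone_width(fit$final_zone),
               max(zone_width(fit$zone_boot), zone_width(fit$zone_tol)))
  expect_equal(unname(coef(fit)["auc"]), fit$auc)
  expect_output(print(fit), "AUC")
  expect_output(print(summary(fit)), "binormal")
  # plotting works headlessly
  tf <- tempfile(fileext = ".pdf")
  grDevices::pdf(tf)
  plot(fit, type = "tgroc")
  plot(fit, type = "roc")
  grDevices::dev.off()
  expect_true(file.exists(tf))
  unlink(tf)
})
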