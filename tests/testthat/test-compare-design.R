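test_that("AUC z-comparison matches the closed form to high precision", {
  r <- fisher_z_compare(0.92, 0.05, 0.68, 0.10)
  z_ref <- (0.92 - 0.68) / sqrt(0.05^2 + 0.10^2)
  expect_equal(r$z, z_ref, tolerance = 1e-10)
  expect_equal(r$p, 2 * (1 - stats::pnorm(abs(z_ref))), tolerance = 1e-10)
  expect_equal(r$z, 2.1466, tolerance = 1e-4)
  expect_equal(r$p, 0.0318, tolerance = 1e-3)
})

test_that("AUC z-comparison is antisymmetric and null at equality", {
  eq <- fisher_z_compare(0.8, 0.06, 0.8, 0.04)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)
  a <- fisher_z_compare(0.9, 0.05, 0.7, 0.08)
  b <- fisher_z_compare(0.7, 0.08, 0.9, 0.05)
  expect_equal(a$z, -b$z)
  expect_equal(a$p, b$p)
  expect_error(fisher_z_compare(0.9, 0, 0.7, 0.08), "standard errors")
  expect_error(fisher_z_compare(1.2, 0.1, 0.7, 0.08), "0, 1")
})

test_that("pairwise matrix covers all pairs and is permutation equivariant", {
  fits <- lapply(c(0.92, 0.88, 0.78, 0.68), function(a)
    list(auc = a, auc_se = 0.05 + a / 20))
  names(fits) <- c("w", "x", "y", "z")
  m <- pairwise_auc_matrix(fits)
  expect_equal(sum(!is.na(m[lower.tri(m)])), 6)
  expect_equal(unclass(m), t(unclass(m)))
  perm <- c(3, 1, 4, 2)
  m2 <- pairwise_auc_matrix(fits[perm])
  strip <- function(x) {
    x <- unclass(x)
    attr(x, "auc") <- NULL
    x
  }
  expect_equal(strip(m2), strip(m)[perm, perm])
  expect_equal(unname(m["w", "x"]),
               fisher_z_compare(0.92, fits$w$auc_se,
                                0.88, fits$x$auc_se)$p)
  same <- pairwise_auc_matrix(list(a = fits$w, b = fits$w))
  expect_equal(unname(same["a", "b"]), 1)
  expect_error(pairwise_auc_matrix(fits[1]), "two")
})

test_that("sample-size design reproduces the standard closed forms", {
  d <- required_sample_size(alpha = 0.05, power = 0.8, sd_pct = 20,
                            effect_pct = 15, dropouts = 2)
  expect_identical(d$n_evaluable, 28L)
  expect_identical(d$n_total, 30L)
  # effect equal to the SD: 2 * (1.96 + 0.8416)^2 = 15.7 -> 16
  d2 <- required_sample_size(effect_pct = 20)
  expect_identical(d2$n_evaluable, 16L)
  expect_identical(d2$n_total, 18L)
  # power 1/2 drops the z_beta term entirely
  d3 <- required_sample_size(power = 0.5)
  expect_identical(d3$n_evaluable,
                   as.integer(ceiling(2 * stats::qnorm(0.975)^2 *
                                        (20 / 15)^2)))
  expect_error(required_sample_size(effect_pct = 0), "> 0")
})

test_that("required sample size is monotone in its design inputs", {
  base <- required_sample_size()$n_evaluable
  expect_lte(required_sample_size(effect_pct = 18)$n_evaluable, base)
  expect_gte(required_sample_size(sd_pct = 25)$n_evaluable, base)
  expect_gte(required_sample_size(power = 0.9)$n_evaluable, base)
  expect_lte(required_sample_size(paired = TRUE)$n_evaluable, base)
})

test_that("simulated power matches theory, size, and monotonicity", {
  p28 <- simulated_power(28, reps = 20000, seed = 3)
  expect_equal(p28, closed_form_power(28), tolerance = 0.01)
  # null effect: rejection rate is the test size
  size <- simulated_power(28, effect_pct = 0, reps = 20000, seed = 4)
  expect_equal(size, 0.05, tolerance = 0.007)
  # more patients, more power
  grid <- sapply(c(10, 20, 40), function(n)
    simulated_power(n, reps = 20000, seed = 5))
  expect_true(all(diff(grid) > 0))
  expect_identical(simulated_power(28, reps = 2000, seed = 6),
                   simulated_power(28, reps = 2000, seed = 6))
  expect_error(simulated_power(28, reps = 100), "reps")
})
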