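test_that("AUC equals exhaustive pair counting on the worked example", {
  scores <- c(3, 4, 5, 1, 2, 3)
  labels <- rep(c(TRUE, FALSE), each = 3)
  r <- roc_auc(scores, labels)
  expect_equal(r$auc, 8.5 / 9)
  expect_equal(r$auc, brute_auc(scores, labels))
})

test_that("AUC limits: all ties give 1/2, separation gives 1", {
  labels <- rep(c(TRUE, FALSE), each = 4)
  tied <- roc_auc(rep(7, 8), labels)
  expect_equal(tied$auc, 0.5)
  expect_equal(tied$p, 1)
  sep <- roc_auc(c(5:8, 1:4), labels)
  expect_equal(sep$auc, 1)
  expect_equal(sep$p, 0)
  expect_true(all(sep$ci >= 0 & sep$ci <= 1))
})

test_that("AUC is complementary under score reversal", {
  set.seed(13)
  for (i in 1:50) {
    inst <- random_instance()
    a <- roc_auc(inst$scores, inst$labels)$auc
    b <- roc_auc(-inst$scores, inst$labels)$auc
    expect_identical(a + b, 1)
    expect_identical(a, brute_auc(inst$scores, inst$labels))
  }
})

test_that("AUC confidence interval brackets the point estimate", {
  set.seed(17)
  for (i in 1:20) {
    inst <- random_instance()
    r <- roc_auc(inst$scores, inst$labels)
    expect_lte(r$ci[1], r$auc)
    expect_gte(r$ci[2], r$auc)
  }
})

test_that("AUC and CI agree with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(19)
  for (i in 1:10) {
    f <- binormal_fixture()
    r <- roc_auc(f$scores, f$labels)
    ref <- pROC::roc(response = f$labels, predictor = f$scores,
                     direction = "<", quiet = TRUE)
    expect_equal(r$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  }
})

test_that("empirical ROC is monotone and hits both corners", {
  set.seed(23)
  for (i in 1:30) {
    inst <- random_instance()
    roc <- empirical_roc(inst$scores, inst$labels)
    expect_true(all(diff(roc$se) <= 0))
    expect_true(all(diff(roc$sp) >= 0))
    expect_equal(roc$se[1], 1)
    expect_equal(roc$sp[1], 0)
    expect_equal(roc$se[nrow(roc)], 0)
    expect_equal(roc$sp[nrow(roc)], 1)
  }
  expect_error(empirical_roc(1:4, rep(TRUE, 4)), "both classes")
})

test_that("random labels give a near-diagonal curve", {
  set.seed(27)
  scores <- stats::rnorm(4000)
  labels <- stats::rbinom(4000, 1, 0.5) == 1
  expect_lt(abs(roc_auc(scores, labels)$auc - 0.5), 0.03)
})

test_that("Youden threshold separates the worked example at 15", {
  f <- separable_fixture()
  y <- youden_threshold(f$scores, f$labels)
  expect_equal(y$threshold, 15)
  expect_equal(y$j, 1)
  expect_equal(y$se, 1)
  expect_equal(y$sp, 1)
})

test_that("Youden threshold is translation equivariant", {
  set.seed(29)
  for (i in 1:20) {
    inst <- random_instance()
    y0 <- youden_threshold(inst$scores, inst$labels)
    y1 <- youden_threshold(inst$scores + 7.25, inst$labels)
    expect_equal(y1$threshold, y0$threshold + 7.25)
    expect_equal(y1$j, y0$j)
  }
})

test_that("binormal fit recovers known parameters and its AUC form", {
  # mu0 = 0, mu1 = 1.81, unit SDs: AUC = pnorm(1.81 / sqrt(2)) ~ 0.90
  set.seed(37)
  n <- 60000
  scores <- c(stats::rnorm(n, 1.81), stats::rnorm(n, 0))
  labels <- rep(c(TRUE, FALSE), each = n)
  fit <- binormal_fit(scores, labels)
  se_a <- sqrt((2 + 1.81^2 / 2) / n)   # delta method, unit SDs
  se_b <- sqrt(1 / n)
  expect_lt(abs(fit$a - 1.81), 3 * se_a)
  expect_lt(abs(fit$b - 1), 3 * se_b)
  expect_equal(fit$auc, stats::pnorm(1.81 / sqrt(2)), tolerance = 0.01)
  # equal class distributions: chance only
  eq <- binormal_fit(c(stats::rnorm(500), stats::rnorm(500)),
                     rep(c(TRUE, FALSE), each = 500))
  expect_equal(eq$auc, 0.5, tolerance = 0.1)
  expect_error(binormal_fit(c(1, 1, 1, 2, 3, 4),
                            rep(c(TRUE, FALSE), each = 3)), "variance")
})

test_that("binormal smooth curve matches its closed-form Se/Sp", {
  set.seed(39)
  f <- binormal_fixture(n1 = 200, n0 = 200)
  fit <- binormal_fit(f$scores, f$labels)
  th <- seq(-2, 3, by = 0.5)
  expect_equal(fit$se_fun(th), 1 - pnorm((th - fit$mu1) / fit$sd1))
  expect_equal(fit$sp_fun(th), pnorm((th - fit$mu0) / fit$sd0))
})
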