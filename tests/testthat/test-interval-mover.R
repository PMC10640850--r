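test_that("log-mean component limits match both chi-squared conventions", {
  f <- uncensoredFit(25)
  f$sigma2_hat <- 1; f$n_obs <- 25L
  lim <- muLimits(f, alpha = 0.05, chi_mode = "expected")
  # expected mode collapses to the Wald half-width z * sigma / sqrt(n)
  expect_equal(lim[2] - f$mu_hat, qnorm(0.975) / 5, tolerance = 1e-10)
  expect_equal(f$mu_hat - lim[1], lim[2] - f$mu_hat)
  # the median quantile of chi-squared sits below its mean: wider limits
  limm <- muLimits(f, alpha = 0.05, chi_mode = "median")
  expect_gt(limm[2] - limm[1], lim[2] - lim[1])
  # alpha -> 1 gives zero width
  expect_equal(diff(muLimits(f, alpha = 1 - 1e-12)), 0, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("variance component limits are the standard chi-squared bounds", {
  f <- uncensoredFit(11)
  f$sigma2_hat <- 1; f$n_obs <- 11L
  lim <- sigma2Limits(f, alpha = 0.05)
  expect_equal(lim[1], 0.4882, tolerance = 1e-4)   # 10 / 20.483
  expect_equal(lim[2], 3.0798, tolerance = 1e-4)   # 10 / 3.247
  expect_lt(lim[1], 1); expect_gt(lim[2], 1)
  f2 <- f; f2$sigma2_hat <- 3.5
  expect_equal(sigma2Limits(f2), 3.5 * lim)
})

test_that("recovered mean limits bracket the point estimate and widen monotonically", {
  f <- uncensoredFit(20)
  th <- lognormalMean(f)
  # degenerate component limits collapse onto the point estimate
  pt <- thetaLimits(f, rep(f$mu_hat, 2), rep(f$sigma2_hat, 2))
  expect_equal(pt, c(th, th))

  ml <- muLimits(f); sl <- sigma2Limits(f)
  tl <- thetaLimits(f, ml, sl)
  expect_lte(tl[1], th); expect_gte(tl[2], th)
  # widening the mu interval strictly widens the recovered limits
  wider <- thetaLimits(f, f$mu_hat + 2 * (ml - f$mu_hat), sl)
  expect_lt(wider[1], tl[1]); expect_gt(wider[2], tl[2])
})

test_that("ratio limits contain the estimate and respect the symmetry of identical groups", {
  set.seed(33)
  for (i in 1:25) {
    f1 <- uncensoredFit(sample(10:40, 1), mu = runif(1, -1, 1), sig = runif(1, 0.2, 1))
    f2 <- uncensoredFit(sample(10:40, 1), mu = runif(1, -1, 1), sig = runif(1, 0.2, 1))
    ci <- moverRatioInterval(f1, f2)
    expect_lte(ci$lower, ratioOfMeans(f1, f2))
    expect_gte(ci$upper, ratioOfMeans(f1, f2))
    # swapping the groups keeps the reciprocal estimate inside the swapped limits
    sw <- moverRatioInterval(f2, f1)
    expect_lte(sw$lower, ratioOfMeans(f2, f1))
    expect_gte(sw$upper, ratioOfMeans(f2, f1))
  }
  f <- uncensoredFit(30)
  same <- moverRatioInterval(f, f)
  expect_lte(same$lower, 1); expect_gte(same$upper, 1)
})

test_that("degenerate component limits trip the named guards", {
  f1 <- uncensoredFit(20); f2 <- uncensoredFit(20)
  t1 <- lognormalMean(f1); t2 <- lognormalMean(f2)
  # u2 = 2 * theta2 makes the lower-limit denominator exactly zero
  expect_error(moverRatioInterval(f1, f2,
                                  theta_lim1 = c(0.5 * t1, 1.5 * t1),
                                  theta_lim2 = c(0.5 * t2, 2 * t2)),
               "zero lower-limit denominator")
  expect_error(moverRatioInterval(f1, f2,
                                  theta_lim1 = c(0.5 * t1, 1.5 * t1),
                                  theta_lim2 = c(-1, 1.5 * t2)),
               "positive")
})

test_that("wide component limits enter the flagged breakdown regime but stay ordered", {
  f1 <- uncensoredFit(20); f2 <- uncensoredFit(20)
  t1 <- lognormalMean(f1); t2 <- lognormalMean(f2)
  ci <- moverRatioInterval(f1, f2,
                           theta_lim1 = c(0.2 * t1, 5 * t1),
                           theta_lim2 = c(0.2 * t2, 5 * t2))
  expect_true(ci$meta$breakdown)
  expect_true(is.finite(ci$lower) && is.finite(ci$upper))
  expect_lte(ci$lower, ci$upper)
  expect_lte(ci$lower, t1 / t2); expect_gte(ci$upper, t1 / t2)
})
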