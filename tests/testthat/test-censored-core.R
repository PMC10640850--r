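test_that("censorSplit classifies zeros, ties, missing and threshold exceedances", {
  rain <- rainfallData()

  s1 <- censorSplit(rain$chiang_rai, 0.10)
  expect_equal(s1$n, 30L)
  expect_equal(s1$n_cens, 18L)   # 15 zeros + the single 0.1 (tie) + 2 missing
  expect_equal(s1$n_obs, 12L)
  expect_equal(s1$h, 18 / 30)

  s2 <- censorSplit(rain$chiang_mai, 0.10)
  expect_equal(c(s2$n, s2$n_cens, s2$n_obs), c(30L, 23L, 7L))

  # dropped policy removes the missing records from n entirely
  s1d <- censorSplit(rain$chiang_rai, 0.10, missing_policy = "dropped")
  expect_equal(s1d$n, 28L)
  expect_equal(s1d$n_obs, 12L)

  # all values above the threshold: log 1 = 0, no spread
  s <- censorSplit(c(1, 1, 1), 0.5)
  expect_equal(s$n_cens, 0L)
  expect_equal(s$h, 0)
  expect_equal(s$ybar, 0)
  expect_equal(s$s2, 0)

  # values equal to the threshold are censored, strictly-above retained
  s <- censorSplit(c(0.5, 0.5, 2, 3, 4), 0.5)
  expect_equal(s$n_cens, 2L)

  expect_error(censorSplit(c(0, 0, 0.2, 5), 1), "at least 2")
})

test_that("retained-log summaries use the divisor-n(2) convention", {
  rain <- rainfallData()
  s1 <- censorSplit(rain$chiang_rai, 0.10)
  # hand-summed over the 12 logs of the values above 0.10 mm
  expect_equal(s1$ybar, 0.8416581, tolerance = 1e-6)
  expect_equal(s1$s2, 3.291965, tolerance = 1e-6)
  # unbiased switch rescales by n2/(n2-1)
  s1u <- censorSplit(rain$chiang_rai, 0.10, unbiased = TRUE)
  expect_equal(s1u$s2, s1$s2 * 12 / 11)
})

test_that("psi correction matches its closed form and boundary behaviour", {
  expect_equal(psiCensored(0, c(-3, -1, 0, 0.5, 2)), rep(0, 5))
  expect_equal(psiCensored(0.5, 0), 1)
  # plug-in value arising in the heavier-censored rainfall group
  expect_equal(psiCensored(0.6, -1.733), 0.6492941, tolerance = 1e-6)
  # direct evaluation against an explicit Mills-ratio computation
  h <- 0.3; a <- -1.2
  V <- h * (dnorm(-a) / (1 - pnorm(-a))) / (1 - h)
  expect_equal(psiCensored(h, a), V / (V - a))
  expect_error(psiCensored(1, -1), "h must lie in")
  # nonnegative below the degenerate point
  set.seed(1)
  hh <- runif(50, 0.05, 0.9); aa <- runif(50, -4, -0.01)
  expect_true(all(psiCensored(hh, aa) >= 0))
})

test_that("all fit modes reduce exactly to (ybar, s2) without censoring", {
  set.seed(42)
  for (i in 1:10) {
    x <- exp(rnorm(sample(8:40, 1), runif(1, -1, 1), runif(1, 0.3, 2)))
    s <- censorSplit(x, min(x) / 2)
    expect_identical(s$n_cens, 0L)
    for (mode in c("one_step", "iterated", "direct_ml")) {
      f <- fitCensoredNormal(s, mode = mode)
      expect_identical(f$mu_hat, s$ybar)
      expect_identical(f$sigma2_hat, s$s2)
      expect_identical(f$psi_hat, 0)
    }
  }
})

test_that("one-step fit evaluates the correction at the plug-in point", {
  rain <- rainfallData()
  s1 <- censorSplit(rain$chiang_rai, 0.10)
  f1 <- fitCensoredNormal(s1, mode = "one_step")
  expect_equal(f1$a_hat, (log(0.10) - s1$ybar) / sqrt(s1$s2))
  # direct evaluation of the correction equations at that point
  expect_equal(f1$mu_hat, -1.199885, tolerance = 1e-5)
  expect_equal(f1$sigma2_hat, 9.711074, tolerance = 1e-5)
  expect_true(f1$psi_hat > 0 && f1$psi_hat < 1)
})

test_that("direct likelihood maximization is consistent at large n", {
  set.seed(7)
  x <- exp(rnorm(1e5, 0, 1))
  f <- fitCensoredNormal(censorSplit(x, 0.10), mode = "direct_ml")
  expect_equal(f$mu_hat, 0, tolerance = 0.02)
  expect_equal(f$sigma2_hat, 1, tolerance = 0.02)
})

test_that("censored log-likelihood reduces to the normal one and peaks at the MLE", {
  set.seed(3)
  x <- exp(rnorm(25, 0.3, 1.2))
  s0 <- censorSplit(x, min(x) / 2)   # nothing censored
  mu <- 0.1; sig <- 1.4
  expect_equal(logLikCensoredNormal(s0, mu, sig),
               sum(dnorm(log(x), mu, sig, log = TRUE)))

  s <- censorSplit(x, as.numeric(quantile(x, 0.4)))
  f <- fitCensoredNormal(s, mode = "direct_ml")
  grid <- expand.grid(mu = f$mu_hat + seq(-1, 1, length.out = 21),
                      sig = sqrt(f$sigma2_hat) * exp(seq(-0.5, 0.5, length.out = 21)))
  ll <- mapply(function(m, s_) logLikCensoredNormal(s, m, s_), grid$mu, grid$sig)
  expect_true(all(ll <= f$loglik + 1e-8))
})

test_that("fits are equivariant under a common rescaling of data and threshold", {
  set.seed(10)
  for (i in 1:10) {
    cc <- runif(1, 0.2, 8)
    x <- exp(rnorm(50, 0.5, 1))
    xi <- as.numeric(quantile(x, 0.4))
    f <- fitCensoredNormal(censorSplit(x, xi))
    fc <- fitCensoredNormal(censorSplit(cc * x, cc * xi))
    expect_equal(fc$mu_hat, f$mu_hat + log(cc), tolerance = 1e-10)
    expect_equal(fc$sigma2_hat, f$sigma2_hat, tolerance = 1e-10)
    expect_equal(fc$psi_hat, f$psi_hat, tolerance = 1e-10)
    expect_equal(fc$h, f$h)
  }
})

test_that("mean estimates and their ratio follow the lognormal mean formula", {
  expect_equal(lognormalMean(0, 1e-12), 1, tolerance = 1e-9)
  # the published per-group estimates, reproduced from their components
  expect_equal(lognormalMean(-1.24, 9.84), 39.6464, tolerance = 1e-4)
  expect_equal(lognormalMean(-1.65, 13.57), 169.8643, tolerance = 1e-4)
  expect_equal(ratioOfMeans(39.61, 168.88), 0.2345, tolerance = 1e-3)
  expect_equal(round(ratioOfMeans(39.61, 168.88), 2), 0.23)
  expect_equal(ratioOfMeans(5, 5), 1)
  expect_equal(ratioOfMeans(3.2, 0.7) * ratioOfMeans(0.7, 3.2), 1)
  f <- uncensoredFit(20)
  expect_equal(lognormalMean(f), exp(f$mu_hat + f$sigma2_hat / 2))
})

test_that("delta-lognormal mean thins the positive-part mean by 1 - delta", {
  expect_equal(deltaLognormalMean(0.4, 1.3, 0), exp(0.4 + 0.65))
  expect_equal(deltaLognormalMean(0, 1e-12, 0.5), 0.5, tolerance = 1e-9)
  expect_equal(deltaLognormalMean(0, 2 * log(2), 0), 2)
  expect_error(deltaLognormalMean(0, 1, 1), "delta")
})
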