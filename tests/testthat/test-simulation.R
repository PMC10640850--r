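test_that("delta-lognormal generator produces the right zero mass and positives", {
  set.seed(2)
  g <- generateGroup(200, 0, 1, delta = 1)
  expect_true(all(g$values == 0))

  g <- generateGroup(100, 0.7, 1e-8, delta = 0)
  expect_equal(g$values, rep(exp(0.7), 100), tolerance = 1e-6)

  g <- generateGroup(1e5, 0, 1, delta = 0.10)
  expect_lt(abs(mean(g$values == 0) - 0.10), 0.003)
  expect_true(all(g$values >= 0))
})

test_that("scenario grid reproduces the study design", {
  cfg <- scenarioConfig(run = 5, n1 = 20, n2 = 20)
  expect_equal(cfg$true_theta, exp(0.5) / exp(2))
  expect_equal(cfg$sigma, c(1, 2))

  grid <- table2Grid()
  expect_length(grid, 63)
  run0 <- grid[[1]]
  expect_null(run0$xi)
  expect_equal(run0$sigma, c(0.3, 0.3))
  run8 <- Filter(function(g) isTRUE(g$run == 8) && all(g$n == c(20, 20)), grid)[[1]]
  expect_equal(run8$sigma, c(1, 2))
  expect_equal(run8$delta, c(0.10, 0.25))
  expect_equal(run8$xi, c(0.10, 0.25))
  expect_true(all(vapply(grid, function(g) g$M, numeric(1)) == 5000))
  expect_error(scenarioConfig(run = 9, n1 = 10, n2 = 10), "run must be")
})

test_that("a single-replicate scenario yields a 0/1 coverage indicator", {
  cfg <- scenarioConfig(run = 1, n1 = 20, n2 = 20, M = 1, m = 200, seed = 3)
  res <- runScenario(cfg, methods = c("bayes", "mover"))
  expect_true(all(res$coverage %in% c(0, 1)))
  expect_true(all(res$avg_length >= 0))
})

test_that("identical seeds give bit-identical simulation results", {
  cfg <- scenarioConfig(run = 4, n1 = 20, n2 = 20, M = 25, m = 300, seed = 99)
  r1 <- runScenario(cfg, methods = c("bayes", "pb", "mover"))
  r2 <- runScenario(cfg, methods = c("bayes", "pb", "mover"))
  expect_identical(r1$coverage, r2$coverage)
  expect_identical(r1$avg_length, r2$avg_length)
})

test_that("the no-censoring run reduces the fit to the positive-part summaries", {
  cfg <- scenarioConfig(run = 0, n1 = 30, n2 = 30, M = 1, m = 100, seed = 7)
  set.seed(7)
  rep1 <- runReplicate(cfg, methods = "mover")
  expect_true(rep1$mover$length >= 0)
  # the fit of an uncensored summary is (ybar, s2) exactly
  set.seed(1)
  g <- generateGroup(30, 0, 0.3, 0.1)
  s <- censorSplit(g, NULL)
  f <- fitCensoredNormal(s)
  expect_identical(f$mu_hat, s$ybar)
  expect_identical(f$sigma2_hat, s$s2)
  expect_equal(s$n_cens, sum(g$values == 0))
})

test_that("a known-parameter z-interval control attains nominal coverage", {
  # internal control on the generator: with (mu, sigma) known, the
  # delta-method interval for the log ratio of positive-part means
  # should cover 0 at about 95%
  set.seed(123)
  M <- 400; n <- 100; sig <- 0.3
  hit <- logical(M)
  for (i in 1:M) {
    est <- vapply(1:2, function(g) {
      x <- generateGroup(n, 0, sig, 0.1)$values
      y <- log(x[x > 0])
      k <- length(y)
      c(mean(y) + mean((y - mean(y))^2) / 2, k)
    }, numeric(2))
    v <- sum(sig^2 / est[2, ] + sig^4 / (2 * est[2, ]))
    d <- est[1, 1] - est[1, 2]
    hit[i] <- abs(d) <= qnorm(0.975) * sqrt(v)
  }
  expect_gte(mean(hit), 0.92)
  expect_lte(mean(hit), 0.98)
})

test_that("degenerate datasets are regenerated and counted", {
  # tiny samples with heavy zero mass force regeneration events
  cfg <- scenarioConfig(run = NULL, n1 = 5, n2 = 5, mu = c(0, 0),
                        sigma = c(1, 1), delta = c(0.7, 0.7),
                        xi = c(0.1, 0.1), M = 10, m = 100, seed = 17)
  res <- suppressWarnings(runScenario(cfg, methods = "bayes"))
  expect_gt(res$regenerated, 0)
  expect_equal(res$M, 10)
})
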