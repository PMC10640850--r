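# Table 1 parameter grid of the coverage study: per run,
# (mu1, mu2), (sigma1, sigma2), (delta1, delta2), (xi1, xi2);
# run 0 is the no-censoring control.
.runTable <- list(
  `0` = list(mu = c(0, 0), sigma = c(0.3, 0.3), delta = c(0.10, 0.10), xi = NULL),
  `1` = list(mu = c(0, 0), sigma = c(1, 1), delta = c(0.10, 0.10), xi = c(0.10, 0.10)),
  `2` = list(mu = c(0, 0), sigma = c(1, 1), delta = c(0.10, 0.10), xi = c(0.10, 0.25)),
  `3` = list(mu = c(0, 0), sigma = c(1, 1), delta = c(0.10, 0.25), xi = c(0.10, 0.10)),
  `4` = list(mu = c(0, 0), sigma = c(1, 1), delta = c(0.10, 0.25), xi = c(0.10, 0.25)),
  `5` = list(mu = c(0, 0), sigma = c(1, 2), delta = c(0.10, 0.10), xi = c(0.10, 0.10)),
  `6` = list(mu = c(0, 0), sigma = c(1, 2), delta = c(0.10, 0.10), xi = c(0.10, 0.25)),
  `7` = list(mu = c(0, 0), sigma = c(1, 2), delta = c(0.10, 0.25), xi = c(0.10, 0.10)),
  `8` = list(mu = c(0, 0), sigma = c(1, 2), delta = c(0.10, 0.25), xi = c(0.10, 0.25)))

#' Simulation scenario configuration
#'
#' One cell of the coverage study: delta-lognormal population parameters
#' for two groups, their censoring thresholds, sample sizes and
#' Monte-Carlo sizes. Either give a \code{run} id (0-8, the study's
#' parameter grid: \eqn{\mu = (0,0)}, \eqn{\sigma \in \{(1,1),(1,2)\}},
#' \eqn{\delta \in \{(.1,.1),(.1,.25)\}},
#' \eqn{\xi \in \{(.1,.1),(.1,.25)\}}, with run 0 an uncensored control
#' at \eqn{\sigma = (0.3, 0.3)}) or the parameters explicitly.
#'
#' @param run run id 0-8, or \code{NULL} when parameters are explicit.
#' @param n1,n2 group sample sizes.
#' @param mu,sigma,delta length-2 parameter vectors (overriding the run).
#' @param xi length-2 thresholds or \code{NULL} for no censoring.
#' @param M number of simulation replicates (study default 5000).
#' @param m inner Monte-Carlo size for GCI/Bayes/bootstrap (default 2500).
#' @param alpha two-sided error level.
#' @param seed integer seed for the scenario's random stream.
#' @return an object of class \code{scenarioConfig}; its
#'   \code{true_theta} is the target ratio
#'   \eqn{\exp(\mu_1 + \sigma_1^2/2)/\exp(\mu_2 + \sigma_2^2/2)}.
#' @export
scenarioConfig <- function(run = NULL, n1, n2, mu = NULL, sigma = NULL,
                           delta = NULL, xi = NULL, M = 5000L, m = 2500L,
                           alpha = 0.05, seed = 1L) {
  base <- if (!is.null(run)) {
    key <- as.character(run)
    if (!key %in% names(.runTable)) stop("scenarioConfig: run must be 0-8", call. = FALSE)
    .runTable[[key]]
  } else list(mu = NULL, sigma = NULL, delta = NULL, xi = NULL)
  mu <- if (is.null(mu)) base$mu else mu
  sigma <- if (is.null(sigma)) base$sigma else sigma
  delta <- if (is.null(delta)) base$delta else delta
  if (is.null(xi) && !is.null(run)) xi <- base$xi
  stopifnot(length(mu) == 2, length(sigma) == 2, length(delta) == 2,
            all(sigma > 0), all(delta >= 0 & delta < 1))
  structure(list(run = run, n = c(n1, n2), mu = mu, sigma = sigma,
                 delta = delta, xi = xi, M = as.integer(M), m = as.integer(m),
                 alpha = alpha, seed = as.integer(seed),
                 true_theta = exp(mu[1] + sigma[1]^2 / 2) /
                              exp(mu[2] + sigma[2]^2 / 2)),
            class = "scenarioConfig")
}

#' @export
print.scenarioConfig <- function(x, ...) {
  cat("scenarioConfig", if (!is.null(x$run)) paste0("(run ", x$run, ")"), ":",
      "n =", paste(x$n, collapse = "/"),
      " mu =", paste(x$mu, collapse = "/"),
      " sigma =", paste(x$sigma, collapse = "/"),
      " delta =", paste(x$delta, collapse = "/"),
      " xi =", if (is.null(x$xi)) "none" else paste(x$xi, collapse = "/"), "\n")
  cat("  M =", x$M, " m =", x$m, " alpha =", x$alpha,
      " true theta =", format(x$true_theta, digits = 5), "\n")
  invisible(x)
}

#' Generate one delta-lognormal sample
#'
#' Each observation is 0 with probability \code{delta}, otherwise
#' lognormal\eqn{(\mu, \sigma^2)}.
#'
#' @param n sample size.
#' @param mu,sigma log-scale normal parameters (\code{sigma > 0}).
#' @param delta zero-mass probability in \eqn{[0, 1]}.
#' @param label group label.
#' @return a \code{\link{groupSample}}.
#' @export
generateGroup <- function(n, mu, sigma, delta, label = "simulated") {
  z <- numeric(n)
  pos <- runif(n) >= delta
  z[pos] <- exp(rnorm(sum(pos), mu, sigma))
  groupSample(z, label = label)
}

#' All 63 cells of the coverage study
#'
#' The 9 parameter runs crossed with sample-size pairs (20,20), (30,30),
#' (20,30), (50,50), (30,50), (100,100), (50,100), at the study defaults
#' \code{M = 5000}, \code{m = 2500}, \code{alpha = 0.05}.
#'
#' @param M,m,alpha overrides for the study defaults.
#' @param seed base seed; cell \code{i} gets \code{seed + i}.
#' @return a list of 63 \code{\link{scenarioConfig}} objects.
#' @export
table2Grid <- function(M = 5000L, m = 2500L, alpha = 0.05, seed = 1L) {
  sizes <- list(c(20, 20), c(30, 30), c(20, 30), c(50, 50), c(30, 50),
                c(100, 100), c(50, 100))
  configs <- list()
  i <- 0L
  for (sz in sizes) for (run in 0:8) {
    i <- i + 1L
    configs[[i]] <- scenarioConfig(run = run, n1 = sz[1], n2 = sz[2],
                                   M = M, m = m, alpha = alpha,
                                   seed = seed + i)
  }
  configs
}

# Generate one two-group dataset and its censored summaries;
# regenerates (counted) until both groups retain at least min_obs
# values above their thresholds.
.replicateData <- function(config, min_obs = 3L, max_regen = 1000L) {
  for (attempt in seq_len(max_regen)) {
    ok <- TRUE
    sums <- vector("list", 2L)
    for (g in 1:2) {
      smp <- generateGroup(config$n[g], config$mu[g], config$sigma[g],
                           config$delta[g], label = paste0("group", g))
      xi_g <- if (is.null(config$xi)) NULL else config$xi[g]
      n_ret <- if (is.null(xi_g)) sum(smp$values > 0) else sum(smp$values > xi_g)
      if (n_ret < min_obs) { ok <- FALSE; break }
      sums[[g]] <- censorSplit(smp, xi_g)
    }
    if (ok) return(list(summaries = sums, regenerated = attempt - 1L))
  }
  stop(".replicateData: could not generate a dataset with enough retained values",
       call. = FALSE)
}

#' Run one simulation replicate
#'
#' Generates the two delta-lognormal samples of a scenario, censors them
#' at their thresholds (zeros and sub-threshold positives form the
#' censored class), fits the left-censored normals, and constructs the
#' requested intervals; each is compared to the scenario's true ratio.
#'
#' @param config a \code{\link{scenarioConfig}}.
#' @param methods subset of \code{c("gci", "bayes", "pb", "mover")}.
#' @param fit_mode censored-fit mode (default \code{"one_step"}).
#' @return list with per-method entries \code{list(interval, covered,
#'   length)} (\code{NULL} for a MOVER guard failure) plus the
#'   regeneration count.
#' @export
runReplicate <- function(config, methods = c("gci", "bayes", "pb", "mover"),
                         fit_mode = "one_step") {
  dat <- .replicateData(config)
  s1 <- dat$summaries[[1]]; s2 <- dat$summaries[[2]]
  f1 <- fitCensoredNormal(s1, mode = fit_mode)
  f2 <- fitCensoredNormal(s2, mode = fit_mode)
  out <- list(regenerated = dat$regenerated)
  for (meth in methods) {
    ci <- if (meth == "mover") {
      tryCatch(moverRatioInterval(f1, f2, alpha = config$alpha),
               error = function(e) NULL)
    } else switch(meth,
      gci = gciInterval(gpqRatioDraws(f1, f2, s1$n, s2$n, config$m,
                                      mode = fit_mode), config$alpha),
      bayes = hpdInterval(posteriorRatioDraws(f1, f2, config$m), config$alpha),
      pb = pbInterval(bootstrapRatioDraws(f1, f2, m = config$m), config$alpha))
    out[[meth]] <- if (is.null(ci)) NULL else
      list(interval = ci,
           covered = ci$lower <= config$true_theta && config$true_theta <= ci$upper,
           length = ci$length)
  }
  out
}

#' Estimate coverage probability and average length over M replicates
#'
#' Repeats \code{\link{runReplicate}} \code{M} times under the
#' scenario's seed and aggregates, per method, the fraction of intervals
#' covering the true ratio and the mean interval length. Datasets with
#' fewer than 3 retained values in either group are regenerated
#' (counted); a MOVER guard failure triggers a fresh replicate for the
#' MOVER tally only (counted).
#'
#' @inheritParams runReplicate
#' @return an object of class \code{simulationResult}: per-method
#'   \code{coverage} and \code{avg_length}, \code{M},
#'   \code{regenerated} and \code{mover_guard_failures} counts, and the
#'   \code{config}.
#' @export
runScenario <- function(config, methods = c("gci", "bayes", "pb", "mover"),
                        fit_mode = "one_step") {
  stopifnot(inherits(config, "scenarioConfig"), config$M >= 1)
  set.seed(config$seed)
  cov <- len <- setNames(numeric(length(methods)), methods)
  regen <- 0L
  guard_fail <- 0L
  for (i in seq_len(config$M)) {
    rep <- runReplicate(config, methods, fit_mode)
    regen <- regen + rep$regenerated
    if ("mover" %in% methods && is.null(rep$mover)) {
      # guard failed: regenerate the whole replicate for MOVER's tally only
      for (try in 1:100) {
        guard_fail <- guard_fail + 1L
        rep2 <- runReplicate(config, "mover", fit_mode)
        if (!is.null(rep2$mover)) { rep$mover <- rep2$mover; break }
      }
      if (is.null(rep$mover))
        stop("runScenario: MOVER guard failed 100 times in a row", call. = FALSE)
    }
    for (meth in methods) {
      cov[meth] <- cov[meth] + rep[[meth]]$covered
      len[meth] <- len[meth] + rep[[meth]]$length
    }
  }
  if (regen > 0.01 * config$M)
    warning(sprintf("runScenario: %d of %d replicates required regeneration (>1%%)",
                    regen, config$M))
  structure(list(coverage = cov / config$M, avg_length = len / config$M,
                 M = config$M, regenerated = regen,
                 mover_guard_failures = guard_fail, config = config),
            class = "simulationResult")
}

#' @export
print.simulationResult <- function(x, ...) {
  cat("simulationResult over M =", x$M, "replicates",
      if (!is.null(x$config$run)) paste0("(run ", x$config$run, ", n = ",
                                         paste(x$config$n, collapse = "/"), ")"),
      "\n")
  tab <- rbind(coverage = round(x$coverage, 4),
               avg_length = round(x$avg_length, 4))
  print(tab)
  if (x$regenerated > 0 || x$mover_guard_failures > 0)
    cat("  regenerated datasets:", x$regenerated,
        "; MOVER guard failures:", x$mover_guard_failures, "\n")
  invisible(x)
}
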