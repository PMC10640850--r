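#' Interval result container
#'
#' Common container for the four interval constructions.
#' @param lower,upper interval limits.
#' @param method one of \code{"GCI"}, \code{"BAYES"}, \code{"PB"},
#'   \code{"MOVER"}.
#' @param alpha two-sided error level.
#' @param m Monte-Carlo draw count (0 for the closed-form MOVER).
#' @param meta named list of construction metadata (conventions used).
#' @return an object of class \code{intervalResult}.
#' @export
intervalResult <- function(lower, upper, method, alpha, m = 0L, meta = list()) {
  if (upper < lower)
    stop("intervalResult: upper < lower", call. = FALSE)
  structure(list(lower = lower, upper = upper, length = upper - lower,
                 method = method, alpha = alpha, m = as.integer(m),
                 meta = meta),
            class = "intervalResult")
}

#' @export
print.intervalResult <- function(x, ...) {
  cat(sprintf("%s %g%% interval: [%.4f, %.4f]  (length %.4f%s)\n",
              x$method, 100 * (1 - x$alpha), x$lower, x$upper, x$length,
              if (x$m > 0) sprintf(", m = %d draws", x$m) else ""))
  invisible(x)
}

# Vectorized one-step censored fit of m standard-normal samples of size
# n censored at a_star (values <= a_star are censored). Returns mu_star
# and sigma_star vectors. Columns with fewer than 2 retained values (or
# zero retained spread) are redrawn whole, up to max_redraw times.
.stdCensFitDraws <- function(n, a_star, m, max_redraw = 100L) {
  if (n < 3L) stop(".stdCensFitDraws: n must be at least 3", call. = FALSE)
  mu <- numeric(m); sig2 <- numeric(m)
  todo <- seq_len(m)
  for (round in 0:max_redraw) {
    if (!length(todo)) break
    if (round == max_redraw)
      stop(sprintf("standard censored fit: redraw cap (%d) exceeded; the censoring point %.3g is too extreme for n = %d",
                   max_redraw, a_star, n), call. = FALSE)
    k <- length(todo)
    z <- matrix(rnorm(n * k), nrow = n)
    if (is.finite(a_star)) {
      cens <- z <= a_star
      zc <- z; zc[cens] <- 0
      nc <- colSums(cens)
    } else {
      zc <- z
      nc <- integer(k)
    }
    nobs <- n - nc
    ybar <- colSums(zc) / nobs
    v <- colSums(zc^2) / nobs - ybar^2
    ok <- nobs >= 2L & v > 0
    if (any(ok)) {
      i <- todo[ok]
      if (is.finite(a_star)) {
        h <- nc[ok] / n
        d <- ybar[ok] - a_star
        a0 <- -d / sqrt(v[ok])
        psi <- psiCensored(h, a0)
        mu[i] <- ybar[ok] - psi * d
        sig2[i] <- v[ok] + psi * d^2
      } else {
        mu[i] <- ybar[ok]
        sig2[i] <- v[ok]
      }
    }
    todo <- todo[!ok]
  }
  list(mu = mu, sigma = sqrt(sig2))
}

#' Censored fit of a standard-normal calibration sample
#'
#' Draws \code{n} standard-normal variates, censors them at
#' \code{a_star} (values at or below are censored) and fits the
#' left-censored normal, giving the pivot ingredients
#' \eqn{(\hat\mu^*, \hat\sigma^*)} used by the generalized pivotal
#' quantities. Samples with fewer than 2 retained values are redrawn
#' whole.
#'
#' @param n calibration sample size (at least 3).
#' @param a_star standardized censoring point; \code{-Inf} for no
#'   censoring.
#' @param mode fit mode passed to \code{\link{fitCensoredNormal}}.
#' @param max_redraw redraw cap for degenerate samples (default 100).
#' @return list with \code{mu_star} and \code{sigma_star}.
#' @export
standardCensoredFit <- function(n, a_star, mode = "one_step", max_redraw = 100L) {
  if (mode == "one_step") {
    d <- .stdCensFitDraws(n, a_star, 1L, max_redraw)
    return(list(mu_star = d$mu, sigma_star = d$sigma))
  }
  for (round in seq_len(max_redraw)) {
    z <- rnorm(n)
    retained <- z[z > a_star]
    if (length(retained) < 2L) next
    s <- structure(list(n = n, n_cens = n - length(retained),
                        n_obs = length(retained),
                        ybar = mean(retained),
                        s2 = mean((retained - mean(retained))^2),
                        h = (n - length(retained)) / n,
                        xi = exp(a_star), log_xi = a_star,
                        censored = is.finite(a_star), unbiased = FALSE,
                        label = "calibration"),
                   class = "censSummary")
    f <- fitCensoredNormal(s, mode = mode)
    return(list(mu_star = f$mu_hat, sigma_star = sqrt(f$sigma2_hat)))
  }
  stop(sprintf("standard censored fit: redraw cap (%d) exceeded; the censoring point %.3g is too extreme for n = %d",
               max_redraw, a_star, n), call. = FALSE)
}

# Pivot assembly: R_mu = mu_hat - (mu*/sigma*) sigma_hat,
# R_sigma = sigma_hat/sigma*, R_theta = exp(R_mu + R_sigma^2/2).
.gpqTheta <- function(fit, mu_star, sigma_star) {
  sig_hat <- sqrt(fit$sigma2_hat)
  r_mu <- fit$mu_hat - (mu_star / sigma_star) * sig_hat
  r_sigma <- sig_hat / sigma_star
  exp(r_mu + r_sigma^2 / 2)
}

#' Generalized pivotal quantity draws for the ratio of means
#'
#' For each of \code{m} draws and each group, fits a censored
#' standard-normal calibration sample of the group's size and assembles
#' the pivotal quantities
#' \eqn{R_\mu = \hat\mu - (\hat\mu^*/\hat\sigma^*)\hat\sigma},
#' \eqn{R_\sigma = \hat\sigma/\hat\sigma^*} and
#' \eqn{R_\theta = \exp(R_\mu + R_\sigma^2/2)}; returns the ratio
#' \eqn{R_{\theta_1}/R_{\theta_2}}.
#'
#' The calibration censoring point defaults to the standardized
#' observed threshold \eqn{a^* = (\log\xi - \hat\mu)/\hat\sigma} of each
#' group's fit (pivot-matching choice, recorded in metadata).
#'
#' @param fit1,fit2 \code{censNormFit} objects for the two groups.
#' @param n1,n2 group sample sizes (total \eqn{n}, censored class
#'   included).
#' @param m number of pivotal draws (at least 2).
#' @param a_star1,a_star2 calibration censoring points; default
#'   \eqn{(\log\xi - \hat\mu)/\hat\sigma} from each fit.
#' @param mode calibration fit mode (default \code{"one_step"}).
#' @return numeric vector of \code{m} ratio pivot draws.
#' @export
gpqRatioDraws <- function(fit1, fit2, n1, n2, m,
                          a_star1 = NULL, a_star2 = NULL,
                          mode = "one_step") {
  stopifnot(inherits(fit1, "censNormFit"), inherits(fit2, "censNormFit"),
            m >= 2)
  if (is.null(a_star1))
    a_star1 <- if (is.finite(fit1$log_xi))
      (fit1$log_xi - fit1$mu_hat) / sqrt(fit1$sigma2_hat) else -Inf
  if (is.null(a_star2))
    a_star2 <- if (is.finite(fit2$log_xi))
      (fit2$log_xi - fit2$mu_hat) / sqrt(fit2$sigma2_hat) else -Inf
  if (mode == "one_step") {
    s1 <- .stdCensFitDraws(n1, a_star1, m)
    s2 <- .stdCensFitDraws(n2, a_star2, m)
    r1 <- .gpqTheta(fit1, s1$mu, s1$sigma)
    r2 <- .gpqTheta(fit2, s2$mu, s2$sigma)
  } else {
    r1 <- r2 <- numeric(m)
    for (i in seq_len(m)) {
      c1 <- standardCensoredFit(n1, a_star1, mode)
      c2 <- standardCensoredFit(n2, a_star2, mode)
      r1[i] <- .gpqTheta(fit1, c1$mu_star, c1$sigma_star)
      r2[i] <- .gpqTheta(fit2, c2$mu_star, c2$sigma_star)
    }
  }
  r1 / r2
}

#' Percentile interval from pivotal draws
#'
#' Empirical \eqn{100(\alpha/2)} and \eqn{100(1-\alpha/2)} percentiles
#' of the ratio pivot draws (linear interpolation of order statistics,
#' \code{\link[stats]{quantile}} type 7; the convention is recorded in
#' the result metadata).
#'
#' @param draws numeric vector of pivotal ratio draws (at least 2).
#' @param alpha two-sided error level.
#' @return an \code{\link{intervalResult}} with method \code{"GCI"}.
#' @export
gciInterval <- function(draws, alpha = 0.05) {
  stopifnot(length(draws) >= 2)
  q <- unname(quantile(draws, c(alpha / 2, 1 - alpha / 2), type = 7))
  intervalResult(q[1], q[2], "GCI", alpha, m = length(draws),
                 meta = list(percentile = "type 7 (linear interpolation)"))
}
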