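#' Parametric bootstrap draws of the ratio of means
#'
#' Per draw and group, simulates \eqn{n_{(2)}} normal variates with the
#' fitted \eqn{(\hat\mu, \hat\sigma^2)} of the censored-normal fit (the
#' bootstrap world is uncensored: only the retained-part sample size is
#' resampled and no re-censoring is applied), computes the divisor-
#' \eqn{n_{(2)}} mean and variance \eqn{(\bar y^*, s^{2*})} and
#' \eqn{\hat\theta^* = \exp(\bar y^* + s^{2*}/2)}; returns the ratio of
#' the two groups' \eqn{\hat\theta^*}.
#'
#' @param fit1,fit2 \code{censNormFit} objects for the two groups.
#' @param n1_obs,n2_obs retained counts \eqn{n_{(2)}} (at least 2);
#'   default taken from the fits.
#' @param m number of bootstrap draws.
#' @return numeric vector of \code{m} bootstrap ratio draws.
#' @export
bootstrapRatioDraws <- function(fit1, fit2, n1_obs = fit1$n_obs,
                                n2_obs = fit2$n_obs, m = 2500L) {
  stopifnot(inherits(fit1, "censNormFit"), inherits(fit2, "censNormFit"),
            n1_obs >= 2, n2_obs >= 2, m >= 2)
  drawTheta <- function(fit, nobs) {
    y <- matrix(rnorm(nobs * m, mean = fit$mu_hat, sd = sqrt(fit$sigma2_hat)),
                nrow = nobs)
    ybar <- colMeans(y)
    s2 <- colMeans(y^2) - ybar^2
    exp(ybar + s2 / 2)
  }
  drawTheta(fit1, n1_obs) / drawTheta(fit2, n2_obs)
}

#' Normal-approximation interval from bootstrap draws
#'
#' \eqn{\bar{\hat\theta^*} \pm z_{1-\alpha/2}\, sd(\hat\theta^*)}, with
#' the divisor-\eqn{(m-1)} sample standard deviation (recorded in the
#' metadata). The lower limit may be negative and is deliberately not
#' truncated at zero.
#'
#' @param draws numeric vector of bootstrap ratio draws (at least 2).
#' @param alpha two-sided error level.
#' @return an \code{\link{intervalResult}} with method \code{"PB"}.
#' @export
pbInterval <- function(draws, alpha = 0.05) {
  stopifnot(length(draws) >= 2)
  z <- qnorm(1 - alpha / 2)
  mu <- mean(draws)
  s <- sd(draws)
  intervalResult(mu - z * s, mu + z * s, "PB", alpha, m = length(draws),
                 meta = list(sd = "sample sd, divisor m-1",
                             note = "lower limit not truncated at zero"))
}
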