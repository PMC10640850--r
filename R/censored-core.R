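#' Two-group samples of nonnegative measurements
#'
#' Constructs a \code{groupSample}: a vector of nonnegative measurements
#' (e.g., daily rainfall in mm) together with a count of missing records.
#' Missing entries may be supplied either as \code{NA} values in
#' \code{values} or through \code{n_missing}.
#'
#' @param values numeric vector of nonnegative measurements; \code{NA}
#'   entries are counted as missing records.
#' @param n_missing additional missing-record count (default 0).
#' @param label optional group label used in error messages and reports.
#' @return an object of class \code{groupSample} with elements
#'   \code{values} (the non-missing measurements), \code{n_missing} and
#'   \code{label}.
#' @export
groupSample <- function(values, n_missing = 0L, label = NULL) {
  values <- as.numeric(values)
  n_missing <- as.integer(n_missing) + sum(is.na(values))
  values <- values[!is.na(values)]
  if (any(values < 0))
    stop("groupSample: all values must be nonnegative", call. = FALSE)
  structure(list(values = values, n_missing = n_missing,
                 label = if (is.null(label)) "group" else as.character(label)),
            class = "groupSample")
}

#' @export
print.groupSample <- function(x, ...) {
  cat("groupSample '", x$label, "': ", length(x$values), " recorded values (",
      sum(x$values > 0), " positive), ", x$n_missing, " missing\n", sep = "")
  invisible(x)
}

#' Split a sample at a left-censoring threshold
#'
#' Classifies the observations of a nonnegative sample against a
#' detection threshold \eqn{\xi}: zeros, values at or below \eqn{\xi}
#' and (by default) missing records form the censored class; values
#' strictly above \eqn{\xi} are retained and log-transformed. The mean
#' \eqn{\bar y} and variance \eqn{s^2} of the retained logs use the
#' divisor \eqn{n_{(2)}} (the retained count), not \eqn{n_{(2)}-1}.
#'
#' @param sample a \code{groupSample}, or a numeric vector (coerced;
#'   \code{NA}s counted as missing).
#' @param xi positive censoring threshold on the measurement scale, or
#'   \code{NULL} for the no-censoring analysis in which only the
#'   positive values are modelled (retained set = values > 0 and the
#'   threshold plays no further role).
#' @param missing_policy how missing records enter the classification:
#'   \code{"censored"} (default; counted in the censored class, the
#'   convention under which a trace/unrecorded day is treated as below
#'   the detection limit) or \code{"dropped"} (excluded from \code{n}).
#' @param unbiased if \code{TRUE}, use the divisor \eqn{n_{(2)}-1} for
#'   \eqn{s^2} instead (sensitivity analysis only).
#' @return an object of class \code{censSummary}: a list with \code{n},
#'   \code{n_cens}, \code{n_obs}, \code{ybar}, \code{s2}, \code{h}
#'   (censored fraction \eqn{n_{(1)}/n}), \code{xi}, \code{log_xi}
#'   (\code{-Inf} when \code{xi} is \code{NULL}), \code{censored} flag
#'   and \code{label}.
#' @export
censorSplit <- function(sample, xi,
                        missing_policy = c("censored", "dropped"),
                        unbiased = FALSE) {
  if (!inherits(sample, "groupSample")) sample <- groupSample(sample)
  missing_policy <- match.arg(missing_policy)
  v <- sample$values
  no_censoring <- is.null(xi) || (length(xi) == 1L && is.na(xi))
  if (no_censoring) {
    xi <- NA_real_
    log_xi <- -Inf
    retained <- v[v > 0]
  } else {
    if (!(is.numeric(xi) && length(xi) == 1L && xi > 0))
      stop("censorSplit: xi must be a positive scalar (or NULL)", call. = FALSE)
    log_xi <- log(xi)
    retained <- v[v > xi]            # ties at xi are censored
  }
  n_obs <- length(retained)
  dropped <- if (missing_policy == "dropped") sample$n_missing else 0L
  n <- length(v) + sample$n_missing - dropped
  n_cens <- n - n_obs
  if (n_obs < 2L)
    stop(sprintf("censorSplit: group '%s' has %d value(s) above the threshold; at least 2 are required",
                 sample$label, n_obs), call. = FALSE)
  y <- log(retained)
  ybar <- mean(y)
  s2 <- sum((y - ybar)^2) / (n_obs - if (unbiased) 1L else 0L)
  structure(list(n = n, n_cens = n_cens, n_obs = n_obs,
                 ybar = ybar, s2 = s2, h = n_cens / n,
                 xi = xi, log_xi = log_xi,
                 censored = !no_censoring, unbiased = unbiased,
                 label = sample$label),
            class = "censSummary")
}

#' @export
print.censSummary <- function(x, ...) {
  cat("censSummary '", x$label, "': n = ", x$n, ", censored n(1) = ", x$n_cens,
      ", retained n(2) = ", x$n_obs, "\n", sep = "")
  if (x$censored)
    cat("  threshold xi = ", format(x$xi), " (log xi = ",
        format(x$log_xi, digits = 4), ")\n", sep = "")
  else cat("  no censoring threshold (positives only)\n")
  cat("  retained-log mean ybar = ", format(x$ybar, digits = 6),
      ", variance s2 = ", format(x$s2, digits = 6),
      " (divisor ", if (x$unbiased) "n(2)-1" else "n(2)", ")\n", sep = "")
  invisible(x)
}

# Mills-type ratio W(a) = phi(a) / (1 - Phi(a)), computed on the log
# scale so that extreme arguments do not underflow.
millsRatio <- function(a) {
  exp(dnorm(a, log = TRUE) - pnorm(a, lower.tail = FALSE, log.p = TRUE))
}

#' Censoring correction factor for the left-censored normal fit
#'
#' The correction \eqn{\psi(h, a) = V / (V - a)} with
#' \eqn{V(h, a) = h\,W(-a)/(1 - h)} and \eqn{W} the standard-normal
#' Mills-type ratio \eqn{\phi/(1-\Phi)}, where \eqn{h} is the censored
#' fraction and \eqn{a} the standardized censoring point. It scales the
#' shrinkage of the retained-part mean and variance toward the
#' threshold; \eqn{\psi(0, a) = 0} for every \eqn{a}.
#'
#' @param h censored fraction(s) in \eqn{[0, 1)}.
#' @param a standardized censoring point(s); recycled against \code{h}.
#' @return numeric vector of \eqn{\psi} values.
#' @export
psiCensored <- function(h, a) {
  k <- max(length(h), length(a))
  h <- rep_len(h, k); a <- rep_len(a, k)
  if (any(h < 0 | h >= 1))
    stop("psiCensored: h must lie in [0, 1); h = 1 means every observation is censored",
         call. = FALSE)
  out <- numeric(k)
  pos <- h > 0
  if (any(pos)) {
    # W(-a) = phi(a) / Phi(a)
    w_neg <- exp(dnorm(a[pos], log = TRUE) - pnorm(a[pos], log.p = TRUE))
    V <- h[pos] * w_neg / (1 - h[pos])
    den <- V - a[pos]
    if (any(!is.finite(den)) || any(abs(den) < .Machine$double.eps))
      stop("psiCensored: V(h, a) - a vanished; the configuration is numerically degenerate",
           call. = FALSE)
    out[pos] <- V / den
  }
  out
}

#' Log-likelihood of the singly left-censored normal model
#'
#' Type-I left-censored normal log-likelihood
#' \deqn{\ell(\mu, \sigma) = n_{(1)} \log \Phi\!\left(\frac{\log\xi - \mu}{\sigma}\right)
#'   + \sum_{retained} \log\left[\phi\!\left(\frac{y - \mu}{\sigma}\right)/\sigma\right],}
#' evaluated from the sufficient statistics (\code{n_cens}, \code{n_obs},
#' \code{ybar}, \code{s2}) of a \code{censSummary}; the retained part is
#' normal, so the summary carries all information.
#'
#' @param summary a \code{censSummary}.
#' @param mu,sigma parameter values (\code{sigma > 0}); vectorized.
#' @return the log-likelihood value(s).
#' @export
logLikCensoredNormal <- function(summary, mu, sigma) {
  stopifnot(inherits(summary, "censSummary"))
  if (any(sigma <= 0)) stop("logLikCensoredNormal: sigma must be positive", call. = FALSE)
  n2 <- summary$n_obs
  ll <- -n2 * log(sigma) - n2 / 2 * log(2 * pi) -
    n2 * (summary$s2 + (summary$ybar - mu)^2) / (2 * sigma^2)
  if (summary$n_cens > 0L && is.finite(summary$log_xi))
    ll <- ll + summary$n_cens * pnorm((summary$log_xi - mu) / sigma, log.p = TRUE)
  ll
}

#' Fit the singly left-censored normal model
#'
#' Estimates \eqn{(\mu, \sigma^2)} of the log-scale normal from a
#' censored summary, using the correction form
#' \deqn{\hat\mu = \bar y - \psi(h, a)(\bar y - \log\xi), \qquad
#'   \hat\sigma^2 = s^2 + \psi(h, a)(\bar y - \log\xi)^2.}
#' Three modes resolve the standardized censoring point \eqn{a}:
#' \describe{
#'   \item{\code{one_step}}{plug in \eqn{a_0 = (\log\xi - \bar y)/s};
#'     closed form, the default (cheap enough to sit inside Monte-Carlo
#'     loops).}
#'   \item{\code{iterated}}{fixed-point iteration re-evaluating
#'     \eqn{a = (\log\xi - \hat\mu)/\hat\sigma} until successive
#'     \eqn{(\hat\mu, \hat\sigma^2)} change by less than \code{tol};
#'     its fixed point is the restricted maximum-likelihood solution.}
#'   \item{\code{direct_ml}}{numerical maximization of
#'     \code{\link{logLikCensoredNormal}} over \eqn{(\mu, \log\sigma)}.}
#' }
#' With no censored observations all modes return \eqn{(\bar y, s^2)}
#' exactly.
#'
#' @param summary a \code{censSummary} from \code{\link{censorSplit}}.
#' @param mode fit mode, see Details.
#' @param tol convergence tolerance on
#'   \eqn{\max(|\Delta\hat\mu|, |\Delta\hat\sigma^2|)} for the iterated
#'   mode (default \code{1e-10}).
#' @param max_iter iteration cap for the iterated mode (default 500).
#' @return an object of class \code{censNormFit}: \code{mu_hat},
#'   \code{sigma2_hat}, \code{a_hat} (standardized censoring point the
#'   correction was evaluated at), \code{psi_hat}, \code{mode},
#'   \code{iterations}, \code{loglik}, plus the summary's counts and
#'   \code{log_xi}.
#' @export
fitCensoredNormal <- function(summary,
                              mode = c("one_step", "iterated", "direct_ml"),
                              tol = 1e-10, max_iter = 500L) {
  stopifnot(inherits(summary, "censSummary"))
  mode <- match.arg(mode)
  if (summary$h >= 1)
    stop("fitCensoredNormal: every observation is censored (h = 1)", call. = FALSE)
  ybar <- summary$ybar; s2 <- summary$s2; lxi <- summary$log_xi
  mk <- function(mu, sig2, a, psi, iters) {
    structure(list(mu_hat = mu, sigma2_hat = sig2, a_hat = a, psi_hat = psi,
                   mode = mode, iterations = iters,
                   n = summary$n, n_cens = summary$n_cens, n_obs = summary$n_obs,
                   ybar = ybar, s2 = s2,
                   h = summary$h, log_xi = lxi,
                   loglik = if (sig2 > 0)
                     logLikCensoredNormal(summary, mu, sqrt(sig2)) else NA_real_,
                   label = summary$label),
              class = "censNormFit")
  }
  # uncensored reduction: psi(0, .) = 0 so the correction vanishes
  if (summary$n_cens == 0L || !is.finite(lxi)) {
    a0 <- if (is.finite(lxi) && s2 > 0) (lxi - ybar) / sqrt(s2) else -Inf
    return(mk(ybar, s2, a0, 0, 0L))
  }
  if (s2 <= 0)
    stop("fitCensoredNormal: retained logs have zero spread", call. = FALSE)
  d <- ybar - lxi
  h <- summary$h
  a0 <- -d / sqrt(s2)
  psi0 <- psiCensored(h, a0)
  mu0 <- ybar - psi0 * d
  sig20 <- s2 + psi0 * d^2
  if (mode == "one_step") return(mk(mu0, sig20, a0, psi0, 1L))
  if (mode == "iterated") {
    # Self-consistent solution: re-evaluating the correction at
    # a = (log xi - mu_hat)/sigma_hat makes the estimate a fixed point
    # of the scalar map
    # g(a) = -d (1 - psi(h, a)) / sqrt(s2 + psi(h, a) d^2).
    # The map can have several fixed points — a = 0 (psi = 1, estimate
    # pinned at the threshold) is always one, and the genuine solution
    # may sit at positive a (estimated mean below the threshold) where
    # plain iteration is captured by the spurious root. All roots of
    # f(a) = g(a) - a are therefore located by bracketed root-finding
    # over the admissible range, and the self-consistent root with the
    # highest censored log-likelihood is returned.
    g <- function(a) {
      psi <- psiCensored(h, a)
      -d * (1 - psi) / sqrt(s2 + psi * d^2)
    }
    f <- function(a) g(a) - a
    # upper end of the admissible range: psi (hence sigma2) blows up
    # where V(h, a) = a; beyond it psi < 0 and the variance can turn
    # negative
    vma <- function(a) h * millsRatio(-a) / (1 - h) - a
    a_sing <- if (vma(1e-8) > 0)
      tryCatch(uniroot(vma, c(1e-8, 1e8), tol = 1e-12)$root,
               error = function(e) Inf) else 1e-8
    a_lo <- min(8 * a0, -10)
    a_hi <- if (is.finite(a_sing)) a_sing * (1 - 1e-9) else 10
    grid <- sort(unique(c(seq(a_lo, a_hi, length.out = 512L), a0, -1e-9, 1e-9)))
    fv <- vapply(grid, function(a) tryCatch(f(a), error = function(e) NA_real_),
                 numeric(1))
    roots <- 0  # the threshold-pinned fixed point, always present
    ok <- is.finite(fv)
    for (j in which(ok[-length(ok)] & ok[-1])) {
      if (fv[j] == 0) roots <- c(roots, grid[j])
      else if (fv[j] * fv[j + 1] < 0)
        roots <- c(roots, uniroot(f, grid[c(j, j + 1)], tol = 1e-14)$root)
    }
    roots <- roots[abs(roots) > 1e-7 | roots == 0]
    best <- NULL
    for (a in roots) {
      psi <- psiCensored(h, a)
      mu <- ybar - psi * d
      sig2 <- s2 + psi * d^2
      if (!is.finite(sig2) || sig2 <= 0) next
      ll <- logLikCensoredNormal(summary, mu, sqrt(sig2))
      if (is.null(best) || ll > best$ll)
        best <- list(mu = mu, sig2 = sig2, a = a, psi = psi, ll = ll)
    }
    if (is.null(best))
      stop("fitCensoredNormal: no self-consistent solution found", call. = FALSE)
    return(mk(best$mu, best$sig2, best$a, best$psi, length(roots)))
  }
  # direct_ml: maximize over (mu, log sigma), started at the one-step
  # fit, with the analytic score for full numerical precision
  n1 <- summary$n_cens; n2 <- summary$n_obs
  nll <- function(p) -logLikCensoredNormal(summary, p[1], exp(p[2]))
  ngr <- function(p) {
    mu <- p[1]; sig <- exp(p[2])
    cc <- (lxi - mu) / sig
    wc <- exp(dnorm(cc, log = TRUE) - pnorm(cc, log.p = TRUE))  # phi/Phi
    dmu <- -n1 * wc / sig + n2 * (ybar - mu) / sig^2
    dsig <- -n1 * wc * cc / sig - n2 / sig + n2 * (s2 + (ybar - mu)^2) / sig^3
    -c(dmu, dsig * sig)
  }
  opt <- nlminb(c(mu0, 0.5 * log(sig20)), nll, gradient = ngr,
                control = list(rel.tol = 1e-15, iter.max = 1000L))
  if (opt$convergence != 0 && opt$iterations >= 1000L)
    stop("fitCensoredNormal: direct likelihood maximization did not converge; trajectory message: ",
         opt$message, call. = FALSE)
  # Newton polish on the analytic score (finite-difference Jacobian)
  p <- opt$par
  for (it in 1:20) {
    gcur <- ngr(p)
    if (max(abs(gcur)) < 1e-11) break
    eps <- 1e-6
    J <- cbind((ngr(p + c(eps, 0)) - gcur) / eps,
               (ngr(p + c(0, eps)) - gcur) / eps)
    step <- tryCatch(solve(J, gcur), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    p_new <- p - step
    if (!is.finite(nll(p_new)) || nll(p_new) > nll(p) + 1e-8) break
    p <- p_new
  }
  mu <- p[1]; sig2 <- exp(2 * p[2])
  a <- (lxi - mu) / sqrt(sig2)
  mk(mu, sig2, a, psiCensored(h, a), opt$iterations)
}

#' @export
print.censNormFit <- function(x, ...) {
  cat("censNormFit '", x$label, "' (", x$mode, "): mu_hat = ",
      format(x$mu_hat, digits = 6), ", sigma2_hat = ",
      format(x$sigma2_hat, digits = 6), "\n", sep = "")
  cat("  n = ", x$n, " (censored ", x$n_cens, "), psi_hat = ",
      format(x$psi_hat, digits = 4), ", logLik = ",
      format(x$loglik, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Mean of the fitted lognormal distribution
#'
#' \eqn{\hat\theta = \exp(\hat\mu + \hat\sigma^2/2)}, the mean of the
#' lognormal distribution on the original measurement scale implied by a
#' log-scale normal fit.
#'
#' @param est a \code{censNormFit}, or a numeric \code{mu} when
#'   \code{sigma2} is given.
#' @param sigma2 optional variance when \code{est} is numeric.
#' @return positive scalar mean estimate.
#' @export
lognormalMean <- function(est, sigma2 = NULL) {
  if (inherits(est, "censNormFit")) return(exp(est$mu_hat + est$sigma2_hat / 2))
  exp(est + sigma2 / 2)
}

#' Ratio of two lognormal mean estimates
#'
#' @param est1,est2 \code{censNormFit} objects or numeric mean estimates.
#' @return positive scalar \eqn{\hat\theta_1/\hat\theta_2}.
#' @export
ratioOfMeans <- function(est1, est2) {
  t1 <- if (inherits(est1, "censNormFit")) lognormalMean(est1) else as.numeric(est1)
  t2 <- if (inherits(est2, "censNormFit")) lognormalMean(est2) else as.numeric(est2)
  if (t2 <= 0) stop("ratioOfMeans: denominator mean must be positive", call. = FALSE)
  t1 / t2
}

#' Mean of a delta-lognormal distribution
#'
#' The delta-lognormal places mass \code{delta} at zero and is
#' lognormal\eqn{(\mu, \sigma^2)} on the positives, so its mean is
#' \eqn{\gamma = (1 - \delta)\exp(\mu + \sigma^2/2)}. Provided for
#' reference; the interval methods target the positive-part mean
#' \eqn{\theta = \exp(\mu + \sigma^2/2)}.
#'
#' @param mu,sigma2 log-scale normal parameters.
#' @param delta zero-mass probability in \eqn{[0, 1)}.
#' @return the distribution mean.
#' @export
deltaLognormalMean <- function(mu, sigma2, delta = 0) {
  if (any(delta < 0 | delta >= 1))
    stop("deltaLognormalMean: delta must lie in [0, 1)", call. = FALSE)
  (1 - delta) * exp(mu + sigma2 / 2)
}
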