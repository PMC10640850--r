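# Random delta-lognormal-style censored datasets for property tests.
# Returns a censSummary with n_obs >= min_obs, or NULL if the draw was
# too degenerate (caller skips and redraws).
randomCensoredSummary <- function(n_range = c(10, 60), min_obs = 5) {
  n <- sample(seq(n_range[1], n_range[2]), 1)
  mu <- runif(1, -1, 1)
  sig <- runif(1, 0.4, 2)
  x <- exp(rnorm(n, mu, sig))
  xi <- as.numeric(quantile(x, runif(1, 0.1, 0.65)))
  if (xi <= 0 || sum(x > xi) < min_obs) return(NULL)
  censorSplit(x, xi)
}

# An effectively-uncensored fit built from lognormal data with a
# threshold below every observation.
uncensoredFit <- function(n, mu = 0, sig = 1) {
  x <- exp(rnorm(n, mu, sig))
  fitCensoredNormal(censorSplit(x, min(x) / 2))
}
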