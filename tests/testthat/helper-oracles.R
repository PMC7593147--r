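# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: moments come from numerical integration or direct
# summation, and the REML oracle maximizes the restricted likelihood by
# golden-section search.

# truncated-normal mean by numerical integration of x * density
oracle_truncnorm_mean <- function(mean, sd, lower, upper) {
  z <- stats::pnorm(upper, mean, sd) - stats::pnorm(lower, mean, sd)
  stats::integrate(function(x) x * stats::dnorm(x, mean, sd) / z,
                   lower = max(lower, mean - 12 * sd),
                   upper = min(upper, mean + 12 * sd))$value
}

# conditional mean of Poisson(lambda) given X >= lower, by direct summation
oracle_truncpois_mean <- function(lambda, lower) {
  k <- lower:max(200, ceiling(lambda + 20 * sqrt(lambda)))
  p <- stats::dpois(k, lambda)
  sum(k * p) / sum(p)
}

# restricted log-likelihood of the random-effects model, profiled over mu
oracle_reml_loglik <- function(tau2, yi, vi) {
  w <- 1 / (vi + tau2)
  mu <- sum(w * yi) / sum(w)
  -0.5 * (sum(log(vi + tau2)) + log(sum(w)) + sum(w * (yi - mu)^2))
}

oracle_reml_tau2 <- function(yi, vi) {
  upper <- max(1e-6, 10 * stats::var(yi))
  stats::optimize(oracle_reml_loglik, c(0, upper), yi = yi, vi = vi,
                  maximum = TRUE, tol = 1e-10)$maximum
}

# a small complete mean-difference table with hand-chosen values
tiny_md_data <- function() {
  data.frame(
    mean_c = c(1.0, 1.2, 0.8, 1.5, 1.1, 0.9),
    mean_t = c(2.0, 1.8, 1.6, 2.5, 2.2, 1.7),
    sd_c   = c(0.25, 0.30, 0.20, 0.40, 0.35, 0.15),
    sd_t   = c(0.50, 0.45, 0.35, 0.60, 0.55, 0.30),
    n_c    = c(10, 8, 12, 6, 9, 11),
    n_t    = c(10, 9, 11, 7, 8, 12)
  )
}
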