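#' Sample from a truncated normal distribution
#'
#' Draws by inverse-CDF on the truncated probability interval, so sampling is
#' exact, vectorized and has deterministic cost even under extreme truncation.
#'
#' @param n Number of draws.
#' @param mean,sd Mean and standard deviation of the parent normal; `sd = 0`
#'   is the degenerate point mass at `mean` (which must lie inside the bounds).
#' @param lower,upper Truncation bounds; `-Inf`/`Inf` for one-sided or no
#'   truncation. `lower < upper` is required.
#' @return Numeric vector of length `n`, all values in `[lower, upper]`.
#' @examples
#' set.seed(1)
#' range(rtruncnorm(1000, mean = 0.25, sd = 0.125, lower = 0.01, upper = 1))
#' @export
rtruncnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  if (length(n) != 1L || is.na(n) || n < 0) stop("'n' must be a single count >= 0")
  if (sd < 0) stop("'sd' must be >= 0")
  if (!(lower < upper)) stop("invalid truncation bounds: 'lower' must be < 'upper'")
  if (n == 0) return(numeric(0))
  if (sd == 0) {
    if (mean < lower || mean > upper) {
      stop("degenerate distribution: 'mean' lies outside the truncation bounds")
    }
    return(rep(mean, n))
  }
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  # clamp guards against qnorm rounding at extreme tail probabilities
  pmin(pmax(stats::qnorm(u, mean, sd), lower), upper)
}

#' Mean of a truncated normal distribution
#'
#' Closed-form first moment of the parent normal conditioned on
#' `[lower, upper]`; used to parameterize generators and to reason about
#' truncation bias of the simulated quantities.
#'
#' @inheritParams rtruncnorm
#' @return The analytic mean of the truncated distribution.
#' @export
truncnorm_mean <- function(mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  if (!(lower < upper)) stop("invalid truncation bounds")
  if (sd == 0) return(mean)
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

#' Sample from a lower-truncated Poisson distribution
#'
#' Poisson(`lambda`) conditioned on `X >= lower`, drawn by inverse-CDF on the
#' truncated probability interval.
#'
#' @param n Number of draws.
#' @param lambda Poisson rate, `> 0`.
#' @param lower Lower truncation bound (integer `>= 0`); `0` recovers the
#'   untruncated distribution.
#' @return Integer vector of length `n`, all values `>= lower`.
#' @examples
#' set.seed(1)
#' min(rtruncpois(1000, lambda = 10, lower = 5))
#' @export
rtruncpois <- function(n, lambda, lower = 0) {
  if (length(n) != 1L || is.na(n) || n < 0) stop("'n' must be a single count >= 0")
  if (!is.finite(lambda) || lambda <= 0) stop("'lambda' must be > 0")
  if (lower < 0) stop("'lower' must be >= 0")
  if (n == 0) return(integer(0))
  p0 <- if (lower > 0) stats::ppois(lower - 1, lambda) else 0
  u <- stats::runif(n, p0, 1)
  as.integer(stats::qpois(u, lambda))
}
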