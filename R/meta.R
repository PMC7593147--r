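## Random-effects fits are delegated to metafor's rma.uni (REML), the
## standard tool for intercept-only inverse-variance meta-analysis; this file
## wraps it in the package's estimate container and adds Rubin pooling.

z_crit <- function() stats::qnorm(0.975)

fit_rma <- function(yi, vi) {
  fit <- tryCatch(
    suppressWarnings(metafor::rma.uni(yi = yi, vi = vi, method = "REML",
                                      control = list(maxiter = 2000, threshold = 1e-8))),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    # step-halved retry for hard instances; give up with an informative error
    fit <- tryCatch(
      suppressWarnings(metafor::rma.uni(yi = yi, vi = vi, method = "REML",
                                        control = list(maxiter = 5000, stepadj = 0.25))),
      error = function(e) stop("REML fit failed to converge: ", conditionMessage(e))
    )
  }
  fit
}

#' REML estimate of the between-study variance
#'
#' Restricted maximum-likelihood estimate of tau-squared for the
#' random-effects model `yi ~ N(mu, vi + tau^2)`.
#'
#' @param yi Effect estimates (finite, length `>= 2`).
#' @param vi Sampling variances, all `> 0`.
#' @return Non-negative tau-squared estimate.
#' @export
reml_tau2 <- function(yi, vi) {
  check_meta_input(yi, vi)
  fit_rma(yi, vi)$tau2
}

check_meta_input <- function(yi, vi) {
  if (length(yi) < 2) stop("at least 2 effect sizes are required")
  if (length(vi) != length(yi)) stop("'yi' and 'vi' must have equal length")
  if (!all(is.finite(yi)) || !all(is.finite(vi))) stop("non-finite effect sizes or variances")
  if (any(vi <= 0)) stop("all sampling variances must be > 0")
  invisible(TRUE)
}

#' Fit the intercept-only random-effects meta-analysis
#'
#' Estimates tau-squared by REML and the grand mean by inverse-variance
#' weighting with weights `1 / (vi + tau^2)`; the 95% confidence interval
#' uses the normal approximation `mu -/+ 1.96 se`. Passing `vi = NULL` gives
#' the unweighted analysis: all sampling variances set to one, heterogeneity
#' still estimated.
#'
#' @param yi Effect estimates.
#' @param vi Sampling variances, or `NULL` for unit weights.
#' @return An object of class `"meta_estimate"`: a list with `mu`, `se`,
#'   `ci_low`, `ci_high`, `tau2` and `k`.
#' @export
random_effects_fit <- function(yi, vi = NULL) {
  if (is.null(vi)) vi <- rep(1, length(yi))
  check_meta_input(yi, vi)
  fit <- fit_rma(yi, vi)
  mu <- as.numeric(fit$beta)
  se <- as.numeric(fit$se)
  structure(
    list(mu = mu, se = se,
         ci_low = mu - z_crit() * se, ci_high = mu + z_crit() * se,
         tau2 = fit$tau2, k = length(yi)),
    class = "meta_estimate"
  )
}

#' @export
print.meta_estimate <- function(x, ...) {
  cat(sprintf("Random-effects estimate (k = %d)\n", x$k))
  cat(sprintf("  mu = %.4f  se = %.4f  95%% CI [%.4f, %.4f]  tau2 = %.4f\n",
              x$mu, x$se, x$ci_low, x$ci_high, x$tau2))
  invisible(x)
}

#' Pool estimates from multiply imputed data sets by Rubin's rules
#'
#' Combines `m` per-imputation estimates: the pooled point estimate is the
#' mean of the `mu_j`, the total variance is the mean within-imputation
#' variance plus `(1 + 1/m)` times the between-imputation variance of the
#' `mu_j`, and the 95% interval is the normal approximation around the pooled
#' mean. Estimates with non-finite components (failed imputations) are
#' dropped and `m_used` records how many entered the pool.
#'
#' @param estimates A list of [random_effects_fit()] results, or a data frame
#'   with columns `mu` and `se`.
#' @return An object of class `"pooled_estimate"`: a list with `mu`, `se`
#'   (total), `ci_low`, `ci_high`, `within_var`, `between_var` and `m_used`.
#' @export
rubin_pool <- function(estimates) {
  if (is.data.frame(estimates)) {
    mu <- estimates$mu
    se <- estimates$se
  } else {
    mu <- vapply(estimates, function(e) e$mu, numeric(1))
    se <- vapply(estimates, function(e) e$se, numeric(1))
  }
  ok <- is.finite(mu) & is.finite(se)
  mu <- mu[ok]
  se <- se[ok]
  m <- length(mu)
  if (m == 0) stop("no usable estimates to pool")
  mu_bar <- mean(mu)
  within <- mean(se^2)
  between <- if (m > 1) stats::var(mu) else 0
  se_total <- sqrt(within + (1 + 1 / m) * between)
  structure(
    list(mu = mu_bar, se = se_total,
         ci_low = mu_bar - z_crit() * se_total,
         ci_high = mu_bar + z_crit() * se_total,
         within_var = within, between_var = between, m_used = m),
    class = "pooled_estimate"
  )
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("Rubin-pooled estimate (m = %d)\n", x$m_used))
  cat(sprintf("  mu = %.4f  se = %.4f  95%% CI [%.4f, %.4f]\n",
              x$mu, x$se, x$ci_low, x$ci_high))
  cat(sprintf("  within var = %.5f  between var = %.5f\n",
              x$within_var, x$between_var))
  invisible(x)
}
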