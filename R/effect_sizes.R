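#' Small-sample bias-corrected log response ratio
#'
#' With `correction = TRUE` (the default) returns the bias-corrected log
#' response ratio and its sampling variance:
#' \deqn{y = \ln(m_t/m_c) + \tfrac12\left[\frac{sd_t^2}{n_t m_t^2} -
#'   \frac{sd_c^2}{n_c m_c^2}\right]}
#' \deqn{v = \frac{sd_t^2}{n_t m_t^2} + \frac{sd_c^2}{n_c m_c^2} +
#'   \tfrac12\left[\frac{sd_t^4}{n_t^2 m_t^4} +
#'   \frac{sd_c^4}{n_c^2 m_c^4}\right]}
#' With `correction = FALSE` returns the simple log ratio `ln(m_t/m_c)` and a
#' missing variance; this is the computable form when SDs or sample sizes are
#' unreported. Rows with missing inputs yield missing outputs rather than
#' errors; non-positive means are a domain error.
#'
#' @param mean_c,mean_t Group means, `> 0`.
#' @param sd_c,sd_t Group standard deviations (ignored when
#'   `correction = FALSE`).
#' @param n_c,n_t Group sample sizes (ignored when `correction = FALSE`).
#' @param correction Apply the small-sample bias correction and compute the
#'   sampling variance?
#' @return A data frame with columns `yi` and `vi`.
#' @export
lnrr <- function(mean_c, mean_t, sd_c = NULL, sd_t = NULL, n_c = NULL, n_t = NULL,
                 correction = TRUE) {
  if (any(!is.na(mean_c) & mean_c <= 0) || any(!is.na(mean_t) & mean_t <= 0)) {
    stop("log response ratio requires strictly positive group means")
  }
  if (!correction) {
    yi <- log(mean_t / mean_c)
    return(data.frame(yi = yi, vi = rep(NA_real_, length(yi))))
  }
  tc <- sd_c^2 / (n_c * mean_c^2)
  tt <- sd_t^2 / (n_t * mean_t^2)
  yi <- log(mean_t / mean_c) + 0.5 * (tt - tc)
  vi <- tt + tc + 0.5 * (tt^2 + tc^2)
  data.frame(yi = yi, vi = vi)
}

#' Hedges' d standardized mean difference
#'
#' Pooled-SD standardized difference with the small-sample correction factor
#' `J = 1 - 3 / (4(n_c + n_t - 2) - 1)` and sampling variance
#' `(n_c + n_t)/(n_c n_t) + d^2 / (2(n_c + n_t))`. Rows with missing inputs
#' yield missing outputs; a zero pooled SD is a domain error.
#'
#' @param mean_c,mean_t Group means.
#' @param sd_c,sd_t Group standard deviations.
#' @param n_c,n_t Group sample sizes.
#' @return A data frame with columns `yi` and `vi`.
#' @export
hedges_d <- function(mean_c, mean_t, sd_c, sd_t, n_c, n_t) {
  sp2 <- ((n_c - 1) * sd_c^2 + (n_t - 1) * sd_t^2) / (n_c + n_t - 2)
  if (any(!is.na(sp2) & sp2 <= 0)) {
    stop("Hedges' d requires a positive pooled standard deviation")
  }
  j <- 1 - 3 / (4 * (n_c + n_t - 2) - 1)
  yi <- j * (mean_t - mean_c) / sqrt(sp2)
  vi <- (n_c + n_t) / (n_c * n_t) + yi^2 / (2 * (n_c + n_t))
  data.frame(yi = yi, vi = vi)
}

#' Fisher's z-transformed correlation
#'
#' `yi = artanh(r)` with sampling variance `1/(n - 3)`. The transform itself
#' does not need a sample size, so rows with missing `n` get a finite `yi`
#' and a missing `vi`; `|r| >= 1` or a reported `n <= 3` are domain errors.
#'
#' @param r Correlation coefficients, strictly inside `(-1, 1)`.
#' @param n Study sample sizes.
#' @return A data frame with columns `yi` and `vi`.
#' @export
fishers_z <- function(r, n) {
  if (any(!is.na(r) & abs(r) >= 1)) {
    stop("Fisher's z requires |r| < 1")
  }
  if (any(!is.na(n) & n <= 3)) {
    stop("Fisher's z variance requires n > 3")
  }
  data.frame(yi = atanh(r), vi = 1 / (n - 3))
}

#' Sample-size approximation of the effect-size variance
#'
#' `(n_t + n_c) / (n_t * n_c)`: the variance surrogate used when only sample
#' sizes are reported. Symmetric in its arguments and strictly decreasing in
#' each.
#'
#' @param n_c,n_t Group sample sizes, `>= 1`; missing values propagate.
#' @return Numeric vector of approximate variances.
#' @export
ss_approx_variance <- function(n_c, n_t) {
  if (any(!is.na(n_c) & n_c < 1) || any(!is.na(n_t) & n_t < 1)) {
    stop("sample sizes must be >= 1")
  }
  (n_t + n_c) / (n_t * n_c)
}

#' Effect sizes and sampling variances for a meta-analysis table
#'
#' Computes the chosen effect size for every row. With `fallback = TRUE` the
#' log response ratio falls back, row by row, to the simple uncorrected ratio
#' wherever SDs or sample sizes are unreported (the corrected form and its
#' variance need both); the variance stays missing for those rows. Missing
#' inputs otherwise propagate to missing `yi`/`vi`.
#'
#' @param data A meta-analysis data frame (possibly with missing cells).
#' @param measure `"lnrr"`, `"hedges_d"` or `"fishers_z"`; the latter only
#'   for correlation data, the former two only for mean-difference data.
#' @param fallback Use the simple log ratio where the corrected one is not
#'   computable (only affects `measure = "lnrr"`).
#' @return A data frame with one `yi`, `vi` row per study.
#' @export
effect_sizes <- function(data, measure = c("lnrr", "hedges_d", "fishers_z"),
                         fallback = FALSE) {
  measure <- match.arg(measure)
  kind <- dataset_kind(data)
  if (measure == "fishers_z") {
    if (kind != "correlation") stop("Fisher's z requires a correlation data set")
    return(fishers_z(data$r, data$n))
  }
  if (kind != "mean_difference") {
    stop("'", measure, "' requires a mean-difference data set")
  }
  if (measure == "lnrr") {
    es <- lnrr(data$mean_c, data$mean_t, data$sd_c, data$sd_t, data$n_c, data$n_t)
    if (fallback) {
      miss <- is.na(es$yi)
      es$yi[miss] <- log(data$mean_t[miss] / data$mean_c[miss])
    }
    es
  } else {
    hedges_d(data$mean_c, data$mean_t, data$sd_c, data$sd_t, data$n_c, data$n_t)
  }
}
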