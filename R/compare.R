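#' Compare all applicable treatments on a user-supplied meta-analysis table
#'
#' Runs every treatment option that applies to the supplied (possibly
#' incomplete) meta-analysis table and tabulates the resulting grand means
#' and confidence intervals, so the sensitivity of one's own meta-analysis to
#' the handling of missing SDs/sample sizes can be assessed directly. There
#' is no fully informed reference here — with real data the complete values
#' are unknown — so the table reports the estimates themselves.
#'
#' @param data A meta-analysis data frame (columns
#'   `mean_c, mean_t, sd_c, sd_t, n_c, n_t` or `r, n`), missing cells as
#'   `NA`.
#' @param measure Effect size, see [effect_sizes()]; defaults to the first
#'   one the data support.
#' @param options Treatment option ids (default all 14).
#' @param m Imputations per multiple-imputation option (default 100).
#' @param seed Optional integer seed.
#' @param ... Passed on to [impute_missing()].
#' @return A data frame with one row per option: estimate, interval, `k`,
#'   `m_used`, `status` and `reason`.
#' @export
compare_treatments <- function(data, measure = NULL, options = 1:14, m = 100,
                               seed = NULL, ...) {
  kind <- dataset_kind(data)
  if (is.null(measure)) measure <- es_measures(kind)[1]
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(options, function(option) {
    opt <- resolve_option(option)
    res <- run_treatment(data, opt$id, measure, m = m,
                         seed = if (is.null(seed)) NULL
                                else derive_seed(seed, "compare", opt$id),
                         ...)
    data.frame(option_id = opt$id, option = opt$key, label = opt$label,
               measure = measure, status = res$status, mu = res$mu,
               se = res$se, ci_low = res$ci_low, ci_high = res$ci_high,
               k = res$k, m_used = res$m_used, reason = res$reason)
  })
  do.call(rbind, rows)
}
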