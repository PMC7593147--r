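#' The fourteen treatment options for missing SDs and sample sizes
#'
#' @return A data frame with one row per option: `id` (1-14), `key` (the
#'   method key used programmatically), `label`, and `class`
#'   (`"analysis"` for options that refit on the incomplete data,
#'   `"single"`/`"multiple"` for imputation options).
#' @export
treatment_options <- function() {
  data.frame(
    id = 1:14,
    key = c("complete_case", "unweighted", "ss_weighted", "mean", "median",
            "random_sample", "linear_regression", "pmm", "cart",
            "random_forest", "bayes_pmm", "bootstrap_em", "missforest",
            "addreg_boot_pmm"),
    label = c("Complete-case analysis", "Unweighted analysis",
              "Sample-size weighted analysis", "Mean value imputation",
              "Median value imputation", "MICE random sample",
              "MICE linear regression", "MICE predictive mean matching",
              "MICE classification and regression trees", "MICE random forest",
              "Bayes predictive mean matching",
              "Bootstrap expectation maximization",
              "Nonparametric random forest",
              "Additive regression with bootstrap PMM"),
    class = c("analysis", "analysis", "analysis", "single", "single",
              rep("multiple", 9))
  )
}

resolve_option <- function(option) {
  opts <- treatment_options()
  if (is.numeric(option)) {
    row <- opts[opts$id == option, ]
  } else {
    row <- opts[opts$key == option, ]
  }
  if (nrow(row) != 1) stop("unknown treatment option: ", option)
  row
}

# deterministic 31-bit hash so every factorial cell gets its own decoupled
# seed from the master seed
derive_seed <- function(master, ...) {
  key <- paste(c(master, ...), collapse = "|")
  h <- 7
  for (cc in utf8ToInt(key)) h <- (h * 131 + cc) %% 2147483629
  as.integer(h + 1)
}

es_measures <- function(kind) {
  if (kind == "correlation") "fishers_z" else c("lnrr", "hedges_d")
}

treatment_result <- function(status, est = NULL, k = NA_integer_,
                             m_used = NA_integer_, reason = NA_character_) {
  list(status = status,
       mu = if (is.null(est)) NA_real_ else est$mu,
       se = if (is.null(est)) NA_real_ else est$se,
       ci_low = if (is.null(est)) NA_real_ else est$ci_low,
       ci_high = if (is.null(est)) NA_real_ else est$ci_high,
       k = k, m_used = m_used, reason = reason)
}

#' Fully informed weighted meta-analysis of a complete data set
#'
#' The reference analysis all treatments are compared against: effect sizes
#' and sampling variances from the complete data, inverse-variance REML fit.
#'
#' @param data A complete meta-analysis data frame.
#' @param measure Effect size, see [effect_sizes()].
#' @return A [random_effects_fit()] estimate.
#' @export
fully_informed_reference <- function(data, measure) {
  if (anyNA(data)) stop("the fully informed reference requires complete data")
  es <- effect_sizes(data, measure)
  random_effects_fit(es$yi, es$vi)
}

fit_weighted <- function(data, measure) {
  es <- effect_sizes(data, measure)
  keep <- is.finite(es$yi) & is.finite(es$vi)
  if (sum(keep) < 2) stop("fewer than 2 usable effect sizes")
  list(est = random_effects_fit(es$yi[keep], es$vi[keep]), k = sum(keep))
}

#' Apply one treatment option to an incomplete data set
#'
#' Options 1-3 refit directly: complete-case drops rows missing any field the
#' effect size needs; unweighted fits with unit weights on every row whose
#' effect size is computable (the log response ratio falls back to its
#' uncorrected form); sample-size weighting uses `(n_t + n_c)/(n_t n_c)` as
#' the variance (for Fisher's z, `1/(n - 3)`) on rows with reported sample
#' sizes, and is not applicable to Hedges' d, whose computation itself needs
#' the missing values. Options 4-5 single-impute and refit. Options 6-14
#' produce `m` completed data sets, fit each, and pool by Rubin's rules.
#'
#' @param data An incomplete meta-analysis data frame.
#' @param option Option id (1-14) or key, see [treatment_options()].
#' @param measure Effect size, see [effect_sizes()].
#' @param m Number of imputations for the multiple methods.
#' @param seed Optional integer seed.
#' @param ... Passed on to [impute_missing()].
#' @return A list with `status` (`"ok"`, `"skipped"` or `"failed"`), `mu`,
#'   `se`, `ci_low`, `ci_high`, `k` (effect sizes in the fit), `m_used` and
#'   `reason`.
#' @export
run_treatment <- function(data, option, measure, m = 100, seed = NULL, ...) {
  opt <- resolve_option(option)
  kind <- dataset_kind(data)
  if (!(measure %in% es_measures(kind))) {
    stop("measure '", measure, "' does not apply to ", kind, " data")
  }
  if (!is.null(seed)) set.seed(seed)
  if (opt$key == "ss_weighted" && measure == "hedges_d") {
    return(treatment_result("skipped",
      reason = "sample-size weighting is not applicable to Hedges' d"))
  }
  out <- tryCatch({
    if (opt$key == "complete_case") {
      keep <- stats::complete.cases(data)
      fit <- fit_weighted(data[keep, , drop = FALSE], measure)
      treatment_result("ok", fit$est, k = fit$k)
    } else if (opt$key == "unweighted") {
      es <- effect_sizes(data, measure, fallback = TRUE)
      keep <- is.finite(es$yi)
      if (sum(keep) < 2) stop("fewer than 2 computable effect sizes")
      est <- random_effects_fit(es$yi[keep], vi = NULL)
      treatment_result("ok", est, k = sum(keep))
    } else if (opt$key == "ss_weighted") {
      es <- effect_sizes(data, measure, fallback = TRUE)
      vi <- if (kind == "correlation") 1 / (data$n - 3)
            else ss_approx_variance(data$n_c, data$n_t)
      keep <- is.finite(es$yi) & is.finite(vi)
      if (sum(keep) < 2) stop("fewer than 2 usable effect sizes")
      est <- random_effects_fit(es$yi[keep], vi[keep])
      treatment_result("ok", est, k = sum(keep))
    } else if (opt$class == "single") {
      fit <- fit_weighted(impute_single(data, opt$key), measure)
      treatment_result("ok", fit$est, k = fit$k, m_used = 1L)
    } else {
      res <- impute_missing(data, opt$key, m = m, ...)
      if (res$status != "ok") {
        treatment_result(res$status, reason = res$reason %||%
                           paste(res$failures, collapse = "; "))
      } else {
        fits <- lapply(completed_datasets(res), function(d) {
          tryCatch(fit_weighted(d, measure), error = function(e) NULL)
        })
        fits <- fits[!vapply(fits, is.null, logical(1))]
        if (length(fits) == 0) stop("all per-imputation fits failed")
        pooled <- rubin_pool(lapply(fits, `[[`, "est"))
        treatment_result("ok", pooled, k = fits[[1]]$k, m_used = pooled$m_used)
      }
    }
  }, error = function(e) treatment_result("failed", reason = conditionMessage(e)))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default fraction grid: 16 deletion steps from 10% to 90%
#' @return Numeric vector of 16 deletion fractions.
#' @export
default_fractions <- function() seq(0.1, 0.9, length.out = 16)

#' Enumerate the factorial design of incomplete data sets
#'
#' One row per incomplete data set to be created: scenario x deleted-data
#' type (SD, SS or BOTH for mean-difference replicates; SS for correlation
#' replicates) x replicate x deletion fraction. The default design (4
#' scenarios, 10 replicates of each kind, 16 fractions) enumerates 2,560
#' data sets.
#'
#' @param scenarios Missingness scenarios.
#' @param n_replicates Replicate data sets per kind.
#' @param fractions Deletion fraction grid.
#' @param md_targets Deleted-data types for mean-difference replicates.
#' @param kinds Data set kinds to include.
#' @return A data frame with columns `scenario`, `kind`, `target`,
#'   `replicate`, `fraction`.
#' @export
plan_factorial <- function(scenarios = c("MCAR", "MAR", "MNAR", "corMCAR"),
                           n_replicates = 10,
                           fractions = default_fractions(),
                           md_targets = c("SD", "SS", "BOTH"),
                           kinds = c("mean_difference", "correlation")) {
  types <- rbind(
    if ("mean_difference" %in% kinds) {
      expand.grid(kind = "mean_difference", target = md_targets,
                  replicate = seq_len(n_replicates), stringsAsFactors = FALSE)
    },
    if ("correlation" %in% kinds) {
      expand.grid(kind = "correlation", target = "SS",
                  replicate = seq_len(n_replicates), stringsAsFactors = FALSE)
    }
  )
  plan <- merge(merge(data.frame(scenario = scenarios), types, by = NULL),
                data.frame(fraction = fractions), by = NULL)
  plan[order(plan$scenario, plan$kind, plan$target, plan$replicate,
             plan$fraction), , drop = FALSE]
}

#' Run the factorial simulation experiment
#'
#' For every cell of [plan_factorial()] and every requested treatment option
#' and effect size: simulate (or reuse) the replicate's complete data set,
#' re-pair it for the corMCAR scenario, delete SDs/SSs, apply the treatment,
#' and record the deviation of the grand mean and of the confidence-interval
#' width from the replicate-matched fully informed reference. Per-cell seeds
#' are derived from `master_seed`, so reruns are reproducible and cells are
#' decoupled. Individual cell failures are recorded, never aborting the
#' sweep.
#'
#' @param scenarios,n_replicates,fractions,md_targets,kinds Design, see
#'   [plan_factorial()].
#' @param options Treatment option ids to apply (default all 14).
#' @param measures Effect sizes to compute, or `NULL` for all the data kind
#'   supports.
#' @param n_studies Studies per data set (default 100).
#' @param m Imputations per multiple-imputation treatment (default 100; the
#'   full published design — consider 5 for exploration).
#' @param master_seed Integer master seed.
#' @param md_params,cor_params Generator settings, see [md_params()] and
#'   [cor_params()].
#' @param ... Passed on to [impute_missing()].
#' @return A deviation-record data frame: one row per cell x option x effect
#'   size with the estimate, the reference, `dev_mu` and `dev_ci_width`, and
#'   a `status` field.
#' @export
run_factorial <- function(scenarios = c("MCAR", "MAR", "MNAR", "corMCAR"),
                          n_replicates = 10,
                          fractions = default_fractions(),
                          md_targets = c("SD", "SS", "BOTH"),
                          kinds = c("mean_difference", "correlation"),
                          options = 1:14,
                          measures = NULL,
                          n_studies = 100,
                          m = 100,
                          master_seed = 1,
                          md_params = metamiss::md_params(),
                          cor_params = metamiss::cor_params(),
                          ...) {
  plan <- plan_factorial(scenarios, n_replicates, fractions, md_targets, kinds)
  base_data <- list()
  refs <- list()
  records <- vector("list", 0)
  for (i in seq_len(nrow(plan))) {
    cell <- plan[i, ]
    dkey <- paste(cell$kind, cell$replicate)
    if (is.null(base_data[[dkey]])) {
      dseed <- derive_seed(master_seed, "data", cell$kind, cell$replicate)
      base_data[[dkey]] <- if (cell$kind == "mean_difference") {
        simulate_md_data(n_studies, md_params, seed = dseed)
      } else {
        simulate_cor_data(n_studies, cor_params, seed = dseed)
      }
    }
    complete <- base_data[[dkey]]
    if (cell$scenario == "corMCAR") complete <- sort_cormcar(complete)
    inc <- apply_deletion(complete, cell$scenario, cell$target, cell$fraction,
                          seed = derive_seed(master_seed, "delete", cell$scenario,
                                             cell$kind, cell$target,
                                             cell$replicate, cell$fraction))
    cell_measures <- es_measures(cell$kind)
    if (!is.null(measures)) cell_measures <- intersect(cell_measures, measures)
    for (measure in cell_measures) {
      rkey <- paste(dkey, cell$scenario == "corMCAR", measure)
      if (is.null(refs[[rkey]])) {
        refs[[rkey]] <- fully_informed_reference(complete, measure)
      }
      ref <- refs[[rkey]]
      for (option in options) {
        opt <- resolve_option(option)
        res <- run_treatment(inc, opt$id, measure, m = m,
                             seed = derive_seed(master_seed, "treat",
                                                cell$scenario, cell$kind,
                                                cell$target, cell$replicate,
                                                cell$fraction, opt$id, measure),
                             ...)
        records[[length(records) + 1L]] <- data.frame(
          scenario = cell$scenario, kind = cell$kind, deleted = cell$target,
          fraction = cell$fraction, replicate = cell$replicate,
          measure = measure, option_id = opt$id, option = opt$key,
          status = res$status, mu = res$mu, se = res$se,
          ci_low = res$ci_low, ci_high = res$ci_high,
          k = res$k, m_used = res$m_used,
          ref_mu = ref$mu, ref_ci_width = ref$ci_high - ref$ci_low,
          dev_mu = res$mu - ref$mu,
          dev_ci_width = (res$ci_high - res$ci_low) - (ref$ci_high - ref$ci_low),
          reason = res$reason
        )
      }
    }
  }
  do.call(rbind, records)
}

#' Average deviation records over replicates
#'
#' Aggregates `dev_mu` and `dev_ci_width` over `replicate` for every
#' scenario x deleted-type x fraction x effect-size x option combination,
#' using successful records only.
#'
#' @param records Output of [run_factorial()].
#' @return A data frame of replicate means with an `n_ok` count.
#' @export
summarize_deviation <- function(records) {
  if (is.null(records) || nrow(records) == 0) stop("no deviation records")
  ok <- records[records$status == "ok", , drop = FALSE]
  if (nrow(ok) == 0) stop("no successful deviation records")
  agg <- stats::aggregate(
    cbind(dev_mu, dev_ci_width) ~ scenario + kind + deleted + fraction +
      measure + option_id + option,
    data = ok, FUN = mean
  )
  cnt <- stats::aggregate(
    cbind(n_ok = replicate) ~ scenario + kind + deleted + fraction +
      measure + option_id + option,
    data = ok, FUN = length
  )
  out <- merge(agg, cnt)
  out[order(out$scenario, out$measure, out$deleted, out$option_id,
            out$fraction), , drop = FALSE]
}
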