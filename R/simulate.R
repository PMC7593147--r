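## Column layout of the two data set kinds:
##   mean difference: mean_c, mean_t, sd_c, sd_t, n_c, n_t
##   correlation:     r, n
## Kind is inferred from the columns throughout the package.

#' Infer the kind of a meta-analysis data set
#'
#' @param data A data frame in one of the two package layouts.
#' @return `"mean_difference"` or `"correlation"`.
#' @export
dataset_kind <- function(data) {
  if (all(c("mean_c", "mean_t", "sd_c", "sd_t", "n_c", "n_t") %in% names(data))) {
    "mean_difference"
  } else if (all(c("r", "n") %in% names(data))) {
    "correlation"
  } else {
    stop("not a recognized meta-analysis table: expected columns ",
         "mean_c, mean_t, sd_c, sd_t, n_c, n_t or r, n")
  }
}

#' Default generating distributions for mean-difference data sets
#'
#' Control-group means come from TN(1, 0.25) bounded below at 0.001 and
#' treatment-group means from TN(2, 0.5) likewise, so both groups are strictly
#' positive and the log response ratio is defined. Control and treatment SDs
#' come from TN(0.25, 0.125) and TN(0.5, 0.25) on [0.01, 1]; group sample
#' sizes from a Poisson(10) truncated below at 5.
#'
#' @return A named list of distribution specifications.
#' @export
md_params <- function() {
  list(
    mean_c = list(mean = 1,    sd = 0.25,  lower = 0.001, upper = Inf),
    mean_t = list(mean = 2,    sd = 0.5,   lower = 0.001, upper = Inf),
    sd_c   = list(mean = 0.25, sd = 0.125, lower = 0.01,  upper = 1),
    sd_t   = list(mean = 0.5,  sd = 0.25,  lower = 0.01,  upper = 1),
    n      = list(lambda = 10, lower = 5)
  )
}

#' Default generating distributions for correlation data sets
#'
#' Correlation coefficients from TN(0.5, 0.125) on [-1, 1]; sample sizes from
#' a Poisson(10) truncated below at 5.
#'
#' @return A named list of distribution specifications.
#' @export
cor_params <- function() {
  list(
    r = list(mean = 0.5, sd = 0.125, lower = -1, upper = 1),
    n = list(lambda = 10, lower = 5)
  )
}

#' Simulate a complete mean-difference meta-analysis data set
#'
#' Each row is one hypothetical two-group study with its own group means,
#' standard deviations and sample sizes, drawn independently from the
#' truncated distributions in `params`.
#'
#' @param n_studies Number of studies (rows); default 100.
#' @param params Distribution specifications, see [md_params()].
#' @param seed Optional integer seed set before drawing.
#' @return A data frame with columns `mean_c, mean_t, sd_c, sd_t, n_c, n_t`.
#' @examples
#' head(simulate_md_data(10, seed = 1))
#' @export
simulate_md_data <- function(n_studies = 100, params = md_params(), seed = NULL) {
  if (n_studies < 0) stop("'n_studies' must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  p <- params
  tn <- function(sp) rtruncnorm(n_studies, sp$mean, sp$sd, sp$lower, sp$upper)
  data.frame(
    mean_c = tn(p$mean_c),
    mean_t = tn(p$mean_t),
    sd_c   = tn(p$sd_c),
    sd_t   = tn(p$sd_t),
    n_c    = rtruncpois(n_studies, p$n$lambda, p$n$lower),
    n_t    = rtruncpois(n_studies, p$n$lambda, p$n$lower)
  )
}

#' Simulate a complete correlation meta-analysis data set
#'
#' @param n_studies Number of studies (rows); default 100.
#' @param params Distribution specifications, see [cor_params()].
#' @param seed Optional integer seed set before drawing.
#' @return A data frame with columns `r, n`.
#' @export
simulate_cor_data <- function(n_studies = 100, params = cor_params(), seed = NULL) {
  if (n_studies < 0) stop("'n_studies' must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    r = rtruncnorm(n_studies, params$r$mean, params$r$sd, params$r$lower, params$r$upper),
    n = rtruncpois(n_studies, params$n$lambda, params$n$lower)
  )
}

#' Re-pair a complete data set so effect sizes correlate with precision
#'
#' Builds the effect-size-correlated scenario: larger effect sizes are paired
#' with smaller SDs and larger sample sizes. The (mean_c, mean_t) pairs are
#' ranked by their raw log ratio descending, the (sd_c, sd_t) pairs by their
#' sum ascending and the (n_c, n_t) pairs by their sum descending, then the
#' three families are zipped row by row. For correlation data, r descending is
#' paired with n descending. Each column family keeps its multiset of values:
#' the operation is a pure re-pairing.
#'
#' The ordering uses the raw (uncorrected) log ratio so that the pairing does
#' not depend on the SDs being re-paired.
#'
#' @param data A complete data set from [simulate_md_data()] or
#'   [simulate_cor_data()].
#' @return A data frame of the same shape with rows re-paired.
#' @export
sort_cormcar <- function(data) {
  if (anyNA(data)) stop("sort_cormcar() requires a complete data set")
  kind <- dataset_kind(data)
  if (kind == "mean_difference") {
    es <- log(data$mean_t / data$mean_c)
    means <- data[order(es, decreasing = TRUE), c("mean_c", "mean_t"), drop = FALSE]
    sds   <- data[order(data$sd_c + data$sd_t), c("sd_c", "sd_t"), drop = FALSE]
    ns    <- data[order(data$n_c + data$n_t, decreasing = TRUE),
                  c("n_c", "n_t"), drop = FALSE]
    out <- cbind(means, sds, ns)
  } else {
    out <- data.frame(
      r = sort(data$r, decreasing = TRUE),
      n = sort(data$n, decreasing = TRUE)
    )
  }
  rownames(out) <- NULL
  out
}

#' Write a meta-analysis table to CSV
#'
#' Missing cells are written as empty fields.
#'
#' @param data Meta-analysis data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_meta_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a meta-analysis table from CSV
#'
#' Accepts the two package layouts (`mean_c,...,n_t` or `r,n`); empty cells
#' become missing values.
#'
#' @param path CSV file path.
#' @return A meta-analysis data frame.
#' @export
read_meta_csv <- function(path) {
  data <- utils::read.csv(path, na.strings = c("", "NA"))
  dataset_kind(data)  # validates the layout
  for (col in names(data)) data[[col]] <- as.numeric(data[[col]])
  data
}
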