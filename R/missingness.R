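#' Per-row deletion weights under a missingness scenario
#'
#' Returns the sampling weights used to choose which rows lose their SDs
#' and/or sample sizes:
#' \describe{
#'   \item{MCAR, corMCAR}{uniform weights (the corMCAR scenario encodes its
#'     structure in the data pairing, not in the deletion process).}
#'   \item{MAR}{the chance of deletion increases linearly with the rank
#'     position of the effect size when effect sizes are ranked in decreasing
#'     order, so the smallest effect size gets the largest weight. The raw
#'     log ratio (or r) orders the rows.}
#'   \item{MNAR}{weights proportional to the sum of the rank of
#'     `sd_c + sd_t` ascending and the rank of `n_c + n_t` descending, so
#'     imprecise, small studies are deleted preferentially. For correlation
#'     data only the sample-size rank applies.}
#' }
#' Ties are broken by original row order; weights sum to one.
#'
#' @param data A complete meta-analysis data frame.
#' @param scenario One of `"MCAR"`, `"MAR"`, `"MNAR"`, `"corMCAR"`.
#' @return Numeric vector of positive weights summing to 1.
#' @export
deletion_weights <- function(data, scenario = c("MCAR", "MAR", "MNAR", "corMCAR")) {
  scenario <- match.arg(scenario)
  kind <- dataset_kind(data)
  n <- nrow(data)
  if (n == 0) return(numeric(0))
  w <- switch(scenario,
    MCAR = ,
    corMCAR = rep(1, n),
    MAR = {
      es <- if (kind == "mean_difference") {
        if (anyNA(data$mean_c) || anyNA(data$mean_t)) {
          stop("MAR weights need complete mean columns")
        }
        log(data$mean_t / data$mean_c)
      } else {
        if (anyNA(data$r)) stop("MAR weights need a complete r column")
        data$r
      }
      rank(-es, ties.method = "first")
    },
    MNAR = {
      if (kind == "mean_difference") {
        cols <- c("sd_c", "sd_t", "n_c", "n_t")
        if (anyNA(data[cols])) stop("MNAR weights need complete SD and SS columns")
        rank(data$sd_c + data$sd_t, ties.method = "first") +
          rank(-(data$n_c + data$n_t), ties.method = "first")
      } else {
        if (anyNA(data$n)) stop("MNAR weights need a complete n column")
        rank(-data$n, ties.method = "first")
      }
    }
  )
  w / sum(w)
}

#' Delete SDs and/or sample sizes from a complete data set
#'
#' Selects `round(fraction * nrow)` rows by weighted sampling without
#' replacement (weights from [deletion_weights()]) and blanks the SD pair
#' and/or, from an independent draw, the sample-size pair of the selected
#' rows. Within a row both group values are always removed together.
#' Surviving values are never altered.
#'
#' @param data A complete meta-analysis data frame.
#' @param scenario Missingness scenario, see [deletion_weights()].
#' @param target `"SD"`, `"SS"` or `"BOTH"`; correlation data only support
#'   `"SS"`.
#' @param fraction Fraction of rows to delete, in `[0, 0.9]`.
#' @param seed Optional integer seed set before sampling.
#' @return The data frame with missing cells, plus logical attributes
#'   `sd_deleted` and `ss_deleted` flagging the affected rows.
#' @export
apply_deletion <- function(data, scenario, target = c("SD", "SS", "BOTH"),
                           fraction, seed = NULL) {
  target <- match.arg(target)
  kind <- dataset_kind(data)
  if (anyNA(data)) stop("apply_deletion() requires a complete data set")
  if (kind == "correlation" && target != "SS") {
    stop("correlation data sets only support target = \"SS\"")
  }
  if (!is.finite(fraction) || fraction < 0 || fraction > 0.9) {
    stop("'fraction' must lie in [0, 0.9]")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(data)
  k <- round(fraction * n)
  if (k > n) stop("requested deletion count exceeds the number of rows")
  w <- deletion_weights(data, scenario)
  out <- data
  sd_mask <- rep(FALSE, n)
  ss_mask <- rep(FALSE, n)
  if (target %in% c("SD", "BOTH") && k > 0) {
    idx <- sample.int(n, k, prob = w)
    sd_mask[idx] <- TRUE
    out$sd_c[idx] <- NA_real_
    out$sd_t[idx] <- NA_real_
  }
  if (target %in% c("SS", "BOTH") && k > 0) {
    idx <- sample.int(n, k, prob = w)
    ss_mask[idx] <- TRUE
    if (kind == "mean_difference") {
      out$n_c[idx] <- NA_real_
      out$n_t[idx] <- NA_real_
    } else {
      out$n[idx] <- NA_real_
    }
  }
  attr(out, "sd_deleted") <- sd_mask
  attr(out, "ss_deleted") <- ss_mask
  attr(out, "scenario") <- scenario
  attr(out, "fraction") <- fraction
  out
}
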