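## Imputation of missing SDs and sample sizes.
##
## Two single-imputation methods plus nine multiple-imputation methods,
## implemented from their published descriptions: a chained-equations engine
## with per-variable plug-ins (random sample, linear regression, predictive
## mean matching, CART, a 10-tree forest, Bayesian PMM, additive regression
## with bootstrap PMM), a bootstrap expectation-maximization method under a
## multivariate normal, and an iterative random-forest method.
##
## Conventions shared by all methods:
##   * imputed SDs are restricted to [0.01, 1]; imputed sample sizes are
##     rounded to integers and restricted to >= 5
##   * variables are imputed in the order sd_t, sd_c, n_t, n_c (n for
##     correlation data)
##   * observed cells are never modified; complete data pass through as
##     exact copies

#' Names of the supported multiple-imputation methods
#' @return Character vector of method keys accepted by [impute_missing()].
#' @export
mi_methods <- function() {
  c("random_sample", "linear_regression", "pmm", "cart", "random_forest",
    "bayes_pmm", "bootstrap_em", "missforest", "addreg_boot_pmm")
}

# imputation order per the study design; only columns with missing cells
target_cols <- function(data) {
  order <- c("sd_t", "sd_c", "n_t", "n_c", "n")
  cols <- intersect(order, names(data))
  cols[vapply(cols, function(cl) anyNA(data[[cl]]), logical(1))]
}

col_bounds <- function(col) {
  if (col %in% c("sd_c", "sd_t")) {
    list(lower = 0.01, upper = 1, integer = FALSE)
  } else if (col %in% c("n_c", "n_t", "n")) {
    list(lower = 5, upper = Inf, integer = TRUE)
  } else {
    stop("no bounds defined for column '", col, "'")
  }
}

# round-then-clamp for sample sizes; clamp for SDs (model-based plug-ins
# additionally redraw before this final safeguard applies)
enforce_bounds <- function(vals, col) {
  b <- col_bounds(col)
  if (b$integer) vals <- round(vals)
  pmin(pmax(vals, b$lower), b$upper)
}

# predictors for the chained-equations family: means / r plus whichever
# SD-SS columns are fully observed
predictor_cols <- function(data) {
  if (dataset_kind(data) == "correlation") return("r")
  extra <- c("sd_c", "sd_t", "n_c", "n_t")
  complete <- extra[!vapply(extra, function(cl) anyNA(data[[cl]]), logical(1))]
  c("mean_c", "mean_t", complete)
}

#' Single imputation by the column mean or median
#'
#' Fills every missing cell of a column with the mean (or median) of that
#' column's reported values; sample sizes are rounded and kept `>= 5`, SDs
#' kept in `[0.01, 1]`.
#'
#' @param data An incomplete meta-analysis data frame.
#' @param stat `"mean"` or `"median"`.
#' @return A completed data frame.
#' @export
impute_single <- function(data, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  fun <- if (stat == "mean") mean else stats::median
  out <- data
  for (col in target_cols(data)) {
    obs <- !is.na(data[[col]])
    if (!any(obs)) stop("column '", col, "' has no reported values to impute from")
    out[[col]][!obs] <- enforce_bounds(fun(data[[col]][obs]), col)
  }
  out
}

## ---- chained-equations plug-ins ------------------------------------------
## Each plug-in receives the observed responses y, model frames Xo (observed
## rows) and Xm (rows to impute), and returns one drawn value per row of Xm.

# posterior draw of the linear-regression parameters under the reference
# (normal-inverse-gamma) prior; shared by the regression-based plug-ins
beta_sigma_draw <- function(y, Xo, Xm) {
  Xo <- cbind(1, as.matrix(Xo))
  Xm <- cbind(1, as.matrix(Xm))
  qrx <- qr(Xo)
  keep <- qrx$pivot[seq_len(qrx$rank)]
  Xo <- Xo[, keep, drop = FALSE]
  Xm <- Xm[, keep, drop = FALSE]
  p <- ncol(Xo)
  R <- chol(crossprod(Xo) + diag(1e-8, p))
  bhat <- backsolve(R, forwardsolve(t(R), crossprod(Xo, y)))
  res <- y - Xo %*% bhat
  df <- max(length(y) - p, 1)
  sigma2 <- sum(res^2) / stats::rchisq(1, df)
  beta_star <- bhat + sqrt(sigma2) * backsolve(R, stats::rnorm(p))
  list(pred_obs = drop(Xo %*% bhat),
       pred_mis = drop(Xm %*% bhat),
       pred_mis_star = drop(Xm %*% beta_star),
       sigma2 = sigma2)
}

draw_random_sample <- function(y, Xo, Xm, donors, col) {
  sample(y, nrow(Xm), replace = TRUE)
}

# "proper" stochastic regression: parameter draw plus residual noise, so the
# between-imputation variance does not collapse; out-of-bounds draws are
# redrawn up to 10 times before the final clamp
draw_linear_regression <- function(y, Xo, Xm, donors, col) {
  b <- col_bounds(col)
  d <- beta_sigma_draw(y, Xo, Xm)
  vals <- d$pred_mis_star + stats::rnorm(length(d$pred_mis_star), 0, sqrt(d$sigma2))
  if (!b$integer) {
    for (i in seq_len(10)) {
      bad <- vals < b$lower | vals > b$upper
      if (!any(bad)) break
      vals[bad] <- d$pred_mis_star[bad] +
        stats::rnorm(sum(bad), 0, sqrt(d$sigma2))
    }
  }
  vals
}

match_donors <- function(y, pred_obs, pred_mis, donors) {
  vapply(pred_mis, function(p) {
    pool <- order(abs(pred_obs - p))[seq_len(min(donors, length(y)))]
    y[pool[sample.int(length(pool), 1)]]
  }, numeric(1))
}

draw_pmm <- function(y, Xo, Xm, donors, col) {
  d <- beta_sigma_draw(y, Xo, Xm)
  match_donors(y, d$pred_obs, d$pred_mis_star, donors)
}

# Bayesian generalized linear model (normal link) with donor matching: the
# reference-prior posterior draw is the same NIG draw as beta_sigma_draw
draw_bayes_pmm <- function(y, Xo, Xm, donors, col) {
  d <- beta_sigma_draw(y, Xo, Xm)
  match_donors(y, d$pred_obs, d$pred_mis_star, donors)
}

# donors from the leaf a missing row falls into; leaves are identified by
# their fitted value (constant within a leaf), with a nearest-prediction
# fallback should two leaves share a fitted value
cart_leaf_donors <- function(y, pred_obs, pred_mis, donors) {
  vapply(pred_mis, function(p) {
    pool <- which(pred_obs == p)
    if (length(pool) == 0) {
      pool <- order(abs(pred_obs - p))[seq_len(min(donors, length(y)))]
    }
    y[pool[sample.int(length(pool), 1)]]
  }, numeric(1))
}

draw_cart <- function(y, Xo, Xm, donors, col) {
  df_o <- data.frame(.y = y, Xo)
  fit <- rpart::rpart(.y ~ ., data = df_o, method = "anova",
                      control = rpart::rpart.control(minbucket = 5, cp = 1e-4,
                                                     xval = 0))
  cart_leaf_donors(y, predict(fit, df_o), predict(fit, data.frame(Xm)), donors)
}

# 10 regression trees, each on a bootstrap resample; a missing cell draws a
# donor from its leaf in one randomly chosen tree
draw_forest <- function(y, Xo, Xm, donors, col, ntree = 10) {
  n <- length(y)
  trees <- lapply(seq_len(ntree), function(t) {
    idx <- sample.int(n, n, replace = TRUE)
    df_b <- data.frame(.y = y[idx], Xo[idx, , drop = FALSE])
    fit <- rpart::rpart(.y ~ ., data = df_b, method = "anova",
                        control = rpart::rpart.control(minbucket = 5, cp = 1e-4,
                                                       xval = 0))
    list(y = y[idx], pred_obs = predict(fit, df_b),
         pred_mis = predict(fit, data.frame(Xm)))
  })
  vapply(seq_len(nrow(Xm)), function(i) {
    tr <- trees[[sample.int(ntree, 1)]]
    cart_leaf_donors(tr$y, tr$pred_obs, tr$pred_mis[i], donors)
  }, numeric(1))
}

# bootstrap the fitting rows, fit an additive (natural-spline) regression,
# then match each prediction to the nearest observed value
draw_addreg_boot_pmm <- function(y, Xo, Xm, donors, col) {
  n <- length(y)
  idx <- sample.int(n, n, replace = TRUE)
  yb <- y[idx]
  Xb <- Xo[idx, , drop = FALSE]
  terms <- vapply(names(Xo), function(v) {
    if (length(unique(Xb[[v]])) > 4) sprintf("splines::ns(%s, df = 3)", v) else v
  }, character(1))
  fml <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
  fit <- stats::lm(fml, data = data.frame(.y = yb, Xb))
  pred_obs <- suppressWarnings(predict(fit, Xo))
  pred_mis <- suppressWarnings(predict(fit, data.frame(Xm)))
  vapply(pred_mis, function(p) y[which.min(abs(pred_obs - p))], numeric(1))
}

chained_plugins <- function() {
  list(random_sample     = draw_random_sample,
       linear_regression = draw_linear_regression,
       pmm               = draw_pmm,
       cart              = draw_cart,
       random_forest     = draw_forest,
       bayes_pmm         = draw_bayes_pmm,
       addreg_boot_pmm   = draw_addreg_boot_pmm)
}

imputation_result <- function(method, status, datasets = list(), m = length(datasets),
                              failures = character(), reason = NULL) {
  structure(
    list(method = method, status = status, datasets = datasets,
         m = m, m_used = sum(!vapply(datasets, is.null, logical(1))),
         failures = failures, reason = reason),
    class = "imputation_result"
  )
}

#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf("Imputation by '%s': status = %s, %d of %d data sets completed\n",
              x$method, x$status, x$m_used, x$m))
  if (!is.null(x$reason)) cat("  reason:", x$reason, "\n")
  if (length(x$failures)) cat("  failures:", length(x$failures), "\n")
  invisible(x)
}

completed_datasets <- function(x) {
  x$datasets[!vapply(x$datasets, is.null, logical(1))]
}

chained_impute <- function(data, method, m, maxit, donors, order = NULL) {
  plugin <- chained_plugins()[[method]]
  targets <- target_cols(data)
  if (!is.null(order)) {
    if (!setequal(order, targets)) {
      stop("'order' must be a permutation of the incomplete columns: ",
           paste(targets, collapse = ", "))
    }
    targets <- order
  }
  preds <- predictor_cols(data)
  mis <- lapply(data[targets], is.na)
  for (col in targets) {
    if (sum(!mis[[col]]) < 5) {
      stop("method '", method, "': fewer than 5 complete rows for column '",
           col, "'")
    }
  }
  datasets <- vector("list", m)
  failures <- character()
  for (j in seq_len(m)) {
    imp <- data
    for (col in targets) {
      obs_vals <- data[[col]][!mis[[col]]]
      imp[[col]][mis[[col]]] <- sample(obs_vals, sum(mis[[col]]), replace = TRUE)
    }
    ok <- TRUE
    for (it in seq_len(maxit)) {
      for (col in targets) {
        y <- data[[col]][!mis[[col]]]
        Xo <- imp[!mis[[col]], preds, drop = FALSE]
        Xm <- imp[mis[[col]], preds, drop = FALSE]
        vals <- tryCatch(plugin(y, Xo, Xm, donors, col), error = function(e) e)
        if (inherits(vals, "error")) {
          failures <- c(failures,
                        sprintf("imputation %d: %s", j, conditionMessage(vals)))
          ok <- FALSE
          break
        }
        imp[[col]][mis[[col]]] <- enforce_bounds(vals, col)
      }
      if (!ok) break
    }
    if (ok) datasets[[j]] <- imp
  }
  list(datasets = datasets, failures = failures)
}

## ---- bootstrap expectation maximization ----------------------------------

# EM for the mean and covariance of a multivariate normal with missing cells
em_mvnorm <- function(X, maxit = 500, tol = 1e-6) {
  n <- nrow(X)
  p <- ncol(X)
  M <- is.na(X)
  mu <- colMeans(X, na.rm = TRUE)
  v <- apply(X, 2, stats::var, na.rm = TRUE)
  v[!is.finite(v) | v <= 0] <- 1e-4
  sigma <- diag(v, p)
  X0 <- X
  pat <- apply(M, 1, function(z) paste(as.integer(z), collapse = ""))
  groups <- split(seq_len(n), pat)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    s1 <- numeric(p)
    s2 <- matrix(0, p, p)
    for (rows in groups) {
      misv <- M[rows[1], ]
      if (!any(misv)) {
        xc <- X0[rows, , drop = FALSE]
        s1 <- s1 + colSums(xc)
        s2 <- s2 + crossprod(xc)
        next
      }
      obsv <- !misv
      soo <- sigma[obsv, obsv, drop = FALSE] + diag(1e-10, sum(obsv))
      a <- sigma[misv, obsv, drop = FALSE] %*% solve(soo)
      cv <- sigma[misv, misv, drop = FALSE] - a %*% sigma[obsv, misv, drop = FALSE]
      xo <- X0[rows, obsv, drop = FALSE]
      cm <- sweep(xo, 2, mu[obsv]) %*% t(a)
      cm <- sweep(cm, 2, mu[misv], `+`)
      xc <- X0[rows, , drop = FALSE]
      xc[, misv] <- cm
      s1 <- s1 + colSums(xc)
      s2 <- s2 + crossprod(xc)
      add <- matrix(0, p, p)
      add[misv, misv] <- length(rows) * cv
      s2 <- s2 + add
    }
    mu_new <- s1 / n
    sigma_new <- s2 / n - tcrossprod(mu_new)
    sigma_new <- (sigma_new + t(sigma_new)) / 2
    # scale-aware convergence: parameters span means ~1 and covariances ~10
    scale <- max(abs(sigma), abs(mu), 1)
    delta <- max(abs(mu_new - mu), abs(sigma_new - sigma)) / scale
    mu <- mu_new
    sigma <- sigma_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  list(mu = mu, sigma = sigma, converged = converged)
}

# draw the missing cells of one row from their conditional normal given the
# observed cells; out-of-bounds cells redrawn from the truncated univariate
# conditional marginal
conditional_draw <- function(x, mu, sigma, cols) {
  misv <- is.na(x)
  obsv <- !misv
  soo <- sigma[obsv, obsv, drop = FALSE] + diag(1e-10, sum(obsv))
  a <- sigma[misv, obsv, drop = FALSE] %*% solve(soo)
  cm <- drop(mu[misv] + a %*% (x[obsv] - mu[obsv]))
  cv <- sigma[misv, misv, drop = FALSE] - a %*% sigma[obsv, misv, drop = FALSE]
  cv <- (cv + t(cv)) / 2
  L <- tryCatch(chol(cv), error = function(e) chol(cv + diag(1e-8, nrow(cv))))
  vals <- cm + drop(crossprod(L, stats::rnorm(length(cm))))
  csd <- sqrt(pmax(diag(cv), 1e-12))
  for (k in seq_along(vals)) {
    b <- col_bounds(cols[misv][k])
    if (vals[k] < b$lower || vals[k] > b$upper) {
      vals[k] <- rtruncnorm(1, cm[k], csd[k], b$lower, b$upper)
    }
  }
  vals
}

impute_bootstrap_em <- function(data, m, missing_cap) {
  targets <- target_cols(data)
  frac <- max(vapply(data[targets], function(cl) mean(is.na(cl)), numeric(1)))
  if (frac > missing_cap) {
    return(imputation_result(
      "bootstrap_em", "skipped", m = m,
      reason = sprintf("missing fraction %.2f exceeds the %.0f%% operational cap",
                       frac, 100 * missing_cap)
    ))
  }
  vars <- names(data)
  X <- as.matrix(data[vars])
  n <- nrow(X)
  datasets <- vector("list", m)
  failures <- character()
  need <- which(apply(is.na(X), 1, any))
  for (j in seq_len(m)) {
    em <- tryCatch(em_mvnorm(X[sample.int(n, n, replace = TRUE), , drop = FALSE]),
                   error = function(e) e)
    if (inherits(em, "error")) {
      failures <- c(failures, sprintf("imputation %d: %s", j, conditionMessage(em)))
      next
    }
    if (!em$converged) {
      failures <- c(failures, sprintf("imputation %d: EM did not converge", j))
      next
    }
    imp <- data
    bad <- FALSE
    for (i in need) {
      vals <- tryCatch(conditional_draw(X[i, ], em$mu, em$sigma, vars),
                       error = function(e) e)
      if (inherits(vals, "error")) {
        failures <- c(failures, sprintf("imputation %d: %s", j, conditionMessage(vals)))
        bad <- TRUE
        break
      }
      miscols <- vars[is.na(X[i, ])]
      for (k in seq_along(miscols)) {
        imp[[miscols[k]]][i] <- enforce_bounds(vals[k], miscols[k])
      }
    }
    if (!bad) datasets[[j]] <- imp
  }
  res <- imputation_result("bootstrap_em",
                           if (any(!vapply(datasets, is.null, logical(1)))) "ok" else "failed",
                           datasets, m, failures)
  res
}

## ---- iterative random forest ---------------------------------------------

impute_missforest_one <- function(data, ntree = 100, max_iter = 10) {
  targets <- target_cols(data)
  mis <- lapply(data[targets], is.na)
  imp <- data
  for (col in targets) {
    imp[[col]][mis[[col]]] <-
      enforce_bounds(mean(data[[col]][!mis[[col]]]), col)
  }
  ord <- targets[order(vapply(mis[targets], sum, integer(1)))]
  prev_diff <- Inf
  for (it in seq_len(max_iter)) {
    old <- imp
    for (col in ord) {
      obs <- !mis[[col]]
      xcols <- setdiff(names(imp), col)
      fit <- randomForest::randomForest(x = imp[obs, xcols, drop = FALSE],
                                        y = data[[col]][obs], ntree = ntree)
      imp[[col]][!obs] <-
        enforce_bounds(predict(fit, imp[!obs, xcols, drop = FALSE]), col)
    }
    num <- 0
    den <- 0
    for (col in targets) {
      num <- num + sum((imp[[col]][mis[[col]]] - old[[col]][mis[[col]]])^2)
      den <- den + sum(imp[[col]][mis[[col]]]^2)
    }
    diff <- if (den > 0) num / den else 0
    # missForest stopping rule: keep the previous iteration once the change
    # in imputed values starts increasing
    if (diff >= prev_diff) {
      imp <- old
      break
    }
    prev_diff <- diff
    if (diff == 0) break
  }
  imp
}

impute_missforest <- function(data, m, ntree) {
  targets <- target_cols(data)
  for (col in targets) {
    if (sum(!is.na(data[[col]])) < 5) {
      stop("method 'missforest': fewer than 5 complete rows for column '",
           col, "'")
    }
  }
  datasets <- vector("list", m)
  failures <- character()
  for (j in seq_len(m)) {
    imp <- tryCatch(impute_missforest_one(data, ntree = ntree),
                    error = function(e) e)
    if (inherits(imp, "error")) {
      failures <- c(failures, sprintf("imputation %d: %s", j, conditionMessage(imp)))
    } else {
      datasets[[j]] <- imp
    }
  }
  imputation_result("missforest",
                    if (any(!vapply(datasets, is.null, logical(1)))) "ok" else "failed",
                    datasets, m, failures)
}

## ---- front end ------------------------------------------------------------

#' Multiply impute missing SDs and sample sizes
#'
#' Produces `m` completed data sets by the requested method. The
#' chained-equations methods (`random_sample`, `linear_regression`, `pmm`,
#' `cart`, `random_forest`, `bayes_pmm`, `addreg_boot_pmm`) initialize
#' missing cells by random draws from the observed values and cycle `maxit`
#' times through the variables in the order `sd_t, sd_c, n_t, n_c`, refitting
#' the per-variable model on the currently completed data; predictors are the
#' group means (or `r`) plus fully observed SD-SS columns. `bootstrap_em`
#' fits a multivariate normal by EM on a bootstrap resample and draws missing
#' cells from their conditional normal; it refuses data with more than
#' `em_missing_cap` missing (a `"skipped"` result, mirroring the instability
#' of the algorithm at high missingness). `missforest` iterates random-forest
#' predictions over all variables until the change in imputed values rises.
#'
#' All imputed SDs are restricted to `[0.01, 1]`, all imputed sample sizes
#' rounded to integers `>= 5`. Complete inputs are returned as `m` identical
#' copies. Failed imputations are recorded, not raised.
#'
#' @param data An incomplete meta-analysis data frame.
#' @param method One of [mi_methods()], or `"mean"`/`"median"` for single
#'   imputation (then `m` is forced to 1).
#' @param m Number of imputed data sets (default 100).
#' @param maxit Chained-equations cycles (default 5).
#' @param donors Donor-pool size for predictive mean matching (default 5).
#' @param em_missing_cap Maximum missing fraction accepted by
#'   `bootstrap_em` (default 0.6).
#' @param ntree Trees per forest for `missforest` (default 100).
#' @param order Optional permutation of the incomplete columns overriding the
#'   default imputation order (chained-equations methods only).
#' @param seed Optional integer seed set before imputing.
#' @return An object of class `"imputation_result"` with fields `method`,
#'   `status` (`"ok"`, `"skipped"` or `"failed"`), `datasets` (list of
#'   completed data frames, `NULL` where an imputation failed), `m`,
#'   `m_used`, `failures` and `reason`.
#' @export
impute_missing <- function(data, method, m = 100, maxit = 5, donors = 5,
                           em_missing_cap = 0.6, ntree = 100, order = NULL,
                           seed = NULL) {
  method <- match.arg(method, c(mi_methods(), "mean", "median"))
  if (!is.null(seed)) set.seed(seed)
  if (m < 1) stop("'m' must be >= 1")
  if (length(target_cols(data)) == 0) {
    return(imputation_result(method, "ok", rep(list(data), m), m))
  }
  if (method %in% c("mean", "median")) {
    return(imputation_result(method, "ok", list(impute_single(data, method)), 1))
  }
  if (method == "bootstrap_em") {
    return(impute_bootstrap_em(data, m, em_missing_cap))
  }
  if (method == "missforest") {
    return(impute_missforest(data, m, ntree))
  }
  out <- chained_impute(data, method, m, maxit, donors, order)
  imputation_result(method,
                    if (any(!vapply(out$datasets, is.null, logical(1)))) "ok" else "failed",
                    out$datasets, m, out$failures)
}
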