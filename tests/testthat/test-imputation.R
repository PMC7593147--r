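md_with_missing <- function(n = 60, fraction = 0.3, target = "BOTH", seed = 1) {
  d <- simulate_md_data(n, seed = seed)
  apply_deletion(d, "MCAR", target, fraction, seed = seed + 100)
}

test_that("single imputation fills with the column mean or median", {
  d <- tiny_md_data()[1:3, ]
  d$sd_t <- c(0.2, 0.4, NA)
  expect_equal(impute_single(d, "mean")$sd_t[3], 0.3)
  expect_equal(impute_single(d, "median")$sd_t[3], 0.3)

  d4 <- tiny_md_data()[1:4, ]
  d4$sd_t <- c(0.1, 0.1, 0.9, NA)
  expect_equal(impute_single(d4, "mean")$sd_t[4], mean(c(0.1, 0.1, 0.9)))
  expect_equal(impute_single(d4, "median")$sd_t[4], 0.1)

  # identity on complete data, error when nothing is reported
  comp <- tiny_md_data()
  expect_identical(impute_single(comp, "mean"), comp)
  allna <- tiny_md_data()
  allna$n_t <- NA_real_
  expect_error(impute_single(allna, "mean"), "no reported values")

  # imputed sample sizes are integers
  d5 <- tiny_md_data()
  d5$n_t[1:2] <- NA
  out <- impute_single(d5, "mean")
  expect_equal(out$n_t[1], round(mean(d5$n_t[3:6])))
})

test_that("all methods return exact copies when nothing is missing", {
  d <- simulate_md_data(30, seed = 2)
  for (method in c(mi_methods(), "mean", "median")) {
    res <- impute_missing(d, method, m = 3, seed = 3)
    expect_equal(res$status, "ok")
    for (imp in res$datasets) expect_identical(imp, d)
  }
})

test_that("chained-equations imputations respect bounds and observed cells", {
  inc <- md_with_missing(fraction = 0.5)
  obs_sd <- which(!is.na(inc$sd_t))
  for (method in c("linear_regression", "pmm", "cart")) {
    res <- impute_missing(inc, method, m = 3, seed = 4)
    expect_equal(res$status, "ok")
    expect_equal(res$m_used, 3)
    for (imp in res$datasets) {
      expect_false(anyNA(imp))
      expect_true(all(imp$sd_c >= 0.01 & imp$sd_c <= 1))
      expect_true(all(imp$sd_t >= 0.01 & imp$sd_t <= 1))
      expect_true(all(imp$n_c >= 5 & imp$n_c == round(imp$n_c)))
      # observed cells are never modified
      expect_identical(imp$sd_t[obs_sd], inc$sd_t[obs_sd])
      expect_identical(imp$mean_c, inc$mean_c)
    }
  }
})

test_that("donor-based methods impute only observed values", {
  inc <- md_with_missing(fraction = 0.4, seed = 5)
  mis <- is.na(inc$sd_t)
  donors <- inc$sd_t[!mis]
  for (method in c("random_sample", "pmm", "cart", "random_forest",
                   "bayes_pmm", "addreg_boot_pmm")) {
    res <- impute_missing(inc, method, m = 2, seed = 6)
    for (imp in res$datasets) {
      expect_true(all(imp$sd_t[mis] %in% donors), label = method)
    }
  }
})

test_that("multiple imputation is stochastic across repetitions", {
  inc <- md_with_missing(fraction = 0.4, seed = 7)
  mis <- is.na(inc$sd_t)
  for (method in mi_methods()) {
    res <- impute_missing(inc, method, m = 4, seed = 8)
    sets <- Filter(Negate(is.null), res$datasets)
    expect_gte(length(sets), 2)
    vals <- sapply(sets, function(imp) imp$sd_t[mis])
    expect_gt(max(apply(vals, 1, var)), 0, label = method)
  }
})

test_that("regression imputation recovers the observed mean under MCAR", {
  inc <- md_with_missing(n = 100, fraction = 0.3, target = "SD", seed = 9)
  mis <- is.na(inc$sd_t)
  res <- impute_missing(inc, "linear_regression", m = 100, seed = 10)
  imputed <- unlist(lapply(res$datasets, function(imp) imp$sd_t[mis]))
  obs <- inc$sd_t[!mis]
  # under MCAR the imputed and observed cells share a mean
  expect_lt(abs(mean(imputed) - mean(obs)), 3 * sd(obs) / sqrt(sum(mis)))
})

test_that("the imputation order only perturbs results stochastically", {
  inc <- md_with_missing(n = 80, fraction = 0.4, seed = 11)
  fit_pool <- function(order) {
    res <- impute_missing(inc, "pmm", m = 20, order = order, seed = 12)
    ests <- lapply(res$datasets, function(imp) {
      es <- effect_sizes(imp, "lnrr")
      random_effects_fit(es$yi, es$vi)
    })
    rubin_pool(ests)
  }
  p1 <- fit_pool(NULL)
  p2 <- fit_pool(c("n_c", "n_t", "sd_c", "sd_t"))
  expect_lt(abs(p1$mu - p2$mu), 3 * sqrt(p1$se^2 + p2$se^2))
})

test_that("bootstrap EM recovers parameters and honors its missingness cap", {
  # parameter recovery of the EM core on bivariate normal data
  set.seed(13)
  rho <- 0.6
  ests <- replicate(10, {
    n <- 200
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    y[sample(n, 40)] <- NA
    em <- metamiss:::em_mvnorm(cbind(x, y))
    em$sigma[1, 2] / sqrt(em$sigma[1, 1] * em$sigma[2, 2])
  })
  expect_lt(abs(mean(ests) - rho), 3 * sd(ests) / sqrt(10))

  inc <- md_with_missing(n = 100, fraction = 0.5, seed = 14)
  res <- impute_missing(inc, "bootstrap_em", m = 3, seed = 15)
  expect_equal(res$status, "ok")
  for (imp in Filter(Negate(is.null), res$datasets)) {
    expect_true(all(imp$sd_c >= 0.01 & imp$sd_c <= 1))
    expect_true(all(imp$n_c >= 5 & imp$n_c == round(imp$n_c)))
  }

  inc70 <- md_with_missing(n = 100, fraction = 0.7, seed = 16)
  skip70 <- impute_missing(inc70, "bootstrap_em", m = 3, seed = 17)
  expect_equal(skip70$status, "skipped")
  expect_match(skip70$reason, "cap")
  expect_equal(length(completed <- Filter(Negate(is.null), skip70$datasets)), 0)
})

test_that("missforest imputes within bounds with forest variability", {
  inc <- md_with_missing(n = 60, fraction = 0.4, seed = 18)
  res <- impute_missing(inc, "missforest", m = 2, ntree = 30, seed = 19)
  expect_equal(res$status, "ok")
  mis <- is.na(inc$sd_t)
  for (imp in res$datasets) {
    expect_false(anyNA(imp))
    expect_true(all(imp$sd_t >= 0.01 & imp$sd_t <= 1))
    expect_true(all(imp$n_t >= 5 & imp$n_t == round(imp$n_t)))
    expect_identical(imp$sd_t[!mis], inc$sd_t[!mis])
  }
})

test_that("too few complete rows is an error naming the method", {
  d <- tiny_md_data()
  d$sd_t[1:3] <- NA  # only 3 observed
  expect_error(impute_missing(d, "pmm", m = 1), "pmm")
  expect_error(impute_missing(d, "missforest", m = 1), "missforest")
})
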