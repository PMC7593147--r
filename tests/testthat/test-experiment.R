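test_that("the fully informed reference is deterministic and complete-only", {
  d <- simulate_md_data(100, seed = 1)
  ref <- fully_informed_reference(d, "lnrr")
  expect_equal(ref$k, 100)
  expect_true(is.finite(ref$mu) && ref$se > 0)
  expect_identical(ref, fully_informed_reference(d, "lnrr"))
  inc <- apply_deletion(d, "MCAR", "SD", 0.2, seed = 2)
  expect_error(fully_informed_reference(inc, "lnrr"), "complete")
})

test_that("complete-case analysis keeps exactly the fully reported studies", {
  d <- simulate_md_data(100, seed = 3)
  inc <- apply_deletion(d, "MCAR", "SD", 0.5, seed = 4)
  res <- run_treatment(inc, 1, "lnrr")
  expect_equal(res$status, "ok")
  expect_equal(res$k, 50)  # k_used + deleted rows = 100
})

test_that("inapplicable and degenerate option combinations are flagged", {
  d <- simulate_md_data(50, seed = 5)
  inc <- apply_deletion(d, "MCAR", "SD", 0.4, seed = 6)
  res <- run_treatment(inc, 3, "hedges_d")
  expect_equal(res$status, "skipped")
  expect_match(res$reason, "Hedges")
  expect_error(run_treatment(inc, 1, "fishers_z"), "does not apply")

  # all rows unusable -> failed record, not an exception
  tiny <- apply_deletion(tiny_md_data(), "MCAR", "SD", 0.9, seed = 7)
  res2 <- run_treatment(tiny, 1, "hedges_d")
  expect_equal(res2$status, "failed")
})

test_that("the default factorial plan enumerates the full design", {
  plan <- plan_factorial()
  expect_equal(nrow(plan), 2560)
  expect_equal(length(unique(plan$fraction)), 16)
  expect_setequal(unique(plan$target[plan$kind == "correlation"]), "SS")
  # a restricted plan keeps the factorial structure
  small <- plan_factorial(scenarios = "MCAR", n_replicates = 2,
                          fractions = c(0.1, 0.5), md_targets = "SD",
                          kinds = "mean_difference")
  expect_equal(nrow(small), 4)
})

test_that("a unit factorial cell produces records with correct statuses", {
  rec <- run_factorial(scenarios = "MNAR", n_replicates = 1, fractions = 0.4,
                       md_targets = "SD", kinds = "mean_difference",
                       options = c(1, 2, 3, 4), m = 2, master_seed = 21)
  expect_equal(nrow(rec), 8)  # 4 options x 2 effect sizes
  skip <- rec[rec$option_id == 3 & rec$measure == "hedges_d", ]
  expect_equal(skip$status, "skipped")
  ok <- rec[rec$status == "ok", ]
  expect_true(all(is.finite(ok$dev_mu) & is.finite(ok$dev_ci_width)))
})

test_that("the factorial sweep is reproducible under a master seed", {
  args <- list(scenarios = "MCAR", n_replicates = 2, fractions = c(0.2, 0.6),
               md_targets = "SS", kinds = "mean_difference",
               options = c(1, 6), measures = "lnrr", m = 2, master_seed = 99)
  r1 <- do.call(run_factorial, args)
  r2 <- do.call(run_factorial, args)
  expect_identical(r1, r2)
})

test_that("deviation summaries aggregate over replicates only", {
  rec <- run_factorial(scenarios = "MCAR", n_replicates = 3, fractions = 0.3,
                       md_targets = "SD", kinds = "mean_difference",
                       options = 1, measures = "lnrr", master_seed = 31)
  s <- summarize_deviation(rec)
  expect_equal(nrow(s), 1)
  expect_equal(s$n_ok, 3)
  expect_equal(s$dev_mu, mean(rec$dev_mu))

  one <- rec[1, ]
  expect_equal(summarize_deviation(one)$dev_mu, one$dev_mu)
  sym <- rbind(one, one)
  sym$dev_mu <- c(0.25, -0.25)
  expect_equal(summarize_deviation(sym)$dev_mu, 0)
  expect_error(summarize_deviation(rec[0, ]), "records")
})

test_that("imputation keeps MCAR lnRR grand means near the reference", {
  rec <- run_factorial(scenarios = "MCAR", n_replicates = 3, fractions = 0.3,
                       md_targets = "BOTH", kinds = "mean_difference",
                       options = c(4, 6, 8), measures = "lnrr", m = 3,
                       master_seed = 41)
  s <- summarize_deviation(rec)
  expect_true(all(abs(s$dev_mu) < 0.05))
})

test_that("effect-size-correlated data bias the unweighted analysis", {
  rec <- run_factorial(scenarios = c("MCAR", "corMCAR"), n_replicates = 5,
                       fractions = 0.6, md_targets = "SD",
                       kinds = "mean_difference", options = 2,
                       measures = "lnrr", master_seed = 51)
  dev <- aggregate(abs(dev_mu) ~ scenario, rec, mean)
  expect_gt(dev$`abs(dev_mu)`[dev$scenario == "corMCAR"],
            dev$`abs(dev_mu)`[dev$scenario == "MCAR"])
})

test_that("comparing treatments on a user table returns one row per option", {
  d <- simulate_md_data(40, seed = 61)
  inc <- apply_deletion(d, "MCAR", "SD", 0.3, seed = 62)
  tab <- compare_treatments(inc, "lnrr", options = c(1, 2, 4, 8), m = 2,
                            seed = 63)
  expect_equal(nrow(tab), 4)
  expect_true(all(tab$status == "ok"))
  expect_true(all(is.finite(tab$mu)))
})

test_that("YAML configuration overrides merge into the shipped defaults", {
  expect_equal(default_config()$m, 100)
  expect_equal(length(default_config()$fractions), 16)
  path <- withr::local_tempfile(
    lines = c("n_replicates: 2", "m: 5", "fractions: [0.2, 0.6]",
              "options: [1, 2]"),
    fileext = ".yaml"
  )
  cfg <- read_config(path)
  expect_equal(cfg$n_replicates, 2)
  expect_equal(cfg$m, 5)
  expect_equal(cfg$fractions, c(0.2, 0.6))
  expect_identical(cfg$options, c(1L, 2L))
  expect_equal(cfg$n_studies, 100)  # untouched default
  rec <- run_factorial_config(utils::modifyList(
    cfg, list(scenarios = "MCAR", fractions = 0.3)))
  expect_true(nrow(rec) > 0)
})

test_that("deviation summaries plot without error", {
  rec <- run_factorial(scenarios = "MCAR", n_replicates = 2, fractions = c(0.2, 0.6),
                       md_targets = "SD", kinds = "mean_difference",
                       options = c(1, 2), measures = "lnrr", master_seed = 71)
  p <- plot_deviation(summarize_deviation(rec))
  expect_s3_class(p, "ggplot")
})
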