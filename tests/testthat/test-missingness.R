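test_that("deletion weights implement the four mechanisms", {
  d <- simulate_md_data(100, seed = 1)
  expect_equal(deletion_weights(d, "MCAR"), rep(0.01, 100))
  expect_equal(deletion_weights(d, "corMCAR"), rep(0.01, 100))

  # four studies with effect sizes already sorted descending: MAR weight is
  # the rank position in decreasing order, normalized
  d4 <- data.frame(mean_c = rep(1, 4), mean_t = c(4, 3, 2, 1.5),
                   sd_c = rep(0.2, 4), sd_t = rep(0.4, 4),
                   n_c = rep(10, 4), n_t = rep(10, 4))
  expect_equal(deletion_weights(d4, "MAR"), c(1, 2, 3, 4) / 10)

  # study A: largest SD sum and smallest n sum -> maximal MNAR weight
  d3 <- data.frame(mean_c = rep(1, 3), mean_t = rep(2, 3),
                   sd_c = c(0.9, 0.2, 0.1), sd_t = c(0.9, 0.2, 0.1),
                   n_c = c(5, 20, 30), n_t = c(5, 20, 30))
  w <- deletion_weights(d3, "MNAR")
  expect_equal(which.max(w), 1L)
  expect_equal(sum(w), 1)

  # correlation data: MNAR weight grows as n shrinks
  dc <- data.frame(r = c(0.1, 0.5, 0.9), n = c(30, 10, 5))
  expect_equal(order(deletion_weights(dc, "MNAR")), c(1, 2, 3))

  d$sd_c[1] <- NA
  expect_error(deletion_weights(d, "MNAR"), "complete")
})

test_that("apply_deletion removes exact paired counts and nothing else", {
  d <- simulate_md_data(100, seed = 2)

  zero <- apply_deletion(d, "MCAR", "BOTH", 0, seed = 3)
  expect_equal(as.data.frame(zero), d, ignore_attr = TRUE)
  expect_false(any(attr(zero, "sd_deleted")))

  inc <- apply_deletion(d, "MCAR", "SD", 0.5, seed = 4)
  expect_equal(sum(is.na(inc$sd_c)), 50)
  expect_identical(is.na(inc$sd_c), is.na(inc$sd_t))  # paired deletion
  expect_false(anyNA(inc$n_c))
  # surviving values unaltered
  keep <- !is.na(inc$sd_c)
  expect_identical(inc$sd_c[keep], d$sd_c[keep])
  expect_identical(inc$mean_t, d$mean_t)

  both <- apply_deletion(d, "MNAR", "BOTH", 0.3, seed = 5)
  expect_equal(sum(is.na(both$sd_t)), 30)
  expect_equal(sum(is.na(both$n_t)), 30)
  expect_identical(is.na(both$n_c), is.na(both$n_t))

  dc <- simulate_cor_data(40, seed = 6)
  expect_error(apply_deletion(dc, "MCAR", "SD", 0.2), "target")
  expect_error(apply_deletion(d, "MCAR", "SD", 1.2), "fraction")
  expect_error(apply_deletion(both, "MCAR", "SD", 0.1), "complete")
})

test_that("MAR deletion frequency increases with the weight rank", {
  d <- simulate_md_data(100, seed = 7)
  w <- deletion_weights(d, "MAR")
  reps <- 4000
  cnt <- numeric(100)
  set.seed(8)
  for (i in seq_len(reps)) {
    cnt <- cnt + is.na(apply_deletion(d, "MAR", "SS", 0.3)$n_c)
  }
  freq <- cnt[order(w)] / reps
  iso <- stats::isoreg(freq)
  r2 <- 1 - sum((iso$y - iso$yf)^2) / sum((iso$y - mean(iso$y))^2)
  expect_gt(r2, 0.99)
})

test_that("MCAR masks are uniform and SD/SS masks independent", {
  d <- simulate_md_data(50, seed = 9)
  reps <- 2000
  cnt <- numeric(50)
  joint <- matrix(0, 2, 2)
  set.seed(10)
  for (i in seq_len(reps)) {
    inc <- apply_deletion(d, "corMCAR", "BOTH", 0.3)
    sd_m <- is.na(inc$sd_c)
    ss_m <- is.na(inc$n_c)
    cnt <- cnt + sd_m
    joint <- joint + table(factor(sd_m, c(FALSE, TRUE)),
                           factor(ss_m, c(FALSE, TRUE)))
  }
  mc_se <- sqrt(0.3 * 0.7 / reps)
  expect_lt(max(abs(cnt / reps - 0.3)), 5 * mc_se)
  expect_gt(suppressWarnings(stats::chisq.test(joint)$p.value), 0.001)
})
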