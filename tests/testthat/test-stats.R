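test_that("bootstrap p-value follows the (count+1)/(n+1) formula", {
  # strongly one-sided sample: no resampled mean can fall at or below 0,
  # so the count on the null side is 0 and p attains its minimum 1/(n+1)
  bt <- bootstrap_test(rep(5, 10), mean, baseline = 0, n = 10000,
                       side = "greater", seed = 1)
  expect_equal(bt$p_value, 1 / 10001)
  expect_equal(round(bt$p_value, 4), 1e-04)

  # count = n: every resampled statistic is on the null side
  bt2 <- bootstrap_test(rep(-5, 10), mean, baseline = 0, n = 200,
                        side = "greater", seed = 1)
  expect_equal(bt2$p_value, 1)

  # generic consistency between the retained distribution and the p-value
  bt3 <- bootstrap_test(rnorm(20), mean, baseline = 0, n = 500,
                        side = "greater", seed = 7)
  expect_equal(bt3$p_value, (sum(bt3$boot <= 0) + 1) / 501)
  expect_gte(bt3$p_value, 1 / 501)
})

test_that("bootstrap test resamples groups independently and is seeded", {
  s <- list(a = rnorm(8), b = rnorm(8) + 3)
  stat <- function(x) median(x$b) - median(x$a)
  b1 <- bootstrap_test(s, stat, n = 200, side = "greater", seed = 3)
  b2 <- bootstrap_test(s, stat, n = 200, side = "greater", seed = 3)
  expect_identical(b1$boot, b2$boot)
  expect_lt(b1$p_value, 0.05)
  expect_true(b1$ci[1] <= b1$statistic && b1$statistic <= b1$ci[2])
})

test_that("permutation test matches exhaustive enumeration on a tiny instance", {
  x <- c(1.2, 3.4, 2.2); y <- c(5.1, 6.3)
  stat <- function(a, b) mean(a) - mean(b)
  # independent oracle: enumerate all choose(5, 3) = 10 relabelings directly
  pool <- c(x, y)
  idx <- combn(5, 3)
  null <- apply(idx, 2, function(i) stat(pool[i], pool[-i]))
  obs <- stat(x, y)
  p_low <- sum(null <= obs + 1e-12) / ncol(idx)
  res <- permutation_test(x, y, stat, n = 10000, side = "less")
  expect_equal(res$p_value, p_low)
  expect_equal(res$n_resamples, 10)
  expect_match(res$method, "exhaustive")
})

test_that("permutation test on identical groups is non-significant", {
  x <- rnorm(6); res <- permutation_test(x, x, n = 500, seed = 2)
  expect_gt(res$p_value, 0.5)
})

test_that("rank-sum matches exhaustive rank enumeration for small n", {
  x <- c(1.1, 4.2, 6.5, 9.9); y <- c(2.0, 3.1, 5.5, 7.2)
  # oracle: exact distribution of the rank-sum statistic by enumeration
  r <- rank(c(x, y))
  w_obs <- sum(r[1:4]) - 4 * 5 / 2           # Mann-Whitney U of x
  combs <- combn(8, 4)
  u_null <- apply(combs, 2, function(i) sum(r[i]) - 10)
  p_two <- sum(abs(u_null - 8) >= abs(w_obs - 8)) / ncol(combs)  # center U = nm/2
  res <- ranksum_test(x, y)
  expect_equal(res$p_value, p_two)
})

test_that("rank-sum and sign-rank handle degenerate input", {
  x <- rnorm(10)
  expect_gt(ranksum_test(x, x)$p_value, 0.5)
  expect_warning(r <- ranksum_test(rep(1, 5), rep(1, 6)), "tied")
  expect_equal(r$p_value, 1)
  expect_warning(s <- signrank_test(rep(0, 5)), "null value")
  expect_equal(s$p_value, 1)
  # a large common offset is detected by the sign-rank test
  expect_lt(signrank_test(rnorm(20) + 5)$p_value, 1e-3)
})

test_that("rank-sum detects a 1.5 SD shift with good power", {
  set.seed(41)
  hits <- mean(replicate(200, {
    ranksum_test(rnorm(20), rnorm(20) + 1.5)$p_value < 0.05
  }))
  expect_gt(hits, 0.8)
})

test_that("resampling tests keep nominal type-I error under the null", {
  set.seed(17)
  p_perm <- replicate(200, permutation_test(rnorm(5), rnorm(4),
                                            n = 200)$p_value)
  # binomial error around alpha = 0.05 for 200 simulations
  expect_lt(abs(mean(p_perm < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 200) + 0.01)
  p_rs <- replicate(200, ranksum_test(rnorm(8), rnorm(8))$p_value)
  expect_lt(mean(p_rs < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("Benjamini-Hochberg step-up matches the hand-applied rule", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.6)
  fc <- fdr_correct(p, alpha = 0.05)
  expect_equal(fc$adjusted, c(0.005, 0.02, 0.05125, 0.05125, 0.6))
  expect_equal(fc$flags, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_true(fdr_correct(0.01, 0.05)$flags)
  expect_false(any(fdr_correct(rep(1, 10))$flags))
  expect_length(fdr_correct(numeric(0))$flags, 0)
  # monotonicity: lowering alpha never adds flags
  fa <- fdr_correct(p, 0.05)$flags; fb <- fdr_correct(p, 0.01)$flags
  expect_true(all(fa | !fb))
})

test_that("summary-statistic t-test reproduces demographic p-values", {
  expect_equal(ttest_from_summary(63.41, 6.10, 22, 63.56, 6.41, 18)$p_value,
               0.94, tolerance = 0.005)
  expect_equal(ttest_from_summary(15, 4.18, 22, 14.72, 5.02, 18)$p_value,
               0.85, tolerance = 0.005)
  expect_equal(ttest_from_summary(10, 2, 10, 10, 2, 10)$p_value, 1)
  # Welch variant agrees with stats::t.test on raw data
  set.seed(8)
  a <- rnorm(12, 1, 1); b <- rnorm(9, 0, 2)
  w <- ttest_from_summary(mean(a), sd(a), 12, mean(b), sd(b), 9, welch = TRUE)
  expect_equal(w$p_value, t.test(a, b)$p.value, tolerance = 1e-10)
})

test_that("test results serialise to tidy records", {
  d <- as.data.frame(bootstrap_test(rnorm(10), mean, n = 50, seed = 1))
  expect_equal(nrow(d), 1)
  expect_true(all(c("method", "p_value", "ci_low", "se") %in% names(d)))
})
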