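test_that("permutation p uses the add-one convention and is seed-stable", {
  res <- permutation_test(0, function(i) stats::rnorm(1), 499,
                          alternative = "less", seed = 42)
  res2 <- permutation_test(0, function(i) stats::rnorm(1), 499,
                           alternative = "less", seed = 42)
  expect_identical(res$p_value, res2$p_value)
  expect_identical(res$null_value, res2$null_value)
  # observed below every resample hits the floor 1/(N+1)
  floor_res <- permutation_test(-10, function(i) stats::rnorm(1), 499,
                                alternative = "less", seed = 1)
  expect_equal(floor_res$p_value, 1 / 500)
  # observed at the null median gives p near 0.5
  mid <- permutation_test(0, function(i) stats::rnorm(1), 1999,
                          alternative = "less", seed = 3)
  expect_gt(mid$p_value, 0.4)
  expect_lt(mid$p_value, 0.6)
  expect_error(permutation_test(NaN, function(i) 1, 100, seed = 1),
               "not finite")
  expect_warning(permutation_test(0, function(i) stats::rnorm(1), 50,
                                  seed = 1), "fewer than 100")
})

test_that("Monte Carlo permutation agrees with exhaustive enumeration", {
  set.seed(21)
  for (rep in 1:25) {
    values <- stats::rnorm(8)
    is_a <- c(rep(TRUE, 4), rep(FALSE, 4))
    exact <- oracle_perm_p_less(values, is_a)
    mc <- permutation_test(
      mean(values[is_a]),
      function(i) mean(values[sample(8, 4)]),
      n_resamples = 4000, alternative = "less", seed = rep)
    # within 4 Monte-Carlo standard errors of the exhaustive value
    se <- sqrt(exact * (1 - exact) / 4000)
    expect_lt(abs(mc$p_value - exact), 4 * se + 1 / 4000)
  }
})

test_that("Spearman correlation matches the rank-formula oracle", {
  expect_equal(spearman_correlation(1:10, (1:10)^2)$statistic, 1)
  expect_equal(spearman_correlation(1:10, -(1:10))$statistic, -1)
  set.seed(22)
  for (rep in 1:200) {
    x <- stats::rnorm(6); y <- stats::rnorm(6)
    expect_equal(spearman_correlation(x, y)$statistic,
                 oracle_spearman_r(x, y), tolerance = 1e-12)
  }
  # mid-rank ties agree with the Pearson-on-ranks definition
  x <- c(1, 1, 2, 3, 4, 4); y <- c(2, 1, 3, 3, 5, 6)
  expect_equal(spearman_correlation(x, y)$statistic,
               stats::cor(rank(x), rank(y)))
  expect_error(spearman_correlation(rep(1, 5), 1:5), "constant")
})

test_that("KS statistic equals the pooled ECDF-scan oracle", {
  a <- stats::rnorm(30)
  expect_equal(ks_two_sample(a, a)$statistic, 0)
  expect_equal(ks_two_sample(1:50, 101:150)$statistic, 1)
  set.seed(23)
  for (rep in 1:200) {
    a <- stats::rnorm(sample(5:200, 1))
    b <- stats::rnorm(sample(5:200, 1), mean = stats::runif(1, -1, 1))
    expect_equal(ks_two_sample(a, b)$statistic, oracle_ks_D(a, b),
                 tolerance = 1e-12)
  }
})

test_that("Fisher exact matches hypergeometric enumeration", {
  res <- fisher_exact(matrix(c(1, 1, 1, 1), 2))
  expect_equal(res$statistic, 1)
  expect_equal(res$p_value, 1)
  r2 <- fisher_exact(matrix(c(10, 3, 2, 9), 2))
  expect_equal(r2$statistic, (10 * 9) / (2 * 3))
  expect_equal(r2$p_value, oracle_fisher_p(matrix(c(10, 3, 2, 9), 2)),
               tolerance = 1e-9)
  set.seed(24)
  for (rep in 1:300) {
    tab <- matrix(stats::rbinom(4, 30, 0.3), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact(tab)$p_value, oracle_fisher_p(tab),
                 tolerance = 1e-9)
  }
  # zero cell: Haldane-corrected OR, flagged; forced margins give p = 1
  z <- fisher_exact(matrix(c(5, 0, 7, 3), 2))
  expect_true(z$details$haldane)
  forced <- fisher_exact(matrix(c(4, 6, 0, 0), 2))
  expect_equal(forced$p_value, 1)
})

test_that("test_result enforces the p-value range invariant", {
  expect_error(test_result("m", 1, p_value = 0, n = 5, alternative = "less"))
  expect_error(test_result("m", 1, p_value = 1.2, n = 5, alternative = "less"))
})
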