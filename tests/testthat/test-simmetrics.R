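test_that("five-pair fixture matches a direct-formula recomputation", {
  b <- c(0.21, 0.18, 0.25, 0.19, 0.22)
  s <- c(0.02, 0.03, 0.025, 0.02, 0.03)
  truth <- 0.2
  got <- summarize_estimates(data.frame(beta_hat = b, se = s), truth)

  # spreadsheet-style recomputation, independent of the implementation
  n <- 5
  expect_equal(got$bias, mean(b) - truth, tolerance = 1e-12)
  expect_equal(got$empirical_se, sqrt(sum((b - mean(b))^2) / (n - 1)),
               tolerance = 1e-12)
  expect_equal(got$model_se, sqrt(mean(s^2)), tolerance = 1e-12)
  expect_equal(got$relative_error_model_se,
               100 * (sqrt(mean(s^2)) / sd(b) - 1), tolerance = 1e-12)
  expect_equal(got$mse, mean((b - truth)^2), tolerance = 1e-12)
  expect_equal(got$coverage, mean(abs(b - truth) <= 1.96 * s),
               tolerance = 1e-12)
  expect_equal(got$bias_eliminated_coverage,
               mean(abs(b - mean(b)) <= 1.96 * s), tolerance = 1e-12)
  expect_equal(got$bias_mcse, sd(b) / sqrt(n), tolerance = 1e-12)
  expect_equal(got$empirical_se_mcse, sd(b) / sqrt(2 * (n - 1)),
               tolerance = 1e-12)
  expect_equal(got$coverage_mcse,
               sqrt(got$coverage * (1 - got$coverage) / n), tolerance = 1e-12)
})

test_that("degenerate all-exact replicates give zero bias and full coverage", {
  d <- data.frame(beta_hat = rep(0.2, 10), se = 0.1)
  m <- summarize_estimates(d, 0.2)
  expect_identical(m$bias, 0)
  expect_identical(m$coverage, 1)
  expect_identical(m$bias_eliminated_coverage, 1)
  expect_identical(m$empirical_se, 0)
  expect_true(is.na(m$relative_error_model_se))
})

test_that("mse identity and replicate-order invariance hold", {
  set.seed(19)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    d <- data.frame(beta_hat = rnorm(n, 0.2, 0.1), se = runif(n, 0.05, 0.2))
    m <- summarize_estimates(d, 0.2)
    expect_equal(m$mse, m$bias^2 + m$empirical_se^2 * (n - 1) / n,
                 tolerance = 1e-12)
    m2 <- summarize_estimates(d[sample.int(n), ], 0.2)
    expect_equal(m2, m, tolerance = 1e-12)
  }
})

test_that("nominal coverage is calibrated for a correct Gaussian toy", {
  set.seed(20)
  n <- 10000
  d <- data.frame(beta_hat = rnorm(n, 0.2, 0.05), se = 0.05)
  m <- summarize_estimates(d, 0.2)
  # 1.96 intervals: expected coverage 0.95
  expect_lt(abs(m$coverage - 0.95), 0.007)
  expect_equal(m$coverage_mcse, sqrt(m$coverage * (1 - m$coverage) / n),
               tolerance = 1e-12)
})

test_that("NA replicates are excluded with a count; non-finite SEs error", {
  d <- data.frame(beta_hat = c(0.2, NA, 0.3, 0.1), se = c(0.1, NA, 0.1, 0.1))
  m <- summarize_estimates(d, 0.2)
  expect_identical(m$n_reps, 3L)
  expect_identical(m$n_excluded, 1L)
  bad <- data.frame(beta_hat = c(0.2, 0.3, 0.1), se = c(0.1, Inf, 0.1))
  expect_error(summarize_estimates(bad, 0.2), "replicate")
  expect_error(summarize_estimates(data.frame(beta_hat = 1, se = 1), 0.2),
               "at least 2")
})

test_that("r2 summaries use the reduced formula set", {
  x <- c(0.09, 0.11, 0.10, 0.08)
  m <- summarize_r2(x, 0.1)
  expect_equal(m$bias, mean(x) - 0.1, tolerance = 1e-12)
  expect_equal(m$empirical_se, sd(x), tolerance = 1e-12)
  expect_equal(m$mse, mean((x - 0.1)^2), tolerance = 1e-12)
  expect_null(m$coverage)
  expect_identical(summarize_r2(rep(0.1, 5), 0.1)$bias, 0)
})

test_that("zipper table ranks by |z| and is consistent with coverage", {
  b <- c(0.25, 0.19, 0.31, 0.205)
  s <- c(0.02, 0.02, 0.02, 0.02)
  zt <- zipper_table(data.frame(beta_hat = b, se = s), 0.2, fraction = 1)
  # hand ranking: |z| = 2.5, 0.5, 5.5, 0.25 -> order 3, 1, 2, 4
  expect_identical(zt$rep, c(3L, 1L, 2L, 4L))
  m <- summarize_estimates(data.frame(beta_hat = b, se = s), 0.2)
  expect_equal(mean(zt$covers), m$coverage, tolerance = 1e-12)

  half <- zipper_table(data.frame(beta_hat = b, se = s), 0.2, fraction = 0.5)
  expect_identical(nrow(half), 2L)
  expect_identical(half$rep, c(3L, 1L))
  expect_error(zipper_table(data.frame(beta_hat = b, se = s), 0.2, 0),
               "fraction")
})

test_that("symmetric null gives balanced left/right non-coverage", {
  set.seed(21)
  b <- rnorm(20000, 0.2, 0.06)
  zt <- zipper_table(data.frame(beta_hat = b, se = 0.05), 0.2, fraction = 1)
  miss <- zt[!zt$covers, ]
  frac_left <- mean(miss$beta_hat < 0.2)
  expect_lt(abs(frac_left - 0.5), 3 * sqrt(0.25 / nrow(miss)))
})

test_that("precision gain compares arms against the external reference", {
  metrics <- data.frame(framework = c("external", "overlap"),
                        threshold = c(0.05, 0.05),
                        statistic = "beta_hat",
                        empirical_se = c(0.02, 0.01))
  out <- jackknifeMR:::add_precision_gain(metrics, c("threshold", "statistic"))
  expect_equal(out$precision_gain_vs_external,
               c(0, 100 * ((0.02 / 0.01)^2 - 1)), tolerance = 1e-12)
})
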