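test_that("IV with instrument equal to the exposure degenerates to OLS", {
  set.seed(1)
  x <- rnorm(200)
  y <- 0.4 * x + rnorm(200)
  iv <- tsls_fit(y, x, x)
  ols <- summary(lm(y ~ x))$coefficients
  expect_equal(iv$beta_hat, ols[2, 1], tolerance = 1e-12)
  expect_equal(iv$se, ols[2, 2], tolerance = 1e-12)
  expect_gt(iv$fstat, 1e12) # overflow-guarded: perfect first stage
})

test_that("eight-point fixture matches the explicit two-stage oracle", {
  y <- c(1.2, 0.4, -0.3, 2.1, 1.0, -0.8, 0.6, 1.7)
  x <- c(0.5, 0.1, -0.6, 1.4, 0.8, -1.0, 0.2, 1.1)
  z <- c(1, 0, -1, 2, 1, -2, 0, 2)
  got <- tsls_fit(y, x, z)
  want <- oracle_tsls(y, x, z)
  expect_equal(got$beta_hat, want$beta, tolerance = 1e-10)
  expect_equal(got$se, want$se, tolerance = 1e-10)
  expect_equal(got$ci_low, want$beta - 1.96 * want$se, tolerance = 1e-10)
  expect_equal(got$ci_high, want$beta + 1.96 * want$se, tolerance = 1e-10)
})

test_that("2SLS is invariant to instrument rescaling", {
  set.seed(3)
  z <- rnorm(300); x <- z + rnorm(300); y <- 0.2 * x + rnorm(300)
  a <- tsls_fit(y, x, z)
  b <- tsls_fit(y, x, -41.7 * z)
  expect_equal(a$beta_hat, b$beta_hat, tolerance = 1e-10)
  expect_equal(a$se, b$se, tolerance = 1e-10)
  expect_equal(a$fstat, b$fstat, tolerance = 1e-9)
})

test_that("first-stage F equals the squared t and the RSS oracle", {
  set.seed(5)
  z <- rnorm(50); x <- 0.5 * z + rnorm(50)
  f <- first_stage_fstat(x, z)
  tval <- summary(lm(x ~ z))$coefficients[2, 3]
  expect_equal(f, tval^2, tolerance = 1e-10)

  # 20-observation toy with a covariate, vs brute-force nested-model RSS
  set.seed(6)
  W <- matrix(rnorm(20), 20, 1)
  z2 <- rnorm(20); x2 <- 0.3 * z2 + 0.5 * W[, 1] + rnorm(20)
  expect_equal(first_stage_fstat(x2, z2, W), oracle_fstat(x2, z2, W),
               tolerance = 1e-10)

  expect_gt(first_stage_fstat(x, x), 1e12)
})

test_that("adjusted R2 follows the small-sample correction formula", {
  x <- c(1, 2, 3, 4, 5)
  s <- c(1.1, 1.9, 3.2, 3.8, 5.1)
  r2 <- cor(x, s)^2
  expect_equal(adjusted_r2(x, s), 1 - (1 - r2) * 4 / 3, tolerance = 1e-12)
  expect_equal(adjusted_r2(x, 2 * x + 1), 1, tolerance = 1e-12)
  set.seed(7)
  expect_lt(abs(adjusted_r2(rnorm(5000), rnorm(5000))), 0.002)
  expect_error(adjusted_r2(c(1, 2), c(1, 2)), "observations")
})

test_that("rank-based inverse normal transform uses Blom offsets and preserves order", {
  got <- rank_inverse_normal(c(3, 1, 2))
  want <- qnorm((c(3, 1, 2) - 0.375) / 3.25)
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(got[2], -got[1], tolerance = 1e-12) # symmetric around 0
  expect_equal(got[3], 0, tolerance = 1e-12)
  expect_equal(got[1], 0.8694240, tolerance = 1e-6)

  set.seed(8)
  x <- rgamma(1000, 2)
  z <- rank_inverse_normal(x)
  expect_identical(order(z), order(x))
  xn <- rnorm(1000)
  expect_gt(cor(xn, rank_inverse_normal(xn)), 0.99)

  # ties share the average rank
  expect_equal(rank_inverse_normal(c(1, 1, 2))[1],
               rank_inverse_normal(c(1, 1, 2))[2])
  expect_error(rank_inverse_normal(rep(2, 5)), "constant")
  expect_error(rank_inverse_normal(1), "at least 2")
})

test_that("2SLS removes confounding that biases OLS upward", {
  p <- sim_params(n_applied = 5000, n_snp = 60, n_block = 5)
  ols_gt_iv <- 0L
  reps <- 30L
  for (r in seq_len(reps)) {
    set.seed(2000 + r)
    co <- simulate_cohort(p, allocate_true_effects(p), "applied")
    s <- overlap_prs(co, 1)
    iv <- tsls_fit(co$outcome, co$exposure, s)
    ols <- unname(coef(lm(co$outcome ~ co$exposure))[2])
    ols_gt_iv <- ols_gt_iv + (ols > iv$beta_hat)
  }
  expect_identical(ols_gt_iv, reps)
})

test_that("2SLS is consistent at large n with a strong external instrument", {
  p <- sim_params(n_applied = 200000, n_external = 50000, n_snp = 500)
  set.seed(12)
  pair <- simulate_scenario_pair(p)
  s <- external_prs(pair$applied, pair$external, 1e-4)
  fit <- tsls_fit(pair$applied$outcome, pair$applied$exposure, s,
                  true_value = 0.2)
  expect_lt(abs(fit$beta_hat - 0.2), 3 * fit$se)
  expect_lt(fit$se, 0.01)
  expect_gt(fit$fstat, 100)
  expect_equal(fit$z, (fit$beta_hat - 0.2) / fit$se, tolerance = 1e-12)
})

test_that("engine fast path agrees with the public 2SLS fit", {
  co <- small_cohort(n = 800, m = 40, seed = 51)
  s <- overlap_prs(co, 0.1)
  pub <- tsls_fit(co$outcome, co$exposure, s)
  quick <- jackknifeMR:::tsls_quick(co$outcome, co$exposure, s$values)
  expect_equal(quick$beta_hat, pub$beta_hat, tolerance = 1e-10)
  expect_equal(quick$se, pub$se, tolerance = 1e-10)
  expect_equal(quick$fstat, pub$fstat, tolerance = 1e-8)
  expect_equal(quick$r2_adj, pub$r2_adj, tolerance = 1e-10)
})

test_that("multivariable 2SLS solves the just-identified moment equations", {
  set.seed(14)
  n <- 3000
  z1 <- rnorm(n); z2 <- rnorm(n)
  x1 <- z1 + 0.2 * z2 + rnorm(n)
  x2 <- z2 + rnorm(n)
  y <- 0.5 * x1 - 0.3 * x2 + rnorm(n)
  fit <- tsls_multivariable(y, cbind(x1 = x1, x2 = x2), list(z1, z2))
  resid <- y - cbind(1, x1, x2) %*% c(mean(y) - sum(fit$beta_hat * c(mean(x1), mean(x2))),
                                      fit$beta_hat)
  # moment conditions Z'(y - X beta) = 0 at the estimate
  expect_lt(abs(sum(z1 * (resid - mean(resid)))), 1e-6 * n)
  expect_lt(abs(sum(z2 * (resid - mean(resid)))), 1e-6 * n)
  expect_equal(unname(fit$beta_hat), c(0.5, -0.3), tolerance = 0.1)
  expect_error(tsls_multivariable(y, cbind(x1, x2), list(z1, z1)),
               "rank|collinear")
})

test_that("an irrelevant second exposure leaves the first estimate unchanged", {
  set.seed(15)
  n <- 4000
  z1 <- rnorm(n); x1 <- z1 + rnorm(n)
  y <- 0.3 * x1 + rnorm(n)
  z2 <- rnorm(n); x2 <- z2 + rnorm(n) # pure noise exposure, valid instrument
  uni <- tsls_fit(y, x1, z1)
  multi <- tsls_multivariable(y, cbind(x1 = x1, x2 = x2), list(z1, z2))
  expect_lt(abs(multi$beta_hat["x1"] - uni$beta_hat), 2 * uni$se)
  expect_lt(abs(multi$beta_hat["x2"]), 3 * multi$se["x2"])
})

test_that("multivariable MR separates direct and mediated effects", {
  # mediation: child -> adult -> outcome with no direct child path
  p <- sim_params(n_applied = 50000, n_snp = 200, n_block = 5)
  set.seed(16)
  G1 <- jackknifeMR:::.sim_genotypes_cpp(50000L, 100L, 0.2)
  G2 <- jackknifeMR:::.sim_genotypes_cpp(50000L, 100L, 0.2)
  b1 <- rnorm(100, 0, 0.1)
  b2 <- rnorm(100, 0, 0.1)
  x_child <- as.vector(G1 %*% b1) + rnorm(50000, 0, 0.8)
  x_adult <- 0.6 * x_child + as.vector(G2 %*% b2) + rnorm(50000, 0, 0.6)
  y <- 0.5 * x_adult + rnorm(50000)
  s1 <- as.vector(G1 %*% b1) # strong valid scores
  s2 <- as.vector(G2 %*% b2)
  uni <- tsls_fit(y, x_child, s1)
  multi <- tsls_multivariable(y, cbind(child = x_child, adult = x_adult),
                              list(s1, s2))
  expect_equal(uni$beta_hat, 0.3, tolerance = 0.2) # total = 0.6 * 0.5
  expect_lt(abs(multi$beta_hat["child"]), 3 * multi$se["child"]) # no direct
  expect_equal(unname(multi$beta_hat["adult"]), 0.5, tolerance = 0.08)
  expect_true(all(multi$fstat > 10))
})
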