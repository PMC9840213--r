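# Independent oracles and small fixture builders used across the suite.
# Everything here is deliberately naive (loop-and-solve) so it cannot share
# a code path with the package implementation it checks.

# Per-SNP OLS scan via lm(), one SNP at a time.
oracle_gwas <- function(G, y) {
  out <- lapply(seq_len(ncol(G)), function(j) {
    fit <- summary(stats::lm(y ~ G[, j]))
    co <- stats::coef(fit)
    data.frame(snp_id = j, beta_hat = co[2, 1], se = co[2, 2],
               pvalue = co[2, 4])
  })
  do.call(rbind, out)
}

# Explicit two-stage 2SLS with the corrected residual variance: stage one
# fits x ~ z, stage two fits y ~ fitted(x), then sigma^2 is recomputed from
# y - a - b * x (observed exposure) and the naive second-stage covariance is
# rescaled accordingly.
oracle_tsls <- function(y, x, z) {
  s1 <- stats::lm(x ~ z)
  xhat <- stats::fitted(s1)
  s2 <- stats::lm(y ~ xhat)
  b <- stats::coef(s2)
  resid_struct <- y - b[1] - b[2] * x
  n <- length(y)
  sigma2 <- sum(resid_struct^2) / (n - 2)
  Xh <- cbind(1, xhat)
  covb <- sigma2 * solve(crossprod(Xh))
  list(beta = unname(b[2]), se = sqrt(covb[2, 2]))
}

# Nested-model RSS F-test for an instrument block.
oracle_fstat <- function(x, z, W = NULL) {
  full <- if (is.null(W)) stats::lm(x ~ z) else stats::lm(x ~ z + W)
  red <- if (is.null(W)) stats::lm(x ~ 1) else stats::lm(x ~ W)
  rss1 <- sum(stats::resid(full)^2)
  rss0 <- sum(stats::resid(red)^2)
  q <- length(stats::coef(full)) - length(stats::coef(red))
  ((rss0 - rss1) / q) / (rss1 / stats::df.residual(full))
}

# Small cohort helper used by framework and MR tests.
small_cohort <- function(n = 400, m = 30, seed = 1, role = "applied",
                         params = NULL) {
  if (is.null(params))
    params <- sim_params(n_applied = n, n_external = n, n_snp = m,
                         n_block = 4)
  set.seed(seed)
  simulate_cohort(params, allocate_true_effects(params), role)
}
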