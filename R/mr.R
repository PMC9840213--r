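# Core 2SLS engine. y: outcome; X: n x p matrix of endogenous regressors
# (exposures); Z: n x q matrix of instruments, q >= p; W: optional covariate
# matrix. An intercept (and W) enters both stages. Point estimates solve the
# projected normal equations (Xhat' X) beta = Xhat' y with Xhat the
# projection of X onto [1, Z, W]; the variance uses the conventional
# homoskedastic model-based estimator sigma^2 (Xhat' Xhat)^{-1} with
# sigma^2 from residuals against the OBSERVED exposures, y - [1, X, W] b,
# divided by n - #regressors.
tsls_engine <- function(y, X, Z, W = NULL) {
  n <- length(y)
  X <- as.matrix(X); Z <- as.matrix(Z)
  Zfull <- cbind(`(Intercept)` = 1, Z, W)
  Xfull <- cbind(`(Intercept)` = 1, X, W)
  if (ncol(Z) < ncol(X))
    stop("under-identified system: fewer instruments than exposures")
  qz <- qr(Zfull)
  if (qz$rank < ncol(Zfull))
    stop("rank-deficient instrument/covariate matrix (collinear columns)")
  Xhat <- qr.fitted(qz, Xfull)
  XtX <- crossprod(Xhat)
  if (rcond(XtX) < 1e-14)
    stop("rank-deficient projected design: instruments too weak or collinear")
  coefs <- drop(solve(XtX, crossprod(Xhat, y)))
  resid <- drop(y - Xfull %*% coefs)
  df <- n - ncol(Xfull)
  sigma2 <- sum(resid^2) / df
  covb <- sigma2 * solve(XtX)
  list(coefs = coefs, se = sqrt(diag(covb)), sigma2 = sigma2, df = df,
       resid = resid, exposure_idx = 1 + seq_len(ncol(X)))
}

# Partial F of an instrument block: compare RSS of target ~ [1, W] against
# target ~ [1, Z, W].
partial_fstat <- function(target, Z, W = NULL) {
  n <- length(target)
  Z <- as.matrix(Z)
  full <- cbind(rep(1, n), Z, W)
  red <- cbind(rep(1, n), W)
  rss1 <- sum(qr.resid(qr(full), target)^2)
  rss0 <- sum(qr.resid(qr(red), target)^2)
  q <- ncol(full) - ncol(red)
  k <- ncol(full)
  if (rss1 <= 0) return(Inf)
  ((rss0 - rss1) / q) / (rss1 / (n - k))
}

#' First-stage F-statistic
#'
#' Instrument-strength diagnostic: the partial F of the instrument block in
#' the first-stage regression of the exposure on instruments (plus
#' covariates and intercept). For a single instrument this equals the
#' squared t-statistic of its first-stage slope. A perfect fit returns
#' `Inf`.
#'
#' @param exposure Length-n numeric vector.
#' @param instrument A `prs_score`, numeric vector, or matrix of
#'   instruments.
#' @param covariates Optional numeric matrix of covariates.
#' @return The F value (possibly `Inf`).
#' @export
first_stage_fstat <- function(exposure, instrument, covariates = NULL) {
  Z <- if (inherits(instrument, "prs_score")) instrument$values else instrument
  partial_fstat(as.numeric(exposure), Z, covariates)
}

#' Adjusted R-squared of the exposure on a score
#'
#' Univariate fit diagnostic: \eqn{1 - (1 - R^2)(n - 1)/(n - 2)} where
#' \eqn{R^2} is the squared sample correlation between exposure and score.
#' Can be slightly negative for an uninformative score.
#'
#' @param exposure Length-n numeric vector (n > 2).
#' @param score A `prs_score` or numeric vector.
#' @return The adjusted R-squared.
#' @export
adjusted_r2 <- function(exposure, score) {
  s <- score_values(score)
  n <- length(exposure)
  if (n <= 2) stop("need more than 2 observations")
  r2 <- stats::cor(exposure, s)^2
  1 - (1 - r2) * (n - 1) / (n - 2)
}

#' One-sample Mendelian randomization by two-stage least squares
#'
#' Fits the just-identified IV model with a single exposure and a single
#' instrument (typically an allele score): the first stage regresses the
#' exposure on the instrument, the second stage regresses the outcome on the
#' predicted exposure. The reported standard error is the conventional
#' homoskedastic model-based 2SLS SE, computed from second-stage residuals
#' using the observed (not fitted) exposure. The 95% CI uses the normal
#' multiplier 1.96.
#'
#' @param outcome Length-n numeric vector.
#' @param exposure Length-n numeric vector.
#' @param instrument A `prs_score` or numeric vector with non-zero variance.
#' @param covariates Optional numeric matrix included in both stages.
#' @param true_value Optional true causal effect; when supplied the fit
#'   carries the standardized deviation `z = (beta_hat - true) / se`.
#' @return An object of class `mr_fit`: list with `beta_hat`, `se`,
#'   `ci_low`, `ci_high`, `fstat` (first-stage F), `r2_adj` (adjusted
#'   R-squared of exposure on instrument), `n`, `n_snps`, `framework`,
#'   `threshold`, and `z` when `true_value` is given.
#' @examples
#' set.seed(1)
#' z <- rnorm(500); x <- z + rnorm(500); y <- 0.5 * x + rnorm(500)
#' tsls_fit(y, x, z)
#' @export
tsls_fit <- function(outcome, exposure, instrument, covariates = NULL,
                     true_value = NULL) {
  z <- score_values(instrument)
  n <- length(outcome)
  stopifnot(length(exposure) == n, length(z) == n)
  if (stats::var(z) <= 0) {
    lab <- if (inherits(instrument, "prs_score"))
      sprintf(" (framework %s, threshold %s)", instrument$framework,
              format(instrument$threshold)) else ""
    stop("empty or constant instrument: no SNPs selected", lab)
  }
  fit <- tsls_engine(outcome, matrix(exposure, ncol = 1), matrix(z, ncol = 1),
                     covariates)
  beta <- fit$coefs[2]
  se <- fit$se[2]
  out <- list(beta_hat = unname(beta), se = unname(se),
              ci_low = unname(beta - 1.96 * se),
              ci_high = unname(beta + 1.96 * se),
              fstat = partial_fstat(exposure, z, covariates),
              r2_adj = adjusted_r2(exposure, z),
              sigma2 = fit$sigma2, n = n,
              n_snps = if (inherits(instrument, "prs_score"))
                instrument$n_snps_used else NA_real_,
              framework = if (inherits(instrument, "prs_score"))
                instrument$framework else "unspecified",
              threshold = if (inherits(instrument, "prs_score"))
                instrument$threshold else NA_real_)
  if (!is.null(true_value)) out$z <- (out$beta_hat - true_value) / out$se
  structure(out, class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, ...) {
  cat("One-sample MR (2SLS)\n")
  k <- length(x$beta_hat)
  lab <- if (k > 1) names(x$beta_hat) else x$framework
  for (i in seq_len(k)) {
    cat(sprintf("  %s: beta = %.4f (SE %.4f), 95%% CI [%.4f, %.4f]\n",
                if (is.null(lab[i]) || is.na(lab[i])) "exposure" else lab[i],
                x$beta_hat[i], x$se[i], x$ci_low[i], x$ci_high[i]))
  }
  cat(sprintf("  first-stage F: %s;  n = %d\n",
              paste(formatC(x$fstat, digits = 4, format = "g"),
                    collapse = ", "), x$n))
  invisible(x)
}

#' Multivariable one-sample MR by two-stage least squares
#'
#' Joint IV estimation of the direct effects of two exposures, each with its
#' own allele-score instrument (a just-identified 2 x 2 system). Standard
#' errors follow the same homoskedastic model-based convention as
#' [tsls_fit()]. The per-exposure conditional F-statistic is computed
#' Sanderson-Windmeijer style: each exposure is residualized on the other
#' exposure's first-stage prediction (plus covariates), and the partial F of
#' the instrument block for that residual is reported with one degree of
#' freedom absorbed per conditioned exposure.
#'
#' @param outcome Length-n numeric vector.
#' @param exposures n x 2 matrix (or data frame / list of two vectors).
#' @param instruments List of two `prs_score` objects or numeric vectors.
#' @param covariates Optional numeric matrix included in both stages.
#' @param true_value Optional length-2 vector of true direct effects.
#' @return An `mr_fit` with vector-valued `beta_hat`, `se`, `ci_low`,
#'   `ci_high`, `fstat` (conditional F per exposure).
#' @export
tsls_multivariable <- function(outcome, exposures, instruments,
                               covariates = NULL, true_value = NULL) {
  if (is.list(exposures) && !is.data.frame(exposures))
    exposures <- do.call(cbind, exposures)
  X <- as.matrix(exposures)
  if (is.null(colnames(X))) colnames(X) <- paste0("exposure", seq_len(ncol(X)))
  Z <- do.call(cbind, lapply(instruments, score_values))
  n <- length(outcome)
  stopifnot(nrow(X) == n, nrow(Z) == n)
  fit <- tsls_engine(outcome, X, Z, covariates)
  idx <- fit$exposure_idx
  beta <- fit$coefs[idx]
  se <- fit$se[idx]
  names(beta) <- names(se) <- colnames(X)
  # conditional F: first-stage fitted values of each exposure
  Zfull <- cbind(1, Z, covariates)
  qz <- qr(Zfull)
  Fhat <- qr.fitted(qz, X)
  condF <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    others <- Fhat[, -j, drop = FALSE]
    e <- qr.resid(qr(cbind(1, others, covariates)), X[, j])
    n_inst <- ncol(Z)
    q_eff <- n_inst - (ncol(X) - 1)
    if (q_eff < 1) q_eff <- 1
    rss1 <- sum(qr.resid(qz, e)^2)
    rss0 <- sum(qr.resid(qr(cbind(rep(1, n), covariates)), e)^2)
    k <- ncol(Zfull)
    condF[j] <- if (rss1 <= 0) Inf else
      ((rss0 - rss1) / q_eff) / (rss1 / (n - k))
  }
  names(condF) <- colnames(X)
  out <- list(beta_hat = beta, se = se, ci_low = beta - 1.96 * se,
              ci_high = beta + 1.96 * se, fstat = condF,
              r2_adj = vapply(seq_len(ncol(X)), function(j)
                adjusted_r2(X[, j], Z[, j]), numeric(1)),
              sigma2 = fit$sigma2, n = n, framework = "multivariable",
              threshold = NA_real_)
  if (!is.null(true_value)) out$z <- (beta - true_value) / se
  structure(out, class = "mr_fit")
}

#' Rank-based inverse normal transformation
#'
#' Maps values through their ranks to normal quantiles with the Blom offset:
#' \eqn{\Phi^{-1}((r_i - 3/8)/(n + 1/4))}, ties sharing the average rank.
#' Used to enforce marginal normality of a phenotype before MR.
#'
#' @param values Numeric vector, length at least 2, not all equal.
#' @return Numeric vector of normal scores, monotone in the input.
#' @examples
#' rank_inverse_normal(c(3, 1, 2))
#' @export
rank_inverse_normal <- function(values) {
  n <- length(values)
  if (n < 2) stop("need at least 2 values")
  if (max(values) == min(values))
    stop("constant vector: all ranks tied, transformation undefined")
  r <- rank(values, ties.method = "average")
  stats::qnorm((r - 0.375) / (n + 0.25))
}
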