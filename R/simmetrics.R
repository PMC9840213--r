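#' Monte Carlo performance metrics for replicate estimates
#'
#' Summarizes a table of per-replicate estimates and model-based standard
#' errors against a known true value, following standard simulation-study
#' methodology: bias, empirical SE (SD of estimates, n - 1 denominator),
#' model-based SE (root mean of squared SEs), relative error in model SE,
#' MSE, coverage of nominal 95% intervals (`estimate +/- 1.96 se`),
#' bias-eliminated coverage (truth replaced by the mean estimate), each with
#' its Monte Carlo standard error where estimable.
#'
#' Rows with `NA` estimates (e.g. replicates whose instrument was empty) are
#' excluded and counted in `n_excluded`; any remaining non-finite SE is an
#' error naming the offending replicate.
#'
#' @param estimates Data frame with columns `beta_hat` and `se` (extra
#'   columns are ignored), or a numeric vector of estimates plus `se`.
#' @param true_value The true parameter value.
#' @param se Standard errors when `estimates` is a bare numeric vector.
#' @return A one-row data frame of class `metrics_row`.
#' @examples
#' set.seed(1)
#' b <- rnorm(1000, 0.2, 0.05)
#' summarize_estimates(data.frame(beta_hat = b, se = 0.05), 0.2)
#' @export
summarize_estimates <- function(estimates, true_value, se = NULL) {
  if (!is.data.frame(estimates))
    estimates <- data.frame(beta_hat = estimates, se = se)
  keep <- !is.na(estimates$beta_hat) & !is.na(estimates$se)
  n_excluded <- sum(!keep)
  b <- estimates$beta_hat[keep]
  s <- estimates$se[keep]
  if (length(b) < 2) stop("need at least 2 usable replicates")
  bad <- which(!is.finite(s) | !is.finite(b))
  if (length(bad))
    stop("non-finite estimate or se in replicate(s): ",
         paste(which(keep)[bad], collapse = ", "))
  n <- length(b)
  emp_se <- stats::sd(b)
  mod_se <- sqrt(mean(s^2))
  bias <- mean(b) - true_value
  mse <- mean((b - true_value)^2)
  cov <- mean(abs(b - true_value) <= 1.96 * s)
  becov <- mean(abs(b - mean(b)) <= 1.96 * s)
  out <- data.frame(
    n_reps = n, n_excluded = n_excluded,
    mean = mean(b), mean_mcse = emp_se / sqrt(n),
    median = stats::median(b),
    bias = bias, bias_mcse = emp_se / sqrt(n),
    empirical_se = emp_se,
    empirical_se_mcse = emp_se / sqrt(2 * (n - 1)),
    model_se = mod_se,
    model_se_mcse = sqrt(stats::var(s^2) / (4 * n * mod_se^2)),
    relative_error_model_se = if (emp_se > 0)
      100 * (mod_se / emp_se - 1) else NA_real_,
    mse = mse, mse_mcse = stats::sd((b - true_value)^2) / sqrt(n),
    coverage = cov, coverage_mcse = sqrt(cov * (1 - cov) / n),
    bias_eliminated_coverage = becov,
    bias_eliminated_coverage_mcse = sqrt(becov * (1 - becov) / n))
  class(out) <- c("metrics_row", "data.frame")
  out
}

#' Monte Carlo metrics for a per-replicate R-squared (or any scalar without
#' a per-replicate SE)
#'
#' Same summaries as [summarize_estimates()] restricted to what is estimable
#' without per-replicate standard errors: mean, median, bias, empirical SE,
#' MSE, and their Monte Carlo standard errors. No coverage or model-SE
#' fields.
#'
#' @param r2 Numeric vector of per-replicate values, or a data frame with a
#'   `r2_adj` column.
#' @param true_value True value of the statistic (e.g. 0.1 for the variance
#'   explained by the score under the primary conditions).
#' @return A one-row data frame of class `metrics_row`.
#' @export
summarize_r2 <- function(r2, true_value) {
  if (is.data.frame(r2)) r2 <- r2$r2_adj
  n_excluded <- sum(is.na(r2))
  x <- r2[!is.na(r2)]
  if (length(x) < 2) stop("need at least 2 usable replicates")
  n <- length(x)
  emp_se <- stats::sd(x)
  out <- data.frame(
    n_reps = n, n_excluded = n_excluded,
    mean = mean(x), mean_mcse = emp_se / sqrt(n),
    median = stats::median(x),
    bias = mean(x) - true_value, bias_mcse = emp_se / sqrt(n),
    empirical_se = emp_se,
    empirical_se_mcse = emp_se / sqrt(2 * (n - 1)),
    mse = mean((x - true_value)^2),
    mse_mcse = stats::sd((x - true_value)^2) / sqrt(n))
  class(out) <- c("metrics_row", "data.frame")
  out
}

#' Zipper-plot table of ranked confidence intervals
#'
#' Computes the standardized deviation `z = (beta_hat - true)/se` per
#' replicate, ranks replicates by `|z|` in descending order, and returns the
#' top `fraction` of them with their 95% CIs and a covers-truth flag — the
#' table behind a "zipper plot" of the worst-covered intervals.
#'
#' @param fits Data frame with columns `beta_hat` and `se` (a `rep` column
#'   is carried through if present).
#' @param true_value True parameter value.
#' @param fraction Fraction of replicates to keep, in (0, 1\]; default 0.5.
#' @return Data frame with columns `rep`, `beta_hat`, `se`, `z`, `centile`
#'   (fractional rank of `|z|`, 1 = most extreme), `ci_low`, `ci_high`,
#'   `covers`.
#' @export
zipper_table <- function(fits, true_value, fraction = 0.5) {
  if (length(fraction) != 1L || fraction <= 0 || fraction > 1)
    stop("'fraction' must lie in (0, 1]")
  keep <- !is.na(fits$beta_hat) & !is.na(fits$se)
  b <- fits$beta_hat[keep]
  s <- fits$se[keep]
  rep_id <- if (!is.null(fits$rep)) fits$rep[keep] else which(keep)
  z <- (b - true_value) / s
  ord <- order(abs(z), decreasing = TRUE)
  k <- ceiling(fraction * length(b))
  ord <- ord[seq_len(k)]
  data.frame(rep = rep_id[ord], beta_hat = b[ord], se = s[ord], z = z[ord],
             centile = rank(-abs(z))[ord] / length(b),
             ci_low = b[ord] - 1.96 * s[ord],
             ci_high = b[ord] + 1.96 * s[ord],
             covers = abs(b[ord] - true_value) <= 1.96 * s[ord])
}

# Percentage gain in precision of each framework relative to the external
# arm within the same scenario cell: 100 ((empSE_ext / empSE)^2 - 1).
# `metrics` must carry `framework`, `empirical_se` and the cell key columns.
add_precision_gain <- function(metrics, cell_keys) {
  metrics$precision_gain_vs_external <- NA_real_
  key <- interaction(metrics[cell_keys], drop = TRUE)
  for (cell in levels(key)) {
    rows <- which(key == cell)
    ext <- rows[metrics$framework[rows] == "external"]
    if (length(ext) != 1L) next
    metrics$precision_gain_vs_external[rows] <-
      100 * ((metrics$empirical_se[ext] / metrics$empirical_se[rows])^2 - 1)
  }
  metrics
}
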