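#' Default P-value threshold grid
#'
#' The 13 selection thresholds used throughout the simulation studies, from
#' the conventional genome-wide significance level up to no selection at all.
#'
#' @return Numeric vector of 13 P-value cutoffs in ascending order.
#' @export
default_thresholds <- function() {
  c(5e-8, 1e-7, 1e-6, 1e-5, 1e-4, 5e-4, 1e-3, 5e-3, 0.01, 0.05, 0.1, 0.5, 1)
}

#' Simulation parameters
#'
#' Bundles the generative parameters of the additive genetic + confounder
#' model used by [simulate_cohort()] and the scenario runners. Defaults are
#' the primary study conditions: applied and external cohorts of 50,000
#' individuals, 500 independent biallelic SNPs with effect-allele frequency
#' 0.2 jointly explaining 10% of the exposure variance, a true causal effect
#' of the exposure on the outcome of 0.2, and confounder effects of 0.4 on
#' the exposure and 0.3 on the outcome.
#'
#' @param n_applied Number of individuals in the applied cohort (the cohort
#'   used for score construction and MR).
#' @param n_external Number of individuals in the external discovery cohort.
#' @param n_snp Number of independent SNPs.
#' @param af Effect-allele frequency shared by all SNPs, in (0, 1).
#' @param var_exp Total fraction of exposure variance explained by all SNPs,
#'   in \[0, 1). The per-SNP effects are rescaled so that
#'   \eqn{\sum_j 2 af (1-af) b_j^2 = var\_exp} exactly.
#' @param beta_xy True causal effect of the exposure on the outcome.
#' @param beta_ux Confounder effect on the exposure.
#' @param beta_uy Confounder effect on the outcome.
#' @param n_block Number of jackknife blocks (at least 2).
#' @param thresholds P-value selection cutoffs, all in (0, 1\].
#' @param effect_mode How per-SNP effects are allocated before rescaling:
#'   `"gaussian"` draws standard-normal raw effects (the default, mirroring
#'   common GWAS simulators), `"equal"` gives every SNP the same effect.
#' @param seed Optional integer seed stored with the parameters; scenario
#'   runners use it as the root of per-replicate substreams.
#'
#' @return An object of class `sim_params` (a named list).
#' @examples
#' p <- sim_params(n_applied = 1000, n_external = 1000, n_snp = 50)
#' p$var_exp
#' @export
sim_params <- function(n_applied = 50000, n_external = 50000, n_snp = 500,
                       af = 0.2, var_exp = 0.1, beta_xy = 0.2,
                       beta_ux = 0.4, beta_uy = 0.3, n_block = 10,
                       thresholds = default_thresholds(),
                       effect_mode = c("gaussian", "equal"), seed = NULL) {
  effect_mode <- match.arg(effect_mode)
  p <- list(n_applied = as.integer(n_applied),
            n_external = as.integer(n_external),
            n_snp = as.integer(n_snp), af = af, var_exp = var_exp,
            beta_xy = beta_xy, beta_ux = beta_ux, beta_uy = beta_uy,
            n_block = as.integer(n_block), thresholds = thresholds,
            effect_mode = effect_mode, seed = seed)
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  stopifnot(is.numeric(p$af), length(p$af) == 1L)
  if (p$af <= 0 || p$af >= 1)
    stop("invalid parameters: 'af' must lie strictly between 0 and 1")
  if (p$var_exp < 0 || p$var_exp >= 1)
    stop("invalid parameters: 'var_exp' must lie in [0, 1)")
  if (p$n_applied < 1L || p$n_external < 1L)
    stop("invalid parameters: cohort sizes must be positive")
  if (p$n_snp < 1L)
    stop("invalid parameters: 'n_snp' must be positive")
  if (p$n_block < 2L)
    stop("invalid parameters: 'n_block' must be at least 2")
  if (any(p$thresholds <= 0) || any(p$thresholds > 1))
    stop("invalid parameters: thresholds must lie in (0, 1]")
  # residual variance of the exposure must stay positive for Var(X) = 1
  if (p$var_exp + p$beta_ux^2 >= 1)
    stop("invalid parameters: var_exp + beta_ux^2 must be < 1 so the ",
         "exposure residual variance is positive")
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Simulation parameters\n")
  cat(sprintf("  cohorts: applied n = %d, external n = %d\n",
              x$n_applied, x$n_external))
  cat(sprintf("  genetics: %d SNPs, AF = %g, Var_exp = %g (%s effects)\n",
              x$n_snp, x$af, x$var_exp, x$effect_mode))
  cat(sprintf("  structural: beta_xy = %g, beta_ux = %g, beta_uy = %g\n",
              x$beta_xy, x$beta_ux, x$beta_uy))
  cat(sprintf("  jackknife blocks: %d\n", x$n_block))
  cat(sprintf("  thresholds: %s\n",
              paste(format(x$thresholds, trim = TRUE), collapse = ", ")))
  invisible(x)
}

# Derive a per-replicate seed from a root seed. A fixed affine-mod map keeps
# replicate streams order-independent (replicate r always gets the same seed
# no matter how many replicates run, or in what order) while staying inside
# 32-bit integer range. `offset` separates scenarios sharing one root seed.
derive_seed <- function(root, rep, offset = 0L) {
  m <- 2147483647 # 2^31 - 1
  s <- (as.double(root) %% m) * 48271 + as.double(rep) * 16807 +
    as.double(offset) * 69621
  as.integer(s %% m) + 1L
}
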