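#' Allocate per-SNP effects under a fixed total variance-explained
#'
#' Draws one effect per SNP and rescales so the expected variance of the
#' genetic component, \eqn{\sum_j 2 af (1-af) b_j^2}, equals `var_exp`
#' exactly (to machine precision). In `"gaussian"` mode raw effects are
#' standard-normal draws before rescaling, so per-SNP effect sizes vary; in
#' `"equal"` mode every SNP gets \eqn{\sqrt{var\_exp / (m \cdot 2 af (1-af))}}.
#'
#' @param params A [sim_params()] object.
#' @return Numeric vector of length `params$n_snp` of per-allele effects.
#' @examples
#' set.seed(1)
#' b <- allocate_true_effects(sim_params(n_snp = 100))
#' sum(2 * 0.2 * 0.8 * b^2) # == var_exp
#' @export
allocate_true_effects <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  m <- params$n_snp
  if (params$var_exp == 0) return(numeric(m))
  het <- 2 * params$af * (1 - params$af)
  if (params$effect_mode == "equal") {
    return(rep(sqrt(params$var_exp / (m * het)), m))
  }
  raw <- stats::rnorm(m)
  raw * sqrt(params$var_exp / (het * sum(raw^2)))
}

# Phenotypes given a prefilled genotype matrix. Residual SDs are chosen so
# the exposure has unit variance with genetic fraction exactly var_exp, and
# (for applied cohorts) the outcome has unit variance under the structural
# model Y = beta_xy X + beta_uy U + e_Y with Cov(X, U) = beta_ux.
simulate_phenotypes <- function(G, effects, params, role) {
  n <- nrow(G)
  U <- stats::rnorm(n)
  sd_x <- sqrt(1 - params$var_exp - params$beta_ux^2)
  X <- as.vector(G %*% effects) + params$beta_ux * U +
    stats::rnorm(n, sd = sd_x)
  out <- list(exposure = X, confounder = U, outcome = NULL)
  if (role == "applied") {
    v_y <- 1 - params$beta_xy^2 - params$beta_uy^2 -
      2 * params$beta_xy * params$beta_ux * params$beta_uy
    sd_y <- sqrt(max(v_y, 1e-12))
    out$outcome <- params$beta_xy * X + params$beta_uy * U +
      stats::rnorm(n, sd = sd_y)
  }
  out
}

#' Simulate one cohort under the additive genetic + confounder model
#'
#' Genotype dosages are drawn iid Binomial(2, `af`) per SNP; the confounder
#' is standard normal; the exposure is
#' \eqn{X = G b + \beta_{UX} U + \epsilon_X} with residual SD chosen so
#' Var(X) = 1 and the genetic fraction equals `var_exp`. Applied cohorts
#' additionally carry the outcome
#' \eqn{Y = \beta_{XY} X + \beta_{UY} U + \epsilon_Y}, scaled to unit
#' variance; external cohorts have no outcome.
#'
#' @param params A [sim_params()] object.
#' @param effects Per-SNP effect vector, typically from
#'   [allocate_true_effects()].
#' @param role `"applied"` or `"external"`; selects the cohort size
#'   (`n_applied` vs `n_external`) and whether the outcome is generated.
#' @param n Optional explicit cohort size overriding the role default.
#' @return An object of class `cohort`: a list with `genotypes` (n x m
#'   dosage matrix), `exposure`, `outcome` (`NULL` for external cohorts),
#'   `confounder`, `true_effects`, and `role`.
#' @examples
#' p <- sim_params(n_applied = 200, n_snp = 20)
#' set.seed(7)
#' co <- simulate_cohort(p, allocate_true_effects(p), "applied")
#' range(co$genotypes)
#' @export
simulate_cohort <- function(params, effects, role = c("applied", "external"),
                            n = NULL) {
  stopifnot(inherits(params, "sim_params"))
  role <- match.arg(role)
  if (length(effects) != params$n_snp)
    stop("'effects' must have length n_snp = ", params$n_snp)
  if (is.null(n)) n <- if (role == "applied") params$n_applied else params$n_external
  n <- as.integer(n)
  if (n < 1L) stop("invalid parameters: cohort size must be positive")
  G <- .sim_genotypes_cpp(n, params$n_snp, params$af)
  ph <- simulate_phenotypes(G, effects, params, role)
  new_cohort(G, ph, effects, role)
}

new_cohort <- function(G, ph, effects, role) {
  structure(list(genotypes = G, exposure = ph$exposure,
                 outcome = ph$outcome, confounder = ph$confounder,
                 true_effects = effects, role = role),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Simulated %s cohort: %d individuals x %d SNPs%s\n",
              x$role, nrow(x$genotypes), ncol(x$genotypes),
              if (is.null(x$outcome)) " (no outcome)" else ""))
  invisible(x)
}

#' Simulate a paired applied/external scenario
#'
#' Draws one per-SNP effect vector and two independent cohorts sharing it:
#' an applied cohort (exposure, outcome, confounder) and an external cohort
#' (exposure only, its own confounder). Genotypes, confounders and residuals
#' are drawn independently between the two cohorts.
#'
#' @param params A [sim_params()] object.
#' @return List with elements `applied` and `external` (both `cohort`
#'   objects sharing `true_effects`) and `effects`.
#' @examples
#' p <- sim_params(n_applied = 100, n_external = 100, n_snp = 10)
#' set.seed(1)
#' pair <- simulate_scenario_pair(p)
#' identical(pair$applied$true_effects, pair$external$true_effects)
#' @export
simulate_scenario_pair <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  effects <- allocate_true_effects(params)
  applied <- simulate_cohort(params, effects, "applied")
  external <- simulate_cohort(params, effects, "external")
  list(applied = applied, external = external, effects = effects)
}

#' Write / read a cohort as plain delimited files
#'
#' Debug/fixture helpers: the genotype matrix goes to `<stem>_genotypes.tsv`
#' (one row per individual, integer dosages, no header) and the phenotypes to
#' `<stem>_phenotypes.tsv` (columns `sample_id`, `exposure`, `outcome`,
#' `confounder`; `outcome` is `NA` for external cohorts). True effects go to
#' `<stem>_effects.tsv`.
#'
#' @param cohort A `cohort` object.
#' @param stem File path stem (directory must exist).
#' @return `write_cohort` returns `stem` invisibly; `read_cohort` returns a
#'   `cohort` object.
#' @export
write_cohort <- function(cohort, stem) {
  stopifnot(inherits(cohort, "cohort"))
  utils::write.table(cohort$genotypes, paste0(stem, "_genotypes.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  ph <- data.frame(sample_id = seq_along(cohort$exposure),
                   exposure = cohort$exposure,
                   outcome = if (is.null(cohort$outcome)) NA_real_ else cohort$outcome,
                   confounder = cohort$confounder)
  utils::write.table(ph, paste0(stem, "_phenotypes.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(effect = cohort$true_effects),
                     paste0(stem, "_effects.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(stem)
}

#' @rdname write_cohort
#' @param role Cohort role to record on read-back.
#' @export
read_cohort <- function(stem, role = c("applied", "external")) {
  role <- match.arg(role)
  G <- as.matrix(utils::read.table(paste0(stem, "_genotypes.tsv"), sep = "\t"))
  dimnames(G) <- NULL
  storage.mode(G) <- "double"
  ph <- utils::read.table(paste0(stem, "_phenotypes.tsv"), sep = "\t",
                          header = TRUE)
  eff <- utils::read.table(paste0(stem, "_effects.tsv"), sep = "\t",
                           header = TRUE)$effect
  outcome <- if (all(is.na(ph$outcome))) NULL else ph$outcome
  new_cohort(G, list(exposure = ph$exposure, outcome = outcome,
                     confounder = ph$confounder), eff, role)
}
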