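#' Describe a simulation scenario grid
#'
#' Light container for a scenario: the base generative parameters, the
#' varied axes, and the replicate count. The four named scenarios mirror the
#' simulation studies run by the scenario runners.
#'
#' @param name One of `"primary"`, `"external_size_sweep"`, `"snp_sweep"`,
#'   `"block_sweep"`.
#' @param base A [sim_params()] object of base parameters.
#' @param reps Number of replicates (at least 2).
#' @param seed Root seed for per-replicate substreams; overrides
#'   `base$seed` when given.
#' @param n_external_grid External-cohort sizes for the size sweep.
#' @param n_snp_grid SNP counts for the SNP sweep.
#' @param n_block_grid Block counts for the block sweep.
#' @param thresholds P-value cutoffs; defaults depend on the scenario (the
#'   full 13-threshold grid for `"primary"`, `5e-8` for the size sweep,
#'   `{5e-8, 0.05, 1}` for the SNP and block sweeps).
#' @param frameworks Subset of `c("external", "overlap", "jackknife")` to
#'   run (all three by default).
#' @param out_dir Optional output directory for `per_rep.csv`,
#'   `metrics.csv` and a run log.
#' @return An object of class `scenario_grid`.
#' @export
scenario_grid <- function(name = c("primary", "external_size_sweep",
                                   "snp_sweep", "block_sweep"),
                          base = sim_params(), reps = 200, seed = 1,
                          n_external_grid = c(10000, 15000, 20000, 25000,
                                              30000, 35000, 40000, 45000,
                                              50000),
                          n_snp_grid = c(100, 200, 300, 400, 500, 800, 1000,
                                         1200, 1500, 2000),
                          n_block_grid = c(3, 6, 10, 20, 30, 50, 100),
                          thresholds = NULL,
                          frameworks = c("external", "overlap", "jackknife"),
                          out_dir = NULL) {
  name <- match.arg(name)
  stopifnot(inherits(base, "sim_params"), reps >= 2)
  frameworks <- match.arg(frameworks, several.ok = TRUE)
  if (is.null(thresholds)) {
    thresholds <- switch(name,
                         primary = base$thresholds,
                         external_size_sweep = 5e-8,
                         c(5e-8, 0.05, 1))
  }
  if (any(thresholds <= 0) || any(thresholds > 1))
    stop("invalid parameters: thresholds must lie in (0, 1]")
  structure(list(name = name, base = base, reps = as.integer(reps),
                 seed = if (!is.null(seed)) seed else base$seed,
                 n_external_grid = as.integer(n_external_grid),
                 n_snp_grid = as.integer(n_snp_grid),
                 n_block_grid = as.integer(n_block_grid),
                 thresholds = sort(thresholds), frameworks = frameworks,
                 out_dir = out_dir),
            class = "scenario_grid")
}

# ---- internal engine ------------------------------------------------------

# Threshold-incremental scoring. scans: list of per-block scan statistics
# (beta_hat, pvalue vectors); block_rows: list of the row indices each
# scan's weights score (one entry covering all rows for a single discovery
# scan). Thresholds must be ascending; selection sets are nested, so each
# threshold accumulates only the newly selected SNPs over only the rows
# they score.
prs_matrix <- function(G, block_rows, scans, thresholds) {
  n <- nrow(G); m <- ncol(G); K <- length(thresholds)
  n_block <- length(scans)
  score <- numeric(n)
  scores <- matrix(0, n, K)
  counts <- matrix(0L, n_block, K)
  selected <- matrix(FALSE, m, n_block)
  for (k in seq_len(K)) {
    for (b in seq_len(n_block)) {
      sc <- scans[[b]]
      new <- which(!selected[, b] & sc$pvalue <= thresholds[k] &
                     is.finite(sc$beta_hat) & is.finite(sc$se))
      if (length(new)) {
        .accumulate_scores_cpp(G, block_rows[[b]], new, sc$beta_hat[new],
                               score)
        selected[new, b] <- TRUE
      }
    }
    scores[, k] <- score
    counts[, k] <- colSums(selected)
  }
  list(scores = scores, counts = counts)
}

# Fast just-identified 2SLS with a single instrument and no covariates,
# algebraically identical to tsls_fit(). Returns NA fields for an empty or
# constant instrument.
tsls_quick <- function(y, x, z) {
  n <- length(y)
  zc <- z - mean(z); xc <- x - mean(x); yc <- y - mean(y)
  szz <- sum(zc^2)
  if (szz <= 0) return(NULL)
  sxz <- sum(zc * xc)
  if (sxz == 0) return(NULL)
  beta <- sum(zc * yc) / sxz
  rss <- sum((yc - beta * xc)^2)
  sigma2 <- rss / (n - 2)
  se <- sqrt(sigma2 * szz) / abs(sxz)
  r2 <- sxz^2 / (szz * sum(xc^2))
  list(beta_hat = beta, se = se,
       fstat = (n - 2) * r2 / (1 - r2),
       r2_adj = 1 - (1 - r2) * (n - 1) / (n - 2))
}

# One row per threshold for a score matrix, all thresholds fitted at once
# from shared cross-products (algebraically identical to tsls_quick per
# column). Empty-instrument cells become NA rows (never aborts): excluded
# replicates are counted downstream.
fit_cells <- function(scores, counts_used, X, Y, thresholds, framework,
                      rep_id, extra = NULL) {
  n <- length(X)
  xc <- X - mean(X); yc <- Y - mean(Y)
  sxx <- sum(xc^2); syy <- sum(yc^2); sxy <- sum(xc * yc)
  mz <- colMeans(scores)
  szz <- colSums(scores * scores) - n * mz^2
  sxz <- as.vector(crossprod(scores, xc))
  szy <- as.vector(crossprod(scores, yc))
  ok <- szz > 0 & counts_used > 0 & sxz != 0
  beta <- ifelse(ok, szy / sxz, NA_real_)
  rss <- pmax(syy - 2 * beta * sxy + beta^2 * sxx, 0)
  se <- sqrt(rss / (n - 2) * szz) / abs(sxz)
  r2 <- ifelse(ok, sxz^2 / (szz * sxx), NA_real_)
  out <- data.frame(framework = framework, threshold = thresholds,
                    rep = rep_id, beta_hat = beta, se = se,
                    ci_low = beta - 1.96 * se, ci_high = beta + 1.96 * se,
                    fstat = (n - 2) * r2 / (1 - r2),
                    r2_adj = 1 - (1 - r2) * (n - 1) / (n - 2),
                    n_snps = counts_used)
  if (!is.null(extra)) for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  out
}

# Shared per-replicate machinery: fill buffers, simulate phenotypes, run the
# requested discovery frameworks, return per-cell rows.
get_buffer <- function(env, key, n, m) {
  buf <- env$bufs[[key]]
  if (is.null(buf) || nrow(buf) != n || ncol(buf) != m) {
    buf <- matrix(0, n, m)
    env$bufs[[key]] <- buf
  }
  buf
}

# Assemble the long metrics table from per-rep rows: one row per scenario
# cell per statistic (beta_hat with full metrics; r2_adj with the reduced
# set), with percentage precision gain relative to the external arm.
metrics_template <- function() {
  data.frame(n_reps = NA_integer_, n_excluded = NA_integer_,
             mean = NA_real_, mean_mcse = NA_real_, median = NA_real_,
             bias = NA_real_, bias_mcse = NA_real_,
             empirical_se = NA_real_, empirical_se_mcse = NA_real_,
             model_se = NA_real_, model_se_mcse = NA_real_,
             relative_error_model_se = NA_real_,
             mse = NA_real_, mse_mcse = NA_real_,
             coverage = NA_real_, coverage_mcse = NA_real_,
             bias_eliminated_coverage = NA_real_,
             bias_eliminated_coverage_mcse = NA_real_)
}

assemble_metrics <- function(per_rep, beta_true, r2_true, cell_keys) {
  key <- interaction(per_rep[cell_keys], drop = TRUE)
  template <- metrics_template()
  rows <- lapply(levels(key), function(cell) {
    d <- per_rep[key == cell, ]
    keys <- d[1, cell_keys, drop = FALSE]
    mb <- tryCatch(summarize_estimates(d, beta_true),
                   error = function(e) NULL)
    beta_row <- template
    if (!is.null(mb)) beta_row[names(mb)] <- mb
    beta_row <- cbind(keys, statistic = "beta_hat", beta_row,
                      row.names = NULL)
    mr2 <- tryCatch(summarize_r2(d$r2_adj, r2_true),
                    error = function(e) NULL)
    r2_row <- template
    if (!is.null(mr2)) r2_row[names(mr2)] <- mr2
    r2_row <- cbind(keys, statistic = "r2_adj", r2_row, row.names = NULL)
    rbind(beta_row, r2_row)
  })
  metrics <- do.call(rbind, rows)
  add_precision_gain(metrics,
                     c(setdiff(cell_keys, "framework"), "statistic"))
}

finish_run <- function(per_rep, grid, beta_true, r2_true, cell_keys,
                       metrics_data = NULL) {
  metrics <- assemble_metrics(if (is.null(metrics_data)) per_rep else
    metrics_data, beta_true, r2_true, cell_keys)
  out <- list(per_rep = per_rep, metrics = metrics, grid = grid)
  class(out) <- "sim_run"
  if (!is.null(grid$out_dir)) {
    dir.create(grid$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(per_rep, file.path(grid$out_dir, "per_rep.csv"),
                     row.names = FALSE)
    utils::write.csv(metrics, file.path(grid$out_dir, "metrics.csv"),
                     row.names = FALSE)
    writeLines(c(sprintf("scenario: %s", grid$name),
                 sprintf("reps: %d", grid$reps),
                 sprintf("seed: %s", format(grid$seed)),
                 sprintf("thresholds: %s",
                         paste(format(grid$thresholds, trim = TRUE),
                               collapse = ", ")),
                 utils::capture.output(print(grid$base))),
               file.path(grid$out_dir, "run_log.txt"))
  }
  out
}

#' @export
print.sim_run <- function(x, ...) {
  cat(sprintf("Simulation run '%s': %d replicates, %d per-rep rows, %d metric rows\n",
              x$grid$name, x$grid$reps, nrow(x$per_rep), nrow(x$metrics)))
  invisible(x)
}

# Scenario offsets keep substreams distinct when one root seed drives
# several scenarios.
scenario_offset <- function(name) {
  match(name, c("primary", "external_size_sweep", "snp_sweep",
                "block_sweep")) * 1000L
}

#' Run the primary simulation grid
#'
#' For each replicate: simulate an applied/external cohort pair, run the
#' three discovery frameworks (one GWAS per framework per replicate; the
#' P-value thresholds are post-hoc filters over the same scan), build the
#' allele score and fit the one-sample 2SLS per framework x threshold cell,
#' then summarize all cells with Monte Carlo metrics. Replicates whose
#' instrument is empty at a threshold are recorded as NA rows and counted,
#' not dropped silently.
#'
#' @param grid A [scenario_grid()] (name `"primary"`).
#' @param verbose Print a progress line every 50 replicates.
#' @return A `sim_run` list: `per_rep` (one row per framework x threshold x
#'   replicate with `beta_hat`, `se`, `ci_low`, `ci_high`, `fstat`,
#'   `r2_adj`, `n_snps`), `metrics` (per-cell [summarize_estimates()] /
#'   [summarize_r2()] rows), and the grid.
#' @export
run_primary_grid <- function(grid, verbose = FALSE) {
  stopifnot(inherits(grid, "scenario_grid"))
  p <- grid$base
  thr <- grid$thresholds
  env <- new.env(); env$bufs <- list()
  all_rows <- list(seq_len(p$n_applied))
  rows <- vector("list", grid$reps)
  offset <- scenario_offset("primary")
  for (r in seq_len(grid$reps)) {
    set.seed(derive_seed(grid$seed, r, offset))
    effects <- allocate_true_effects(p)
    Ga <- get_buffer(env, "applied", p$n_applied, p$n_snp)
    .fill_genotypes_cpp(Ga, p$af)
    pha <- simulate_phenotypes(Ga, effects, p, "applied")
    Ge <- get_buffer(env, "external", p$n_external, p$n_snp)
    .fill_genotypes_cpp(Ge, p$af)
    phe <- simulate_phenotypes(Ge, effects, p, "external")
    blocks <- assign_blocks(p$n_applied, p$n_block)

    rep_rows <- list()
    if ("overlap" %in% grid$frameworks || "jackknife" %in% grid$frameworks) {
      st <- lobo_scan_stats(Ga, pha$exposure, blocks$block_of, p$n_block)
      if ("overlap" %in% grid$frameworks) {
        pm <- prs_matrix(Ga, all_rows, list(st$full), thr)
        rep_rows$overlap <- fit_cells(pm$scores, pm$counts[1, ],
                                      pha$exposure, pha$outcome, thr,
                                      "overlap", r)
      }
      if ("jackknife" %in% grid$frameworks) {
        pm <- prs_matrix(Ga, split(all_rows[[1]], blocks$block_of),
                         st$scans, thr)
        rep_rows$jackknife <- fit_cells(pm$scores, colMeans(pm$counts),
                                        pha$exposure, pha$outcome, thr,
                                        "jackknife", r)
      }
    }
    if ("external" %in% grid$frameworks) {
      ss <- .block_suffstats_cpp(Ge, phe$exposure,
                                 rep.int(1L, p$n_external), 1L)
      scan <- scan_from_sums(p$n_external, ss$sy[1], ss$syy[1], ss$sg[1, ],
                             ss$sgg[1, ], ss$sgy[1, ], warn = FALSE)
      pm <- prs_matrix(Ga, all_rows, list(scan), thr)
      rep_rows$external <- fit_cells(pm$scores, pm$counts[1, ],
                                     pha$exposure, pha$outcome, thr,
                                     "external", r)
    }
    rows[[r]] <- do.call(rbind, unname(rep_rows))
    if (verbose && r %% 50 == 0)
      message(sprintf("  primary grid: replicate %d / %d", r, grid$reps))
  }
  per_rep <- do.call(rbind, rows)
  finish_run(per_rep, grid, p$beta_xy, p$var_exp,
             c("framework", "threshold"))
}

#' Run the external-GWAS sample-size sweep
#'
#' External discovery cohorts of varying size score a fixed applied cohort
#' of `n_applied` individuals; the jackknife and overlap arms on the applied
#' cohort are run once per replicate as references. The selection threshold
#' defaults to genome-wide significance (5e-8).
#'
#' @inheritParams run_primary_grid
#' @return A `sim_run`; per-rep rows carry `n_external` (NA for the
#'   jackknife and overlap arms).
#' @export
run_external_size_sweep <- function(grid, verbose = FALSE) {
  stopifnot(inherits(grid, "scenario_grid"))
  p <- grid$base
  thr <- grid$thresholds
  env <- new.env(); env$bufs <- list()
  all_rows <- list(seq_len(p$n_applied))
  rows <- vector("list", grid$reps)
  offset <- scenario_offset("external_size_sweep")
  for (r in seq_len(grid$reps)) {
    set.seed(derive_seed(grid$seed, r, offset))
    effects <- allocate_true_effects(p)
    Ga <- get_buffer(env, "applied", p$n_applied, p$n_snp)
    .fill_genotypes_cpp(Ga, p$af)
    pha <- simulate_phenotypes(Ga, effects, p, "applied")
    blocks <- assign_blocks(p$n_applied, p$n_block)

    rep_rows <- list()
    if ("overlap" %in% grid$frameworks || "jackknife" %in% grid$frameworks) {
      st <- lobo_scan_stats(Ga, pha$exposure, blocks$block_of, p$n_block)
      if ("overlap" %in% grid$frameworks) {
        pm <- prs_matrix(Ga, all_rows, list(st$full), thr)
        rep_rows$overlap <- fit_cells(pm$scores, pm$counts[1, ],
                                      pha$exposure, pha$outcome, thr,
                                      "overlap", r,
                                      extra = list(n_external = NA_integer_))
      }
      if ("jackknife" %in% grid$frameworks) {
        pm <- prs_matrix(Ga, split(all_rows[[1]], blocks$block_of),
                         st$scans, thr)
        rep_rows$jackknife <- fit_cells(pm$scores, colMeans(pm$counts),
                                        pha$exposure, pha$outcome, thr,
                                        "jackknife", r,
                                        extra = list(n_external = NA_integer_))
      }
    }
    if ("external" %in% grid$frameworks) {
      # nested discovery cohorts: one draw of the largest external cohort,
      # each smaller size is its leading rows (iid, so a valid cohort of
      # that size); banded sufficient statistics give every size's scan in
      # one pass
      sizes <- sort(grid$n_external_grid)
      ne_max <- sizes[length(sizes)]
      Ge <- get_buffer(env, "external", ne_max, p$n_snp)
      .fill_genotypes_cpp(Ge, p$af)
      phe <- simulate_phenotypes(Ge, effects, p, "external")
      band <- rep.int(seq_along(sizes), times = diff(c(0L, sizes)))
      ss <- .block_suffstats_cpp(Ge, phe$exposure, band, length(sizes))
      sg <- 0; sgg <- 0; sgy <- 0; sy <- 0; syy <- 0
      for (k in seq_along(sizes)) {
        sg <- sg + ss$sg[k, ]; sgg <- sgg + ss$sgg[k, ]
        sgy <- sgy + ss$sgy[k, ]
        sy <- sy + ss$sy[k]; syy <- syy + ss$syy[k]
        scan <- scan_from_sums(sizes[k], sy, syy, sg, sgg, sgy, warn = FALSE)
        pm <- prs_matrix(Ga, all_rows, list(scan), thr)
        rep_rows[[paste0("ext", sizes[k])]] <-
          fit_cells(pm$scores, pm$counts[1, ], pha$exposure, pha$outcome,
                    thr, "external", r,
                    extra = list(n_external = sizes[k]))
      }
    }
    rows[[r]] <- do.call(rbind, unname(rep_rows))
    if (verbose && r %% 50 == 0)
      message(sprintf("  size sweep: replicate %d / %d", r, grid$reps))
  }
  per_rep <- do.call(rbind, rows)
  md <- per_rep
  md$cell_n_ext <- ifelse(is.na(md$n_external), 0L, md$n_external)
  out <- finish_run(per_rep, grid, p$beta_xy, p$var_exp,
                    c("framework", "threshold", "cell_n_ext"),
                    metrics_data = md)
  out$metrics$n_external <- ifelse(out$metrics$cell_n_ext == 0L, NA_integer_,
                                   out$metrics$cell_n_ext)
  out$metrics$cell_n_ext <- NULL
  out
}

#' Run the SNP-number sweep
#'
#' Repeats the primary comparison while varying the number of simulated
#' SNPs, the total exposure variance explained held at `var_exp`. More SNPs
#' means less variance per SNP, weaker per-SNP power, and stronger
#' winner's-curse overfitting for the overlapping-sample score.
#'
#' @inheritParams run_primary_grid
#' @return A `sim_run`; rows carry `n_snp`.
#' @export
run_snp_sweep <- function(grid, verbose = FALSE) {
  stopifnot(inherits(grid, "scenario_grid"))
  thr <- grid$thresholds
  env <- new.env(); env$bufs <- list()
  rows <- vector("list", grid$reps)
  offset <- scenario_offset("snp_sweep")
  all_rows <- list(seq_len(grid$base$n_applied))
  for (r in seq_len(grid$reps)) {
    set.seed(derive_seed(grid$seed, r, offset))
    rep_rows <- list()
    for (ms in grid$n_snp_grid) {
      p <- grid$base
      p$n_snp <- as.integer(ms)
      effects <- allocate_true_effects(p)
      Ga <- get_buffer(env, paste0("applied", ms), p$n_applied, ms)
      .fill_genotypes_cpp(Ga, p$af)
      pha <- simulate_phenotypes(Ga, effects, p, "applied")
      blocks <- assign_blocks(p$n_applied, p$n_block)
      if ("overlap" %in% grid$frameworks ||
          "jackknife" %in% grid$frameworks) {
        st <- lobo_scan_stats(Ga, pha$exposure, blocks$block_of, p$n_block)
        if ("overlap" %in% grid$frameworks) {
          pm <- prs_matrix(Ga, all_rows, list(st$full), thr)
          rep_rows[[paste0("ov", ms)]] <-
            fit_cells(pm$scores, pm$counts[1, ], pha$exposure, pha$outcome,
                      thr, "overlap", r, extra = list(n_snp = ms))
        }
        if ("jackknife" %in% grid$frameworks) {
          pm <- prs_matrix(Ga, split(all_rows[[1]], blocks$block_of),
                           st$scans, thr)
          rep_rows[[paste0("jk", ms)]] <-
            fit_cells(pm$scores, colMeans(pm$counts), pha$exposure,
                      pha$outcome, thr, "jackknife", r,
                      extra = list(n_snp = ms))
        }
      }
      if ("external" %in% grid$frameworks) {
        Ge <- get_buffer(env, paste0("external", ms), p$n_external, ms)
        .fill_genotypes_cpp(Ge, p$af)
        phe <- simulate_phenotypes(Ge, effects, p, "external")
        ss <- .block_suffstats_cpp(Ge, phe$exposure,
                                   rep.int(1L, p$n_external), 1L)
        scan <- scan_from_sums(p$n_external, ss$sy[1], ss$syy[1],
                               ss$sg[1, ], ss$sgg[1, ], ss$sgy[1, ],
                               warn = FALSE)
        pm <- prs_matrix(Ga, all_rows, list(scan), thr)
        rep_rows[[paste0("ex", ms)]] <-
          fit_cells(pm$scores, pm$counts[1, ], pha$exposure, pha$outcome,
                    thr, "external", r, extra = list(n_snp = ms))
      }
    }
    rows[[r]] <- do.call(rbind, unname(rep_rows))
    if (verbose && r %% 50 == 0)
      message(sprintf("  SNP sweep: replicate %d / %d", r, grid$reps))
  }
  per_rep <- do.call(rbind, rows)
  finish_run(per_rep, grid, grid$base$beta_xy, grid$base$var_exp,
             c("framework", "threshold", "n_snp"))
}

#' Run the block-number sweep
#'
#' Varies the number of jackknife blocks (fresh random assignment per block
#' count per replicate), with the external and overlap arms on the same
#' replicate as references.
#'
#' @inheritParams run_primary_grid
#' @return A `sim_run`; rows carry `n_block` (NA for the reference arms).
#' @export
run_block_sweep <- function(grid, verbose = FALSE) {
  stopifnot(inherits(grid, "scenario_grid"))
  p <- grid$base
  thr <- grid$thresholds
  env <- new.env(); env$bufs <- list()
  ones_app <- rep.int(1L, p$n_applied)
  all_rows <- list(seq_len(p$n_applied))
  rows <- vector("list", grid$reps)
  offset <- scenario_offset("block_sweep")
  for (r in seq_len(grid$reps)) {
    set.seed(derive_seed(grid$seed, r, offset))
    effects <- allocate_true_effects(p)
    Ga <- get_buffer(env, "applied", p$n_applied, p$n_snp)
    .fill_genotypes_cpp(Ga, p$af)
    pha <- simulate_phenotypes(Ga, effects, p, "applied")
    Ge <- get_buffer(env, "external", p$n_external, p$n_snp)
    .fill_genotypes_cpp(Ge, p$af)
    phe <- simulate_phenotypes(Ge, effects, p, "external")

    rep_rows <- list()
    if ("overlap" %in% grid$frameworks) {
      ss <- .block_suffstats_cpp(Ga, pha$exposure, ones_app, 1L)
      scan <- scan_from_sums(p$n_applied, ss$sy[1], ss$syy[1], ss$sg[1, ],
                             ss$sgg[1, ], ss$sgy[1, ], warn = FALSE)
      pm <- prs_matrix(Ga, all_rows, list(scan), thr)
      rep_rows$overlap <- fit_cells(pm$scores, pm$counts[1, ],
                                    pha$exposure, pha$outcome, thr,
                                    "overlap", r,
                                    extra = list(n_block = NA_integer_))
    }
    if ("external" %in% grid$frameworks) {
      ss <- .block_suffstats_cpp(Ge, phe$exposure,
                                 rep.int(1L, p$n_external), 1L)
      scan <- scan_from_sums(p$n_external, ss$sy[1], ss$syy[1], ss$sg[1, ],
                             ss$sgg[1, ], ss$sgy[1, ], warn = FALSE)
      pm <- prs_matrix(Ga, all_rows, list(scan), thr)
      rep_rows$external <- fit_cells(pm$scores, pm$counts[1, ],
                                     pha$exposure, pha$outcome, thr,
                                     "external", r,
                                     extra = list(n_block = NA_integer_))
    }
    if ("jackknife" %in% grid$frameworks) {
      for (nb in grid$n_block_grid) {
        blocks <- assign_blocks(p$n_applied, nb)
        st <- lobo_scan_stats(Ga, pha$exposure, blocks$block_of, nb)
        pm <- prs_matrix(Ga, split(all_rows[[1]], blocks$block_of),
                         st$scans, thr)
        rep_rows[[paste0("jk", nb)]] <-
          fit_cells(pm$scores, colMeans(pm$counts), pha$exposure,
                    pha$outcome, thr, "jackknife", r,
                    extra = list(n_block = as.integer(nb)))
      }
    }
    rows[[r]] <- do.call(rbind, unname(rep_rows))
    if (verbose && r %% 25 == 0)
      message(sprintf("  block sweep: replicate %d / %d", r, grid$reps))
  }
  per_rep <- do.call(rbind, rows)
  md <- per_rep
  md$cell_nb <- ifelse(is.na(md$n_block), 0L, md$n_block)
  out <- finish_run(per_rep, grid, p$beta_xy, p$var_exp,
                    c("framework", "threshold", "cell_nb"),
                    metrics_data = md)
  out$metrics$n_block <- ifelse(out$metrics$cell_nb == 0L, NA_integer_,
                                out$metrics$cell_nb)
  out$metrics$cell_nb <- NULL
  out
}

#' Read a flat key-value simulation config
#'
#' Lines of the form `key = value` (or `key: value`); `#` starts a comment.
#' Keys matching [sim_params()] fields build the base parameters; `scenario`,
#' `reps` and `seed` configure the grid. List-valued keys (`thresholds`,
#' `n_external_grid`, `n_snp_grid`, `n_block_grid`) take comma-separated
#' values.
#'
#' @param path Config file path.
#' @return A [scenario_grid()] object.
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    if (!grepl("[=:]", ln)) stop("cannot parse config line: ", ln)
    key <- trimws(sub("^([^=:]+)[=:].*$", "\\1", ln))
    val <- trimws(sub("^[^=:]+[=:]", "", ln))
    kv[[key]] <- val
  }
  num_list <- function(x) as.numeric(trimws(strsplit(x, ",")[[1]]))
  par_names <- c("n_applied", "n_external", "n_snp", "af", "var_exp",
                 "beta_xy", "beta_ux", "beta_uy", "n_block")
  par_args <- list()
  for (nm in intersect(par_names, names(kv)))
    par_args[[nm]] <- as.numeric(kv[[nm]])
  if (!is.null(kv$effect_mode)) par_args$effect_mode <- kv$effect_mode
  if (!is.null(kv$thresholds)) par_args$thresholds <- num_list(kv$thresholds)
  base <- do.call(sim_params, par_args)
  grid_args <- list(base = base)
  if (!is.null(kv$scenario)) grid_args$name <- kv$scenario
  if (!is.null(kv$reps)) grid_args$reps <- as.integer(kv$reps)
  if (!is.null(kv$seed)) grid_args$seed <- as.integer(kv$seed)
  if (!is.null(kv$thresholds)) grid_args$thresholds <- num_list(kv$thresholds)
  for (nm in c("n_external_grid", "n_snp_grid", "n_block_grid"))
    if (!is.null(kv[[nm]])) grid_args[[nm]] <- num_list(kv[[nm]])
  if (!is.null(kv$frameworks))
    grid_args$frameworks <- trimws(strsplit(kv$frameworks, ",")[[1]])
  if (!is.null(kv$out_dir)) grid_args$out_dir <- kv$out_dir
  do.call(scenario_grid, grid_args)
}

#' Dispatch a scenario grid to its runner
#'
#' @param grid A [scenario_grid()].
#' @param verbose Print progress.
#' @return The `sim_run` from the matching runner.
#' @export
run_scenario <- function(grid, verbose = FALSE) {
  switch(grid$name,
         primary = run_primary_grid(grid, verbose),
         external_size_sweep = run_external_size_sweep(grid, verbose),
         snp_sweep = run_snp_sweep(grid, verbose),
         block_sweep = run_block_sweep(grid, verbose))
}
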