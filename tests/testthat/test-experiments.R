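small_primary_grid <- function(reps = 2, seed = 9, thresholds = c(0.05, 1)) {
  scenario_grid("primary",
                sim_params(n_applied = 500, n_external = 500, n_snp = 20,
                           n_block = 5),
                reps = reps, seed = seed, thresholds = thresholds)
}

test_that("primary runner produces the full cell grid with finite liberal cells", {
  r <- run_primary_grid(small_primary_grid())
  expect_identical(nrow(r$per_rep), 2L * 3L * 2L)
  expect_setequal(unique(r$per_rep$framework),
                  c("external", "overlap", "jackknife"))
  lib <- r$per_rep[r$per_rep$threshold == 1, ]
  expect_true(all(is.finite(lib$beta_hat)))
  expect_true(all(is.finite(lib$se)))
  expect_true(all(is.finite(lib$r2_adj)))
  expect_true(all(lib$n_snps > 0))
  # metrics: one beta row and one r2 row per framework x threshold
  expect_identical(nrow(r$metrics), 3L * 2L * 2L)
})

test_that("runs are reproducible bit-for-bit from the root seed", {
  a <- run_primary_grid(small_primary_grid(seed = 33))
  b <- run_primary_grid(small_primary_grid(seed = 33))
  expect_identical(a$per_rep, b$per_rep)
  c <- run_primary_grid(small_primary_grid(seed = 34))
  expect_false(identical(a$per_rep$beta_hat, c$per_rep$beta_hat))
})

test_that("engine replicates match the public single-threshold pipeline", {
  g <- small_primary_grid(reps = 2, seed = 55, thresholds = c(0.05, 1))
  r <- run_primary_grid(g)
  p <- g$base
  # rebuild replicate 1 with public-API calls and the same substream
  set.seed(jackknifeMR:::derive_seed(55, 1, jackknifeMR:::scenario_offset("primary")))
  pair <- simulate_scenario_pair(p)
  blocks <- assign_blocks(p$n_applied, p$n_block)
  for (thr in c(0.05, 1)) {
    s_ext <- external_prs(pair$applied, pair$external, thr)
    fit <- tsls_fit(pair$applied$outcome, pair$applied$exposure, s_ext)
    row <- r$per_rep[r$per_rep$framework == "external" &
                       r$per_rep$threshold == thr & r$per_rep$rep == 1, ]
    expect_equal(row$beta_hat, fit$beta_hat, tolerance = 1e-10)
    expect_equal(row$se, fit$se, tolerance = 1e-10)
    expect_equal(row$r2_adj, fit$r2_adj, tolerance = 1e-10)
    expect_identical(as.integer(row$n_snps), s_ext$n_snps_used)

    jk <- jackknife_prs(pair$applied, threshold = thr, blocks = blocks)
    fit_jk <- tsls_fit(pair$applied$outcome, pair$applied$exposure, jk$score)
    row_jk <- r$per_rep[r$per_rep$framework == "jackknife" &
                          r$per_rep$threshold == thr & r$per_rep$rep == 1, ]
    expect_equal(row_jk$beta_hat, fit_jk$beta_hat, tolerance = 1e-10)
    expect_equal(row_jk$r2_adj, fit_jk$r2_adj, tolerance = 1e-10)
  }
})

test_that("empty-instrument cells become counted NA rows, not failures", {
  g <- scenario_grid("primary",
                     sim_params(n_applied = 400, n_external = 400,
                                n_snp = 30, var_exp = 0, n_block = 4),
                     reps = 3, seed = 77, thresholds = c(5e-8, 1))
  r <- run_primary_grid(g)
  strict <- r$per_rep[r$per_rep$threshold == 5e-8, ]
  expect_true(all(is.na(strict$beta_hat)))
  m <- r$metrics[r$metrics$threshold == 5e-8 &
                   r$metrics$statistic == "beta_hat", ]
  expect_true(all(m$n_excluded == 3L | is.na(m$n_excluded)))
})

test_that("size sweep and block sweep carry their axis columns", {
  p <- sim_params(n_applied = 400, n_external = 400, n_snp = 20, n_block = 4)
  gs <- scenario_grid("external_size_sweep", p, reps = 2, seed = 5,
                      n_external_grid = c(200, 400), thresholds = 1)
  rs <- run_external_size_sweep(gs)
  expect_setequal(unique(rs$per_rep$n_external[rs$per_rep$framework == "external"]),
                  c(200L, 400L))
  expect_true(all(is.na(rs$per_rep$n_external[rs$per_rep$framework != "external"])))

  gb <- scenario_grid("block_sweep", p, reps = 2, seed = 5,
                      n_block_grid = c(2, 4), thresholds = 1)
  rb <- run_block_sweep(gb)
  expect_setequal(unique(rb$per_rep$n_block[rb$per_rep$framework == "jackknife"]),
                  c(2L, 4L))

  gn <- scenario_grid("snp_sweep", p, reps = 2, seed = 5,
                      n_snp_grid = c(10, 20), thresholds = 1,
                      frameworks = "overlap")
  rn <- run_snp_sweep(gn)
  expect_setequal(unique(rn$per_rep$n_snp), c(10L, 20L))
  expect_setequal(unique(rn$per_rep$framework), "overlap")
})

test_that("output files and config round-trip through the scenario interface", {
  dir <- withr::local_tempdir()
  g <- scenario_grid("primary",
                     sim_params(n_applied = 300, n_external = 300,
                                n_snp = 10, n_block = 3),
                     reps = 2, seed = 13, thresholds = 1,
                     out_dir = file.path(dir, "run"))
  r <- run_scenario(g)
  expect_true(file.exists(file.path(dir, "run", "per_rep.csv")))
  expect_true(file.exists(file.path(dir, "run", "metrics.csv")))
  back <- utils::read.csv(file.path(dir, "run", "per_rep.csv"))
  expect_equal(back$beta_hat, r$per_rep$beta_hat, tolerance = 1e-10)

  cfg <- file.path(dir, "sim.cfg")
  writeLines(c("scenario = primary", "n_applied = 300", "n_external = 300",
               "n_snp = 10", "n_block = 3", "reps = 2", "seed = 13",
               "thresholds = 1", "# comment", "af = 0.2"), cfg)
  g2 <- read_sim_config(cfg)
  expect_identical(g2$name, "primary")
  expect_identical(g2$base$n_snp, 10L)
  r2 <- run_scenario(g2)
  expect_identical(r2$per_rep$beta_hat, r$per_rep$beta_hat)
})
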