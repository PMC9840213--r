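# jackknifeMR

One-sample Mendelian randomization (MR) with **block jackknife resampled
polygenic score instruments** — cross-fitted allele scores built from
leave-one-block-out GWAS so that no participant's data enter the discovery
scan that produced their own score weights.

## The problem and who this is for

MR uses genetic variants as instruments for a modifiable exposure X to
estimate its causal effect β<sub>XY</sub> on an outcome Y by two-stage
least squares (2SLS), with a polygenic score
s<sub>i</sub> = Σ<sub>j</sub> w<sub>j</sub> g<sub>ij</sub> as the
instrument. When the SNPs and weights come from a GWAS on the *same*
individuals analysed by MR (increasingly unavoidable as large biobanks
dominate GWAS), winner's curse and overfitting inflate the score–exposure
association, shrink standard errors, and bias β̂<sub>XY</sub> towards the
confounded OLS slope. The block jackknife construction removes the overlap
while keeping every individual for both discovery and analysis:

1. split the cohort randomly into N<sub>block</sub> balanced blocks
   (default 10);
2. for each block, run the exposure GWAS on everyone *outside* it;
3. score the block's members with the SNPs passing the P-value threshold
   in that scan, weighted by their estimated effects;
4. pool all blocks and use the assembled score as one instrument in a
   single 2SLS fit.

The package is aimed at genetic epidemiologists who want (a) the estimator
itself on individual-level data (dosage matrix + phenotypes), and (b) a
fully reproducible simulation laboratory that quantifies sample-overlap
bias: a fast cohort simulator under an additive genetic + confounder model,
per-SNP association scans, threshold-and-score instrument construction
under external / overlapping / jackknife discovery frameworks, univariable
and multivariable 2SLS with first-stage diagnostics, and Monte Carlo
performance metrics (bias, empirical and model-based SE, coverage,
bias-eliminated coverage, each with Monte Carlo standard errors).

## A worked example

```r
library(jackknifeMR)

p <- sim_params(n_applied = 20000, n_external = 20000, n_snp = 200)
set.seed(7)
pair <- simulate_scenario_pair(p)

s_ext <- external_prs(pair$applied, pair$external, 5e-8)
s_ovl <- overlap_prs(pair$applied, 5e-8)
s_jk  <- jackknife_prs(pair$applied, n_block = 10, threshold = 5e-8)$score

sapply(list(external = s_ext, overlap = s_ovl, jackknife = s_jk),
       function(s) adjusted_r2(pair$applied$exposure, s))
#>   external    overlap  jackknife
#> 0.03930009 0.04285528 0.03124063

tsls_fit(pair$applied$outcome, pair$applied$exposure, s_jk, true_value = 0.2)
#> One-sample MR (2SLS)
#>   jackknife: beta = 0.1390 (SE 0.0384), 95% CI [0.0637, 0.2144]
#>   first-stage F: 645.9;  n = 20000
```

The overlapping-sample score explains more exposure variance (0.043) than
the externally weighted score (0.039) on the same draw — that surplus is
overfitting, not signal — while the jackknife score (0.031) pays a small
honest price for its slightly smaller leave-one-block-out discovery scans.
The jackknife 2SLS estimate covers the true effect 0.2, and its first-stage
F of ~646 indicates a strong instrument; the naive OLS slope on this draw
is 0.317, reflecting the built-in confounding (true 0.2 plus
β<sub>UX</sub>·β<sub>UY</sub> = 0.12).

At scale (200+ replicates of n = 50,000 cohorts, selection at P < 5×10⁻⁸)
the mean adjusted R² is ≈0.034 (jackknife) vs ≈0.040 (external) vs ≈0.048
(overlap), and the overlap gap widens sharply at liberal thresholds —
run the scenario below to see these numbers produced live.

## Simulation studies

Four scenario runners rerun the reference simulation studies at configurable
replicate counts:

```r
run <- run_primary_grid(scenario_grid("primary", sim_params(), reps = 200, seed = 1))
subset(run$metrics, statistic == "r2_adj" & threshold == 5e-8,
       c(framework, mean, bias, empirical_se))
```

plus `run_external_size_sweep()` (external discovery cohorts of 10–50k),
`run_snp_sweep()` (100–2000 SNPs at fixed total heritability) and
`run_block_sweep()` (3–100 jackknife blocks). A thin CLI wraps them:

```sh
inst/cli/jackknifemr run --scenario primary --config sim.cfg --reps 200 --seed 1 --out out/
inst/cli/jackknifemr metrics --in out/per_rep.csv --truth 0.2 --out metrics.csv
inst/cli/jackknifemr zipper  --in out/per_rep.csv --truth 0.2 --fraction 0.5
```

See `vignettes/block-jackknife-mr.Rmd` for the model, estimation
conventions, and design rationale.

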