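---
title: "Block jackknife resampling Mendelian randomization: model, design and simulation methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Block jackknife resampling Mendelian randomization: model, design and simulation methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

One-sample Mendelian randomization (MR) estimates the causal effect of an
exposure $X$ on an outcome $Y$ by two-stage least squares (2SLS), using a
polygenic allele score as the instrument. The score is a weighted sum of
effect-allele dosages, $s_i = \sum_j w_j g_{ij}$, with the SNPs and weights
taken from a discovery genome-wide association scan (GWAS) of the exposure.
When the discovery scan runs on the *same* individuals later used for the
MR fit, two linked problems appear:

* **Winner's curse** — SNPs are selected because their in-sample association
  passed a P-value threshold, so their estimated weights are inflated
  towards whatever noise favoured them.
* **Overfitting / sample-overlap bias** — the score inherits in-sample noise
  correlated with the exposure residuals, inflating the score–exposure
  association, shrinking the 2SLS standard error, and biasing the causal
  estimate towards the confounded ordinary-least-squares slope.

The classical fix is an external discovery cohort, but the largest GWAS of
many phenotypes now overlap every available biobank, and splitting one
cohort into discovery and analysis halves sacrifices power.

## The block jackknife resampling estimator

`jackknifeMR` implements a cross-fitting construction that removes the
overlap without discarding anyone:

1. randomly partition the $n$ individuals into $N_{block}$ balanced blocks;
2. for each block $b$, run the exposure GWAS on all individuals *not* in
   $b$;
3. score the members of block $b$ with the SNPs and weights selected from
   that leave-one-block-out scan (selection at a P-value threshold,
   independently per block, with no harmonization of the per-block SNP
   sets — harmonizing across blocks would reintroduce leakage);
4. pool all blocks and use the assembled score as a single instrument in
   one 2SLS fit over the full sample.

No individual's data ever enter the scan that produced their own weights —
a structural guarantee the test suite checks directly by permuting and
perturbing phenotypes within and outside a held-out block. The assembled
score is intentionally heterogeneous across blocks (different SNP sets and
weights); it is used as one pooled instrument, not meta-analyzed per block.

## The generative model of the simulator

All simulation studies draw cohorts from an additive genetic + confounder
model:

* dosages $g_{ij} \sim \mathrm{Binomial}(2, AF)$, independent SNPs (no LD),
  shared allele frequency $AF$ (default 0.2); dosages are used raw (0/1/2),
  never centred or standardized, matching the definition of the score as a
  weighted count of effect alleles;
* per-SNP effects $b_j$ drawn standard-normal and rescaled so that
  $\sum_j 2\,AF(1-AF)\,b_j^2 = Var_{exp}$ exactly (default 0.1);
* confounder $U \sim N(0,1)$;
* exposure $X = \sum_j b_j g_{ij} + \beta_{UX} U + \varepsilon_X$ with
  $\mathrm{sd}(\varepsilon_X) = \sqrt{1 - Var_{exp} - \beta_{UX}^2}$, so
  $\mathrm{Var}(X) = 1$ and the genetic fraction is exactly $Var_{exp}$;
* outcome (applied cohorts only)
  $Y = \beta_{XY} X + \beta_{UY} U + \varepsilon_Y$, scaled so
  $\mathrm{Var}(Y) = 1$ given $\mathrm{Cov}(X, U) = \beta_{UX}$.

Defaults: $n = 50{,}000$ per cohort, 500 SNPs, $\beta_{XY} = 0.2$,
$\beta_{UX} = 0.4$, $\beta_{UY} = 0.3$, 10 jackknife blocks, and the
13-threshold selection grid from $5\times10^{-8}$ to 1. Under these values
the confounded OLS slope of $Y$ on $X$ is
$\beta_{XY} + \beta_{UX}\beta_{UY} = 0.32$, so overfitting pulls estimates
*upward* from the true 0.2.

**Effect-size distribution.** Only the total variance explained is pinned
down by the study conditions; the split across SNPs is a design choice. The
default draws raw effects from a standard normal before rescaling (the
convention of the common GWAS simulators this generator mirrors); an
`"equal"` mode gives every SNP the same effect. The choice matters a great
deal at stringent thresholds: with 500 SNPs sharing 10% of variance
equally, no single SNP has realistic power at $P < 5\times10^{-8}$ in
50,000 individuals, selection collapses, and the score-exposure $R^2$ is
three orders of magnitude below the values the gaussian mode produces
(~0.03–0.05). Every quantitative check in this package's acceptance
machinery therefore runs under the gaussian default; the equal mode is kept
for sensitivity analysis.

**What the generator does not emulate:** linkage disequilibrium, realistic
allele-frequency spectra, binary traits, population structure, assortative
mating, or pleiotropy. Passing tests show the estimator's behaviour under
clean additive confounded data — they do not certify robustness to invalid
instruments, which is outside this package's scope.

## Estimation conventions

* **GWAS scans** are per-SNP univariate OLS with intercept; two-sided
  P-values from the $t$ distribution with $n-2$ df (exact at the small $n$
  used in tests). Monomorphic SNPs get slope 0, SE $\infty$, P 1, so they
  keep their row (index alignment) but can never pass any threshold.
* **Selection** is inclusive (`pvalue <= threshold`); ties at the cutoff
  are measure-zero for continuous simulated statistics.
* **Leave-one-block-out scans** are computed from block-wise sufficient
  statistics (column totals minus the held-out block), one pass over the
  genotype matrix for all blocks; this is algebraically identical to
  scanning each complement and is verified against direct subset scans at
  1e-8 relative tolerance.
* **2SLS** uses the conventional homoskedastic model-based standard error,
  computed from second-stage residuals against the *observed* exposure
  ($y - X\hat\beta$, not the first-stage fitted values), with residual
  degrees of freedom $n - p$. Confidence intervals use the normal 1.96
  multiplier ($n$ is large in every scenario). Robust/sandwich errors are
  deliberately not used: the coverage quantities this package reproduces
  are defined for model-based intervals.
* **Scores are not standardized** before 2SLS; the estimator is invariant
  to instrument scaling (tested exactly for the F-statistic, to 1e-10 for
  the rest).
* **Multivariable MR** (two exposures, two score instruments) solves the
  just-identified system jointly; the per-exposure conditional
  F-statistic follows the Sanderson–Windmeijer idea — each exposure is
  residualized on the other exposure's first-stage prediction before the
  partial F of the instrument block is formed, with one numerator degree of
  freedom absorbed per conditioned exposure. The exact construction used in
  published multivariable MR analyses is not specified anywhere we could anchor to,
  so this interpretation is documented rather than asserted.
* **Rank-based inverse normal transformation** uses Blom offsets,
  $\Phi^{-1}\!\big((r_i - 3/8)/(n + 1/4)\big)$, average ranks for ties, and
  refuses constant input.
* **Degenerate cells**: an empty selection yields an all-zero score;
  the 2SLS front end refuses a zero-variance instrument with an error
  naming the framework and threshold, while the scenario runners record
  such replicate cells as NA rows and report exclusion counts — silently
  dropping them would bias between-framework comparisons invisibly.

## Monte Carlo metrics

Per scenario cell the runners report, for both the causal estimate and the
score-exposure adjusted $R^2$: mean, median, bias, empirical SE ($n-1$
denominator), model-based SE ($\sqrt{\mathrm{mean}(se^2)}$), relative
error in model SE, MSE, coverage and bias-eliminated coverage of nominal
95% intervals, percentage precision gain relative to the external arm
($100[(empSE_{ext}/empSE)^2 - 1]$), and a Monte Carlo standard error for
each estimable summary (bias: $empSE/\sqrt{n}$; empirical SE:
$empSE/\sqrt{2(n-1)}$; coverage: binomial). The algebraic identity
$MSE = bias^2 + \frac{n-1}{n} empSE^2$ is enforced in tests at 1e-12. The
zipper table ranks replicates by $|z| = |\hat\beta - \beta|/\widehat{SE}$
(descending) and returns the top fraction (default half) with their
intervals and covers-truth flags; "top-|z| half" was chosen over an evenly
spaced half as the reading of a fractional-centile-ranked display most
faithful to its purpose of exposing the worst-covered intervals.

## Randomness and reproducibility

One root seed drives everything. Each replicate gets its own substream via
a fixed affine map of (root, replicate index, scenario offset) into 32-bit
seed space, so replicate $r$ is identical no matter how many replicates run
or in what order. Genotypes are drawn by inverse-CDF on one uniform per
entry in column-major order, so cohort draws are bit-reproducible from
`set.seed()` across the pure-R and compiled paths.

## Problem sizes and numerical performance

The full-scale versions of these studies used 1000 (primary and
size sweep), 300 (SNP sweep) and 100 (block sweep) replicates. This
package's own acceptance runs use 200 / 200 / 300 / 100 replicates with the
axes reduced to their informative points (size sweep at external sizes
30–50k, SNP sweep at the endpoint panels of 100 and 2000 SNPs, block sweep
at 3/10/100 blocks) — chosen so each study finishes in minutes on one core
while keeping Monte Carlo standard errors small enough for meaningful
three-MCSE bands. The hot paths (genotype generation, block sufficient
statistics, score accumulation) are small C++ kernels; thresholds are
scored incrementally along the nested selection sets, and each framework
runs one GWAS per replicate with all thresholds applied as post-hoc
filters. In the external-size sweep the discovery cohorts are nested: one
draw of the largest external cohort is made per replicate and each smaller
size is its leading rows — every size is a valid iid cohort of that size,
the sizes are positively coupled within a replicate (which stabilizes the
monotonicity comparison), and the per-size scans come from one banded pass
of sufficient statistics.

## Known limitations

* Pleiotropy-robust estimators (IVW over SNPs, MR-Egger, median-based),
  weak-instrument-robust inference and LIML are out of scope.
* Block assignment is uniform; stratified or clustered assignment (by
  relatedness, centre, ancestry) — a genuine concern for real cohorts — is
  not implemented.
* The simulator's clean additive model means the reproduced quantities
  validate the resampling machinery, not real-data robustness.
* With very liberal thresholds and very many SNPs the overlapping-sample
  arm is severely biased by construction; its cells are reported faithfully
  (that collapse is the phenomenon under study, not a defect).

## A worked example

```{r, eval = FALSE}
library(jackknifeMR)

p <- sim_params(n_applied = 20000, n_external = 20000, n_snp = 200)
set.seed(7)
pair <- simulate_scenario_pair(p)

# three instruments at genome-wide significance
s_ext <- external_prs(pair$applied, pair$external, 5e-8)
s_ovl <- overlap_prs(pair$applied, 5e-8)
s_jk  <- jackknife_prs(pair$applied, n_block = 10, threshold = 5e-8)$score

sapply(list(external = s_ext, overlap = s_ovl, jackknife = s_jk),
       function(s) adjusted_r2(pair$applied$exposure, s))

tsls_fit(pair$applied$outcome, pair$applied$exposure, s_jk, true_value = 0.2)
```
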