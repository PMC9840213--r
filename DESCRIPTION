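Package: jackknifeMR
Title: Block Jackknife Resampling Mendelian Randomization
Version: 0.1.0
Authors@R:
    person("Sam", "Fielding", email = "sam.fielding@example.org",
           role = c("aut", "cre"))
Description: One-sample Mendelian randomization with cross-fitted polygenic
    score instruments built by leave-one-block-out (block jackknife) genome-wide
    association scans, so that no individual's data enter the discovery scan
    that produced their own score weights. Includes a fast additive-model
    cohort simulator, per-SNP linear-regression association scans,
    threshold-based allele-score construction under external, overlapping-sample
    and block-jackknife discovery frameworks, univariable and multivariable
    two-stage least squares estimation with first-stage diagnostics, Monte
    Carlo performance metrics (bias, empirical and model-based standard errors,
    coverage, bias-eliminated coverage, with Monte Carlo standard errors), and
    scenario runners for simulation studies comparing the three frameworks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
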