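# Per-SNP association statistics from sufficient sums. For each SNP j with
# sums over the analysis sample (n, sum y, sum y^2, sum g, sum g^2, sum gy):
#   Sxx = sum g^2 - (sum g)^2 / n,  Sxy = sum gy - sum g sum y / n
#   beta = Sxy / Sxx,  RSS = Syy - beta * Sxy,  se = sqrt(RSS / ((n-2) Sxx))
# Two-sided P from the t distribution with n - 2 df. Monomorphic SNPs
# (Sxx ~ 0) get beta 0, se Inf, P 1 so they can never pass a threshold.
scan_from_sums <- function(n, sy, syy, sg, sgg, sgy, warn = TRUE) {
  sxx <- sgg - sg^2 / n
  sxy <- sgy - sg * sy / n
  syy_c <- syy - sy^2 / n
  # guard against negative roundoff from the subtraction scheme
  tol <- 1e-9 * pmax(sgg, 1)
  mono <- sxx <= tol
  beta <- ifelse(mono, 0, sxy / ifelse(mono, 1, sxx))
  rss <- pmax(syy_c - beta * sxy, 0)
  se <- sqrt(rss / ((n - 2) * ifelse(mono, 1, sxx)))
  se[mono] <- Inf
  tstat <- beta / se
  tstat[mono] <- 0
  pval <- 2 * stats::pt(-abs(tstat), df = n - 2)
  pval[mono] <- 1
  if (warn && any(mono))
    warning(sum(mono), " monomorphic SNP(s): beta set to 0, se to Inf, P to 1")
  list(beta_hat = beta, se = se, pvalue = pval, n = n)
}

#' Per-SNP association scan by simple linear regression
#'
#' Regresses the phenotype on each dosage column in turn (univariate OLS
#' with intercept), returning the slope, its standard error and a two-sided
#' P-value from the t distribution with n - 2 degrees of freedom. The
#' computation is vectorized over SNPs via sufficient sums and agrees with a
#' per-SNP `lm()` loop to near machine precision.
#'
#' Monomorphic SNPs (zero dosage variance) get `beta_hat = 0`, `se = Inf`,
#' `pvalue = 1` with a warning, so they can never be selected downstream
#' while keeping SNP indexing aligned.
#'
#' @param genotypes n x m dosage matrix (or a `cohort` object, in which case
#'   its genotypes and exposure are used).
#' @param phenotype Length-n numeric vector; ignored when `genotypes` is a
#'   cohort.
#' @return A data frame of class `gwas_result` with columns `snp_id`,
#'   `beta_hat`, `se`, `pvalue`, `n`, one row per SNP in column order.
#' @examples
#' set.seed(1)
#' G <- matrix(rbinom(600, 2, 0.3), 100, 6)
#' y <- G[, 1] * 0.5 + rnorm(100)
#' head(gwas_scan(G, y))
#' @export
gwas_scan <- function(genotypes, phenotype = NULL) {
  if (inherits(genotypes, "cohort")) {
    phenotype <- genotypes$exposure
    genotypes <- genotypes$genotypes
  }
  stopifnot(is.matrix(genotypes), length(phenotype) == nrow(genotypes))
  n <- nrow(genotypes)
  if (n < 3L) stop("at least 3 individuals are required for a scan")
  if (!is.double(genotypes)) storage.mode(genotypes) <- "double"
  ss <- .block_suffstats_cpp(genotypes, as.double(phenotype),
                             rep.int(1L, n), 1L)
  res <- scan_from_sums(n, ss$sy[1], ss$syy[1], ss$sg[1, ], ss$sgg[1, ],
                        ss$sgy[1, ])
  out <- data.frame(snp_id = seq_len(ncol(genotypes)),
                    beta_hat = res$beta_hat, se = res$se,
                    pvalue = res$pvalue, n = n)
  class(out) <- c("gwas_result", "data.frame")
  out
}

# Leave-one-block-out scans from one pass of block sufficient statistics.
# Returns the per-block complement statistics plus the full-sample totals.
lobo_scan_stats <- function(G, y, block_of, n_block, warn = FALSE) {
  ss <- .block_suffstats_cpp(G, as.double(y), block_of, n_block)
  tot_sg <- colSums(ss$sg); tot_sgg <- colSums(ss$sgg)
  tot_sgy <- colSums(ss$sgy)
  tot_sy <- sum(ss$sy); tot_syy <- sum(ss$syy); n <- sum(ss$nb)
  scans <- vector("list", n_block)
  for (b in seq_len(n_block)) {
    nb <- n - ss$nb[b]
    if (nb < 3L) stop("invalid parameters: a leave-one-block-out scan has ",
                      "fewer than 3 individuals")
    scans[[b]] <- scan_from_sums(nb, tot_sy - ss$sy[b], tot_syy - ss$syy[b],
                                 tot_sg - ss$sg[b, ], tot_sgg - ss$sgg[b, ],
                                 tot_sgy - ss$sgy[b, ], warn = warn)
  }
  full <- scan_from_sums(n, tot_sy, tot_syy, tot_sg, tot_sgg, tot_sgy,
                         warn = warn)
  list(scans = scans, full = full)
}

#' Leave-one-block-out association scans
#'
#' For each block b, scans the phenotype against every SNP using all
#' individuals \emph{not} in block b. Computed in one pass over the data via
#' block-wise sufficient statistics (totals minus the held-out block), which
#' is algebraically identical to scanning each complement subset directly.
#'
#' @param genotypes n x m dosage matrix.
#' @param phenotype Length-n numeric vector.
#' @param blocks A [assign_blocks()] result, or an integer vector of block
#'   labels in `1..n_block`.
#' @return List of `gwas_result` data frames, one per block (the scan that
#'   block's members were excluded from), with the full-sample scan attached
#'   as attribute `"full"`.
#' @export
gwas_scan_blocks <- function(genotypes, phenotype, blocks) {
  stopifnot(is.matrix(genotypes), length(phenotype) == nrow(genotypes))
  if (inherits(blocks, "block_assignment")) {
    block_of <- blocks$block_of; n_block <- blocks$n_block
  } else {
    block_of <- as.integer(blocks); n_block <- max(block_of)
  }
  stopifnot(length(block_of) == nrow(genotypes))
  if (!is.double(genotypes)) storage.mode(genotypes) <- "double"
  st <- lobo_scan_stats(genotypes, phenotype, block_of, n_block)
  m <- ncol(genotypes)
  out <- lapply(st$scans, function(s) {
    d <- data.frame(snp_id = seq_len(m), beta_hat = s$beta_hat, se = s$se,
                    pvalue = s$pvalue, n = s$n)
    class(d) <- c("gwas_result", "data.frame")
    d
  })
  full <- data.frame(snp_id = seq_len(m), beta_hat = st$full$beta_hat,
                     se = st$full$se, pvalue = st$full$pvalue, n = st$full$n)
  class(full) <- c("gwas_result", "data.frame")
  attr(out, "full") <- full
  out
}

#' Write / read GWAS summary statistics
#'
#' Tab-delimited with header `snp_id effect_allele beta se pvalue n`;
#' the effect allele is fixed to `"A"` for simulated data. Numbers are
#' written with 17 significant digits so a round trip is lossless.
#'
#' @param gwas A `gwas_result` data frame.
#' @param path Output file path.
#' @return `write_sumstats` returns `path` invisibly; `read_sumstats`
#'   returns a `gwas_result` data frame.
#' @export
write_sumstats <- function(gwas, path) {
  d <- data.frame(snp_id = gwas$snp_id, effect_allele = "A",
                  beta = formatC(gwas$beta_hat, digits = 17, format = "g"),
                  se = formatC(gwas$se, digits = 17, format = "g"),
                  pvalue = formatC(gwas$pvalue, digits = 17, format = "g"),
                  n = gwas$n)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = c("integer", "character", "numeric",
                                        "numeric", "numeric", "integer"))
  out <- data.frame(snp_id = d$snp_id, beta_hat = d$beta, se = d$se,
                    pvalue = d$pvalue, n = d$n)
  class(out) <- c("gwas_result", "data.frame")
  out
}
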