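#' Select SNPs passing a P-value threshold
#'
#' Filters a discovery scan at `pvalue <= threshold` (inclusive) and keeps
#' the discovery slope as the score weight, preserving SNP order. An empty
#' selection is legal and is handled downstream ([compute_prs()] returns an
#' all-zero score; [tsls_fit()] then refuses the zero-variance instrument).
#'
#' @param gwas A `gwas_result` data frame.
#' @param threshold P-value cutoff in (0, 1\].
#' @param source Label recording which discovery framework produced the
#'   weights (`"external"`, `"overlap"`, `"jackknife-block-<b>"`, ...).
#' @return A data frame of class `prs_weights` with columns `snp_id`,
#'   `weight`, `pvalue` and attributes `threshold` and `source`.
#' @examples
#' g <- data.frame(snp_id = 1:3, beta_hat = c(0.5, -0.2, 0.1),
#'                 se = c(0.1, 0.1, 0.1), pvalue = c(1e-9, 0.2, 0.04), n = 100)
#' select_snps(g, 0.05)
#' @export
select_snps <- function(gwas, threshold, source = "unspecified") {
  if (length(threshold) != 1L || threshold <= 0 || threshold > 1)
    stop("'threshold' must be a single P-value in (0, 1]")
  keep <- which(gwas$pvalue <= threshold & is.finite(gwas$beta_hat) &
                  is.finite(gwas$se))
  out <- data.frame(snp_id = gwas$snp_id[keep],
                    weight = gwas$beta_hat[keep],
                    pvalue = gwas$pvalue[keep])
  attr(out, "threshold") <- threshold
  attr(out, "source") <- source
  class(out) <- c("prs_weights", "data.frame")
  out
}

#' Weighted allele score from selected SNPs
#'
#' Scores each individual as the weighted sum of effect-allele dosages over
#' the selected SNPs: \eqn{s_i = \sum_j w_j g_{ij}}. Dosages are used as-is
#' (0/1/2, not centred or standardized). Empty weights yield an all-zero
#' score with `n_snps_used = 0`.
#'
#' @param genotypes n x m dosage matrix (or `cohort` object).
#' @param weights A `prs_weights` data frame; `snp_id` values must index
#'   columns of `genotypes`.
#' @return An object of class `prs_score`: list with `values` (length-n
#'   numeric), `n_snps_used`, `threshold`, `framework`.
#' @examples
#' G <- matrix(c(0, 1, 2, 2, 1, 0), 3, 2)
#' w <- data.frame(snp_id = 1:2, weight = c(0.5, -0.25), pvalue = c(0, 0))
#' compute_prs(G, w)$values
#' @export
compute_prs <- function(genotypes, weights) {
  if (inherits(genotypes, "cohort")) genotypes <- genotypes$genotypes
  stopifnot(is.matrix(genotypes))
  idx <- as.integer(weights$snp_id)
  if (length(idx) && (any(is.na(idx)) || any(idx < 1L) ||
                      any(idx > ncol(genotypes))))
    stop("unknown snp_id in weights: weight/genotype misalignment")
  values <- if (length(idx)) {
    as.vector(genotypes[, idx, drop = FALSE] %*% weights$weight)
  } else {
    numeric(nrow(genotypes))
  }
  new_prs_score(values, length(idx),
                threshold = attr(weights, "threshold"),
                framework = attr(weights, "source"))
}

new_prs_score <- function(values, n_snps_used, threshold = NA_real_,
                          framework = "unspecified") {
  structure(list(values = values, n_snps_used = n_snps_used,
                 threshold = if (is.null(threshold)) NA_real_ else threshold,
                 framework = framework),
            class = "prs_score")
}

#' @export
print.prs_score <- function(x, ...) {
  cat(sprintf("Allele score (%s framework): %d individuals, %s SNPs, threshold %s\n",
              x$framework, length(x$values),
              paste(format(x$n_snps_used), collapse = "/"),
              format(x$threshold)))
  invisible(x)
}

# Accept either a prs_score or a bare numeric vector as an instrument.
score_values <- function(x) {
  if (inherits(x, "prs_score")) x$values else as.numeric(x)
}

#' Write / read score and weight tables
#'
#' Scores go to a tab-delimited `sample_id score` table; weights to a
#' `snp_id weight pvalue` table.
#'
#' @param score A `prs_score` object.
#' @param weights A `prs_weights` data frame.
#' @param path File path.
#' @return Writers return `path` invisibly; readers return the object.
#' @export
write_scores <- function(score, path) {
  d <- data.frame(sample_id = seq_along(score$values),
                  score = formatC(score$values, digits = 17, format = "g"))
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE)
  new_prs_score(as.numeric(d$score), NA_integer_)
}

#' @rdname write_scores
#' @export
write_weights <- function(weights, path) {
  d <- data.frame(snp_id = weights$snp_id,
                  weight = formatC(weights$weight, digits = 17, format = "g"),
                  pvalue = formatC(weights$pvalue, digits = 17, format = "g"))
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_weights <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = c("integer", "numeric", "numeric"))
  class(d) <- c("prs_weights", "data.frame")
  d
}
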