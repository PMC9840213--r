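#' Randomly partition individuals into balanced jackknife blocks
#'
#' Assigns each of `n` individuals to one of `n_block` blocks uniformly at
#' random, with block sizes balanced to within one individual (sizes
#' `floor(n/n_block)` or `floor(n/n_block) + 1`). Balancing equalizes the
#' leave-one-block-out discovery sample sizes at roughly
#' `(n_block - 1) / n_block` of `n`.
#'
#' @param n Number of individuals.
#' @param n_block Number of blocks, `2 <= n_block <= n`.
#' @return An object of class `block_assignment`: list with `block_of`
#'   (length-n integer labels in `1..n_block`) and `n_block`.
#' @examples
#' set.seed(1)
#' table(assign_blocks(11, 3)$block_of) # sizes 4, 4, 3 in some order
#' @export
assign_blocks <- function(n, n_block) {
  n <- as.integer(n); n_block <- as.integer(n_block)
  if (n_block < 2L) stop("invalid parameters: 'n_block' must be at least 2")
  if (n < n_block) stop("invalid parameters: need n >= n_block")
  base <- n %/% n_block
  sizes <- rep.int(base, n_block)
  extra <- n %% n_block
  if (extra > 0L) sizes[seq_len(extra)] <- base + 1L
  block_of <- sample(rep.int(seq_len(n_block), times = sizes))
  structure(list(block_of = block_of, n_block = n_block),
            class = "block_assignment")
}

#' @export
print.block_assignment <- function(x, ...) {
  cat(sprintf("Block assignment: %d individuals in %d blocks (sizes %s)\n",
              length(x$block_of), x$n_block,
              paste(sort(tabulate(x$block_of, x$n_block)), collapse = ", ")))
  invisible(x)
}

#' Write / read a block assignment
#'
#' Tab-delimited `sample_id block` table.
#' @param blocks A `block_assignment` object.
#' @param path File path.
#' @export
write_blocks <- function(blocks, path) {
  utils::write.table(data.frame(sample_id = seq_along(blocks$block_of),
                                block = blocks$block_of),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_blocks
#' @export
read_blocks <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE)
  structure(list(block_of = as.integer(d$block),
                 n_block = max(d$block)), class = "block_assignment")
}

#' Externally weighted allele score
#'
#' Framework A: the discovery scan runs on an independent external cohort's
#' exposure; SNPs passing the threshold are scored (with their external
#' weights) in the applied cohort. No applied individual contributes to the
#' discovery scan.
#'
#' @param applied Applied `cohort` (scored and later used for MR).
#' @param external External `cohort` (discovery scan only).
#' @param threshold P-value selection cutoff in (0, 1\].
#' @return A `prs_score` for the applied cohort, framework `"external"`.
#' @export
external_prs <- function(applied, external, threshold) {
  scan <- gwas_scan(external$genotypes, external$exposure)
  w <- select_snps(scan, threshold, source = "external")
  compute_prs(applied$genotypes, w)
}

#' Overlapping-sample allele score
#'
#' Framework B: discovery scan, SNP selection and scoring all use the same
#' applied cohort (100% sample overlap). This is the construction that
#' suffers winner's-curse/overfitting inflation of the score-exposure
#' association.
#'
#' @inheritParams external_prs
#' @return A `prs_score` for the applied cohort, framework `"overlap"`.
#' @export
overlap_prs <- function(applied, threshold) {
  scan <- gwas_scan(applied$genotypes, applied$exposure)
  w <- select_snps(scan, threshold, source = "overlap")
  compute_prs(applied$genotypes, w)
}

#' Block jackknife resampled allele score
#'
#' Framework C: individuals are split into `n_block` random balanced blocks;
#' for each block b a discovery scan of the exposure runs on all individuals
#' \emph{not} in b; SNPs passing the threshold in that scan (with its
#' weights) score only the members of block b. Per-block SNP sets and
#' weights may differ; the assembled score is intentionally heterogeneous
#' across blocks. Structurally, no individual's data ever enter the scan
#' that produced their own weights, which removes discovery/application
#' sample overlap while using every individual for both purposes.
#'
#' @inheritParams external_prs
#' @param n_block Number of jackknife blocks (default 10).
#' @param blocks Optional precomputed [assign_blocks()] result; drawn fresh
#'   when `NULL`.
#' @return List with `score` (a `prs_score`, framework `"jackknife"`, where
#'   `n_snps_used` is the per-block mean count), `block_weights` (list of
#'   `prs_weights`, one per block), and `blocks` (the assignment).
#' @examples
#' p <- sim_params(n_applied = 300, n_snp = 30, thresholds = 1)
#' set.seed(2)
#' co <- simulate_cohort(p, allocate_true_effects(p), "applied")
#' jk <- jackknife_prs(co, n_block = 3, threshold = 1)
#' length(jk$score$values)
#' @export
jackknife_prs <- function(applied, n_block = 10, threshold, blocks = NULL) {
  G <- applied$genotypes
  n <- nrow(G)
  if (is.null(blocks)) blocks <- assign_blocks(n, n_block)
  scans <- gwas_scan_blocks(G, applied$exposure, blocks)
  values <- numeric(n)
  block_weights <- vector("list", blocks$n_block)
  counts <- integer(blocks$n_block)
  for (b in seq_len(blocks$n_block)) {
    w <- select_snps(scans[[b]], threshold,
                     source = paste0("jackknife-block-", b))
    block_weights[[b]] <- w
    counts[b] <- nrow(w)
    members <- which(blocks$block_of == b)
    values[members] <- compute_prs(G[members, , drop = FALSE], w)$values
  }
  score <- new_prs_score(values, mean(counts), threshold = threshold,
                         framework = "jackknife")
  score$n_snps_per_block <- counts
  list(score = score, block_weights = block_weights, blocks = blocks)
}
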