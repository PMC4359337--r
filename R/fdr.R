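#' Nested sample-label permutation of genotypes
#'
#' Permutes whole per-sample genotype vectors coherently across nested
#' strata, following a three-step scheme: shuffle the genotype rows within
#' the smallest stratum; then, moving to each successively larger stratum,
#' shuffle only the increment samples (those not contained in any smaller
#' stratum) among themselves; repeat until all strata are permuted.  Each
#' sample therefore carries the same permuted genotype vector in every
#' stratum that contains it, and every stratum's genotype multiset is
#' preserved.  Expression and annotations are untouched.
#'
#' Uses the current R RNG state; call [set.seed()] first for
#' reproducibility.
#'
#' @param geno samples x SNPs dosage matrix.
#' @param stratum_samples list of sample-id vectors, one per stratum; must
#'   be nested (every stratum a subset of every larger one).
#' @return the permuted genotype matrix (same dimnames, rows reassigned
#'   within blocks).
#' @export
nested_permutation <- function(geno, stratum_samples) {
  stopifnot(is.matrix(geno), length(stratum_samples) >= 1)
  ord <- order(lengths(stratum_samples))
  sets <- lapply(stratum_samples[ord], as.character)
  for (i in seq_along(sets)) {
    if (i > 1 && !all(sets[[i - 1]] %in% sets[[i]]))
      .fail("strata are not nested: '%s' is not contained in '%s'",
            names(sets)[i - 1] %||% (i - 1), names(sets)[i] %||% i)
    if (!all(sets[[i]] %in% rownames(geno)))
      .fail("stratum sample(s) missing from genotype matrix")
  }
  out <- geno
  prev <- character()
  for (i in seq_along(sets)) {
    block <- setdiff(sets[[i]], prev)
    if (length(block) > 1)
      out[block, ] <- out[block[sample.int(length(block))], ]
    prev <- sets[[i]]
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.summary_from_counts <- function(false_counts, n_observed, scheme, seed) {
  mean_false <- mean(false_counts)
  fdr <- if (n_observed > 0) 100 * mean_false / n_observed else NA_real_
  structure(list(n_reps = length(false_counts), false_counts = false_counts,
                 mean_false = mean_false, n_observed = n_observed,
                 fdr_pct = fdr, max_false = max(false_counts),
                 scheme = scheme, seed = seed),
            class = "permutation_summary")
}

#' @export
print.permutation_summary <- function(x, ...) {
  cat(sprintf("%s: %d replicate(s)\n", x$scheme, x$n_reps))
  cat(sprintf("mean false associations %.3f (max %d) vs %d observed\n",
              x$mean_false, x$max_false, x$n_observed))
  if (is.na(x$fdr_pct)) cat("FDR: undefined (no observed associations)\n")
  else cat(sprintf("estimated FDR: %.1f%%\n", .round_half_up(x$fdr_pct, 1L)))
  invisible(x)
}

#' Permutation-based FDR of the stratified consensus
#'
#' Per replicate: genotypes are permuted by the nested sample-label scheme,
#' the full stratified-consensus pipeline is re-run against the original
#' expression data, and the resulting consensus size is recorded as that
#' replicate's false-association count.  Replicates use independent
#' deterministic sub-streams of the master seed and are invariant to
#' execution order.
#'
#' @inheritParams run_stratified
#' @param n_reps number of permutation replicates (>= 1).
#' @param n_observed observed consensus size; computed from the unpermuted
#'   data when `NULL`.  If 0, the FDR percentage is reported as `NA`
#'   (undefined) but the counts are still returned.
#' @return object of class `permutation_summary`.
#' @export
permutation_fdr <- function(expr, geno, annotations,
                            strata = default_strata(),
                            config = sem_config(), n_reps = 1000L,
                            n_observed = NULL) {
  stopifnot(n_reps >= 1)
  groups <- stratify_samples(annotations, strata)
  if (is.null(n_observed))
    n_observed <- nrow(stratified_consensus(expr, geno, annotations, strata,
                                            config)$calls)
  counts <- integer(n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(derive_seed(config$seed, paste0("perm-shuffle-", r)))
    g_perm <- nested_permutation(geno, groups)
    cfg <- config
    cfg$seed <- derive_seed(config$seed, paste0("perm-fit-", r))
    counts[r] <- nrow(stratified_consensus(expr, g_perm, annotations, strata,
                                           cfg)$calls)
  }
  .summary_from_counts(counts, n_observed, "nested_permutation", config$seed)
}

#' Random-SNP-panel FDR of the stratified consensus
#'
#' Per replicate: `n_select` SNPs are drawn uniformly without replacement
#' from a large null pool (standing in for the full genotyping array, with
#' the candidate panel excluded), the full stratified-consensus pipeline is
#' run on the redrawn panel, and the consensus size is recorded.
#'
#' @inheritParams permutation_fdr
#' @param snp_pool samples x pool-SNPs dosage matrix.
#' @param n_select panel size per replicate (<= pool size).
#' @return object of class `permutation_summary`.
#' @export
random_snp_fdr <- function(expr, snp_pool, annotations,
                           strata = default_strata(), config = sem_config(),
                           n_select = 35L, n_reps = 1000L,
                           n_observed = NULL) {
  stopifnot(is.matrix(snp_pool), n_reps >= 1)
  if (ncol(snp_pool) < n_select)
    .fail("SNP pool (%d) smaller than n_select (%d)", ncol(snp_pool),
          n_select)
  if (is.null(n_observed)) n_observed <- NA_integer_
  counts <- integer(n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(derive_seed(config$seed, paste0("panel-draw-", r)))
    panel <- sort(sample.int(ncol(snp_pool), n_select))
    cfg <- config
    cfg$seed <- derive_seed(config$seed, paste0("panel-fit-", r))
    counts[r] <- nrow(stratified_consensus(
      expr, snp_pool[, panel, drop = FALSE], annotations, strata,
      cfg)$calls)
  }
  .summary_from_counts(counts,
                       if (is.na(n_observed)) 0L else n_observed,
                       "random_snp_panel", config$seed)
}

#' False-discovery-rate percentage from resampling counts
#'
#' `100 * mean_false / n_observed`, reported rounded half-up to one decimal
#' (the precision at which resampling FDRs are conventionally quoted).
#'
#' @param mean_false mean false-association count over replicates (>= 0).
#' @param n_observed observed consensus size (> 0).
#' @return the FDR percentage, one decimal.
#' @export
estimate_fdr <- function(mean_false, n_observed) {
  stopifnot(mean_false >= 0)
  if (!is.numeric(n_observed) || n_observed <= 0)
    .fail("FDR undefined: n_observed must be positive")
  .round_half_up(100 * mean_false / n_observed, 1L)
}
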