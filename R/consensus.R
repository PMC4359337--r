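#' Default stroma-percentage strata
#'
#' Four nested strata defined by strict thresholds on stroma percentage:
#' `>50%`, `>60%`, `>70%`, `>80%`.
#'
#' @param thresholds strictly increasing numeric thresholds (exclusive).
#' @return data.frame with `label` and `min_stroma_pct`.
#' @export
default_strata <- function(thresholds = c(50, 60, 70, 80)) {
  if (is.unsorted(thresholds, strictly = TRUE))
    .fail("stratum thresholds must be strictly increasing")
  data.frame(label = paste0(">", thresholds, "%"),
             min_stroma_pct = thresholds, stringsAsFactors = FALSE)
}

#' Assign samples to stroma strata
#'
#' A sample belongs to a stratum iff its stroma percentage is strictly
#' greater than the stratum threshold; the strata are therefore nested by
#' construction (each higher-threshold stratum is a subset of the previous).
#'
#' @param annotations data.frame with `sample_id` and `stroma_pct`.
#' @param strata stratum table as from [default_strata()].
#' @return named list mapping stratum label to sample-id vector.
#' @export
stratify_samples <- function(annotations, strata = default_strata()) {
  stopifnot(all(c("sample_id", "stroma_pct") %in% names(annotations)))
  bad <- annotations$sample_id[is.na(annotations$stroma_pct)]
  if (length(bad))
    .fail("missing stroma_pct for sample(s): %s", paste(bad, collapse = ", "))
  out <- lapply(strata$min_stroma_pct, function(th)
    annotations$sample_id[annotations$stroma_pct > th])
  stats::setNames(out, strata$label)
}

#' Run the eQTL engine independently on each stroma stratum
#'
#' Each stratum gets its own fit on its own samples: genotypes are
#' re-prepared per subset (re-imputation; re-exclusion of SNPs monomorphic
#' within the subset), expression is re-standardized within the subset, and
#' the per-stratum seed is derived deterministically from the master
#' `config$seed` and the stratum label.
#'
#' @param expr,geno full samples x transcripts / samples x SNPs matrices.
#' @param annotations data.frame with `sample_id`, `stroma_pct`.
#' @param strata stratum table ([default_strata()]).
#' @param config a [sem_config()]; its `seed` is the master seed.
#' @param min_samples smallest admissible stratum (default 3).
#' @return object of class `stratified_calls`: list with `calls` (named list
#'   of per-stratum call data.frames), `stratum_sizes`, `excluded`
#'   (per-stratum exclusion tables).
#' @export
run_stratified <- function(expr, geno, annotations, strata = default_strata(),
                           config = sem_config(), min_samples = 3L) {
  groups <- stratify_samples(annotations, strata)
  sizes <- lengths(groups)
  too_small <- names(groups)[sizes < min_samples]
  if (length(too_small))
    .fail("stratum %s has fewer than %d samples",
          paste(too_small, collapse = ", "), min_samples)
  calls <- vector("list", length(groups))
  excluded <- vector("list", length(groups))
  names(calls) <- names(excluded) <- names(groups)
  for (lab in names(groups)) {
    ids <- groups[[lab]]
    cfg <- config
    cfg$seed <- derive_seed(config$seed, lab)
    fit <- fit_sem(expr[ids, , drop = FALSE], geno[ids, , drop = FALSE], cfg)
    calls[[lab]] <- call_associations(fit, stratum_label = lab)
    excluded[[lab]] <- fit$excluded_snps
  }
  structure(list(calls = calls, stratum_sizes = sizes, excluded = excluded),
            class = "stratified_calls")
}

#' Intersect per-stratum association calls
#'
#' An association is accepted only if the same (SNP, transcript) pair was
#' called in every stratum's analysis; support values need not agree across
#' strata.  The intersection itself acts as a false-discovery suppressor:
#' a noise pair must clear the support threshold independently in all
#' subsets.
#'
#' @param per_stratum_calls a `stratified_calls` object or a named list of
#'   call data.frames (columns `snp_id`, `transcript_id`, `support`).
#' @return object of class `consensus_set`: list with `calls` (data.frame
#'   `snp_id`, `transcript_id`, ordered by SNP then transcript),
#'   `per_stratum_support` (long data.frame), `stratum_sizes` (if known).
#' @export
intersect_calls <- function(per_stratum_calls) {
  sizes <- NULL
  if (inherits(per_stratum_calls, "stratified_calls")) {
    sizes <- per_stratum_calls$stratum_sizes
    per_stratum_calls <- per_stratum_calls$calls
  }
  if (length(per_stratum_calls) < 1) .fail("need at least one stratum")
  keys <- lapply(per_stratum_calls, function(d)
    paste(d$snp_id, d$transcript_id, sep = "\r"))
  common <- Reduce(intersect, keys)
  common <- sort(common)
  parts <- strsplit(common, "\r", fixed = TRUE)
  calls <- data.frame(
    snp_id = vapply(parts, `[`, character(1), 1),
    transcript_id = vapply(parts, `[`, character(1), 2),
    stringsAsFactors = FALSE)
  if (nrow(calls))
    calls <- calls[order(calls$snp_id, calls$transcript_id), , drop = FALSE]
  rownames(calls) <- NULL
  supp <- do.call(rbind, lapply(names(per_stratum_calls), function(lab) {
    d <- per_stratum_calls[[lab]]
    k <- paste(d$snp_id, d$transcript_id, sep = "\r")
    keep <- k %in% common
    if (!any(keep)) return(NULL)
    data.frame(snp_id = d$snp_id[keep], transcript_id = d$transcript_id[keep],
               stratum = lab, support = d$support[keep],
               stringsAsFactors = FALSE)
  }))
  if (is.null(supp))
    supp <- data.frame(snp_id = character(), transcript_id = character(),
                       stratum = character(), support = numeric())
  structure(list(calls = calls, per_stratum_support = supp,
                 stratum_sizes = sizes),
            class = "consensus_set")
}

#' @export
print.consensus_set <- function(x, ...) {
  cat(sprintf("consensus_set: %d association(s) present in all %s strata\n",
              nrow(x$calls),
              if (is.null(x$stratum_sizes)) "input"
              else length(x$stratum_sizes)))
  if (nrow(x$calls)) print(utils::head(x$calls, 10))
  invisible(x)
}

#' @export
as.data.frame.consensus_set <- function(x, ...) {
  calls <- x$calls
  if (nrow(calls) == 0) {
    wide <- data.frame(association_id = integer(), snp_id = character(),
                       transcript_id = character())
    for (lab in unique(x$per_stratum_support$stratum))
      wide[[paste0("support_", lab)]] <- numeric()
    return(wide)
  }
  wide <- data.frame(association_id = seq_len(nrow(calls)), calls,
                     stringsAsFactors = FALSE)
  supp <- x$per_stratum_support
  for (lab in unique(supp$stratum)) {
    s <- supp[supp$stratum == lab, ]
    m <- match(paste(calls$snp_id, calls$transcript_id),
               paste(s$snp_id, s$transcript_id))
    wide[[paste0("support_", lab)]] <- s$support[m]
  }
  wide
}

#' Stratified-consensus pipeline
#'
#' Convenience wrapper: stratify, fit per stratum, intersect.  This is the
#' discovery pipeline the resampling FDR procedures repeat on null data.
#'
#' @inheritParams run_stratified
#' @return a `consensus_set`.
#' @export
stratified_consensus <- function(expr, geno, annotations,
                                 strata = default_strata(),
                                 config = sem_config(), min_samples = 3L) {
  intersect_calls(run_stratified(expr, geno, annotations, strata, config,
                                 min_samples))
}
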