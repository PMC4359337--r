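#' Read a genotype dosage matrix
#'
#' Two dialects are supported: a TSV matrix (samples in rows, first column
#' sample ids, header row of SNP ids, body entries in \{0, 1, 2\} or `NA`)
#' and a minimal diploid VCF (CHROM/POS/ID/REF/ALT + per-sample `GT`), in
#' which dosages are counted copies of the designated risk allele (`"ALT"`
#' by default).  Missing entries are preserved as `NA`; imputation happens
#' at model-entry time, not at read time.
#'
#' @param path file to read.
#' @param format_hint `"auto"` (by extension/content), `"tsv"` or `"vcf"`.
#' @param risk_allele for VCF input: `"ALT"` (default) or `"REF"`.
#' @return samples x SNPs numeric matrix with dimnames; VCF input also
#'   carries a `"risk_allele"` attribute (per-SNP base).
#' @export
read_genotypes <- function(path, format_hint = c("auto", "tsv", "vcf"),
                           risk_allele = "ALT") {
  format_hint <- match.arg(format_hint)
  if (!file.exists(path)) .fail("genotype file not found: %s", path)
  if (format_hint == "auto") {
    first <- readLines(path, n = 1L)
    format_hint <- if (grepl("^##fileformat=VCF", first) ||
                       grepl("\\.vcf$", path)) "vcf" else "tsv"
  }
  if (format_hint == "vcf") return(.read_genotypes_vcf(path, risk_allele))
  tab <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    row.names = 1L, check.names = FALSE,
                    colClasses = "character")
  if (ncol(tab) < 1L) .fail("genotype TSV has no SNP columns: %s", path)
  if (anyDuplicated(rownames(tab)))
    .fail("duplicate sample id(s) in %s: %s", path,
          paste(unique(rownames(tab)[duplicated(rownames(tab))]),
                collapse = ", "))
  if (anyDuplicated(colnames(tab)))
    .fail("duplicate SNP id(s) in %s", path)
  m <- as.matrix(tab)
  suppressWarnings(num <- matrix(as.numeric(m), nrow = nrow(m),
                                 dimnames = dimnames(m)))
  bad <- which(is.na(num) & !(is.na(m) | m %in% c("NA", "")),
               arr.ind = TRUE)
  if (nrow(bad))
    .fail("non-dosage entry '%s' at row %s (sample %s), column %s",
          m[bad[1, 1], bad[1, 2]], bad[1, 1], rownames(m)[bad[1, 1]],
          colnames(m)[bad[1, 2]])
  out_of_range <- which(!is.na(num) & !(num %in% c(0, 1, 2)), arr.ind = TRUE)
  if (nrow(out_of_range))
    .fail("dosage %g outside {0,1,2} at sample %s, SNP %s",
          num[out_of_range[1, 1], out_of_range[1, 2]],
          rownames(num)[out_of_range[1, 1]],
          colnames(num)[out_of_range[1, 2]])
  num
}

.read_genotypes_vcf <- function(path, risk_allele = "ALT") {
  if (!requireNamespace("vcfR", quietly = TRUE))
    .fail("reading VCF genotypes requires the 'vcfR' package")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")  # variants x samples
  ids <- vcfR::getID(vcf)
  if (anyDuplicated(ids)) .fail("duplicate SNP id(s) in VCF %s", path)
  rownames(gt) <- ids
  alleles <- strsplit(gsub("\\|", "/", as.character(gt)), "/", fixed = FALSE)
  n_al <- lengths(alleles)
  if (any(!is.na(gt) & n_al != 2L)) {
    i <- which(!is.na(gt) & n_al != 2L)[1]
    .fail("non-diploid GT '%s' in VCF %s", as.character(gt)[i], path)
  }
  alt_count <- vapply(alleles, function(a) {
    if (anyNA(a) || any(a == ".")) return(NA_real_)
    sum(a != "0")
  }, numeric(1))
  dos <- matrix(alt_count, nrow = nrow(gt), dimnames = dimnames(gt))
  if (identical(risk_allele, "REF")) dos <- 2 - dos
  out <- t(dos)  # samples x SNPs
  base <- if (identical(risk_allele, "REF")) vcfR::getREF(vcf)
          else vcfR::getALT(vcf)
  attr(out, "risk_allele") <- stats::setNames(base, ids)
  out
}

#' Read a normalized expression matrix
#'
#' TSV, samples in rows (first column sample ids), transcripts in columns
#' (probe-set-style identifiers preserved verbatim), numeric log-scale body.
#' Any non-numeric cell is an error reported with its coordinates.
#'
#' @param path file to read.
#' @return samples x transcripts numeric matrix.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) .fail("expression file not found: %s", path)
  if (file.size(path) == 0) .fail("expression file is empty: %s", path)
  tab <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    row.names = 1L, check.names = FALSE,
                    colClasses = "character")
  if (nrow(tab) == 0 || ncol(tab) == 0)
    .fail("expression file has no data body: %s", path)
  if (anyDuplicated(rownames(tab)) || anyDuplicated(colnames(tab)))
    .fail("duplicate sample or transcript id(s) in %s", path)
  m <- as.matrix(tab)
  suppressWarnings(num <- matrix(as.numeric(m), nrow = nrow(m),
                                 dimnames = dimnames(m)))
  bad <- which(!is.finite(num), arr.ind = TRUE)
  if (nrow(bad))
    .fail("non-numeric expression cell '%s' at sample %s, transcript %s",
          m[bad[1, 1], bad[1, 2]], rownames(m)[bad[1, 1]],
          colnames(m)[bad[1, 2]])
  num
}

#' Read a per-sample annotation table
#'
#' @param path TSV with at least `sample_id`, `stroma_pct`; typically also
#'   `tumor_pct`, `relapse`, `followup_time` and clinical covariates.
#' @return data.frame.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) .fail("annotation file not found: %s", path)
  tab <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(tab))
    .fail("annotation table lacks a sample_id column: %s", path)
  if (anyDuplicated(tab$sample_id))
    .fail("duplicate sample id(s) in annotations: %s", path)
  tab
}

#' Write a matrix as TSV (samples in rows)
#'
#' @param m matrix with dimnames.
#' @param path output path.
#' @param id_col header name of the first (row id) column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "sample_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an annotation table as TSV
#' @param annotations data.frame with a `sample_id` column.
#' @param path output path.
#' @export
write_annotations <- function(annotations, path) {
  write.table(annotations, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic study to a directory
#'
#' Emits `genotypes.tsv`, `expression.tsv`, `annotations.tsv` and
#' `truth.tsv` in the same TSV dialects the readers accept.
#'
#' @param study a [make_study()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(study$genotypes, file.path(dir, "genotypes.tsv"))
  write_matrix_tsv(study$expression, file.path(dir, "expression.tsv"))
  write_annotations(study$annotations, file.path(dir, "annotations.tsv"))
  write.table(study$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Average replicate arrays to one row per patient
#'
#' Some patients contribute two or three biological replicate arrays; the
#' analysis wants one expression row per patient, the arithmetic mean of the
#' patient's replicate rows.
#'
#' @param expr samples x transcripts matrix (rows are array samples).
#' @param replicate_map named character vector or two-column data.frame
#'   (`array_id`, `patient_id`) assigning every array row to a patient.
#' @return patients x transcripts matrix, one row per patient, in first-seen
#'   patient order.
#' @export
average_replicates <- function(expr, replicate_map) {
  if (is.data.frame(replicate_map)) {
    stopifnot(all(c("array_id", "patient_id") %in% names(replicate_map)))
    map <- stats::setNames(replicate_map$patient_id, replicate_map$array_id)
  } else map <- replicate_map
  missing <- setdiff(rownames(expr), names(map))
  if (length(missing))
    .fail("array sample(s) absent from replicate_map: %s",
          paste(missing, collapse = ", "))
  patient <- as.character(map[rownames(expr)])
  patients <- unique(patient)
  out <- t(vapply(patients, function(p)
    colMeans(expr[patient == p, , drop = FALSE]), numeric(ncol(expr))))
  dimnames(out) <- list(patients, colnames(expr))
  out
}

#' Write consensus and FDR results as annotated TSV
#'
#' Mirrors the discovery-table schema (association id, probe set, SNP,
#' support per stratum) with run metadata as leading `#` comment lines, and
#' writes the per-replicate FDR counts alongside.
#'
#' @param consensus a `consensus_set` (see [intersect_calls()]).
#' @param permutation_summaries optional (possibly named) list of
#'   `permutation_summary` objects.
#' @param path output directory (created if needed).
#' @param metadata optional named character vector of extra metadata lines.
#' @return paths of the files written, invisibly.
#' @export
write_results <- function(consensus, permutation_summaries = NULL, path,
                          metadata = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  ok <- file.access(path, 2) == 0
  if (!ok) .fail("output path not writable: %s", path)
  files <- character()

  meta <- c(sprintf("generated_by=stromaQTL %s",
                    as.character(utils::packageVersion("stromaQTL"))),
            sprintf("date=%s", format(Sys.time(), "%Y-%m-%d")),
            if (!is.null(metadata)) paste0(names(metadata), "=", metadata))
  tab <- as.data.frame(consensus)
  f <- file.path(path, "consensus_calls.tsv")
  con <- file(f, "w")
  writeLines(paste0("# ", meta), con)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  files <- c(files, f)

  if (!is.null(permutation_summaries) && length(permutation_summaries)) {
    if (is.null(names(permutation_summaries)))
      names(permutation_summaries) <-
        vapply(permutation_summaries, function(s) s$scheme, character(1))
    sumtab <- do.call(rbind, lapply(names(permutation_summaries), function(nm) {
      s <- permutation_summaries[[nm]]
      data.frame(scheme = s$scheme, n_reps = s$n_reps,
                 mean_false = s$mean_false, max_false = s$max_false,
                 n_observed = s$n_observed,
                 fdr_pct = ifelse(is.na(s$fdr_pct), NA,
                                  .round_half_up(s$fdr_pct, 1L)))
    }))
    f2 <- file.path(path, "fdr_summary.tsv")
    con <- file(f2, "w")
    writeLines(paste0("# ", meta), con)
    write.table(sumtab, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    counts <- do.call(rbind, lapply(names(permutation_summaries), function(nm) {
      s <- permutation_summaries[[nm]]
      data.frame(scheme = s$scheme, replicate = seq_len(s$n_reps),
                 false_count = s$false_counts)
    }))
    f3 <- file.path(path, "fdr_replicate_counts.tsv")
    write.table(counts, f3, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f2, f3)
  }
  invisible(files)
}

#' Re-read a written consensus-calls table
#'
#' Inverse of the consensus part of [write_results()]; `#` metadata lines
#' are skipped.
#'
#' @param path the `consensus_calls.tsv` file.
#' @return data.frame in the written schema.
#' @export
read_consensus <- function(path) {
  read.delim(path, sep = "\t", comment.char = "#", check.names = FALSE,
             stringsAsFactors = FALSE)
}
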