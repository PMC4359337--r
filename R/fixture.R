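#' Load the packaged discovery-table fixture
#'
#' The package ships the published table of 47 trans-eQTL associations
#' between 8 prostate-cancer risk SNPs and 46 transcripts (probe sets) in
#' tumor-adjacent stroma, flattened so every row carries its SNP's id, risk
#' allele and locus.  The fixture is validated on load: the association ids
#' must be unique and contiguous from 1, every row must have a nonempty
#' probe set and SNP id, and the column schema must be intact.
#'
#' @return data.frame of class `association_table` with columns
#'   `association_id`, `probe_set`, `gene_symbol`, `gene_location`,
#'   `snp_id`, `risk_allele`, `snp_locus`.
#' @export
load_association_fixture <- function() {
  path <- system.file("extdata", "table2_associations.tsv",
                      package = "stromaQTL")
  if (!nzchar(path) || !file.exists(path))
    .fail("packaged association fixture is missing")
  tab <- read.delim(path, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
  expected <- c("association_id", "probe_set", "gene_symbol", "gene_location",
                "snp_id", "risk_allele", "snp_locus")
  if (!identical(names(tab), expected))
    .fail("association fixture is corrupt: unexpected column schema")
  ids <- tab$association_id
  if (anyNA(ids) || !identical(as.integer(ids), seq_len(nrow(tab))))
    .fail("association fixture is corrupt: ids not contiguous from 1")
  if (any(!nzchar(tab$probe_set)) || any(!nzchar(tab$snp_id)))
    .fail("association fixture is corrupt: empty probe_set or snp_id")
  class(tab) <- c("association_table", "data.frame")
  tab
}

#' Summarize an association table
#'
#' Counts are taken from the table itself (reported, never recomputed from
#' expression data): total associations, distinct SNPs, distinct transcripts
#' (by probe set), and per-SNP transcript counts.
#'
#' @param table an association table as returned by
#'   [load_association_fixture()] (any data.frame with `probe_set` and
#'   `snp_id` columns works).
#' @return list of class `association_summary` with elements
#'   `n_associations`, `n_snps`, `n_transcripts`, `per_snp` (named integer
#'   vector, decreasing).
#' @export
summarize_associations <- function(table) {
  stopifnot(all(c("probe_set", "snp_id") %in% names(table)))
  per_snp <- sort(table(table$snp_id), decreasing = TRUE)
  structure(list(n_associations = nrow(table),
                 n_snps = length(unique(table$snp_id)),
                 n_transcripts = length(unique(table$probe_set)),
                 per_snp = stats::setNames(as.integer(per_snp),
                                           names(per_snp))),
            class = "association_summary")
}

#' @export
print.association_summary <- function(x, ...) {
  cat(sprintf("%d associations between %d SNPs and %d transcripts\n",
              x$n_associations, x$n_snps, x$n_transcripts))
  cat("per-SNP transcript counts:\n")
  print(x$per_snp)
  invisible(x)
}
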