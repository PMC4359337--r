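Package: stromaQTL
Title: Stroma-Stratified Trans-eQTL Mapping by Spike-and-Slab Stochastic EM
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint trans-eQTL mapping of candidate risk SNPs against
    transcriptome-wide expression in tumor-adjacent stroma.  All transcripts
    and SNPs are analyzed together in a single multiple-linear-regression
    model with a spike-and-slab prior on every SNP-transcript effect, fitted
    by a Stochastic Expectation-Maximization (SEM) sampler; associations are
    called from iteration support and filtered by a four-way consensus over
    stroma-percentage-stratified sample subsets.  Includes resampling-based
    false discovery rate estimation (nested sample-label permutation and
    random SNP-panel redraws), a risk-group/survival downstream step
    (ordinal logistic regression, Kaplan-Meier and logrank), a synthetic
    study generator with planted associations for end-to-end validation,
    and TSV/VCF readers for the input matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    MASS,
    survival,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
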