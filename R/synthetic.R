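#' Synthetic study configuration
#'
#' Bundles the parameters of the synthetic-study generator.  The defaults
#' emulate the design of the motivating cohort: ~49 stroma-enriched patients
#' genotyped at 35 candidate risk SNPs with expression measured on thousands
#' of transcripts, stroma percentages spanning the >50/60/70/80% strata, and
#' binary biochemical-relapse outcomes with follow-up times (relapse rate
#' 20/47 with 2/49 of patients unknown).
#'
#' `effect_size` is the planted standardized effect: the expression shift per
#' standard deviation of dosage, in units of the residual SD.  The raw
#' per-allele effect stored in the truth table is
#' `effect_size * resid_sd / sd(dosage)`; `effect_size = 1` therefore plants
#' associations that explain half the variance of their transcript, the
#' magnitude a consensus filter over subsets as small as ~25 samples can
#' realistically retain.
#'
#' @param n_samples,n_snps,n_transcripts study dimensions.
#' @param maf_range minor-allele-frequency interval in (0, 0.5]; each SNP's
#'   MAF is drawn uniformly from it.
#' @param n_planted number of planted SNP-transcript associations.
#' @param hub_size how many of the planted pairs to concentrate on the first
#'   SNP (a "hub" mimicking a single variant associated with dozens of
#'   transcripts); the remainder go on distinct SNPs.  0 disables the hub.
#' @param effect_size standardized planted effect (per dosage SD, in residual
#'   SDs).
#' @param resid_sd residual SD of expression noise.
#' @param stroma_range interval in \[0, 100\] for the uniform stroma
#'   percentages.
#' @param relapse_rate probability of biochemical relapse.
#' @param unknown_rate fraction of samples with unknown relapse status.
#' @param seed master seed; all component generators derive from it.
#' @return an object of class `synthetic_config` (a validated list).
#' @seealso [make_study()]
#' @export
synthetic_config <- function(n_samples = 49, n_snps = 35, n_transcripts = 4030,
                             maf_range = c(0.1, 0.5), n_planted = 10,
                             hub_size = 0, effect_size = 1.0, resid_sd = 1.0,
                             stroma_range = c(51, 100),
                             relapse_rate = 20 / 47, unknown_rate = 2 / 49,
                             seed = 1L) {
  stopifnot(n_samples >= 2, n_snps >= 1, n_transcripts >= 1, n_planted >= 0,
            hub_size >= 0, resid_sd >= 0, effect_size >= 0)
  .check_maf_range(maf_range)
  .check_scalar_prob(relapse_rate, "relapse_rate")
  .check_scalar_prob(unknown_rate, "unknown_rate")
  if (length(stroma_range) != 2L || stroma_range[1] > stroma_range[2] ||
      stroma_range[1] < 0 || stroma_range[2] > 100)
    .fail("`stroma_range` must be an interval within [0, 100]")
  if (n_planted > n_snps * n_transcripts)
    .fail("n_planted (%d) exceeds n_snps * n_transcripts (%d)",
          n_planted, n_snps * n_transcripts)
  if (hub_size > n_planted)
    .fail("hub_size (%d) exceeds n_planted (%d)", hub_size, n_planted)
  structure(list(n_samples = as.integer(n_samples),
                 n_snps = as.integer(n_snps),
                 n_transcripts = as.integer(n_transcripts),
                 maf_range = as.numeric(maf_range),
                 n_planted = as.integer(n_planted),
                 hub_size = as.integer(hub_size),
                 effect_size = effect_size, resid_sd = resid_sd,
                 stroma_range = as.numeric(stroma_range),
                 relapse_rate = relapse_rate, unknown_rate = unknown_rate,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

.check_maf_range <- function(maf_range) {
  if (length(maf_range) != 2L || !is.numeric(maf_range) ||
      maf_range[1] > maf_range[2])
    .fail("`maf_range` must be a numeric interval c(lo, hi) with lo <= hi")
  if (maf_range[1] <= 0)
    .fail("`maf_range` lower bound %g violates the open bound > 0",
          maf_range[1])
  if (maf_range[2] > 0.5)
    .fail("`maf_range` upper bound %g violates the bound <= 0.5",
          maf_range[2])
}

.sample_ids <- function(n) sprintf("P%03d", seq_len(n))
.snp_ids <- function(k) sprintf("rs9%05d", seq_len(k))
.transcript_ids <- function(j) sprintf("%06d_at", 200000L + seq_len(j))

#' Simulate a genotype dosage matrix
#'
#' Independent SNPs under Hardy-Weinberg equilibrium: each SNP gets a minor
#' allele frequency drawn uniformly from `maf_range` and dosages drawn
#' `Binomial(2, MAF)` (risk-allele counts in \{0, 1, 2\}).
#'
#' @param n_samples,n_snps dimensions (`n_samples >= 2`).
#' @param maf_range MAF interval in (0, 0.5].
#' @param seed integer seed.
#' @return samples x SNPs integer matrix with sample/SNP ids as dimnames.
#' @export
simulate_genotypes <- function(n_samples, n_snps, maf_range = c(0.1, 0.5),
                               seed = 1L) {
  stopifnot(n_samples >= 2, n_snps >= 1)
  .check_maf_range(maf_range)
  set.seed(seed)
  maf <- runif(n_snps, maf_range[1], maf_range[2])
  g <- vapply(maf, function(p) rbinom(n_samples, 2L, p), integer(n_samples))
  g <- matrix(as.integer(g), nrow = n_samples, ncol = n_snps,
              dimnames = list(.sample_ids(n_samples), .snp_ids(n_snps)))
  attr(g, "maf") <- stats::setNames(maf, colnames(g))
  g
}

#' Simulate log-scale expression with planted trans-effects
#'
#' Generates `y_ij = beta_j + sum_k Z_ik gamma_jk + eps_ij` with
#' `eps ~ N(0, resid_sd^2)`: each transcript is the sum of the contributions
#' of its planted SNP effects plus noise.  Transcript baselines `beta_j`
#' are drawn once per transcript on a log2-microarray-like scale.
#'
#' @param genotypes samples x SNPs dosage matrix (column names are SNP ids).
#' @param truth data.frame with columns `snp_id`, `transcript_id`, `gamma`
#'   (raw per-allele effects); may have zero rows.
#' @param n_transcripts total number of transcripts (>= number named in
#'   `truth`); transcripts without a planted effect are pure noise.
#' @param resid_sd residual SD (0 gives the exact noise-free model).
#' @param seed integer seed.
#' @param transcript_ids optional explicit transcript id vector.
#' @return samples x transcripts numeric matrix; attribute `"beta"` holds the
#'   per-transcript intercepts.
#' @export
simulate_expression <- function(genotypes, truth, n_transcripts,
                                resid_sd = 1.0, seed = 1L,
                                transcript_ids = NULL) {
  stopifnot(is.matrix(genotypes), resid_sd >= 0)
  if (is.null(transcript_ids)) transcript_ids <- .transcript_ids(n_transcripts)
  stopifnot(length(transcript_ids) == n_transcripts)
  truth <- .validate_truth(truth, colnames(genotypes), transcript_ids)
  n <- nrow(genotypes)
  set.seed(seed)
  beta <- rnorm(n_transcripts, mean = 8, sd = 1.5)
  y <- matrix(rep(beta, each = n), nrow = n)  # per-transcript baseline
  for (r in seq_len(nrow(truth))) {
    j <- match(truth$transcript_id[r], transcript_ids)
    y[, j] <- y[, j] + genotypes[, truth$snp_id[r]] * truth$gamma[r]
  }
  if (resid_sd > 0)
    y <- y + matrix(rnorm(n * n_transcripts, 0, resid_sd), nrow = n)
  dimnames(y) <- list(rownames(genotypes), transcript_ids)
  attr(y, "beta") <- stats::setNames(beta, transcript_ids)
  y
}

.validate_truth <- function(truth, snp_ids, transcript_ids) {
  if (is.null(truth) || nrow(truth) == 0)
    return(data.frame(snp_id = character(), transcript_id = character(),
                      gamma = numeric()))
  stopifnot(all(c("snp_id", "transcript_id", "gamma") %in% names(truth)))
  bad <- setdiff(truth$snp_id, snp_ids)
  if (length(bad)) .fail("truth references unknown SNP id(s): %s",
                         paste(bad, collapse = ", "))
  bad <- setdiff(truth$transcript_id, transcript_ids)
  if (length(bad)) .fail("truth references unknown transcript id(s): %s",
                         paste(bad, collapse = ", "))
  truth
}

#' Simulate per-sample annotations
#'
#' Stroma percentages are drawn, by default, from a mixture over the four
#' analysis bins (50-60, 60-70, 70-80, 80-100) weighted to reproduce the
#' published strata sizes (49/41/33/25 out of 49, i.e. bin weights
#' 8:8:8:25), uniform within each bin; `stroma_dist = "uniform"` draws
#' plain uniform over `stroma_range` instead.  The exact patient-level
#' distribution of stroma content is not published — only the stratum
#' counts are — so the mixture is a declared stand-in matched to those
#' counts.  Tumor percentage is uniform on the remainder, relapse flags are
#' Bernoulli(`relapse_rate`) with a configurable fraction set to
#' `"unknown"`, follow-up times exponential with a higher rate for relapse
#' cases (so the survival machinery has signal to find), plus simple
#' clinical covariates (Gleason sum, pre-operative PSA, stage, age, margin
#' status).
#'
#' @param n_samples number of samples (>= 1).
#' @param stroma_range interval within \[0, 100\]; must be non-degenerate
#'   input of length 2.
#' @param relapse_rate probability of relapse.
#' @param unknown_rate fraction of samples with unknown relapse status.
#' @param stroma_dist `"cohort"` (bin mixture matched to the published
#'   stratum counts, used when `stroma_range` covers the bins) or
#'   `"uniform"`.
#' @param seed integer seed.
#' @return data.frame with columns `sample_id`, `stroma_pct`, `tumor_pct`,
#'   `relapse` (`"yes"/"no"/"unknown"`), `followup_time`, `gleason`,
#'   `pre_psa`, `stage`, `age`, `margins`.
#' @export
simulate_annotations <- function(n_samples, stroma_range = c(51, 100),
                                 relapse_rate = 20 / 47,
                                 unknown_rate = 2 / 49,
                                 stroma_dist = c("cohort", "uniform"),
                                 seed = 1L) {
  stopifnot(n_samples >= 1)
  stroma_dist <- match.arg(stroma_dist)
  if (length(stroma_range) != 2L || any(!is.finite(stroma_range)))
    .fail("`stroma_range` must be a finite interval of length 2")
  .check_scalar_prob(relapse_rate, "relapse_rate")
  set.seed(seed)
  stroma <- .draw_stroma(n_samples, stroma_range, stroma_dist)
  tumor <- runif(n_samples, 0, 100 - stroma)
  relapse <- ifelse(runif(n_samples) < relapse_rate, "yes", "no")
  n_unk <- round(unknown_rate * n_samples)
  if (n_unk > 0) relapse[sample.int(n_samples, n_unk)] <- "unknown"
  # follow-up: relapse cases tend to recur early; censoring times longer
  followup <- ifelse(relapse == "yes", rexp(n_samples, rate = 0.4),
                     rexp(n_samples, rate = 0.12))
  followup <- pmax(round(followup, 2), 0.01)
  data.frame(sample_id = .sample_ids(n_samples),
             stroma_pct = round(stroma, 1), tumor_pct = round(tumor, 1),
             relapse = relapse, followup_time = followup,
             gleason = sample(5:9, n_samples, replace = TRUE,
                              prob = c(.1, .3, .4, .15, .05)),
             pre_psa = round(exp(rnorm(n_samples, log(8), 0.6)), 1),
             stage = sample(c("T2", "T3"), n_samples, replace = TRUE,
                            prob = c(.6, .4)),
             age = round(rnorm(n_samples, 63, 7)),
             margins = sample(c("negative", "positive"), n_samples,
                              replace = TRUE, prob = c(.7, .3)),
             stringsAsFactors = FALSE)
}

# stroma percentages: bin mixture weighted by the published stratum counts
# (increments 8, 8, 8, 25 over bins 50-60, 60-70, 70-80, 80-100), uniform
# within bins; falls back to uniform when the requested range does not cover
# the bins or when stroma_dist = "uniform"
.draw_stroma <- function(n, range, dist) {
  edges <- c(50, 60, 70, 80, 100)
  covers <- range[1] >= edges[1] && range[1] < edges[2] &&
    range[2] > edges[4]
  if (dist == "uniform" || !covers)
    return(runif(n, range[1], range[2]))
  lo <- pmax(edges[-5], range[1])
  hi <- pmin(edges[-1], range[2])
  w <- c(8, 8, 8, 25)
  bin <- sample.int(4L, n, replace = TRUE, prob = w)
  runif(n, lo[bin], hi[bin])
}

#' Generate a complete synthetic study
#'
#' Runs the three component simulators under sub-seeds derived from the
#' master seed, plants `n_planted` associations (on distinct SNPs, except
#' for an optional hub SNP carrying `hub_size` of them) at standardized
#' effect `effect_size`, and records the ground truth.
#'
#' @param config a [synthetic_config()].
#' @return an object of class `synthetic_study`: a list with elements
#'   `genotypes`, `expression`, `annotations`, `truth` (data.frame
#'   `snp_id`, `transcript_id`, `gamma`) and `config`.
#' @export
make_study <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  geno <- simulate_genotypes(config$n_samples, config$n_snps,
                             config$maf_range,
                             seed = derive_seed(config$seed, "genotypes"))
  tids <- .transcript_ids(config$n_transcripts)
  truth <- .plant_truth(geno, tids, config)
  expr <- simulate_expression(geno, truth, config$n_transcripts,
                              resid_sd = config$resid_sd,
                              seed = derive_seed(config$seed, "expression"),
                              transcript_ids = tids)
  annot <- simulate_annotations(config$n_samples, config$stroma_range,
                                config$relapse_rate, config$unknown_rate,
                                seed = derive_seed(config$seed, "annotations"))
  structure(list(genotypes = geno, expression = expr, annotations = annot,
                 truth = truth, config = config),
            class = "synthetic_study")
}

# choose planted (snp, transcript) pairs and convert the standardized effect
# into raw per-allele gamma using each SNP's realized dosage SD
.plant_truth <- function(geno, transcript_ids, config) {
  np <- config$n_planted
  if (np == 0)
    return(data.frame(snp_id = character(), transcript_id = character(),
                      gamma = numeric()))
  set.seed(derive_seed(config$seed, "truth"))
  snp_ids <- colnames(geno)
  hub <- config$hub_size
  snps <- character(np)
  if (hub > 0) snps[seq_len(hub)] <- snp_ids[1]
  n_rest <- np - hub
  if (n_rest > 0) {
    pool <- if (hub > 0) snp_ids[-1] else snp_ids
    if (n_rest <= length(pool)) {
      snps[hub + seq_len(n_rest)] <- sample(pool, n_rest)
    } else {  # more planted pairs than SNPs: reuse with replacement
      snps[hub + seq_len(n_rest)] <- sample(pool, n_rest, replace = TRUE)
    }
  }
  transcripts <- sample(transcript_ids, np)  # distinct transcripts
  sdz <- apply(geno[, snps, drop = FALSE], 2, sd)
  sdz[sdz == 0] <- 1  # degenerate column: effect is unidentifiable anyway
  data.frame(snp_id = snps, transcript_id = transcripts,
             gamma = config$effect_size * config$resid_sd / as.numeric(sdz),
             stringsAsFactors = FALSE)
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "synthetic_study: %d samples, %d SNPs, %d transcripts, %d planted pairs\n",
    nrow(x$genotypes), ncol(x$genotypes), ncol(x$expression), nrow(x$truth)))
  invisible(x)
}

#' Simulate a two-group survival cohort
#'
#' Exponential event times with a specified high-vs-low hazard ratio and
#' uniform administrative censoring; used to check hazard-ratio recovery of
#' the survival step on cohorts resembling the motivating study's size and
#' event fraction.
#'
#' @param n cohort size.
#' @param hazard_ratio high-vs-low hazard ratio.
#' @param base_rate event rate in the low-risk group (per time unit).
#' @param followup_max maximum follow-up; censoring uniform on
#'   (0, `followup_max`].
#' @param high_fraction fraction of patients in the high-risk group.
#' @param seed integer seed.
#' @return data.frame with `sample_id`, `group` (`"high"/"low"`), `time`,
#'   `event` (0/1).
#' @export
simulate_survival <- function(n = 49, hazard_ratio = 2.2, base_rate = 0.08,
                              followup_max = 10, high_fraction = 0.5,
                              seed = 1L) {
  stopifnot(n >= 2, hazard_ratio > 0, base_rate > 0, followup_max > 0)
  set.seed(seed)
  group <- ifelse(runif(n) < high_fraction, "high", "low")
  rate <- ifelse(group == "high", base_rate * hazard_ratio, base_rate)
  t_event <- rexp(n, rate)
  t_cens <- runif(n, 0, followup_max)
  data.frame(sample_id = .sample_ids(n), group = group,
             time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens),
             stringsAsFactors = FALSE)
}
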