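#' Configuration of the spike-and-slab Stochastic EM fit
#'
#' The association model treats every transcript's expression as a multiple
#' linear regression on all SNP dosages simultaneously, with each effect
#' under a two-component prior: an exact-zero spike (transcript not in the
#' SNP's associated cluster) or a Normal slab with per-SNP variance.  The
#' sampler alternates a stochastic E-step (draw the cluster indicators from
#' their conditional posterior) with a maximization step (least squares on
#' active effects; bounded update of the per-SNP mixing proportion; floored
#' update of the slab variance; ML residual variances).  An association is
#' called when the transcript sits in the SNP's associated cluster in
#' strictly more than `support_threshold` of the post-burn-in iterations.
#'
#' @param n_iterations total SEM sweeps.
#' @param burn_in sweeps discarded before support is accumulated
#'   (`burn_in < n_iterations`).
#' @param support_threshold call threshold on the support fraction, strict
#'   inequality (default 0.80: "more than 80% of iterations").
#' @param init_pi initial per-SNP mixing proportion.
#' @param pi_bounds bounds for the mixing proportion; `NULL` (default) means
#'   `c(1/(2J), 0.5)` at fit time, which prevents the absorbing states pi=0
#'   (sampler death) and pi>0.5 (inverted cluster semantics).
#' @param slab_var_floor lower floor for the per-SNP slab variance.  This is
#'   the smallest effect scale the associated cluster is allowed to
#'   represent (default 0.1 on the standardized expression scale, i.e.
#'   slab SD >= 0.32 residual SDs per allele); it keeps the slab separated
#'   from the spike — if the slab variance could approach zero the two
#'   mixture components become indistinguishable, the inclusion odds turn
#'   uninformative and the mixing proportions drift freely.
#' @param init_slab_var initial per-SNP slab variance (on the standardized
#'   expression scale).
#' @param maf_min minimum minor-allele frequency a SNP must have within the
#'   analyzed sample subset; the default 0 excludes only monomorphic SNPs.
#' @param resid_prior named vector `c(shape=, scale=)` of the weak
#'   inverse-gamma prior stabilizing residual variances (scale 1 centers it
#'   on the standardized-expression scale).  Without it, a handful of
#'   active effects can interpolate a transcript in a small stratum,
#'   collapse its residual variance and saturate the model.
#' @param slab_prior named vector `c(shape=, scale=)` of the weak
#'   inverse-gamma prior on per-SNP slab variances (prior mode
#'   `scale/(shape+1)`); also defines the slab variance an empty associated
#'   cluster relaxes to.
#' @param pi_shrink sparsity anchor for the mixing-proportion update:
#'   `pi_k` is updated as `m_k / (J + pi_shrink * J)` (the posterior mode
#'   under a Beta prior contributing `pi_shrink * J` pseudo-inactive
#'   transcripts).  The raw active fraction is a near-neutral random walk
#'   under null data — the expected Bayes factor of a null pair is exactly
#'   1 — so an unanchored `pi_k` wanders upward and drags borderline pairs
#'   with it; the pseudo-count gives it a restoring force while letting a
#'   SNP with genuinely associated transcripts raise its own `pi_k`.
#' @param seed integer seed; the fit is deterministic given data + config.
#' @param update_pi,update_slab_var,update_resid_var set `FALSE` to pin the
#'   corresponding hyperparameter at its initial value (used when comparing
#'   the sampler against fixed-hyperparameter posterior enumeration).
#' @return an object of class `sem_config`.
#' @export
sem_config <- function(n_iterations = 3000L, burn_in = 1000L,
                       support_threshold = 0.80, init_pi = 0.01,
                       pi_bounds = NULL, slab_var_floor = 0.1,
                       init_slab_var = 0.1, maf_min = 0, seed = 1L,
                       resid_prior = c(shape = 2, scale = 1),
                       slab_prior = c(shape = 2, scale = 0.3),
                       pi_shrink = 0.15,
                       update_pi = TRUE, update_slab_var = TRUE,
                       update_resid_var = TRUE) {
  stopifnot(n_iterations >= 1, burn_in >= 0)
  if (burn_in >= n_iterations)
    .fail("burn_in (%d) must be smaller than n_iterations (%d)",
          burn_in, n_iterations)
  if (support_threshold <= 0 || support_threshold >= 1)
    .fail("support_threshold must lie in (0, 1)")
  .check_scalar_prob(init_pi, "init_pi")
  if (!is.null(pi_bounds)) {
    stopifnot(length(pi_bounds) == 2L)
    if (pi_bounds[1] <= 0 || pi_bounds[2] >= 1 || pi_bounds[1] > pi_bounds[2])
      .fail("pi_bounds must be an increasing interval within (0, 1)")
  }
  stopifnot(slab_var_floor > 0, init_slab_var > 0, maf_min >= 0, maf_min < 0.5,
            length(resid_prior) == 2L, all(resid_prior > 0),
            length(slab_prior) == 2L, all(slab_prior > 0), pi_shrink >= 0)
  structure(list(n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in),
                 support_threshold = support_threshold, init_pi = init_pi,
                 pi_bounds = pi_bounds, slab_var_floor = slab_var_floor,
                 init_slab_var = init_slab_var, maf_min = maf_min,
                 resid_prior = unname(resid_prior),
                 slab_prior = unname(slab_prior), pi_shrink = pi_shrink,
                 seed = as.integer(seed), update_pi = isTRUE(update_pi),
                 update_slab_var = isTRUE(update_slab_var),
                 update_resid_var = isTRUE(update_resid_var)),
            class = "sem_config")
}

#' Standardize an expression matrix per transcript
#'
#' Centers each transcript to mean 0 and scales it to unit sample variance
#' so slab variances are comparable across transcripts.  Zero-variance
#' transcripts cannot carry association signal and are dropped with a
#' warning (their ids are kept in the `"dropped"` attribute).  The transform
#' is idempotent.
#'
#' @param expr samples x transcripts numeric matrix, at least 3 samples.
#' @return standardized matrix (possibly with fewer columns).
#' @export
standardize <- function(expr) {
  stopifnot(is.matrix(expr), is.numeric(expr))
  if (nrow(expr) < 3) .fail("standardize() needs at least 3 samples")
  sds <- apply(expr, 2, sd)
  dropped <- colnames(expr)[sds == 0 | !is.finite(sds)]
  if (length(dropped)) {
    warning(sprintf("dropping %d zero-variance transcript(s): %s",
                    length(dropped),
                    paste(utils::head(dropped, 5), collapse = ", ")))
    expr <- expr[, !(colnames(expr) %in% dropped), drop = FALSE]
  }
  out <- scale(expr)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Prepare a genotype matrix for model entry
#'
#' Restricts the dosage matrix to the requested sample subset, mean-imputes
#' missing dosages per SNP (across the subset's non-missing samples), and
#' excludes SNPs that are monomorphic — or below `maf_min` — within the
#' subset, reporting each exclusion with its reason.
#'
#' @param geno samples x SNPs dosage matrix.
#' @param samples sample ids to keep (must all be rows of `geno`); default
#'   all.
#' @param maf_min minimum within-subset minor-allele frequency (default 0:
#'   exclude only monomorphic SNPs).
#' @return list with `genotypes` (the prepared matrix) and `excluded`
#'   (data.frame `snp_id`, `reason`).
#' @export
prepare_genotypes <- function(geno, samples = rownames(geno), maf_min = 0) {
  stopifnot(is.matrix(geno))
  if (length(samples) == 0) .fail("empty sample subset")
  missing <- setdiff(samples, rownames(geno))
  if (length(missing))
    .fail("sample(s) not in genotype matrix: %s",
          paste(missing, collapse = ", "))
  g <- geno[samples, , drop = FALSE]
  storage.mode(g) <- "double"
  for (k in seq_len(ncol(g))) {
    nas <- is.na(g[, k])
    if (any(nas)) g[nas, k] <- mean(g[!nas, k])
  }
  af <- colMeans(g) / 2
  maf <- pmin(af, 1 - af)
  mono <- apply(g, 2, function(z) isTRUE(all(z == z[1]))) | !is.finite(maf)
  low <- !mono & maf < maf_min
  excluded <- data.frame(
    snp_id = c(colnames(g)[mono], colnames(g)[low]),
    reason = c(rep("monomorphic", sum(mono)),
               rep(sprintf("maf below %g", maf_min), sum(low))),
    stringsAsFactors = FALSE)
  keep <- !(mono | low)
  list(genotypes = g[, keep, drop = FALSE], excluded = excluded)
}

.init_state <- function(J, K, config, resid_var) {
  list(beta = numeric(J),
       gamma = matrix(0, J, K),
       eta = matrix(as.integer(runif(J * K) < config$init_pi), J, K),
       pi = rep(config$init_pi, K),
       slab_var = rep(config$init_slab_var, K),
       resid_var = resid_var)
}

.pi_bounds <- function(config, J) {
  if (is.null(config$pi_bounds)) c(1 / (2 * J), 0.5) else config$pi_bounds
}

.run_sem <- function(Y, Zc, state, config, n_iter, burn_in) {
  b <- .pi_bounds(config, ncol(Y))
  .sem_run_cpp(Y, Zc, state$beta, state$gamma,
               matrix(as.integer(state$eta), nrow(state$eta)),
               state$pi, state$slab_var, state$resid_var,
               as.integer(n_iter), as.integer(burn_in),
               b[1], b[2], config$slab_var_floor,
               config$update_pi, config$update_slab_var,
               config$update_resid_var,
               config$resid_prior[1], config$resid_prior[2],
               config$slab_prior[1], config$slab_prior[2],
               config$pi_shrink * ncol(Y))
}

#' One Stochastic EM sweep
#'
#' Runs a single S-step + M-step over the full indicator matrix and returns
#' the updated model state, including the inclusion probabilities used for
#' the indicator draws (`$incl_prob`, useful for diagnostics).  Uses the
#' current R RNG state; seed with [set.seed()] for reproducibility.
#'
#' @param state model state as produced by a previous sweep, or `NULL` to
#'   initialize from `config`.
#' @param expr standardized samples x transcripts matrix.
#' @param geno prepared samples x SNPs dosage matrix.
#' @param config a [sem_config()].
#' @return updated state: list with `beta`, `gamma`, `eta`, `pi`,
#'   `slab_var`, `resid_var`, `incl_prob`.
#' @export
sem_step <- function(state, expr, geno, config = sem_config()) {
  stopifnot(nrow(expr) == nrow(geno))
  Zc <- scale(geno, center = TRUE, scale = FALSE)
  if (is.null(state))
    state <- .init_state(ncol(expr), ncol(geno), config,
                         apply(expr, 2, function(y) mean((y - mean(y))^2)))
  .check_state_dims(state, ncol(expr), ncol(geno))
  res <- .run_sem(expr, Zc, state, config, n_iter = 1L, burn_in = 0L)
  res <- res[c("beta", "gamma", "eta", "pi", "slab_var", "resid_var",
               "incl_prob")]
  for (nm in c("beta", "pi", "slab_var", "resid_var"))
    res[[nm]] <- drop(res[[nm]])
  res
}

.check_state_dims <- function(state, J, K) {
  if (!identical(dim(state$gamma), c(J, K)) ||
      length(state$resid_var) != J || length(state$pi) != K)
    .fail("model state dimensions do not match the data (J=%d, K=%d)", J, K)
}

#' Fit the joint spike-and-slab model by Stochastic EM
#'
#' Standardizes expression, prepares genotypes (imputation and monomorphic
#' exclusion), initializes indicators `Bernoulli(init_pi)` under the config
#' seed, runs `n_iterations` sweeps, and records per-pair support: the
#' fraction of post-burn-in iterations in which the transcript sat in the
#' SNP's associated cluster.  Deterministic given (data, config, seed).
#'
#' @param expr samples x transcripts matrix (standardized internally; the
#'   transform is idempotent so pre-standardized input is fine).
#' @param geno samples x SNPs dosage matrix (same samples, same order).
#' @param config a [sem_config()].
#' @return object of class `sem_fit`: list with `support` (transcripts x
#'   SNPs matrix of fractions), `config`, `n_post_burnin`, `excluded_snps`,
#'   `state` (final), `n_collinear_drops`, `dropped_transcripts`.
#' @export
fit_sem <- function(expr, geno, config = sem_config()) {
  stopifnot(is.matrix(expr), is.matrix(geno))
  if (nrow(expr) < 3) .fail("fit_sem() needs at least 3 samples")
  if (nrow(expr) != nrow(geno) ||
      !identical(rownames(expr), rownames(geno)))
    .fail("expression and genotype matrices must cover identical samples")
  Y <- suppressWarnings(standardize(expr))
  prep <- prepare_genotypes(geno, rownames(geno), maf_min = config$maf_min)
  Z <- prep$genotypes
  if (ncol(Z) == 0) .fail("no polymorphic SNPs left after preparation")
  Zc <- scale(Z, center = TRUE, scale = FALSE)
  J <- ncol(Y); K <- ncol(Z)
  set.seed(config$seed)
  state <- .init_state(J, K, config, resid_var = rep(1, J))
  res <- .run_sem(Y, Zc, state, config, config$n_iterations, config$burn_in)
  for (nm in c("beta", "pi", "slab_var", "resid_var"))
    res[[nm]] <- drop(res[[nm]])
  support <- res$support
  dimnames(support) <- list(colnames(Y), colnames(Z))
  structure(list(support = support, config = config,
                 n_post_burnin = res$n_post_burnin,
                 excluded_snps = prep$excluded,
                 state = res[c("beta", "gamma", "eta", "pi", "slab_var",
                               "resid_var")],
                 n_collinear_drops = res$n_collinear_drops,
                 dropped_transcripts = attr(Y, "dropped")),
            class = "sem_fit")
}

#' @export
print.sem_fit <- function(x, ...) {
  cat(sprintf("sem_fit: %d transcripts x %d SNPs, %d post-burn-in sweeps\n",
              nrow(x$support), ncol(x$support), x$n_post_burnin))
  n_call <- sum(x$support > x$config$support_threshold)
  cat(sprintf("pairs above support threshold %.2f: %d\n",
              x$config$support_threshold, n_call))
  invisible(x)
}

#' Call associations from a fitted model
#'
#' Emits exactly the SNP-transcript pairs whose support strictly exceeds the
#' configured threshold, sorted by SNP id and then by descending support.
#'
#' @param fit a [fit_sem()] result.
#' @param stratum_label label attached to each call (e.g. `">50%"`).
#' @return data.frame with columns `snp_id`, `transcript_id`, `support`,
#'   `stratum`.
#' @export
call_associations <- function(fit, stratum_label = NA_character_) {
  stopifnot(inherits(fit, "sem_fit"))
  idx <- which(fit$support > fit$config$support_threshold, arr.ind = TRUE)
  calls <- data.frame(
    snp_id = colnames(fit$support)[idx[, 2]],
    transcript_id = rownames(fit$support)[idx[, 1]],
    support = fit$support[idx],
    stratum = rep(stratum_label, nrow(idx)),
    stringsAsFactors = FALSE)
  calls[order(calls$snp_id, -calls$support, calls$transcript_id), ,
        drop = FALSE]
}
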