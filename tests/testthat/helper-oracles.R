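# Independent oracles used across the test files.  These deliberately take
# different computational routes than the package (dense multivariate-normal
# marginal likelihoods, explicit risk-set enumeration, per-pair OLS scans)
# so that agreement is evidence, not tautology.

# Exhaustive posterior inclusion probabilities for a single-SNP (K = 1)
# spike-and-slab model with fixed hyperparameters: every indicator
# configuration is scored by its exact marginal likelihood
# N(y; 0, s2*I + v*eta*zz'), effects integrated out.
enum_pip_single_snp <- function(Y, z, pi0, v, s2) {
  n <- nrow(Y)
  zc <- z - mean(z)
  logml <- function(y, active) {
    S <- diag(s2, n)
    if (active) S <- S + v * tcrossprod(zc)
    -0.5 * (n * log(2 * pi) + as.numeric(determinant(S)$modulus) +
              drop(crossprod(y, solve(S, y))))
  }
  vapply(seq_len(ncol(Y)), function(j) {
    y <- Y[, j] - mean(Y[, j])
    lodds <- log(pi0 / (1 - pi0)) + logml(y, TRUE) - logml(y, FALSE)
    1 / (1 + exp(-lodds))
  }, numeric(1))
}

# Exact per-transcript posterior over all 2^K indicator configurations
# (fixed hyperparameters, effects integrated out); used both directly and
# as the transition kernel of the Gibbs oracle.
enum_posterior_multi <- function(y, Zc, pi0, v, s2) {
  K <- ncol(Zc)
  n <- length(y)
  configs <- as.matrix(expand.grid(rep(list(0:1), K)))
  logw <- apply(configs, 1, function(eta) {
    S <- diag(s2, n)
    act <- which(eta == 1)
    if (length(act))
      S <- S + Zc[, act, drop = FALSE] %*% (v * t(Zc[, act, drop = FALSE]))
    lp <- sum(eta) * log(pi0) + sum(1 - eta) * log(1 - pi0)
    lp - 0.5 * (as.numeric(determinant(S)$modulus) +
                  drop(crossprod(y, solve(S, y))))
  })
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  colSums(configs * w)  # marginal inclusion probability per SNP
}

# Marginal per-pair OLS t-statistics for all transcript x SNP pairs.
ols_t_matrix <- function(expr, geno) {
  n <- nrow(expr)
  Y <- scale(expr)
  Z <- scale(geno)
  r <- crossprod(Y, Z) / (n - 1)  # correlations, transcripts x SNPs
  r * sqrt((n - 2) / pmax(1 - r^2, 1e-12))
}

# Hand-enumerated two-group logrank statistic: walk the risk sets at every
# distinct event time, accumulate observed-minus-expected for group 2 and
# the hypergeometric variance.
logrank_by_hand <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2)
  g2 <- group == sort(unique(group))[2]
  o_minus_e <- 0
  v <- 0
  for (tt in sort(unique(time[event == 1]))) {
    at_risk <- time >= tt
    n_tot <- sum(at_risk)
    n2 <- sum(at_risk & g2)
    d <- sum(time == tt & event == 1)
    d2 <- sum(time == tt & event == 1 & g2)
    o_minus_e <- o_minus_e + (d2 - d * n2 / n_tot)
    if (n_tot > 1)
      v <- v + d * (n2 / n_tot) * (1 - n2 / n_tot) * (n_tot - d) / (n_tot - 1)
  }
  (o_minus_e)^2 / v
}

# Small planted study used by several files.
tiny_study <- function(seed = 1, n = 49, k = 12, j = 80, planted = 3,
                       hub = 0, effect = 1) {
  make_study(synthetic_config(
    n_samples = n, n_snps = k, n_transcripts = j, n_planted = planted,
    hub_size = hub, effect_size = effect, seed = seed))
}

truth_keys <- function(study) paste(study$truth$snp_id, study$truth$transcript_id)
call_keys <- function(calls) paste(calls$snp_id, calls$transcript_id)
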