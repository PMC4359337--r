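test_that("standardization centers, scales, drops degenerate columns, and is idempotent", {
  m <- cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = rnorm(3))
  expect_warning(s <- standardize(m), "zero-variance")
  expect_identical(attr(s, "dropped"), "b")
  expect_equal(unname(colMeans(s)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(s, 2, sd)), c(1, 1), tolerance = 1e-12)
  expect_equal(standardize(s), s, ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(standardize(m[1:2, ]), "3 samples")
})

test_that("genotype preparation imputes and excludes per subset", {
  g <- cbind(rs_a = c(0, 2, NA, 1), rs_b = c(0, 0, 0, 2),
             rs_c = c(1, 1, 2, 0))
  rownames(g) <- paste0("S", 1:4)
  p <- prepare_genotypes(g, paste0("S", 1:4))
  expect_equal(p$genotypes["S3", "rs_a"], 1)  # mean of 0, 2, 1
  expect_equal(nrow(p$excluded), 0L)

  # rs_b monomorphic within the first three samples
  p3 <- prepare_genotypes(g, paste0("S", 1:3))
  expect_identical(p3$excluded$snp_id, "rs_b")
  expect_identical(p3$excluded$reason, "monomorphic")
  expect_false("rs_b" %in% colnames(p3$genotypes))

  # clean polymorphic input passes through numerically unchanged
  clean <- cbind(rs_a = c(0, 1, 2), rs_c = c(2, 0, 1))
  rownames(clean) <- paste0("S", 1:3)
  expect_equal(prepare_genotypes(clean)$genotypes, clean,
               ignore_attr = TRUE)
  expect_error(prepare_genotypes(g, character()), "empty")
})

test_that("a single sweep draws indicators at their conditional posterior", {
  # noise-free y = z: the inclusion probability must be essentially 1
  set.seed(1)
  z <- rbinom(30, 2, 0.4)
  Y <- scale(matrix(z + rnorm(30, sd = 1e-6), ncol = 1))
  rownames(Y) <- sprintf("P%03d", 1:30)
  colnames(Y) <- "t1"
  Z <- matrix(z, ncol = 1, dimnames = list(rownames(Y), "rs1"))
  cfg <- sem_config(init_pi = 0.01, init_slab_var = 0.5, seed = 1)
  set.seed(2)
  stt <- sem_step(NULL, Y, Z, cfg)
  expect_gt(stt$incl_prob[1, 1], 0.999)
  expect_equal(stt$eta[1, 1], 1L)

  # pure noise: a sweep from a fresh state includes roughly pi of the pairs
  set.seed(3)
  Yn <- scale(matrix(rnorm(40 * 300), 40, 300))
  rownames(Yn) <- sprintf("P%03d", 1:40)
  colnames(Yn) <- paste0("t", 1:300)
  Zn <- simulate_genotypes(40, 10, seed = 4)
  cfgn <- sem_config(init_pi = 0.05, update_pi = FALSE,
                     update_slab_var = FALSE, update_resid_var = FALSE,
                     seed = 5)
  set.seed(6)
  s0 <- sem_step(NULL, Yn, Zn, cfgn)
  s0$eta[] <- 0L; s0$gamma[] <- 0
  incl <- replicate(20, {
    s1 <- sem_step(s0, Yn, Zn, cfgn)
    mean(s1$eta)
  })
  expect_gt(mean(incl), 0.05 * 0.4)
  expect_lt(mean(incl), 0.05 * 2.0)

  # M-step on an all-zero indicator state: intercept-only residuals
  expect_equal(unname(s0$beta), rep(0, 300), tolerance = 1e-9)
})

test_that("spike exactness: gamma is zero exactly where eta is zero", {
  st <- tiny_study(seed = 2, n = 30, k = 6, j = 50, planted = 2)
  Y <- suppressWarnings(standardize(st$expression))
  cfg <- sem_config(seed = 3)
  set.seed(4)
  s <- sem_step(NULL, Y, st$genotypes, cfg)
  for (i in 1:5) s <- sem_step(s, Y, st$genotypes, cfg)
  expect_true(all((s$gamma == 0) == (s$eta == 0)))
})

test_that("fit_sem recovers planted effects and is seed-deterministic", {
  st <- make_study(synthetic_config(49, 35, 200, n_planted = 5,
                                    effect_size = 1, seed = 7))
  cfg <- sem_config(n_iterations = 800, burn_in = 300, seed = 8)
  fit <- fit_sem(st$expression, st$genotypes, cfg)
  idx <- cbind(match(st$truth$transcript_id, rownames(fit$support)),
               match(st$truth$snp_id, colnames(fit$support)))
  expect_true(all(fit$support[idx] > 0.8))
  # cross-check against the marginal OLS oracle: every planted pair is also
  # the kind of pair a per-pair scan would flag
  tmat <- abs(ols_t_matrix(st$expression, st$genotypes))
  expect_true(all(tmat[idx] > 4))

  fit2 <- fit_sem(st$expression, st$genotypes, cfg)
  expect_identical(fit$support, fit2$support)

  expect_error(fit_sem(st$expression[1:10, ], st$genotypes, cfg),
               "identical samples")
})

test_that("pure-noise fits call at most a handful of pairs per stratum", {
  # a single-stratum analysis is allowed occasional extreme-noise calls
  # (that is what the four-way consensus exists to remove); what must hold
  # is that calls are rare relative to the 2000 pairs scanned
  calls <- vapply(1:5, function(s) {
    stn <- make_study(synthetic_config(49, 10, 200, n_planted = 0, seed = s))
    fit <- fit_sem(stn$expression, stn$genotypes,
                   sem_config(n_iterations = 500, burn_in = 200,
                              seed = s + 50))
    nrow(call_associations(fit))
  }, integer(1))
  expect_gte(mean(calls == 0), 0.5)
  expect_lte(max(calls), 5L)
  expect_lte(mean(calls), 1.5)
})

test_that("association calling applies a strict support threshold and ordering", {
  fit <- structure(list(
    support = matrix(c(0.81, 0.80, 0.9, 1.0), 2, 2,
                     dimnames = list(c("tA", "tB"), c("rs2", "rs1"))),
    config = sem_config(seed = 1)), class = "sem_fit")
  calls <- call_associations(fit, ">50%")
  expect_false(any(calls$support <= 0.8))          # 0.80 itself not called
  expect_true(all(c("tA", "tB") %in%
                    calls$transcript_id[calls$snp_id == "rs1"]))
  expect_identical(calls$snp_id, sort(calls$snp_id))  # grouped by SNP
  expect_equal(nrow(calls), 3L)

  fit$support[] <- 0
  expect_equal(nrow(call_associations(fit)), 0L)
  fit$support[] <- 1
  expect_equal(nrow(call_associations(fit)), 4L)
})

test_that("support agrees with exhaustive enumeration on small instances", {
  # K = 1, J = 3, n = 12; hyperparameters pinned so both routes address the
  # same fixed spike-and-slab model
  set.seed(99)
  n <- 12
  z <- rbinom(n, 2, 0.4)
  Y <- matrix(rnorm(n * 3), n, 3)
  Y[, 2] <- Y[, 2] + z * 0.9
  Y <- scale(Y)
  rownames(Y) <- sprintf("P%03d", 1:n)
  colnames(Y) <- paste0("t", 1:3)
  Z <- matrix(z, ncol = 1, dimnames = list(rownames(Y), "rs1"))
  cfg <- sem_config(n_iterations = 6000, burn_in = 500, init_pi = 0.2,
                    pi_bounds = c(0.199, 0.201), init_slab_var = 0.5,
                    update_pi = FALSE, update_slab_var = FALSE,
                    update_resid_var = FALSE, seed = 7)
  fit <- fit_sem(Y, Z, cfg)
  pip <- enum_pip_single_snp(Y, z, pi0 = 0.2, v = 0.5, s2 = 1)
  expect_lt(max(abs(fit$support[, 1] - pip)), 0.05)
})

test_that("SEM and a collapsed Gibbs oracle call the same associations", {
  # 3 transcripts, 2 SNPs, fixed hyperparameters; the Gibbs oracle samples
  # each transcript's indicator configuration exactly from its enumerated
  # conditional, so its long-run calls are the model's posterior calls
  set.seed(12)
  n <- 14
  Z <- cbind(rs1 = rbinom(n, 2, 0.3), rs2 = rbinom(n, 2, 0.45))
  rownames(Z) <- sprintf("P%03d", 1:n)
  Y <- matrix(rnorm(n * 3, sd = 0.6), n, 3)
  Y[, 1] <- Y[, 1] + 1.4 * Z[, "rs1"]
  Y[, 3] <- Y[, 3] + 1.2 * Z[, "rs2"]
  Y <- scale(Y)
  colnames(Y) <- paste0("t", 1:3)
  rownames(Y) <- rownames(Z)
  pi0 <- 0.15; v <- 0.5; s2 <- 1
  cfg <- sem_config(n_iterations = 4000, burn_in = 500, init_pi = pi0,
                    pi_bounds = c(pi0 - 0.001, pi0 + 0.001),
                    init_slab_var = v, update_pi = FALSE,
                    update_slab_var = FALSE, update_resid_var = FALSE,
                    seed = 3)
  fit <- fit_sem(Y, Z, cfg)
  Zc <- scale(Z, scale = FALSE)
  pip <- t(vapply(1:3, function(j)
    enum_posterior_multi(Y[, j] - mean(Y[, j]), Zc, pi0, v, s2),
    numeric(2)))
  sem_called <- fit$support > 0.8
  gibbs_called <- pip > 0.8
  expect_identical(unname(sem_called), unname(gibbs_called))
  expect_lt(max(abs(fit$support - pip)), 0.1)
})

test_that("mean planted support is monotone in effect size", {
  mean_support <- vapply(c(0.4, 0.8, 1.2), function(es) {
    supports <- vapply(1:2, function(s) {
      st <- make_study(synthetic_config(49, 8, 80, n_planted = 3,
                                        effect_size = es, seed = s))
      fit <- fit_sem(st$expression, st$genotypes,
                     sem_config(n_iterations = 600, burn_in = 200,
                                seed = 100 + s))
      idx <- cbind(match(st$truth$transcript_id, rownames(fit$support)),
                   match(st$truth$snp_id, colnames(fit$support)))
      mean(fit$support[idx])
    }, numeric(1))
    mean(supports)
  }, numeric(1))
  expect_true(all(diff(mean_support) > -0.02))
})
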