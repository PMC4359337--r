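# small deterministic cohort shared by the risk-group tests
.mk_clinical <- function(n = 49, seed = 30) {
  st <- make_study(synthetic_config(n, 6, 40, n_planted = 1,
                                    effect_size = 1.3, seed = seed))
  st
}

test_that("risk groups follow the declared genotype x expression rule", {
  st <- .mk_clinical()
  assoc <- c(st$truth$snp_id[1], st$truth$transcript_id[1])
  rg <- assign_risk_groups(assoc, st$genotypes, st$expression)
  expect_s3_class(rg, "risk_groups")
  expect_gt(rg$direction, 0)  # planted effect is positive

  z <- st$genotypes[names(rg$groups), assoc[1]]
  y <- st$expression[names(rg$groups), assoc[2]]
  med <- quantile(y, 0.5, names = FALSE)
  expect_true(all(z[rg$groups == "high"] >= 1))
  expect_true(all(y[rg$groups == "high"] > med))
  expect_true(all(z[rg$groups == "low"] == 0))
  expect_true(all(y[rg$groups == "low"] < med))
  expect_true(all(levels(rg$groups) == c("low", "intermediate", "high")))
  expect_true(all(table(rg$groups) > 0))  # all three groups non-empty

  # missing genotype: patient omitted with a notice, not an error
  g2 <- st$genotypes
  g2[1, assoc[1]] <- NA
  expect_message(rg2 <- assign_risk_groups(assoc, g2, st$expression),
                 "omitting")
  expect_false(rownames(g2)[1] %in% names(rg2$groups))
  expect_error(assign_risk_groups(c("rs_none", assoc[2]), st$genotypes,
                                  st$expression), "rs_none")
})

test_that("ordinal regression reduces to logistic for binary outcomes and is calibrated", {
  st <- .mk_clinical()
  assoc <- c(st$truth$snp_id[1], st$truth$transcript_id[1])
  rg <- assign_risk_groups(assoc, st$genotypes, st$expression)

  # binary outcome: coefficient equals the plain logistic fit
  set.seed(1)
  out <- setNames(sample(c("no", "yes"), length(rg$groups), replace = TRUE),
                  names(rg$groups))
  r <- ordinal_logistic(rg, factor(out, levels = c("no", "yes")))
  ref <- glm(factor(out) ~ I(as.integer(rg$groups) - 1L),
             family = binomial())
  expect_equal(r$coefficient, unname(coef(ref)[2]), tolerance = 1e-6)
  expect_true(r$p_univariate >= 0 && r$p_univariate <= 1)
  expect_true(is.na(r$p_multivariate))

  # null calibration: univariate p roughly uniform over seeds
  ps <- vapply(1:120, function(s) {
    set.seed(s)
    o <- setNames(sample(c("no", "yes"), length(rg$groups), replace = TRUE),
                  names(rg$groups))
    ordinal_logistic(rg, factor(o, levels = c("no", "yes")))$p_univariate
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
  expect_lt(mean(ps < 0.05), 0.15)

  # strong planted ordinal trend is detected
  set.seed(2)
  score <- as.integer(rg$groups) - 1L
  trend <- setNames(
    factor(ifelse(runif(length(score)) < plogis(-1.5 + 1.8 * score),
                  "yes", "no"), levels = c("no", "yes")), names(rg$groups))
  rt <- ordinal_logistic(rg, trend)
  expect_gt(rt$coefficient, 0)

  # three-level ordinal outcome goes through the proportional-odds path
  set.seed(3)
  o3 <- setNames(factor(sample(c("low", "mid", "high"), length(score),
                               replace = TRUE),
                        levels = c("low", "mid", "high"), ordered = TRUE),
                 names(rg$groups))
  r3 <- ordinal_logistic(rg, o3)
  expect_true(is.finite(r3$coefficient))

  # multivariate model reports a covariate-adjusted p-value
  cov <- st$annotations[, c("sample_id", "age", "gleason")]
  rm <- ordinal_logistic(rg, trend, cov)
  expect_false(is.na(rm$p_multivariate))
  expect_identical(rm$covariates, c("age", "gleason"))
})

test_that("logrank matches a hand-enumerated risk-set oracle", {
  # 6 patients, times 1..6, alternating groups, no censoring
  time <- 1:6
  event <- rep(1L, 6)
  grp <- rep(c("low", "high"), 3)
  names(time) <- names(event) <- names(grp) <- paste0("P", 1:6)
  res <- km_logrank(grp, time, event)
  byhand <- logrank_by_hand(time, event, grp)
  expect_equal(res$logrank_stat, byhand, tolerance = 1e-9)
  expect_equal(res$p_value, pchisq(byhand, 1, lower.tail = FALSE))
})

test_that("logrank symmetry: identical groups give statistic 0 and HR 1", {
  time <- c(1, 2, 3, 1, 2, 3)
  event <- c(1, 1, 0, 1, 1, 0)
  grp <- rep(c("low", "high"), each = 3)
  names(time) <- names(event) <- names(grp) <- paste0("P", 1:6)
  res <- km_logrank(grp, time, event)
  expect_equal(res$logrank_stat, 0, tolerance = 1e-12)
  expect_equal(res$hazard_ratio, 1, tolerance = 1e-12)

  # label swap: statistic invariant, HR inverts
  d <- simulate_survival(40, hazard_ratio = 2.5, seed = 4)
  g <- setNames(d$group, d$sample_id)
  tm <- setNames(d$time, d$sample_id)
  ev <- setNames(d$event, d$sample_id)
  r1 <- km_logrank(g, tm, ev)
  gswap <- setNames(ifelse(d$group == "high", "low", "high"), d$sample_id)
  r2 <- km_logrank(gswap, tm, ev)
  expect_equal(r1$logrank_stat, r2$logrank_stat, tolerance = 1e-9)
  expect_equal(r1$hazard_ratio, 1 / r2$hazard_ratio, tolerance = 1e-9)

  # KM estimator equals the empirical survival function without censoring
  allev <- setNames(rep(1L, 40), d$sample_id)
  r3 <- km_logrank(g, tm, allev)
  km <- summary(r3$km)
  grp_of_strata <- sub("g=", "", km$strata)
  for (lab in c("low", "high")) {
    sel <- grp_of_strata == lab
    tt <- km$time[sel]
    emp <- vapply(tt, function(x) mean(tm[g == lab] > x), numeric(1))
    expect_equal(km$surv[sel], emp, tolerance = 1e-9)
  }

  # a group without events is an error, signalled by name
  ev0 <- ev
  ev0[d$group == "low"] <- 0L
  expect_error(km_logrank(g, tm, ev0), "low")
})

test_that("the two-step screen returns one row per consensus association", {
  st <- .mk_clinical()
  cs <- list(calls = data.frame(snp_id = st$truth$snp_id[1],
                                transcript_id = st$truth$transcript_id[1]))
  class(cs) <- "consensus_set"
  scr <- clinical_screen(cs, st$genotypes, st$expression, st$annotations,
                         covariates = c("age", "gleason"))
  expect_equal(nrow(scr), 1L)
  expect_equal(attr(scr, "n_tested"), 1L)
  expect_true(all(c("p_univariate", "p_multivariate") %in% names(scr)))
})
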