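#' Risk-group rule parameters
#'
#' The partition of patients into high / intermediate / low risk groups per
#' association is a declared, configurable rule (the original study's exact
#' definition was published only in supplementary material that is not part
#' of this package's sources): *high* = carries at least `allele_threshold`
#' risk alleles AND expression on the risk-direction side of the cohort
#' quantile; *low* = zero risk alleles AND expression on the opposite side;
#' *intermediate* = everyone else.
#'
#' @param allele_threshold minimum risk-allele count for the high group.
#' @param expression_quantile cohort quantile splitting expression (default
#'   median).
#' @return list of class `risk_rule`.
#' @export
risk_rule <- function(allele_threshold = 1L, expression_quantile = 0.5) {
  stopifnot(allele_threshold >= 1, expression_quantile > 0,
            expression_quantile < 1)
  structure(list(allele_threshold = as.integer(allele_threshold),
                 expression_quantile = expression_quantile),
            class = "risk_rule")
}

#' Assign patients to risk groups for one association
#'
#' The risk direction is the sign of the fitted SNP effect on the
#' transcript (estimated by ordinary least squares of expression on dosage
#' unless supplied).  Patients with a missing dosage are omitted with a
#' message.
#'
#' @param association length-2 character vector or list: `(snp_id,
#'   transcript_id)`.
#' @param genotypes samples x SNPs dosage matrix.
#' @param expression samples x transcripts matrix (same samples).
#' @param rule a [risk_rule()].
#' @param direction optional +1/-1 risk direction; `NULL` estimates it.
#' @return object of class `risk_groups`: list with `groups` (named ordered
#'   factor low < intermediate < high), `rule_parameters`, `direction`,
#'   `association`, `omitted`.
#' @export
assign_risk_groups <- function(association, genotypes, expression,
                               rule = risk_rule(), direction = NULL) {
  snp <- as.character(association[[1]])
  transcript <- as.character(association[[2]])
  if (!snp %in% colnames(genotypes))
    .fail("SNP %s not present in the genotype matrix", snp)
  if (!transcript %in% colnames(expression))
    .fail("transcript %s not present in the expression matrix", transcript)
  samples <- intersect(rownames(genotypes), rownames(expression))
  z <- genotypes[samples, snp]
  y <- expression[samples, transcript]
  omitted <- samples[is.na(z)]
  if (length(omitted))
    message(sprintf("omitting %d sample(s) with missing dosage for %s",
                    length(omitted), snp))
  keep <- !is.na(z)
  z <- z[keep]; y <- y[keep]; samples <- samples[keep]
  if (is.null(direction)) {
    direction <- sign(coef(lm(y ~ z))[["z"]])
    if (is.na(direction) || direction == 0) direction <- 1
  }
  cut <- quantile(y, rule$expression_quantile, names = FALSE)
  risk_side <- if (direction > 0) y > cut else y < cut
  opp_side <- if (direction > 0) y < cut else y > cut
  grp <- rep("intermediate", length(samples))
  grp[z >= rule$allele_threshold & risk_side] <- "high"
  grp[z == 0 & opp_side] <- "low"
  groups <- factor(grp, levels = c("low", "intermediate", "high"),
                   ordered = TRUE)
  names(groups) <- samples
  structure(list(groups = groups, rule_parameters = rule,
                 direction = direction,
                 association = c(snp_id = snp, transcript_id = transcript),
                 omitted = omitted),
            class = "risk_groups")
}

#' Ordinal logistic regression of a clinical outcome on risk groups
#'
#' Fits a proportional-odds model of the outcome on the risk-group trend
#' (groups scored low = 0, intermediate = 1, high = 2), univariately and —
#' when covariates are supplied — multivariately.  Binary outcomes are fit
#' by ordinary logistic regression, the two-level special case of the
#' proportional-odds model.  Complete separation is flagged, and the
#' flagged p-values come from a likelihood-ratio test, which stays
#' informative where Wald statistics degenerate.
#'
#' @param groups a [assign_risk_groups()] result, or a named (ordered)
#'   factor.
#' @param clinical_outcome named vector (factor, character or numeric) with
#'   at least two levels; names are sample ids.
#' @param covariates optional data.frame of clinical covariates with
#'   `sample_id` column (e.g. Gleason sum, pre-PSA, stage, age, margins).
#' @return object of class `ordinal_regression`: list with `coefficient`
#'   (univariate group trend), `p_univariate`, `p_multivariate` (`NA` when
#'   no covariates), `covariates`, `n`, `separation`.
#' @export
ordinal_logistic <- function(groups, clinical_outcome, covariates = NULL) {
  if (inherits(groups, "risk_groups")) groups <- groups$groups
  common <- intersect(names(groups), names(clinical_outcome))
  df <- data.frame(score = as.integer(groups[common]) - 1L,
                   outcome = clinical_outcome[common],
                   stringsAsFactors = FALSE)
  covar_names <- character()
  if (!is.null(covariates)) {
    stopifnot("sample_id" %in% names(covariates))
    m <- match(common, covariates$sample_id)
    covar_names <- setdiff(names(covariates), "sample_id")
    df <- cbind(df, covariates[m, covar_names, drop = FALSE])
  }
  df <- df[complete.cases(df), , drop = FALSE]
  if (length(unique(df$score)) < 2)
    .fail("fewer than 2 non-empty risk groups among complete cases")
  if (!is.numeric(df$outcome)) df$outcome <- factor(df$outcome)
  n_levels <- if (is.factor(df$outcome)) nlevels(droplevels(df$outcome))
              else length(unique(df$outcome))
  if (n_levels < 2) .fail("clinical outcome is constant")

  fit_one <- function(formula) {
    if (is.factor(df$outcome) && n_levels == 2) {
      fit <- glm(formula, data = df, family = stats::binomial())
      co <- summary(fit)$coefficients
      sep <- !fit$converged || any(abs(co[-1, "Estimate"]) > 10)
      p <- co["score", "Pr(>|z|)"]
      if (sep) {  # LRT fallback under (near-)separation
        red <- stats::update(fit, . ~ . - score)
        p <- stats::anova(red, fit, test = "Chisq")[2, "Pr(>Chi)"]
      }
      list(coef = co["score", "Estimate"], p = p, sep = sep)
    } else {
      if (!is.factor(df$outcome))
        df$outcome <- factor(df$outcome, ordered = TRUE)
      else df$outcome <- factor(as.character(df$outcome),
                                levels = levels(df$outcome), ordered = TRUE)
      fit <- MASS::polr(formula, data = df, Hess = TRUE)
      co <- summary(fit)$coefficients
      sep <- any(abs(co[, "Value"]) > 10)
      tval <- co["score", "t value"]
      p <- 2 * pnorm(-abs(tval))
      if (sep) {
        red <- MASS::polr(stats::update(formula, . ~ . - score), data = df)
        p <- pchisq(red$deviance - fit$deviance, df = 1, lower.tail = FALSE)
      }
      list(coef = co["score", "Value"], p = p, sep = sep)
    }
  }

  uni <- fit_one(outcome ~ score)
  multi <- NULL
  if (length(covar_names)) {
    f <- stats::as.formula(paste("outcome ~ score +",
                                 paste(covar_names, collapse = " + ")))
    multi <- fit_one(f)
  }
  structure(list(coefficient = uni$coef, p_univariate = uni$p,
                 p_multivariate = if (is.null(multi)) NA_real_ else multi$p,
                 covariates = covar_names, n = nrow(df),
                 separation = uni$sep || (!is.null(multi) && multi$sep)),
            class = "ordinal_regression")
}

#' @export
print.ordinal_regression <- function(x, ...) {
  cat(sprintf("ordinal regression on risk-group trend (n = %d)\n", x$n))
  cat(sprintf("  coefficient %.3f, univariate p = %.4g\n",
              x$coefficient, x$p_univariate))
  if (!is.na(x$p_multivariate))
    cat(sprintf("  multivariate p = %.4g (covariates: %s)\n",
                x$p_multivariate, paste(x$covariates, collapse = ", ")))
  if (x$separation) cat("  note: (near-)separation; LRT p-values reported\n")
  invisible(x)
}

#' Kaplan-Meier / logrank comparison of high vs low risk groups
#'
#' Compares survival of the high- and low-risk groups only (the
#' intermediate group is excluded).  The logrank statistic is the standard
#' observed-minus-expected chi-square over risk sets (1 df) and the hazard
#' ratio is estimated as `(O_high/E_high) / (O_low/E_low)`.
#'
#' @param groups a [assign_risk_groups()] result, or a named factor/
#'   character vector with levels including `"high"` and `"low"`.
#' @param followup_time named non-negative times.
#' @param event_flag named 0/1 (or logical) event indicators; censored = 0.
#' @return object of class `survival_result`: list with `hazard_ratio`,
#'   `logrank_stat`, `p_value`, `group_sizes`, `events_per_group`, `km`
#'   (the `survfit` object for the two groups).
#' @export
km_logrank <- function(groups, followup_time, event_flag) {
  if (inherits(groups, "risk_groups")) groups <- groups$groups
  common <- Reduce(intersect, list(names(groups), names(followup_time),
                                   names(event_flag)))
  g <- as.character(groups[common])
  keep <- g %in% c("high", "low")
  g <- factor(g[keep], levels = c("low", "high"))
  t <- as.numeric(followup_time[common][keep])
  e <- as.integer(event_flag[common][keep])
  if (any(is.na(t)) || any(t < 0)) .fail("follow-up times must be nonnegative")
  events <- tapply(e, g, sum)
  if (any(is.na(events)) || any(events == 0))
    .fail("each of the high and low groups needs at least one event; got %s",
          paste(names(events), events, sep = "=", collapse = ", "))
  sd <- survival::survdiff(survival::Surv(t, e) ~ g)
  stat <- sd$chisq
  hr <- (sd$obs[2] / sd$exp[2]) / (sd$obs[1] / sd$exp[1])
  structure(list(hazard_ratio = unname(hr), logrank_stat = unname(stat),
                 p_value = pchisq(stat, df = 1, lower.tail = FALSE),
                 group_sizes = table(g), events_per_group = events,
                 km = survival::survfit(survival::Surv(t, e) ~ g)),
            class = "survival_result")
}

#' @export
print.survival_result <- function(x, ...) {
  cat(sprintf(
    "logrank chi-square %.3f (1 df), p = %.4g; hazard ratio (high vs low) %.2f\n",
    x$logrank_stat, x$p_value, x$hazard_ratio))
  cat(sprintf("groups: low n=%d (%d events), high n=%d (%d events)\n",
              x$group_sizes["low"], x$events_per_group["low"],
              x$group_sizes["high"], x$events_per_group["high"]))
  invisible(x)
}

#' Two-step clinical screen over a consensus set
#'
#' For every consensus association: assign risk groups, then test the
#' group-outcome association by ordinal logistic regression (univariate,
#' and multivariate when covariates are given).  No multiple-testing
#' correction is applied across associations — this is a screening step and
#' the number of associations tested is always reported alongside.
#'
#' @param consensus a `consensus_set`.
#' @param genotypes,expression data matrices.
#' @param annotations data.frame with `sample_id`, `relapse` and any
#'   covariate columns.
#' @param covariates character vector of covariate column names in
#'   `annotations` for the multivariate model (default none).
#' @param rule a [risk_rule()].
#' @return data.frame, one row per association, with the group-trend
#'   coefficient and p-values; attribute `"n_tested"` records the number of
#'   screens run.
#' @export
clinical_screen <- function(consensus, genotypes, expression, annotations,
                            covariates = character(), rule = risk_rule()) {
  calls <- if (inherits(consensus, "consensus_set")) consensus$calls
           else consensus
  outcome <- stats::setNames(annotations$relapse, annotations$sample_id)
  outcome <- outcome[outcome %in% c("yes", "no")]
  outcome <- factor(outcome, levels = c("no", "yes"))
  covar <- if (length(covariates))
    annotations[, c("sample_id", covariates), drop = FALSE] else NULL
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    rg <- assign_risk_groups(c(calls$snp_id[i], calls$transcript_id[i]),
                             genotypes, expression, rule = rule)
    fit <- tryCatch(ordinal_logistic(rg, outcome, covar),
                    error = function(e) NULL)
    data.frame(snp_id = calls$snp_id[i],
               transcript_id = calls$transcript_id[i],
               coefficient = if (is.null(fit)) NA_real_ else fit$coefficient,
               p_univariate = if (is.null(fit)) NA_real_ else fit$p_univariate,
               p_multivariate = if (is.null(fit)) NA_real_
                                else fit$p_multivariate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(snp_id = character(), transcript_id = character(),
                      coefficient = numeric(), p_univariate = numeric(),
                      p_multivariate = numeric())
  attr(out, "n_tested") <- nrow(out)
  out
}
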