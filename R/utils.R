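#' @useDynLib stromaQTL, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rbinom rnorm runif rexp var sd quantile lm coef pchisq
#'   pnorm complete.cases median
#' @importFrom utils read.delim write.table
NULL

#' Derive a reproducible sub-seed from a master seed and a tag
#'
#' Strata, permutation replicates and panel redraws each need an independent
#' but reproducible RNG stream.  A multiplicative string hash of
#' `"<seed>:<tag>"` gives a deterministic 31-bit sub-seed; it is not
#' cryptographic and does not need to be.
#'
#' @param seed master integer seed.
#' @param tag character tag naming the stream (e.g. a stratum label or
#'   `"perm-17"`).
#' @return an integer in `[1, 2^31 - 20)` usable with [set.seed()].
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(tag) == 1L)
  m <- 2147483629  # largest prime < 2^31
  h <- as.numeric(seed) %% m
  for (b in utf8ToInt(paste0(":", tag))) h <- (h * 31 + b) %% m
  as.integer(max(1, h))
}

# internal: stop() with a consistent prefix
.fail <- function(...) stop(sprintf(...), call. = FALSE)

.check_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    .fail("`%s` must be a single probability in [0, 1]", name)
}

# round half-up at `digits` decimals (R's round() is round-half-even)
.round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
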