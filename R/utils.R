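# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is restored afterwards so library calls never
# perturb user-level reproducibility.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Population (divide-by-total-weight) weighted covariance. The population
# convention keeps the concentration index exactly consistent with the
# curve-area identity; the sample (n-1) convention would break it.
weighted_cov_pop <- function(a, b, w = NULL) {
  if (is.null(w)) w <- rep(1, length(a))
  W <- sum(w)
  ma <- sum(w * a) / W
  mb <- sum(w * b) / W
  sum(w * (a - ma) * (b - mb)) / W
}

weighted_mean <- function(x, w = NULL) {
  if (is.null(w)) {
    return(mean(x))
  }
  sum(w * x) / sum(w)
}

# Significance stars following the reporting convention used throughout
# the output tables: * p<0.1, ** p<0.05, *** p<0.01.
signif_stars <- function(p) {
  ifelse(p < 0.01, "***", ifelse(p < 0.05, "**", ifelse(p < 0.1, "*", "")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_unmetci <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "unmetci_error")))
}
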