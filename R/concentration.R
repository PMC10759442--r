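#' Fractional income ranks
#'
#' Ranks respondents by a socioeconomic variable (typically deflated
#' per-capita household income) and returns fractional ranks in (0, 1).
#' With weights, the rank of a tie group is the cumulative weight of all
#' strictly poorer respondents plus half the group's own weight, divided by
#' total weight; with equal weights and no ties this reduces to
#' \eqn{r_i = (2i - 1)/(2n)}. The weighted mean rank is exactly 0.5.
#'
#' @param x Ranking variable (no missing values).
#' @param weights Positive weights; default all 1.
#' @param var_name Label recorded for provenance.
#' @return A `fractional_ranks` object: list with `r` (ranks in original row
#'   order), `rank_var` (the ranking values, kept so bootstrap replicates
#'   can re-rank), `weights`, `var_name`, `n` and `tie_groups`.
#' @examples
#' fractional_rank(c(1, 2, 3, 4))$r   # 0.125 0.375 0.625 0.875
#' fractional_rank(c(1, 2, 2, 3))$r   # 0.125 0.500 0.500 0.875
#' @export
fractional_rank <- function(x, weights = NULL, var_name = deparse(substitute(x))) {
  n <- length(x)
  if (n < 1L || anyNA(x)) {
    stop_unmetci("validation error: ranking variable must be non-empty and ",
                 "complete", class = "unmetci_validation_error")
  }
  weights <- weights %||% rep(1, n)
  if (length(weights) != n || anyNA(weights) || any(weights <= 0)) {
    stop_unmetci("validation error: weights must be positive and match length",
                 class = "unmetci_validation_error")
  }
  ord <- order(x)
  xs <- x[ord]
  ws <- weights[ord]
  grp <- cumsum(!duplicated(xs))
  gw <- as.vector(rowsum(ws, grp))
  cum_before <- cumsum(c(0, gw[-length(gw)]))
  r_group <- (cum_before + gw / 2) / sum(ws)
  r <- numeric(n)
  r[ord] <- r_group[grp]
  structure(list(r = r, rank_var = x, weights = weights,
                 var_name = as.character(var_name)[1L], n = n,
                 tie_groups = max(grp)),
            class = "fractional_ranks")
}

#' @export
print.fractional_ranks <- function(x, ...) {
  cat("<fractional_ranks> n = ", x$n, ", ", x$tie_groups,
      " distinct values of '", x$var_name, "'\n", sep = "")
  invisible(x)
}

as_ranks <- function(ranks, weights = NULL) {
  if (inherits(ranks, "fractional_ranks")) {
    return(ranks)
  }
  fractional_rank(ranks, weights, var_name = "rank_var")
}

#' Concentration index of an outcome over income ranks
#'
#' Computes \eqn{CI = (2/\mu)\,\mathrm{cov}(y, r)} with the population
#' (divide-by-total-weight) covariance, where \eqn{\mu} is the (weighted)
#' outcome mean and \eqn{r} the fractional income ranks. Negative values
#' indicate concentration among the poor (pro-poor), positive among the
#' rich. Optionally attaches a percentile-bootstrap 95% interval and the
#' concentration-curve coordinates.
#'
#' @param y Binary or non-negative continuous outcome series.
#' @param ranks A [fractional_rank()] object, or the raw ranking variable
#'   (which will be ranked internally).
#' @param weights Positive weights; defaults to the weights stored in
#'   `ranks`.
#' @param interval `"none"` (default) or `"bootstrap"` (percentile, see
#'   [ci_interval()]).
#' @param B Bootstrap replicates when `interval = "bootstrap"`.
#' @param seed Seed for the bootstrap.
#' @param curve Attach concentration-curve coordinates (default `TRUE`).
#' @return A `ci_result`: list with `ci`, `mu`, `n`, `interval`
#'   (length-2 numeric, `NA` unless requested), `interval_method` and
#'   `curve` (data.frame of cumulative shares, or `NULL`).
#' @examples
#' r <- fractional_rank(c(1, 2, 3, 4))
#' concentration_index(c(0, 0, 1, 1), r)$ci   # +0.5: unmet cases among the rich
#' @export
concentration_index <- function(y, ranks, weights = NULL,
                                interval = c("none", "bootstrap"),
                                B = 1000L, seed = NULL, curve = TRUE) {
  interval <- match.arg(interval)
  ranks <- as_ranks(ranks, weights)
  weights <- weights %||% ranks$weights
  n <- length(y)
  if (n != ranks$n) {
    stop_unmetci("validation error: outcome and ranks differ in length",
                 class = "unmetci_validation_error")
  }
  if (n < 2L) {
    stop_unmetci("validation error: concentration index needs n >= 2",
                 class = "unmetci_validation_error")
  }
  mu <- weighted_mean(y, weights)
  if (mu <= 0) {
    stop_unmetci("undefined index: outcome mean is zero (no cases observed)",
                 class = "unmetci_undefined_error")
  }
  ci <- 2 / mu * weighted_cov_pop(y, ranks$r, weights)
  crv <- if (curve) concentration_curve(y, ranks$rank_var, weights) else NULL
  res <- structure(list(ci = ci, mu = mu, n = n,
                        interval = c(NA_real_, NA_real_),
                        interval_method = "none", curve = crv),
                   class = "ci_result")
  if (interval == "bootstrap") {
    bi <- ci_interval(y, ranks, weights, B = B, seed = seed)
    res$interval <- c(bi$low, bi$high)
    res$interval_method <- bi$method
  }
  res
}

#' @export
print.ci_result <- function(x, digits = 4, ...) {
  cat(sprintf("<ci_result> CI = %.*f (n = %d, mean = %.*f)\n",
              digits, x$ci, x$n, digits, x$mu))
  if (!anyNA(x$interval)) {
    cat(sprintf("  95%% interval (%s): (%.*f, %.*f)\n", x$interval_method,
                digits, x$interval[1L], digits, x$interval[2L]))
  }
  invisible(x)
}

#' Generalized (unscaled) concentration index
#'
#' \eqn{GC = 2\,\mathrm{cov}(y, r)}, i.e. the concentration index without
#' the \eqn{1/\mu} scaling, so that \eqn{GC(y) = \mu\,CI(y)} whenever
#' \eqn{\mu > 0}. The decomposition's residual term is the generalized
#' concentration index of the linearization error divided by the outcome
#' mean.
#'
#' @inheritParams concentration_index
#' @return A single numeric value.
#' @export
generalized_concentration_index <- function(y, ranks, weights = NULL) {
  ranks <- as_ranks(ranks, weights)
  weights <- weights %||% ranks$weights
  if (length(y) != ranks$n || length(y) < 2L) {
    stop_unmetci("validation error: outcome and ranks must match with n >= 2",
                 class = "unmetci_validation_error")
  }
  2 * weighted_cov_pop(y, ranks$r, weights)
}

#' Concentration-curve coordinates
#'
#' Cumulative population share (poorest to richest on the x-axis) against
#' cumulative outcome share, with one point per distinct value of the
#' ranking variable and `(0, 0)` prepended. A curve above the diagonal
#' signals pro-poor concentration (negative concentration index).
#'
#' @param y Outcome series with positive mean.
#' @param rank_var Ranking variable (raw incomes, not ranks).
#' @param weights Positive weights; default all 1.
#' @return A data.frame with columns `cumulative_population_share` and
#'   `cumulative_outcome_share`, suitable for direct CSV export/plotting.
#' @export
concentration_curve <- function(y, rank_var, weights = NULL) {
  n <- length(y)
  weights <- weights %||% rep(1, n)
  stopifnot(length(rank_var) == n, length(weights) == n)
  if (weighted_mean(y, weights) <= 0) {
    stop_unmetci("undefined curve: outcome mean is zero",
                 class = "unmetci_undefined_error")
  }
  ord <- order(rank_var)
  xs <- rank_var[ord]
  ws <- weights[ord]
  ys <- y[ord]
  grp <- cumsum(!duplicated(xs))
  gw <- as.vector(rowsum(ws, grp))
  gyw <- as.vector(rowsum(ws * ys, grp))
  p <- cumsum(gw) / sum(gw)
  L <- cumsum(gyw) / sum(gyw)
  data.frame(cumulative_population_share = c(0, p),
             cumulative_outcome_share = c(0, L))
}

# Trapezoidal area under a concentration curve; CI = 1 - 2 * area when the
# curve carries one point per respondent (population-covariance convention).
curve_area <- function(curve) {
  p <- curve$cumulative_population_share
  L <- curve$cumulative_outcome_share
  sum(diff(p) * (head(L, -1) + tail(L, -1)) / 2)
}

#' Percentile-bootstrap interval for a concentration index
#'
#' Resamples respondents with replacement, re-ranks incomes within each
#' replicate, recomputes the index, and returns the 2.5th and 97.5th
#' percentiles. Fully seeded and reproducible; replicates in which the
#' resampled outcome mean is zero are dropped, and more than 10% such
#' degenerate replicates is an error.
#'
#' @param y Outcome series.
#' @param ranks A [fractional_rank()] object (its stored ranking variable is
#'   re-ranked per replicate), or the raw ranking variable.
#' @param weights Positive weights; defaults to those stored in `ranks`.
#' @param method Only `"bootstrap"` is implemented; the label is recorded in
#'   the result so downstream tables never misattribute the interval type.
#' @param B Number of replicates (at least 100; default 1000).
#' @param seed Integer seed.
#' @return List with `low`, `high`, `method`, `B` and `n_degenerate`.
#' @export
ci_interval <- function(y, ranks, weights = NULL, method = "bootstrap",
                        B = 1000L, seed = NULL) {
  method <- match.arg(method, "bootstrap")
  ranks <- as_ranks(ranks, weights)
  weights <- weights %||% ranks$weights
  n <- length(y)
  stopifnot(n == ranks$n)
  if (B < 100L) {
    stop_unmetci("validation error: bootstrap needs B >= 100",
                 class = "unmetci_validation_error")
  }
  x <- ranks$rank_var
  cis <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      yb <- y[idx]
      wb <- weights[idx]
      if (weighted_mean(yb, wb) <= 0) {
        return(NA_real_)
      }
      rb <- fractional_rank(x[idx], wb, var_name = ranks$var_name)
      2 / weighted_mean(yb, wb) * weighted_cov_pop(yb, rb$r, wb)
    }, numeric(1))
  })
  n_degenerate <- sum(is.na(cis))
  if (n_degenerate > 0.1 * B) {
    stop_unmetci("degenerate resamples: outcome mean was zero in ",
                 n_degenerate, " of ", B, " bootstrap replicates",
                 class = "unmetci_degenerate_error")
  }
  qs <- quantile(cis, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  list(low = qs[1L], high = qs[2L], method = "percentile bootstrap",
       B = as.integer(B), n_degenerate = n_degenerate)
}
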