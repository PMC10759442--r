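#' Decompose a concentration index into covariate contributions
#'
#' Wagstaff-style decomposition of the income-related concentration index
#' of a binary outcome. The pipeline is: build the design matrix, fit a
#' probit, take marginal effects at covariate means \eqn{\gamma_k}, compute
#' each design column's own concentration index \eqn{C_k} over the income
#' ranks, and form elasticities \eqn{\gamma_k \bar z_k / \mu} and
#' contributions (elasticity \eqn{\times C_k}). The residual is the
#' generalized concentration index of the linearization error divided by
#' \eqn{\mu}, with the linear intercept fixed by mean-matching so the
#' adding-up identity
#' \eqn{\sum_k \mathrm{contribution}_k + \mathrm{residual} = CI}
#' holds to machine precision; the identity is asserted, not assumed.
#'
#' The analysis is unweighted (a non-uniform weight column triggers a
#' warning and is ignored), matching the headline survey analysis this
#' mirrors, which describes no design weights.
#'
#' @param cohort A `cohort_table`.
#' @param outcome Name of a binary outcome column with positive mean.
#' @param covariates Covariate names; defaults to all schema covariates.
#' @return A `ci_decomposition`: `outcome`, `ci_total`, `mu`, `n`, `rows`
#'   (data.frame with per-term marginal effect, elasticity, covariate CI,
#'   contribution and percentage), `residual`, `explained`, plus the
#'   underlying `fit` and `mem` objects.
#' @seealso [percentage_contributions()], [group_rollup()],
#'   [format_decomposition()]
#' @export
decompose_ci <- function(cohort, outcome, covariates = NULL) {
  stopifnot(inherits(cohort, "cohort_table"))
  schema <- cohort$schema
  v <- schema_get(schema, outcome)
  if (v$role != "outcome" || v$type != "binary") {
    stop_unmetci("schema error: '", outcome, "' is not a binary outcome",
                 class = "unmetci_schema_error")
  }
  y <- cohort$data[[outcome]]
  w <- cohort_weights(cohort)
  if (length(unique(w)) > 1L) {
    warning("decompose_ci is unweighted; the cohort's weight column is ignored")
  }
  rank_name <- schema_names(schema, "ranking")
  ranks <- fractional_rank(cohort$data[[rank_name]], var_name = rank_name)
  mu <- mean(y)
  if (mu <= 0) {
    stop_unmetci("undefined index: outcome mean is zero",
                 class = "unmetci_undefined_error")
  }
  ci_total <- concentration_index(y, ranks, curve = FALSE)$ci

  design <- build_design(cohort, covariates)
  fit <- fit_probit(design, y)
  mem <- marginal_effects_at_means(fit, design)
  gamma <- mem$table$gamma
  names(gamma) <- mem$table$term
  zbar <- design$means

  # Covariate concentration indices; 2*cov(z_k, r)/zbar_k equals the plain
  # concentration index of the column whenever zbar_k > 0. A zero-mean
  # column has undefined C_k and, by construction, zero elasticity.
  gcov <- apply(design$X, 2, function(col) {
    2 * weighted_cov_pop(col, ranks$r)
  })
  covariate_ci <- ifelse(zbar != 0, gcov / zbar, NA_real_)
  elasticity <- gamma * zbar / mu
  contribution <- ifelse(zbar != 0, elasticity * covariate_ci, 0)

  # Linearized prediction with mean-matched intercept, so the residual is
  # the generalized CI of a mean-zero error divided by mu.
  delta_lin <- mu - sum(gamma * zbar)
  eps <- y - (delta_lin + drop(design$X %*% gamma))
  residual <- generalized_concentration_index(eps, ranks) / mu
  explained <- sum(contribution)
  gap <- explained + residual - ci_total
  if (abs(gap) > 1e-10) {
    stop_unmetci("internal error: adding-up identity violated by ", gap,
                 class = "unmetci_internal_error")
  }

  rows <- data.frame(term = mem$table$term,
                     variable = design$terms$variable,
                     level = design$terms$level,
                     marginal_effect = gamma,
                     me_se = mem$table$se,
                     me_p = mem$table$p,
                     stars = mem$table$stars,
                     mean = unname(zbar),
                     covariate_ci = unname(covariate_ci),
                     elasticity = unname(elasticity),
                     contribution = unname(contribution),
                     stringsAsFactors = FALSE)
  rownames(rows) <- NULL
  res <- structure(list(outcome = outcome, ci_total = ci_total, mu = mu,
                        n = cohort$n, rows = rows, residual = residual,
                        explained = explained, ranking = rank_name,
                        fit = fit, mem = mem),
                   class = "ci_decomposition")
  if (ci_total != 0) {
    res <- percentage_contributions(res)
  } else {
    res$rows$percentage <- NA_real_
  }
  res
}

#' Percentage contributions to the concentration index
#'
#' Fills (or refreshes) `percentage = 100 * contribution / ci_total` for
#' each decomposition row. A contribution with the same sign as the total
#' index therefore yields a positive percentage — the sign convention of
#' published decomposition tables. Near-zero total indices make
#' percentages explode; values beyond 10^4 in magnitude trigger a warning,
#' not an error.
#'
#' @param result A `ci_decomposition`.
#' @return The updated `ci_decomposition`.
#' @export
percentage_contributions <- function(result) {
  stopifnot(inherits(result, "ci_decomposition"))
  if (result$ci_total == 0) {
    stop_unmetci("undefined percentage: total concentration index is zero",
                 class = "unmetci_undefined_error")
  }
  result$rows$percentage <- 100 * result$rows$contribution / result$ci_total
  result$residual_percentage <- 100 * result$residual / result$ci_total
  if (any(abs(result$rows$percentage) > 1e4, na.rm = TRUE)) {
    warning("near-zero total CI: percentage contributions exceed 10^4 ",
            "in magnitude and are numerically fragile")
  }
  result
}

#' Roll indicator contributions up to their parent variables
#'
#' Sums the contributions (and percentages) of the indicator columns that
#' belong to one categorical variable into a single row per variable, and
#' appends the residual as a final row so the percentage column totals
#' 100 when the index is nonzero. Marginal effects and elasticities are
#' not summed across levels (a rolled contribution is a sum of
#' elasticity-times-\eqn{C_k} products, not a product itself).
#'
#' @param result A `ci_decomposition`.
#' @return A data.frame with columns `variable`, `n_terms`, `contribution`,
#'   `percentage`.
#' @export
group_rollup <- function(result) {
  stopifnot(inherits(result, "ci_decomposition"))
  rows <- result$rows
  first_seen <- !duplicated(rows$variable)
  vars <- rows$variable[first_seen]
  agg <- lapply(vars, function(v) {
    sel <- rows$variable == v
    data.frame(variable = v, n_terms = sum(sel),
               contribution = sum(rows$contribution[sel]),
               percentage = if (!is.null(rows$percentage)) {
                 sum(rows$percentage[sel])
               } else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- rbind(out, data.frame(variable = "(residual)", n_terms = NA_integer_,
                               contribution = result$residual,
                               percentage = result$residual_percentage %||% NA_real_,
                               stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Decomposition table in publication layout
#'
#' One row per design column with the usual columns: marginal effect with
#' significance stars, elasticity, contribution and percentage of
#' contribution, rounded to four decimals, plus residual and total rows.
#'
#' @param result A `ci_decomposition`.
#' @param digits Rounding for numeric cells (default 4).
#' @return A data.frame ready for CSV export.
#' @export
format_decomposition <- function(result, digits = 4) {
  stopifnot(inherits(result, "ci_decomposition"))
  rows <- result$rows
  fmt <- function(x) formatC(round(x, digits), format = "f", digits = digits)
  out <- data.frame(
    variable = rows$term,
    marginal_effect = paste0(fmt(rows$marginal_effect), rows$stars),
    elasticity = fmt(rows$elasticity),
    contribution = fmt(rows$contribution),
    percentage = fmt(rows$percentage),
    stringsAsFactors = FALSE)
  out <- rbind(out,
               data.frame(variable = "(residual)", marginal_effect = "",
                          elasticity = "", contribution = fmt(result$residual),
                          percentage = fmt(result$residual_percentage %||% NA_real_),
                          stringsAsFactors = FALSE),
               data.frame(variable = "(total CI)", marginal_effect = "",
                          elasticity = "", contribution = fmt(result$ci_total),
                          percentage = fmt(100),
                          stringsAsFactors = FALSE))
  out
}

#' @export
print.ci_decomposition <- function(x, digits = 4, ...) {
  cat(sprintf("<ci_decomposition> outcome '%s': CI = %.*f (mean %.*f, n = %d)\n",
              x$outcome, digits, x$ci_total, digits, x$mu, x$n))
  cat(sprintf("  explained %.*f + residual %.*f (adding-up exact)\n",
              digits, x$explained, digits, x$residual))
  print(format_decomposition(x, digits), row.names = FALSE)
  invisible(x)
}
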