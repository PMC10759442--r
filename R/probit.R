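#' Fit a probit model by Newton-Raphson
#'
#' Maximum-likelihood probit fit of a binary outcome on a design matrix
#' (an intercept is added internally). Newton iterations use the observed
#' information with step-halving, start deterministically at zero, and
#' declare convergence when the gradient max-norm falls below `tol`.
#' Standard errors come from the inverse observed information at the
#' optimum. Rank-deficient designs raise a collinearity error naming the
#' offending columns; diverging coefficients on standardized columns are
#' flagged as (quasi-)complete separation.
#'
#' @param design A [build_design()] result, or a numeric matrix without
#'   intercept column.
#' @param y Binary outcome series with both classes present.
#' @param tol Gradient max-norm tolerance (default 1e-8).
#' @param max_iter Maximum Newton iterations (default 100).
#' @return A `probit_fit`: list with `coefficients` (named, intercept
#'   first), `vcov`, `loglik`, `converged`, `iterations`, `n` and `terms`.
#' @examples
#' # intercept-only fit recovers qnorm of the outcome mean
#' y <- rep(c(0, 1), c(30, 10))
#' f <- fit_probit(matrix(numeric(0), nrow = 40, ncol = 0), y)
#' all.equal(unname(f$coefficients), qnorm(0.25))
#' @export
fit_probit <- function(design, y, tol = 1e-8, max_iter = 100L) {
  X0 <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  n <- length(y)
  stopifnot(nrow(X0) == n || ncol(X0) == 0L)
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    stop_unmetci("validation error: outcome must be 0/1 with no missing values",
                 class = "unmetci_validation_error")
  }
  if (length(unique(y)) < 2L) {
    stop_unmetci("validation error: outcome has a single class; probit ",
                 "requires both 0 and 1", class = "unmetci_validation_error")
  }
  X <- cbind(`(Intercept)` = rep(1, n), X0)
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop_unmetci("collinearity error: design is rank deficient; offending ",
                 "column(s): ", paste(drop_cols, collapse = ", "),
                 class = "unmetci_collinearity_error")
  }
  col_sd <- apply(X, 2, sd)
  col_sd[1L] <- 1

  loglik <- function(beta) {
    eta <- drop(X %*% beta)
    sum(pnorm(eta, log.p = TRUE)[y == 1]) +
      sum(pnorm(eta, lower.tail = FALSE, log.p = TRUE)[y == 0])
  }
  # Inverse Mills-type score weights, computed on the log scale so extreme
  # linear predictors stay finite.
  score_resid <- function(eta) {
    lam <- numeric(length(eta))
    i1 <- y == 1
    lam[i1] <- exp(dnorm(eta[i1], log = TRUE) - pnorm(eta[i1], log.p = TRUE))
    lam[!i1] <- -exp(dnorm(eta[!i1], log = TRUE) -
                       pnorm(eta[!i1], lower.tail = FALSE, log.p = TRUE))
    lam
  }

  beta <- rep(0, p)
  ll <- loglik(beta)
  converged <- FALSE
  iterations <- 0L
  H <- NULL
  for (it in seq_len(max_iter)) {
    iterations <- it
    eta <- drop(X %*% beta)
    lam <- score_resid(eta)
    g <- drop(crossprod(X, lam))
    w <- lam * (lam + eta)  # observed-information weights, positive a.e.
    H <- crossprod(X, X * w)
    if (max(abs(g)) < tol) {
      converged <- TRUE
      break
    }
    step <- solve(H, g)
    s <- 1
    repeat {
      cand <- beta + s * step
      llc <- loglik(cand)
      if (is.finite(llc) && llc >= ll - 1e-12) break
      s <- s / 2
      if (s < 1e-10) {
        cand <- beta
        llc <- ll
        break
      }
    }
    beta <- cand
    ll <- llc
    if (max(abs(beta * col_sd)) > 20) {
      stop_unmetci("non-convergence error: complete or quasi-complete ",
                   "separation suspected (|beta| diverging)",
                   class = "unmetci_separation_error")
    }
  }
  names(beta) <- colnames(X)
  vcov <- solve(H)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  structure(list(coefficients = beta, vcov = vcov, loglik = ll,
                 converged = converged, iterations = iterations, n = n,
                 terms = colnames(X)),
            class = "probit_fit")
}

#' @export
print.probit_fit <- function(x, digits = 4, ...) {
  cat("<probit_fit> n = ", x$n, ", logLik = ", format(x$loglik, digits = 6),
      ", ", x$iterations, " Newton iterations",
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  se <- sqrt(diag(x$vcov))
  z <- x$coefficients / se
  pv <- 2 * pnorm(-abs(z))
  tab <- data.frame(estimate = round(x$coefficients, digits),
                    se = round(se, digits), p = round(pv, digits),
                    sig = signif_stars(pv))
  print(tab)
  invisible(x)
}

#' Marginal effects at covariate means
#'
#' For a converged probit fit, the marginal effect of covariate `k`
#' evaluated at the covariate mean vector is
#' \eqn{\gamma_k = \phi(\bar z' \hat\beta)\,\hat\beta_k}: one common scalar
#' density factor times each coefficient. Indicator columns are treated in
#' the same derivative form, so a single linear approximation applies
#' uniformly to every design column (which the decomposition requires).
#' Standard errors are delta-method; p-values are two-sided normal.
#'
#' @param fit A converged [fit_probit()] result.
#' @param design The [build_design()] matrix the model was fitted on (its
#'   stored column means define the evaluation point).
#' @return A `marginal_effects` object: `table` (data.frame with `term`,
#'   `beta`, `gamma`, `se`, `p`, `stars`), `evaluated_at`, `density`
#'   (\eqn{\phi(\bar z'\hat\beta)}) and `eta` (\eqn{\bar z'\hat\beta}).
#' @export
marginal_effects_at_means <- function(fit, design) {
  stopifnot(inherits(fit, "probit_fit"))
  if (!fit$converged) {
    stop_unmetci("refusal: probit fit did not converge; marginal effects ",
                 "would be meaningless", class = "unmetci_refusal_error")
  }
  means <- if (inherits(design, "design_matrix")) design$means else colMeans(as.matrix(design))
  m <- c(`(Intercept)` = 1, means)
  if (!identical(names(m), fit$terms)) {
    stop_unmetci("schema error: design columns do not match the fitted model",
                 class = "unmetci_schema_error")
  }
  beta <- fit$coefficients
  eta <- sum(m * beta)
  f <- dnorm(eta)
  idx <- seq_along(beta)[-1L]  # covariate columns (drop intercept)
  gamma <- f * beta[idx]
  # d gamma_k / d beta_j = phi(eta) * [1{k=j} - beta_k * eta * m_j]
  J <- -f * eta * outer(beta[idx], m)
  J[cbind(seq_along(idx), idx)] <- J[cbind(seq_along(idx), idx)] + f
  V <- J %*% fit$vcov %*% t(J)
  se <- sqrt(pmax(diag(V), 0))
  z <- gamma / se
  pv <- 2 * pnorm(-abs(z))
  tab <- data.frame(term = names(beta)[idx], beta = unname(beta[idx]),
                    gamma = unname(gamma), se = unname(se), p = unname(pv),
                    stars = signif_stars(unname(pv)),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, evaluated_at = m, density = f, eta = eta),
            class = "marginal_effects")
}

#' @export
print.marginal_effects <- function(x, digits = 4, ...) {
  cat(sprintf("<marginal_effects> evaluated at covariate means (phi = %.6f)\n",
              x$density))
  tab <- x$table
  tab$beta <- round(tab$beta, digits)
  tab$gamma <- round(tab$gamma, digits)
  tab$se <- round(tab$se, digits)
  tab$p <- round(tab$p, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Fitted probit probabilities
#'
#' \eqn{\Phi(z_i'\hat\beta)} per row of the design; used to form the
#' decomposition residual and for diagnostics.
#'
#' @param fit A converged [fit_probit()] result.
#' @param design The design the model was fitted on, or new data with
#'   identical columns.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_prob <- function(fit, design) {
  stopifnot(inherits(fit, "probit_fit"))
  if (!fit$converged) {
    stop_unmetci("refusal: probit fit did not converge",
                 class = "unmetci_refusal_error")
  }
  X0 <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  X <- cbind(`(Intercept)` = rep(1, nrow(X0)), X0)
  if (!identical(colnames(X), fit$terms)) {
    stop_unmetci("schema error: design columns do not match the fitted model",
                 class = "unmetci_schema_error")
  }
  pnorm(drop(X %*% fit$coefficients))
}

#' Export-ready probit summary table
#'
#' One row per design column: coefficient, SE, marginal effect at means,
#' its SE, p-value and significance stars — the layout used in published
#' decomposition tables.
#'
#' @param fit A converged `probit_fit`.
#' @param mem Matching [marginal_effects_at_means()] result (computed if
#'   omitted).
#' @param design Design matrix, needed when `mem` is omitted.
#' @return A data.frame.
#' @export
probit_summary_table <- function(fit, mem = NULL, design = NULL) {
  if (is.null(mem)) {
    mem <- marginal_effects_at_means(fit, design)
  }
  se_beta <- sqrt(diag(fit$vcov))[-1L]
  data.frame(term = mem$table$term,
             coefficient = mem$table$beta,
             coef_se = unname(se_beta),
             marginal_effect = mem$table$gamma,
             me_se = mem$table$se,
             p = mem$table$p,
             stars = mem$table$stars,
             stringsAsFactors = FALSE)
}
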