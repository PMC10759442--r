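# Shared fixture builders; everything is generated in code at test time.

toy_schema <- function(with_weight = FALSE) {
  vars <- list(
    schema_var("unmet", "outcome", "binary"),
    schema_var("income", "ranking", "continuous", units = "RMB"),
    schema_var("shi", "covariate", "binary"),
    schema_var("education", "covariate", "categorical",
               levels = c("Illiterate", "Primary", "Middle", "High+"),
               reference = "Illiterate"),
    schema_var("age", "covariate", "continuous", units = "years")
  )
  if (with_weight) {
    vars <- c(vars, list(schema_var("w", "weight", "continuous")))
  }
  variable_schema(vars)
}

toy_frame <- function() {
  data.frame(
    unmet = c(0, 1, 0, 1, 0),
    income = c(1200, 800, 15000, 300, 5600),
    shi = c(1, 1, 1, 0, 1),
    education = c("Primary", "Illiterate", "High+", "Illiterate", "Middle"),
    age = c(52, 63, 47, 71, 58),
    stringsAsFactors = FALSE
  )
}

write_toy_csv <- function(df = toy_frame(), path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# Cohort with a prescribed number of unmet cases among n respondents;
# incomes are distinct so ranks are unambiguous.
count_cohort <- function(n_unmet, n_total) {
  sch <- variable_schema(
    schema_var("unmet", "outcome", "binary"),
    schema_var("income", "ranking", "continuous")
  )
  cohort_table(data.frame(unmet = rep(c(1, 0), c(n_unmet, n_total - n_unmet)),
                          income = seq_len(n_total)), sch)
}

# Small random probit fixture used for oracle-equivalence checks.
probit_fixture <- function(n = 200, seed = 1) {
  set.seed(seed)
  x1 <- rnorm(n)
  x2 <- rbinom(n, 1, 0.4)
  x3 <- runif(n, -1, 2)
  beta <- c(runif(1, -0.5, 0.5), runif(3, -1, 1))
  eta <- beta[1] + beta[2] * x1 + beta[3] * x2 + beta[4] * x3
  y <- rbinom(n, 1, pnorm(eta))
  list(X = cbind(x1 = x1, x2 = x2, x3 = x3), y = y, beta = beta)
}

# Brute-force concentration index straight from the defining covariance
# formula with (2i-1)/(2n) ranks; independent of the package's code path.
brute_ci <- function(y, income) {
  n <- length(y)
  ord <- order(income)
  y <- y[ord]
  r <- (2 * seq_len(n) - 1) / (2 * n)
  2 / mean(y) * (mean(y * r) - mean(y) * mean(r))
}
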