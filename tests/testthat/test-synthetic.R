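test_that("identical config and seed reproduce bit-identical cohorts", {
  g1 <- generate_cohort(default_dgp(n = 500, seed = 42), truth = FALSE)
  g2 <- generate_cohort(default_dgp(n = 500, seed = 42), truth = FALSE)
  expect_identical(g1$cohort$data, g2$cohort$data)
  g3 <- generate_cohort(default_dgp(n = 500, seed = 43), truth = FALSE)
  expect_false(identical(g1$cohort$data$income, g3$cohort$data$income))
  # generation restores the caller's RNG stream
  set.seed(1); a <- rnorm(1)
  set.seed(1)
  invisible(generate_cohort(default_dgp(n = 200, seed = 5), truth = FALSE))
  expect_identical(rnorm(1), a)
})

test_that("generated cohorts carry a valid schema and realistic marginals", {
  g <- generate_cohort(default_dgp(n = 5000, seed = 2), truth = FALSE)
  co <- g$cohort
  expect_s3_class(co, "cohort_table")
  expect_identical(co$n, 5000L)
  expect_true(all(co$data$unmet_financial %in% 0:1))
  expect_true(all(co$data$income > 0))
  expect_equal(co$data$ln_income, log1p(co$data$income))
  # near-universal insurance, majority-rural, as configured
  expect_gt(mean(co$data$shi), 0.95)
  expect_lt(mean(co$data$urban), 0.5)
  expect_setequal(unique(co$data$education),
                  c("Illiterate", "Primary school", "Middle school",
                    "High school and above"))
  # positive income association: insured and urban respondents are richer
  expect_gt(mean(co$data$income[co$data$urban == 1]),
            mean(co$data$income[co$data$urban == 0]))
})

test_that("flat DGP (all slopes zero) yields the target incidence and no inequality", {
  cfg <- default_dgp(n = 20000, seed = 3)
  cfg$beta_financial[] <- 0
  cfg$beta_financial[["(Intercept)"]] <- qnorm(0.25)
  cfg$beta_nonfinancial[] <- 0
  cfg$beta_nonfinancial[["(Intercept)"]] <- qnorm(0.25)
  g <- generate_cohort(cfg, truth = FALSE)
  y <- g$cohort$data$unmet_financial
  mc <- sqrt(0.25 * 0.75 / 20000)
  expect_lt(abs(mean(y) - 0.25), 4 * mc)
  ci <- concentration_index(y, fractional_rank(g$cohort$data$income),
                            curve = FALSE)$ci
  # no income gradient means no inequality, up to binomial MC error
  expect_lt(abs(ci), 3 * sqrt((1 - 0.25) / 0.25 / 12) / sqrt(20000) * 2)
  tr <- population_truth(cfg, oracle_n = 1e5, oracle_seed = 9)
  expect_lt(abs(tr$ci[["financial"]]), 1 / sqrt(1e5))
  expect_equal(unname(tr$incidence[["financial"]]), 0.25, tolerance = 1e-3)
})

test_that("oracle truths are stable in the oracle population size", {
  cfg <- default_dgp()
  t1 <- population_truth(cfg, oracle_n = 1e5, oracle_seed = 21)
  t2 <- population_truth(cfg, oracle_n = 2e5, oracle_seed = 22)
  # the Rao-Blackwellised oracle only carries covariate-sampling noise;
  # doubling the population moves the truth by a fraction of the band
  # the recovery tests rely on
  expect_lt(abs(t1$ci[["financial"]] - t2$ci[["financial"]]), 0.004)
  expect_lt(abs(t1$incidence[["nonfinancial"]] - t2$incidence[["nonfinancial"]]),
            0.004)
  expect_error(population_truth(cfg, oracle_n = 5000),
               class = "unmetci_validation_error")
})

test_that("misnamed coefficients are a configuration error", {
  cfg <- default_dgp()
  bad <- cfg$beta_financial
  names(bad)[2] <- "log_income"  # no such design column
  expect_error(dgp_config(n = 1000, seed = 1, covariates = cfg$covariates,
                          beta_financial = bad,
                          beta_nonfinancial = cfg$beta_nonfinancial),
               "log_income", class = "unmetci_config_error")
  expect_error(dgp_config(n = 50, seed = 1, covariates = cfg$covariates,
                          beta_financial = cfg$beta_financial,
                          beta_nonfinancial = cfg$beta_nonfinancial))
})

test_that("cohort incidence agrees with the oracle incidence", {
  cfg <- default_dgp(n = 10000, seed = 1)
  g <- generate_cohort(cfg, truth = TRUE, oracle_n = 2e5, oracle_seed = 77)
  inc <- incidence(g$cohort)
  for (oc in c("financial", "nonfinancial")) {
    est <- inc$percentage[inc$outcome == paste0("unmet_", oc)] / 100
    truth <- g$truth$incidence[[oc]]
    mc <- sqrt(truth * (1 - truth) / 10000)
    expect_lt(abs(est - truth), 4 * mc)
  }
})

test_that("DGP configurations round-trip through YAML", {
  cfg <- default_dgp(n = 500, seed = 6)
  path <- tempfile(fileext = ".yaml")
  covs <- lapply(cfg$covariates, function(cv) {
    e <- Filter(Negate(is.null),
                cv[c("type", "prevalence", "levels", "probs", "reference",
                     "mean", "sd", "income_assoc")])
    e
  })
  names(covs) <- vapply(cfg$covariates, `[[`, character(1), "name")
  yaml::write_yaml(list(n = cfg$n, seed = cfg$seed,
                        income_log_mean = cfg$income_log_mean,
                        income_log_sd = cfg$income_log_sd,
                        covariates = covs,
                        beta_financial = as.list(cfg$beta_financial),
                        beta_nonfinancial = as.list(cfg$beta_nonfinancial)),
                  path)
  cfg2 <- read_dgp_config(path)
  expect_equal(cfg2$beta_financial, cfg$beta_financial)
  expect_equal(cfg2$covariates, cfg$covariates)
  g1 <- generate_cohort(cfg, truth = FALSE)
  g2 <- generate_cohort(cfg2, truth = FALSE)
  expect_identical(g1$cohort$data, g2$cohort$data)
})
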