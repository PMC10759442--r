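test_that("fractional ranks use midpoint-of-tied-block weighting", {
  expect_equal(fractional_rank(c(1, 2, 3, 4))$r, c(0.125, 0.375, 0.625, 0.875))
  expect_equal(fractional_rank(c(5, 5, 5))$r, rep(0.5, 3))
  expect_equal(fractional_rank(c(1, 2, 2, 3))$r, c(0.125, 0.5, 0.5, 0.875))
  # ranks are reported in original row order
  expect_equal(fractional_rank(c(4, 1, 3, 2))$r, c(0.875, 0.125, 0.625, 0.375))
  expect_error(fractional_rank(c(1, 2), weights = c(1, 0)),
               "positive", class = "unmetci_validation_error")
})

test_that("mean fractional rank is exactly 0.5, weighted or not", {
  set.seed(41)
  for (i in 1:20) {
    n <- sample(2:60, 1)
    x <- sample(round(rlnorm(n, 9, 1)), n)  # ties likely after rounding
    w <- runif(n, 0.2, 3)
    fr <- fractional_rank(x, w)
    expect_equal(sum(w * fr$r) / sum(w), 0.5)
    expect_equal(mean(fractional_rank(x)$r), 0.5)
    # non-decreasing in the ranking variable
    expect_true(all(diff(fr$r[order(x)]) >= 0))
  }
})

test_that("concentration index matches the hand-derived worked example", {
  r <- fractional_rank(c(1, 2, 3, 4))
  res <- concentration_index(c(0, 0, 1, 1), r)
  expect_equal(res$ci, 0.5, tolerance = 1e-12)
  expect_equal(res$mu, 0.5)
  # constant outcome has zero covariance with ranks
  expect_equal(concentration_index(rep(1, 4), r)$ci, 0)
  expect_error(concentration_index(c(0, 0, 0, 0), r),
               class = "unmetci_undefined_error")
  expect_error(concentration_index(c(1, 0), fractional_rank(1), weights = 1),
               class = "unmetci_validation_error")
})

test_that("generalized concentration index is the unscaled bilinear form", {
  r <- fractional_rank(c(1, 2, 3, 4))
  y <- c(0, 0, 1, 1)
  expect_equal(generalized_concentration_index(y, r), 0.25)
  expect_equal(generalized_concentration_index(rep(2, 4), r), 0)
  expect_equal(generalized_concentration_index(3 * y, r), 0.75)
  # GC(y) = mu * CI(y)
  set.seed(7)
  y2 <- rbinom(30, 1, 0.4)
  r2 <- fractional_rank(runif(30))
  expect_equal(generalized_concentration_index(y2, r2),
               mean(y2) * concentration_index(y2, r2)$ci)
})

test_that("concentration curve coordinates accumulate shares correctly", {
  crv <- concentration_curve(c(0, 0, 1, 1), c(1, 2, 3, 4))
  expect_equal(crv$cumulative_population_share, c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(crv$cumulative_outcome_share, c(0, 0, 0, 0.5, 1))
  # equal outcomes trace the diagonal
  crv2 <- concentration_curve(rep(1, 4), c(1, 2, 3, 4))
  expect_equal(crv2$cumulative_outcome_share, crv2$cumulative_population_share)
  # a single poor case puts the curve above the diagonal (pro-poor, ci < 0)
  crv3 <- concentration_curve(c(1, 0, 0, 0), c(1, 2, 3, 4))
  expect_equal(crv3$cumulative_outcome_share, c(0, 1, 1, 1, 1))
  ci3 <- concentration_index(c(1, 0, 0, 0), fractional_rank(c(1, 2, 3, 4)))
  expect_lt(ci3$ci, 0)
  # tied incomes collapse to one curve point
  crv4 <- concentration_curve(c(0, 1, 1), c(2, 2, 5))
  expect_equal(crv4$cumulative_population_share, c(0, 2 / 3, 1))
})

test_that("scale invariance and rank antisymmetry hold numerically", {
  set.seed(11)
  for (i in 1:15) {
    n <- sample(5:80, 1)
    income <- rlnorm(n, 9, 0.8)
    y <- rbinom(n, 1, 0.3)
    if (sum(y) == 0) y[1] <- 1
    r <- fractional_rank(income)
    ci <- concentration_index(y, r, curve = FALSE)$ci
    expect_equal(concentration_index(2.7 * y, r, curve = FALSE)$ci, ci,
                 tolerance = 1e-12)
    # reversing the ranking negates the index exactly
    ci_rev <- concentration_index(y, fractional_rank(-income),
                                  curve = FALSE)$ci
    expect_equal(ci_rev, -ci, tolerance = 1e-12)
    expect_lte(abs(ci), 1)
  }
})

test_that("index agrees with the brute-force covariance oracle", {
  set.seed(23)
  for (i in 1:10) {
    n <- sample(4:50, 1)
    income <- sample(seq_len(1000), n)  # distinct
    y <- rbinom(n, 1, 0.4)
    if (sum(y) == 0) y[1] <- 1
    est <- concentration_index(y, fractional_rank(income), curve = FALSE)$ci
    expect_equal(est, brute_ci(y, income), tolerance = 1e-12)
  }
})

test_that("bootstrap intervals are seeded, reproducible and sane", {
  set.seed(3)
  income <- rlnorm(300, 9, 0.8)
  y <- rbinom(300, 1, pnorm(-0.5 - 0.4 * scale(log(income))))
  r <- fractional_rank(income)
  b1 <- ci_interval(y, r, B = 200, seed = 99)
  b2 <- ci_interval(y, r, B = 200, seed = 99)
  expect_identical(b1, b2)
  expect_lt(b1$low, b1$high)
  expect_identical(b1$method, "percentile bootstrap")
  # point estimate falls inside its own interval here
  ci <- concentration_index(y, r, curve = FALSE)$ci
  expect_gt(ci, b1$low)
  expect_lt(ci, b1$high)
  # constant outcome: every replicate index is exactly zero
  b0 <- ci_interval(rep(1, 50), fractional_rank(runif(50)), B = 100, seed = 5)
  expect_equal(c(b0$low, b0$high), c(0, 0))
  expect_error(ci_interval(y, r, B = 50, seed = 1),
               class = "unmetci_validation_error")
  # the seeded bootstrap does not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(ci_interval(y, r, B = 100, seed = 7)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("interval requested through concentration_index covers oracle truth", {
  g <- generate_cohort(default_dgp(n = 10000, seed = 1), truth = FALSE)
  tr <- population_truth(default_dgp(), oracle_n = 1e5, oracle_seed = 314)
  rk <- fractional_rank(g$cohort$data$income)
  res <- concentration_index(g$cohort$data$unmet_financial, rk,
                             interval = "bootstrap", B = 500, seed = 7,
                             curve = FALSE)
  expect_identical(res$interval_method, "percentile bootstrap")
  expect_gte(tr$ci[["financial"]], res$interval[1])
  expect_lte(tr$ci[["financial"]], res$interval[2])
})
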