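test_that("a complete cohort file loads with no rows dropped", {
  path <- write_toy_csv()
  co <- load_cohort(path, toy_schema())
  expect_s3_class(co, "cohort_table")
  expect_identical(co$n, 5L)
  expect_identical(co$n_dropped, 0L)
  expect_equal(co$data$income, toy_frame()$income)
})

test_that("rows with missing required values are dropped and counted", {
  df <- toy_frame()
  df$income[2] <- NA
  co <- load_cohort(write_toy_csv(df), toy_schema())
  expect_identical(co$n, 4L)
  expect_identical(co$n_dropped, 1L)
  expect_identical(unname(co$missing_by_column[["income"]]), 1L)
})

test_that("schema and validation errors are specific", {
  df <- toy_frame()
  df$unmet[3] <- 2
  expect_error(load_cohort(write_toy_csv(df), toy_schema()),
               "row 3", class = "unmetci_validation_error")
  df2 <- toy_frame()[, -2]
  expect_error(load_cohort(write_toy_csv(df2), toy_schema()),
               "income", class = "unmetci_schema_error")
  df3 <- toy_frame()
  df3$education[1] <- "Doctorate"
  expect_error(cohort_table(df3, toy_schema()),
               "unknown level", class = "unmetci_validation_error")
  df4 <- toy_frame()
  df4$income[4] <- -10
  expect_error(cohort_table(df4, toy_schema()),
               "non-negative", class = "unmetci_validation_error")
})

test_that("schemas enforce their own invariants", {
  expect_error(variable_schema(schema_var("y", "outcome", "binary")),
               "ranking", class = "unmetci_schema_error")
  expect_error(schema_var("edu", "covariate", "categorical",
                          levels = c("a", "b"), reference = "z"),
               "reference", class = "unmetci_schema_error")
  expect_error(variable_schema(schema_var("x", "ranking"),
                               schema_var("x", "covariate")),
               "duplicated", class = "unmetci_schema_error")
})

test_that("cohort and schema round-trip through disk unchanged", {
  co <- cohort_table(toy_frame(), toy_schema())
  p <- tempfile(fileext = ".csv")
  write_cohort(co, p)
  co2 <- load_cohort(p, toy_schema())
  expect_identical(co2$data, co$data)

  sp <- tempfile(fileext = ".yaml")
  write_schema(toy_schema(), sp)
  sch2 <- read_schema(sp)
  expect_identical(schema_names(sch2), schema_names(toy_schema()))
  expect_identical(sch2$vars$education$levels, toy_schema()$vars$education$levels)
  expect_identical(sch2$vars$education$reference, "Illiterate")
})

test_that("CPI deflation follows cpi[base]/cpi[year] with base-year identity", {
  cpi <- c("2011" = 100, "2013" = 105, "2015" = 108.1)
  expect_equal(deflate_to_base(100, 2011, cpi, 2011), 100)
  expect_equal(deflate_to_base(100, 2013, cpi, 2011), 95.2381, tolerance = 1e-6)
  # linearity: sign is preserved, validation happens elsewhere
  expect_equal(deflate_to_base(-100, 2013, cpi, 2011), -95.2381,
               tolerance = 1e-6)
  expect_equal(deflate_to_base(c(100, 200), c(2013, 2015), cpi, 2011),
               c(100 * 100 / 105, 200 * 100 / 108.1))
  expect_error(deflate_to_base(100, 2018, cpi, 2011),
               "2018", class = "unmetci_config_error")
})

test_that("log-plus-one transform matches its closed forms", {
  expect_identical(log1_transform(0), 0)
  expect_equal(log1_transform(exp(1) - 1), 1)
  # reference value printed to four decimals: ln(10087.14) = 9.21902...
  expect_lt(abs(log1_transform(10086.14) - 9.2189), 2.5e-4)
  expect_equal(log1_transform(10086.14), log(10087.14), tolerance = 1e-12)
  expect_error(log1_transform(c(1, -2)), "non-negative",
               class = "unmetci_domain_error")
})

test_that("design matrix uses reference-omitted indicator coding", {
  co <- cohort_table(toy_frame(), toy_schema())
  d <- build_design(co)
  expect_identical(colnames(d$X),
                   c("shi", "education.Primary", "education.Middle",
                     "education.High+", "age"))
  # reference-level row has all-zero indicators
  edu_cols <- grep("^education", colnames(d$X))
  expect_equal(unname(rowSums(d$X[, edu_cols])), c(1, 0, 1, 0, 1))
  expect_true(all(rowSums(d$X[, edu_cols]) %in% c(0, 1)))
  # binary covariate passes through unchanged
  expect_equal(unname(d$X[, "shi"]), toy_frame()$shi)
  expect_equal(unname(d$means["age"]), mean(toy_frame()$age))
  expect_error(build_design(co, c("shi", "nope")), "nope",
               class = "unmetci_schema_error")
})

test_that("design column order follows the schema, not row order", {
  df <- toy_frame()
  co1 <- cohort_table(df, toy_schema())
  co2 <- cohort_table(df[rev(seq_len(nrow(df))), ], toy_schema())
  d1 <- build_design(co1)
  d2 <- build_design(co2)
  expect_identical(colnames(d1$X), colnames(d2$X))
  expect_equal(d1$means, d2$means)
  # subsetting covariates keeps schema-relative order
  d3 <- build_design(co1, c("education", "shi"))
  expect_identical(d3$covariates, c("education", "shi"))
})

test_that("the shipped synthetic demo cohort loads cleanly", {
  csv <- system.file("extdata", "synthetic_demo_cohort.csv",
                     package = "unmetci")
  yml <- system.file("extdata", "synthetic_demo_schema.yaml",
                     package = "unmetci")
  co <- load_cohort(csv, read_schema(yml))
  expect_identical(co$n, 120L)
  expect_identical(co$n_dropped, 0L)
  expect_equal(co$data$ln_income, round(log1p(co$data$income), 6))
})
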