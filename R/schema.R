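#' Declare one analysis variable
#'
#' Builds a single schema entry describing a column of a respondent-level
#' cohort table: its role in the analysis, its measurement type, and (for
#' categorical variables) the ordered level set and reference group.
#'
#' @param name Column name in the cohort table.
#' @param role One of `"covariate"`, `"outcome"`, `"ranking"` (the income
#'   variable respondents are ranked by), `"weight"` or `"id"`.
#' @param type One of `"continuous"`, `"binary"` (values 0/1) or
#'   `"categorical"`.
#' @param levels Ordered character vector of levels (categorical only).
#' @param reference Reference level omitted from design matrices; defaults
#'   to the first level.
#' @param units Free-text units, e.g. `"RMB, 2011 prices"`.
#' @return An object of class `schema_var`.
#' @seealso [variable_schema()]
#' @export
schema_var <- function(name,
                       role = c("covariate", "outcome", "ranking", "weight", "id"),
                       type = c("continuous", "binary", "categorical"),
                       levels = NULL, reference = NULL, units = NULL) {
  role <- match.arg(role)
  type <- match.arg(type)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (type == "categorical") {
    if (is.null(levels) || length(levels) < 2L) {
      stop_unmetci("schema error: categorical variable '", name,
                   "' needs at least two levels", class = "unmetci_schema_error")
    }
    levels <- as.character(levels)
    reference <- reference %||% levels[1L]
    if (!reference %in% levels) {
      stop_unmetci("schema error: reference level '", reference,
                   "' of '", name, "' is not among its levels",
                   class = "unmetci_schema_error")
    }
  } else if (!is.null(levels) || !is.null(reference)) {
    stop_unmetci("schema error: levels/reference only apply to categorical ",
                 "variables ('", name, "')", class = "unmetci_schema_error")
  }
  structure(list(name = name, role = role, type = type, levels = levels,
                 reference = reference, units = units),
            class = "schema_var")
}

#' Assemble a variable schema
#'
#' Collects [schema_var()] entries into a validated schema. Exactly one
#' variable must carry the `ranking` role; every categorical variable must
#' declare a reference level drawn from its levels.
#'
#' @param ... `schema_var` objects, or a single list of them.
#' @return An object of class `variable_schema`.
#' @examples
#' sch <- variable_schema(
#'   schema_var("unmet", "outcome", "binary"),
#'   schema_var("income", "ranking", "continuous", units = "RMB"),
#'   schema_var("shi", "covariate", "binary"),
#'   schema_var("education", "covariate", "categorical",
#'              levels = c("Illiterate", "Primary", "Middle", "High+"))
#' )
#' schema_names(sch)
#' @export
variable_schema <- function(...) {
  vars <- list(...)
  if (length(vars) == 1L && !inherits(vars[[1L]], "schema_var") && is.list(vars[[1L]])) {
    vars <- vars[[1L]]
  }
  ok <- vapply(vars, inherits, logical(1), what = "schema_var")
  if (!length(vars) || !all(ok)) {
    stop_unmetci("schema error: variable_schema() takes schema_var entries",
                 class = "unmetci_schema_error")
  }
  nm <- vapply(vars, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    stop_unmetci("schema error: duplicated variable name(s): ",
                 paste(unique(nm[duplicated(nm)]), collapse = ", "),
                 class = "unmetci_schema_error")
  }
  names(vars) <- nm
  roles <- vapply(vars, `[[`, character(1), "role")
  if (sum(roles == "ranking") != 1L) {
    stop_unmetci("schema error: exactly one ranking variable is required",
                 class = "unmetci_schema_error")
  }
  structure(list(vars = vars), class = "variable_schema")
}

#' @export
print.variable_schema <- function(x, ...) {
  cat("<variable_schema> ", length(x$vars), " variables\n", sep = "")
  for (v in x$vars) {
    lev <- if (!is.null(v$levels)) {
      paste0(" [", paste(ifelse(v$levels == v$reference,
                                paste0(v$levels, "*"), v$levels),
                         collapse = ", "), "]")
    } else ""
    cat(sprintf("  %-14s %-9s %-11s%s\n", v$name, v$role, v$type, lev))
  }
  invisible(x)
}

#' Names of schema variables, optionally filtered by role
#' @param schema A `variable_schema`.
#' @param role Optional role filter.
#' @return Character vector of variable names in schema order.
#' @export
schema_names <- function(schema, role = NULL) {
  stopifnot(inherits(schema, "variable_schema"))
  nm <- names(schema$vars)
  if (is.null(role)) {
    return(nm)
  }
  roles <- vapply(schema$vars, `[[`, character(1), "role")
  nm[roles %in% role]
}

schema_get <- function(schema, name) {
  v <- schema$vars[[name]]
  if (is.null(v)) {
    stop_unmetci("schema error: unknown variable '", name, "'",
                 class = "unmetci_schema_error")
  }
  v
}

#' Read or write a variable schema as YAML
#'
#' The on-disk format is one mapping per variable:
#' `name: {role: ..., type: ..., levels: [...], reference: ..., units: ...}`.
#'
#' @param path File path.
#' @return `read_schema()` returns a `variable_schema`; `write_schema()`
#'   returns `path` invisibly.
#' @export
read_schema <- function(path) {
  raw <- yaml::read_yaml(path)
  vars <- lapply(names(raw), function(nm) {
    e <- raw[[nm]]
    schema_var(nm, role = e$role %||% "covariate",
               type = e$type %||% "continuous",
               levels = e$levels, reference = e$reference, units = e$units)
  })
  variable_schema(vars)
}

#' @param schema A `variable_schema` to serialize.
#' @rdname read_schema
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "variable_schema"))
  out <- lapply(schema$vars, function(v) {
    e <- list(role = v$role, type = v$type)
    if (!is.null(v$levels)) {
      e$levels <- v$levels
      e$reference <- v$reference
    }
    if (!is.null(v$units)) e$units <- v$units
    e
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Cohort tables

#' Load and validate a respondent-level cohort table
#'
#' Reads a delimited text file with a header row, checks it against the
#' schema, applies listwise deletion on all schema-required columns, and
#' reports how many rows were dropped. Binary columns must contain only 0/1
#' after validation; categorical values must belong to the declared level
#' set; the ranking (income) variable must be non-negative.
#'
#' @param path Path to a CSV file (UTF-8, header row).
#' @param schema A [variable_schema()] describing the analysis columns.
#' @param sep Field separator, default `","`.
#' @return A `cohort_table`: list with elements `data` (validated
#'   data.frame), `schema`, `n`, `n_read`, `n_dropped` and
#'   `missing_by_column`.
#' @export
load_cohort <- function(path, schema, sep = ",") {
  df <- utils::read.csv(path, sep = sep, check.names = FALSE,
                        stringsAsFactors = FALSE, na.strings = c("NA", ""))
  cohort_table(df, schema)
}

#' Validate an in-memory data frame as a cohort table
#'
#' Same validation path as [load_cohort()]: required columns present, type
#' coercion, listwise deletion with a drop report, binary/level/range
#' checks.
#'
#' @param data A data.frame keyed by schema names.
#' @param schema A [variable_schema()].
#' @return A `cohort_table`.
#' @export
cohort_table <- function(data, schema) {
  stopifnot(inherits(schema, "variable_schema"), is.data.frame(data))
  required <- schema_names(schema)
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stop_unmetci("schema error: missing required column(s): ",
                 paste(missing_cols, collapse = ", "),
                 class = "unmetci_schema_error")
  }
  n_read <- nrow(data)
  df <- data[required]

  for (v in schema$vars) {
    col <- df[[v$name]]
    if (v$type %in% c("continuous", "binary") || v$role %in% c("ranking", "weight")) {
      # always double storage, so cohorts round-trip through CSV unchanged
      suppressWarnings(col <- as.numeric(col))
    }
    if (v$type == "binary") {
      bad <- which(!is.na(col) & !(col %in% c(0, 1)))
      if (length(bad)) {
        stop_unmetci("validation error: column '", v$name,
                     "' must be 0/1 but has value ", col[bad[1L]],
                     " at row ", bad[1L], class = "unmetci_validation_error")
      }
    }
    if (v$type == "categorical") {
      col <- as.character(col)
      bad <- which(!is.na(col) & !(col %in% v$levels))
      if (length(bad)) {
        stop_unmetci("validation error: column '", v$name,
                     "' has unknown level '", col[bad[1L]], "' at row ",
                     bad[1L], class = "unmetci_validation_error")
      }
    }
    df[[v$name]] <- col
  }

  # Listwise deletion over every schema-required column (id included: an
  # unidentifiable row is unusable for provenance).
  missing_by_column <- vapply(df, function(c) sum(is.na(c)), integer(1))
  keep <- stats::complete.cases(df)
  dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL

  rank_name <- schema_names(schema, "ranking")
  if (nrow(df) && any(df[[rank_name]] < 0)) {
    bad <- which(df[[rank_name]] < 0)[1L]
    stop_unmetci("validation error: ranking variable '", rank_name,
                 "' must be non-negative (row ", bad, ")",
                 class = "unmetci_validation_error")
  }
  w_name <- schema_names(schema, "weight")
  if (length(w_name) && nrow(df) && any(df[[w_name]] <= 0)) {
    stop_unmetci("validation error: weights must be positive",
                 class = "unmetci_validation_error")
  }

  structure(list(data = df, schema = schema, n = nrow(df), n_read = n_read,
                 n_dropped = dropped, missing_by_column = missing_by_column),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("<cohort_table> n = ", x$n, " (read ", x$n_read, ", dropped ",
      x$n_dropped, ")\n", sep = "")
  cat("  outcomes: ", paste(schema_names(x$schema, "outcome"), collapse = ", "),
      "\n  ranking:  ", schema_names(x$schema, "ranking"),
      "\n  covariates: ", paste(schema_names(x$schema, "covariate"),
                                collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a cohort table back to CSV
#' @param cohort A `cohort_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  utils::write.csv(cohort$data, path, row.names = FALSE)
  invisible(path)
}

# Per-respondent weights: declared weight column, else all ones.
cohort_weights <- function(cohort) {
  w_name <- schema_names(cohort$schema, "weight")
  if (length(w_name)) cohort$data[[w_name]] else rep(1, cohort$n)
}

#' Deflate a currency series to base-year prices
#'
#' `value_out = value_in * cpi[base_year] / cpi[year]`, leaving base-year
#' rows unchanged. Used to express incomes from several survey waves in
#' constant prices before log transformation.
#'
#' @param values Numeric currency series.
#' @param years Calendar year of each value (recycled if length 1).
#' @param cpi Named numeric vector of consumer-price-index values keyed by
#'   year (e.g. `c("2011" = 100, "2013" = 105.3)`).
#' @param base_year Year whose price level the output is expressed in.
#' @return Deflated numeric series.
#' @examples
#' deflate_to_base(100, 2013, c("2011" = 100, "2013" = 105), 2011)
#' @export
deflate_to_base <- function(values, years, cpi, base_year) {
  years <- as.character(rep_len(years, length(values)))
  base <- as.character(base_year)
  need <- unique(c(base, years))
  absent <- setdiff(need, names(cpi))
  if (length(absent)) {
    stop_unmetci("configuration error: CPI missing for year(s): ",
                 paste(absent, collapse = ", "),
                 class = "unmetci_config_error")
  }
  as.numeric(values * cpi[[base]] / unname(cpi[years]))
}

#' Log-plus-one income transform
#'
#' Natural logarithm of `x + 1`, the standard transform for right-skewed
#' income variables that keeps zero incomes finite.
#'
#' @param values Non-negative numeric series.
#' @return `log(values + 1)`.
#' @export
log1_transform <- function(values) {
  if (any(values < 0, na.rm = TRUE)) {
    stop_unmetci("domain error: log1_transform requires non-negative values",
                 class = "unmetci_domain_error")
  }
  log1p(values)
}

# ---------------------------------------------------------------------------
# Design matrices

#' Build a regression design matrix from a cohort
#'
#' Expands categorical covariates to 0/1 indicators omitting the declared
#' reference level; binary and continuous covariates pass through. Column
#' order follows schema order (and declared level order), never row order,
#' so repeated builds are byte-identical. Column means are recorded for
#' marginal-effect and elasticity computations.
#'
#' @param cohort A `cohort_table`.
#' @param covariates Covariate names to include; defaults to every
#'   schema variable with role `"covariate"`, in schema order.
#' @return A `design_matrix`: list with `X` (numeric matrix, no intercept),
#'   `means`, `terms` (data.frame mapping columns to source variables and
#'   levels) and `covariates`.
#' @export
build_design <- function(cohort, covariates = NULL) {
  stopifnot(inherits(cohort, "cohort_table"))
  schema <- cohort$schema
  all_cov <- schema_names(schema, "covariate")
  covariates <- covariates %||% all_cov
  unknown <- setdiff(covariates, all_cov)
  if (length(unknown)) {
    stop_unmetci("schema error: unknown covariate(s): ",
                 paste(unknown, collapse = ", "),
                 class = "unmetci_schema_error")
  }
  cols <- list()
  terms <- list()
  for (nm in covariates) {
    v <- schema_get(schema, nm)
    if (v$type == "categorical") {
      for (lev in setdiff(v$levels, v$reference)) {
        cn <- paste(nm, lev, sep = ".")
        cols[[cn]] <- as.numeric(cohort$data[[nm]] == lev)
        terms[[cn]] <- data.frame(column = cn, variable = nm, level = lev,
                                  stringsAsFactors = FALSE)
      }
    } else {
      cols[[nm]] <- as.numeric(cohort$data[[nm]])
      terms[[nm]] <- data.frame(column = nm, variable = nm, level = NA_character_,
                                stringsAsFactors = FALSE)
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  terms <- do.call(rbind, terms)
  rownames(terms) <- NULL
  structure(list(X = X, means = colMeans(X), terms = terms,
                 covariates = covariates, n = nrow(X)),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("<design_matrix> ", x$n, " x ", ncol(x$X), " (",
      paste(x$covariates, collapse = ", "), ")\n", sep = "")
  invisible(x)
}
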