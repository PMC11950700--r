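#' Describe the columns of a cohort table
#'
#' A feature schema classifies every column of a cohort table as
#' `continuous`, `binary`, `categorical`, `outcome` or `identifier`, and
#' optionally names the grouping columns used for group-wise imputation
#' (for example cancer type, age range and biological sex).
#'
#' @param columns Named character vector mapping column names to kinds.
#' @param impute_groups Character vector of column names used to group
#'   records when imputing missing values; must reference columns listed
#'   in `columns`. Empty means global mean/mode imputation.
#' @return An object of class `feature_schema`.
#' @examples
#' feature_schema(c(age = "continuous", sex = "binary", anx = "outcome"))
#' @export
feature_schema <- function(columns, impute_groups = character()) {
  kinds <- c("continuous", "binary", "categorical", "outcome", "identifier")
  if (is.null(names(columns)) || any(names(columns) == ""))
    stop("`columns` must be a named character vector")
  bad <- setdiff(unique(columns), kinds)
  if (length(bad))
    stop("unknown column kind(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(names(columns)))
    stop("duplicate column names: ",
         paste(unique(names(columns)[duplicated(names(columns))]), collapse = ", "))
  if (!any(columns == "outcome"))
    stop("schema must declare at least one outcome column")
  missing_keys <- setdiff(impute_groups, names(columns))
  if (length(missing_keys))
    stop("impute_groups reference unknown column(s): ",
         paste(missing_keys, collapse = ", "))
  structure(list(columns = columns, impute_groups = impute_groups),
            class = "feature_schema")
}

#' @export
print.feature_schema <- function(x, ...) {
  tab <- table(x$columns)
  cat("<feature_schema> ", length(x$columns), " columns (",
      paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), ")\n", sep = "")
  if (length(x$impute_groups))
    cat("  impute groups: ", paste(x$impute_groups, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Column names of given kinds, in table order.
schema_columns <- function(schema, kinds) {
  names(schema$columns)[schema$columns %in% kinds]
}

# Candidate predictor columns: everything that is not an outcome or an
# identifier. Categorical columns must be encoded before scoring.
candidate_features <- function(schema) {
  schema_columns(schema, c("continuous", "binary", "categorical"))
}

# Validate a table against its schema; used by load_dataset() and the
# synthetic generator round-trip.
validate_table <- function(table, schema) {
  missing_cols <- setdiff(names(schema$columns), names(table))
  if (length(missing_cols))
    stop("schema references missing column(s): ",
         paste(missing_cols, collapse = ", "))
  for (col in schema_columns(schema, "outcome")) {
    v <- table[[col]]
    if (anyNA(v) || !all(v %in% c(0, 1)))
      stop("outcome column '", col, "' must be binary-coded {0,1} with no missing values")
  }
  for (col in schema_columns(schema, "binary")) {
    v <- table[[col]]
    if (!all(v[!is.na(v)] %in% c(0, 1)))
      stop("binary column '", col, "' contains values outside {0,1}")
  }
  invisible(TRUE)
}

#' Load a cohort table and its schema from disk
#'
#' Reads a CSV cohort file (header row, UTF-8, "." decimal separator) and
#' a YAML schema with a `columns:` map of `name: kind` entries and an
#' optional `impute_groups:` list, validates them against each other, and
#' returns both.
#'
#' @param data_path Path to the cohort CSV.
#' @param schema_path Path to the schema YAML.
#' @return A list with elements `table` (data.frame) and `schema`
#'   (`feature_schema`).
#' @export
load_dataset <- function(data_path, schema_path) {
  if (!file.exists(data_path)) stop("data file not found: ", data_path)
  if (!file.exists(schema_path)) stop("schema file not found: ", schema_path)
  raw <- yaml::read_yaml(schema_path)
  if (is.null(raw$columns)) stop("schema YAML must contain a `columns:` map")
  cols <- vapply(raw$columns, function(x) {
    if (is.list(x)) as.character(x$kind) else as.character(x)
  }, character(1))
  schema <- feature_schema(cols,
                           impute_groups = as.character(raw$impute_groups %||% character()))
  table <- utils::read.csv(data_path, check.names = FALSE,
                           stringsAsFactors = FALSE, encoding = "UTF-8")
  validate_table(table, schema)
  list(table = table, schema = schema)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a cohort table, schema and optional ground truth to disk
#'
#' Emits the same CSV + schema YAML pair that [load_dataset()] consumes,
#' plus a `truth.json` when planted ground truth is supplied (as produced
#' by [generate_cohort()]).
#'
#' @param cohort List with `table`, `schema`, and optionally `truth`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$table, file.path(dir, "cohort.csv"), row.names = FALSE)
  yaml::write_yaml(
    list(columns = as.list(cohort$schema$columns),
         impute_groups = as.list(cohort$schema$impute_groups)),
    file.path(dir, "schema.yaml"))
  if (!is.null(cohort$truth))
    jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
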