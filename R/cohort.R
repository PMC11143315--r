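#' Construct a raw cohort from a data frame
#'
#' A raw cohort is an untyped patient table (rows = admissions) together with
#' its schema and an ordered preprocessing log. Missing values are `NA`.
#'
#' @param data a data.frame whose columns cover the schema's feature columns
#'   (and the label column, if the schema declares one and it is present).
#' @param schema a schema list (see [get_schema()]), or a schema id string.
#' @return an object of class \code{raw_cohort}: list with elements
#'   \code{data}, \code{schema}, \code{log}.
#' @export
raw_cohort <- function(data, schema = "custom") {
  if (is.character(schema)) {
    schema <- if (schema == "custom") {
      custom_schema(setdiff(names(data), c("label", "triage", "acuity")),
                    label_column = intersect(c("triage", "acuity", "label"),
                                             names(data))[1])
    } else get_schema(schema)
  }
  if (anyDuplicated(names(data))) {
    stop2("duplicated column names in cohort table")
  }
  missing_feats <- setdiff(schema$feature_names, names(data))
  if (length(missing_feats)) {
    stop2("schema error: missing feature columns: ",
          paste(missing_feats, collapse = ", "))
  }
  label <- schema$label_column
  if (length(label) && !is.na(label) && !label %in% names(data)) {
    stop2("schema error: label column '", label, "' not found")
  }
  keep <- c(schema$feature_names, if (length(label) && !is.na(label)) label)
  structure(list(data = data[, keep, drop = FALSE],
                 schema = schema, log = list()),
            class = "raw_cohort")
}

#' Load a tabular cohort from a CSV file
#'
#' Reads a delimited patient table with a header row. Empty cells, \code{NA}
#' and \code{NaN} are treated as missing.
#'
#' @param path path to a CSV file.
#' @param schema_id a built-in schema id (\code{"kaggle16"},
#'   \code{"mimic14"}), \code{"custom"}, or a schema list / path to a schema
#'   file (YAML/JSON).
#' @return a [raw_cohort()].
#' @export
load_cohort <- function(path, schema_id = "custom") {
  if (!file.exists(path)) stop2("cannot read cohort file: ", path)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L || !nzchar(trimws(header))) {
    stop2("schema error: empty cohort file: ", path)
  }
  cols <- scan(text = header, what = character(), sep = ",",
               quiet = TRUE, strip.white = TRUE)
  if (anyDuplicated(cols)) {
    stop2("schema error: duplicated header name(s): ",
          paste(unique(cols[duplicated(cols)]), collapse = ", "))
  }
  data <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                   na.strings = c("", "NA", "NaN"))
  schema <- if (is.list(schema_id)) {
    schema_id
  } else if (is.character(schema_id) && file.exists(schema_id) &&
             grepl("\\.(ya?ml|json)$", schema_id, ignore.case = TRUE)) {
    read_schema(schema_id)
  } else schema_id
  raw_cohort(data, schema)
}

#' @export
print.raw_cohort <- function(x, ...) {
  cat("Raw cohort (schema:", x$schema$schema_id, ")\n")
  cat("  rows:", nrow(x$data), " columns:", ncol(x$data), "\n")
  if (length(x$schema$label_column)) {
    cat("  label column:", x$schema$label_column, "\n")
  }
  if (length(x$log)) {
    cat("  log:", length(x$log), "preprocessing action(s)\n")
  }
  invisible(x)
}

log_action <- function(cohort, action, ...) {
  cohort$log[[length(cohort$log) + 1L]] <- c(list(action = action), list(...))
  cohort
}

#' Remove duplicate rows and rows with missing label / mandatory fields
#'
#' Exact duplicate rows are removed first (keeping the first occurrence);
#' then rows whose label is missing; then rows missing a mandatory
#' demographic field (per schema). Every removal is counted in the log, so
#' rows_in = rows_out + duplicates + missing_label + missing_mandatory.
#'
#' @param cohort a [raw_cohort()].
#' @param cfg a [preprocess_config()].
#' @return the cleaned \code{raw_cohort}, with updated log.
#' @export
drop_duplicates_and_nulls <- function(cohort, cfg = preprocess_config()) {
  stopifnot(inherits(cohort, "raw_cohort"))
  d <- cohort$data
  n_in <- nrow(d)
  n_dup <- 0L
  if (isTRUE(cfg$drop_duplicate_rows) && n_in > 0L) {
    dup <- duplicated(d)
    n_dup <- sum(dup)
    d <- d[!dup, , drop = FALSE]
  }
  n_mlab <- 0L
  label <- cohort$schema$label_column
  if (isTRUE(cfg$drop_rows_missing_label) && length(label) &&
      !is.na(label) && label %in% names(d)) {
    miss <- is.na(d[[label]])
    n_mlab <- sum(miss)
    d <- d[!miss, , drop = FALSE]
  }
  n_mand <- 0L
  mand <- intersect(cohort$schema$mandatory, names(d))
  if (length(mand)) {
    miss <- Reduce(`|`, lapply(d[mand], is.na), logical(nrow(d)))
    n_mand <- sum(miss)
    d <- d[!miss, , drop = FALSE]
  }
  rownames(d) <- NULL
  cohort$data <- d
  log_action(cohort, "drop_duplicates_and_nulls",
             rows_in = n_in, duplicates_removed = n_dup,
             missing_label_removed = n_mlab,
             missing_mandatory_removed = n_mand, rows_out = nrow(d))
}

# Mode of a vector ignoring NA; ties broken toward the smallest value under
# the column's natural ordering (numeric order, else lexicographic).
column_mode <- function(x, name = "column") {
  x <- x[!is.na(x)]
  if (length(x) == 0L) {
    stop2("imputation error: column '", name, "' has no observed values")
  }
  tab <- table(x)
  cand <- names(tab)[tab == max(tab)]
  best <- if (is.numeric(x)) {
    cand[which.min(as.numeric(cand))]
  } else {
    sort(cand)[1L]
  }
  if (is.numeric(x)) as.numeric(best) else best
}

#' Impute missing feature values with the column mode
#'
#' Each missing cell is replaced by the most frequent observed value of its
#' column; ties are broken toward the smallest value under the column's
#' natural ordering. The label column is never imputed.
#'
#' @param cohort a [raw_cohort()].
#' @return the imputed \code{raw_cohort}.
#' @export
impute_mode <- function(cohort) {
  stopifnot(inherits(cohort, "raw_cohort"))
  d <- cohort$data
  feats <- intersect(cohort$schema$feature_names, names(d))
  n_filled <- 0L
  for (col in feats) {
    miss <- is.na(d[[col]])
    if (any(miss)) {
      d[[col]][miss] <- column_mode(d[[col]], col)
      n_filled <- n_filled + sum(miss)
    }
  }
  cohort$data <- d
  log_action(cohort, "impute_mode", cells_filled = n_filled)
}

#' Integer-encode categorical columns
#'
#' Each categorical feature column (per schema) and the label column are
#' mapped to integers \code{0..k-1} by lexicographic order of the distinct
#' observed values. The mappings are returned on the cohort so the encoding
#' is invertible.
#'
#' @param cohort a [raw_cohort()] with no missing values in categorical
#'   columns.
#' @return the cohort with categorical columns replaced by integer codes and
#'   an \code{encoders} element (named list of value -> integer maps).
#' @export
encode_categoricals <- function(cohort) {
  stopifnot(inherits(cohort, "raw_cohort"))
  d <- cohort$data
  label <- cohort$schema$label_column
  cat_cols <- intersect(cohort$schema$categorical, names(d))
  if (length(label) && !is.na(label) && label %in% names(d)) {
    cat_cols <- union(cat_cols, label)
  }
  encoders <- list()
  for (col in cat_cols) {
    vals <- as.character(d[[col]])
    lev <- sort(unique(vals[!is.na(vals)]))
    map <- stats::setNames(seq_along(lev) - 1L, lev)
    code <- map[vals]
    if (any(is.na(code) & !is.na(vals))) {
      stop2("encoding error: unseen category in column '", col, "'")
    }
    d[[col]] <- unname(as.integer(code))
    encoders[[col]] <- map
  }
  cohort$data <- d
  cohort$encoders <- encoders
  log_action(cohort, "encode_categoricals", columns = length(cat_cols))
}

#' Decode integer codes back to category values
#'
#' @param codes integer vector of codes.
#' @param encoder a value -> integer map as stored in
#'   \code{cohort$encoders}.
#' @return character vector of original category values.
#' @export
decode_categorical <- function(codes, encoder) {
  names(encoder)[match(codes, encoder)]
}

#' Min-max scale a numeric matrix column-wise to [0, 1]
#'
#' Each column is mapped by \code{(x - min) / (max - min)}; constant columns
#' map to 0.
#'
#' @param X numeric matrix.
#' @return matrix of the same shape with entries in \code{[0, 1]}.
#' @export
minmax_scale <- function(X) {
  X <- as.matrix(X)
  lo <- apply(X, 2L, min)
  hi <- apply(X, 2L, max)
  rng <- hi - lo
  out <- sweep(X, 2L, lo, `-`)
  nz <- rng > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2L, rng[nz], `/`)
  out[, !nz] <- 0
  out
}
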