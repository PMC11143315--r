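#' Preprocessing configuration
#'
#' Controls the cleaning workflow applied by [preprocess_cohort()], in order:
#' duplicate/null removal, mode imputation, label encoding, class balancing,
#' min-max scaling.
#'
#' @param drop_duplicate_rows drop exact duplicate rows (first kept).
#' @param drop_rows_missing_label drop rows whose label is missing.
#' @param impute_strategy only \code{"column-mode"} is defined.
#' @param balance a [balance_config()].
#' @param scale only \code{"min-max"} is defined.
#' @return a list of class \code{preprocess_config}.
#' @export
preprocess_config <- function(drop_duplicate_rows = TRUE,
                              drop_rows_missing_label = TRUE,
                              impute_strategy = "column-mode",
                              balance = balance_config(),
                              scale = "min-max") {
  stopifnot(identical(impute_strategy, "column-mode"),
            identical(scale, "min-max"),
            inherits(balance, "balance_config"))
  structure(list(drop_duplicate_rows = drop_duplicate_rows,
                 drop_rows_missing_label = drop_rows_missing_label,
                 impute_strategy = impute_strategy,
                 balance = balance, scale = scale),
            class = "preprocess_config")
}

#' Run the full preprocessing workflow
#'
#' Applies, in order: duplicate and null-row removal, column-mode imputation,
#' integer encoding of categorical columns, class balancing (SMOTE by
#' default), and min-max scaling to \code{[0, 1]}. The returned object is
#' model-ready: a dense numeric feature matrix with no missing entries and an
#' integer class vector.
#'
#' @param cohort a [raw_cohort()] whose schema declares a label column.
#' @param cfg a [preprocess_config()].
#' @return an object of class \code{prepared_cohort}: list with
#'   \code{X} (n x F matrix in \code{[0,1]}), \code{y} (integer labels in
#'   \code{0..C-1}), \code{feature_names}, \code{class_names},
#'   \code{encoders}, \code{balance_info}, and \code{log} (ordered list of
#'   preprocessing actions with row counts).
#' @export
#' @examples
#' gen <- generate_cohort(cohort_spec(n = 200, seed = 1))
#' pc <- preprocess_cohort(gen$cohort,
#'   preprocess_config(balance = balance_config("none")))
#' range(pc$X)
preprocess_cohort <- function(cohort, cfg = preprocess_config()) {
  stopifnot(inherits(cohort, "raw_cohort"),
            inherits(cfg, "preprocess_config"))
  label <- cohort$schema$label_column
  if (!length(label) || is.na(label) || !label %in% names(cohort$data)) {
    stop2("schema error: preprocessing requires a label column")
  }
  c1 <- drop_duplicates_and_nulls(cohort, cfg)
  c2 <- impute_mode(c1)
  c3 <- encode_categoricals(c2)
  feats <- c3$schema$feature_names
  X <- as.matrix(c3$data[, feats, drop = FALSE])
  if (!is.numeric(X)) {
    stop2("schema error: non-numeric feature column(s) after encoding; ",
          "declare them categorical in the schema")
  }
  y <- as.integer(c3$data[[label]])
  bal <- balance_classes(X, y, cfg$balance)
  c3 <- log_action(c3, "balance_classes", method = cfg$balance$method,
                   rows_in = nrow(X), rows_out = nrow(bal$X))
  Xs <- minmax_scale(bal$X)
  c3 <- log_action(c3, "minmax_scale", columns = ncol(Xs))
  class_map <- c3$encoders[[label]]
  structure(list(
    X = Xs,
    y = bal$y,
    feature_names = feats,
    class_names = if (!is.null(class_map)) names(class_map)
                  else as.character(sort(unique(y))),
    encoders = c3$encoders,
    balance_info = bal$info,
    log = c3$log
  ), class = "prepared_cohort")
}

#' @export
print.prepared_cohort <- function(x, ...) {
  cat("Prepared cohort:", nrow(x$X), "patients x", ncol(x$X), "features\n")
  cat("  classes:", paste(x$class_names, collapse = ", "), "\n")
  cat("  class counts:",
      paste(table(factor(x$y, levels = seq_along(x$class_names) - 1L)),
            collapse = " / "), "\n")
  for (e in x$log) {
    extras <- e[setdiff(names(e), "action")]
    cat("  -", e$action,
        paste(sprintf("%s=%s", names(extras), unlist(extras)),
              collapse = " "), "\n")
  }
  invisible(x)
}

#' Serialize a prepared cohort to disk
#'
#' Writes \code{features.csv} (the scaled matrix), \code{labels.csv}
#' (integer code and class name per row) and \code{log.json} (the
#' preprocessing log) into \code{dir}.
#'
#' @param pc a \code{prepared_cohort}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_prepared <- function(pc, dir) {
  stopifnot(inherits(pc, "prepared_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  feat <- as.data.frame(pc$X)
  names(feat) <- pc$feature_names
  write.csv(feat, file.path(dir, "features.csv"), row.names = FALSE)
  write.csv(data.frame(y = pc$y, class = pc$class_names[pc$y + 1L]),
            file.path(dir, "labels.csv"), row.names = FALSE)
  jsonlite::write_json(pc$log, file.path(dir, "log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
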