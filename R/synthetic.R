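#' Specification of a synthetic patient cohort
#'
#' Describes a schema-conformant cohort with class-correlated Gaussian
#' cluster structure in the numeric features, per-class multinomial tilt in
#' the categorical features, and controllable data-quality defects
#' (duplicates, missing cells, missing labels). Such cohorts let every
#' downstream stage — cleaning, balancing, graph construction, GNN training —
#' be exercised without external data.
#'
#' @param n number of distinct rows to generate (defects are injected on
#'   top: \code{round(duplicate_rate * n)} duplicate copies are appended).
#' @param schema_id \code{"kaggle16"} or \code{"mimic14"}.
#' @param class_proportions length-C vector on the simplex; default is an
#'   imbalanced triage mix (most patients low severity).
#' @param separation Euclidean distance between every pair of class
#'   centroids in the numeric feature space (0 = no class signal).
#' @param noise_sd within-class standard deviation of each numeric feature.
#' @param missing_rate fraction of non-mandatory feature cells set missing.
#' @param missing_label_rate fraction of rows whose label is set missing.
#' @param duplicate_rate fraction of rows duplicated verbatim.
#' @param cat_signal multinomial tilt strength for categorical features:
#'   each class's preferred level gets weight \code{1 + cat_signal}, other
#'   levels weight 1 (0 = uninformative categoricals).
#' @param seed integer seed; the same spec and seed reproduce the cohort
#'   bit-identically.
#' @return a list of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n, schema_id = "kaggle16",
                        class_proportions = c(0.10, 0.18, 0.30, 0.42),
                        separation = 4, noise_sd = 1,
                        missing_rate = 0.01, missing_label_rate = 0.02,
                        duplicate_rate = 0.03, cat_signal = 2, seed = 1L) {
  stopifnot(is_count(n), separation >= 0, noise_sd >= 0,
            missing_rate >= 0, missing_rate < 1,
            missing_label_rate >= 0, missing_label_rate < 1,
            duplicate_rate >= 0, duplicate_rate < 1,
            cat_signal >= 0,
            all(class_proportions > 0),
            abs(sum(class_proportions) - 1) < 1e-8)
  structure(list(n = as.integer(n), schema_id = schema_id,
                 class_proportions = class_proportions,
                 separation = separation, noise_sd = noise_sd,
                 missing_rate = missing_rate,
                 missing_label_rate = missing_label_rate,
                 duplicate_rate = duplicate_rate,
                 cat_signal = cat_signal, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default synthetic profile matching the 16-feature admission schema
#'
#' @param n rows; @param seed seed; @param ... overrides passed to
#'   [cohort_spec()].
#' @return a \code{cohort_spec} with \code{schema_id = "kaggle16"}: 16
#'   feature columns (two categorical) plus a 4-level triage label.
#' @export
kaggle16_profile <- function(n = 2000L, seed = 1L, ...) {
  cohort_spec(n = n, schema_id = "kaggle16", seed = seed, ...)
}

#' Default synthetic profile matching the 14-feature ED triage schema
#'
#' @param n rows; @param seed seed; @param ... overrides passed to
#'   [cohort_spec()].
#' @return a \code{cohort_spec} with \code{schema_id = "mimic14"}: 14
#'   feature columns (six categorical) plus a 4-level acuity label.
#' @export
mimic14_profile <- function(n = 2000L, seed = 1L, ...) {
  cohort_spec(n = n, schema_id = "mimic14", seed = seed, ...)
}

#' Generate a synthetic patient cohort
#'
#' Numeric features are drawn per class from isotropic Gaussian clusters
#' whose centroids are mutually \code{separation} apart; categorical
#' features from per-class tilted multinomials over the schema's declared
#' levels. Duplicate rows, missing feature cells (never in mandatory
#' columns) and missing labels are then injected at the spec's rates, and
#' the injection bookkeeping is returned as ground truth.
#'
#' @param spec a [cohort_spec()].
#' @return list with \code{cohort} (a [raw_cohort()]) and \code{truth}, a
#'   list with \code{injected_duplicates}, \code{injected_missing_cells},
#'   \code{injected_missing_labels}, \code{class_centroids} (C x F_num) and
#'   \code{class_counts}.
#' @export
#' @examples
#' gen <- generate_cohort(cohort_spec(n = 100, seed = 42))
#' gen$truth$injected_duplicates
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  schema <- get_schema(spec$schema_id)
  C <- length(spec$class_proportions)
  num_cols <- setdiff(schema$feature_names, schema$categorical)
  cat_cols <- schema$categorical
  Fnum <- length(num_cols)
  if (spec$separation > 0 && Fnum < C) {
    stop2("spec error: need at least ", C,
          " numeric features to separate ", C, " classes")
  }
  counts <- apportion(spec$class_proportions, spec$n)
  if (any(counts == 0L)) {
    stop2("spec error: class proportions leave a class empty at n = ",
          spec$n)
  }
  class_names <- schema$levels[[schema$label_column]]
  if (is.null(class_names) || length(class_names) != C) {
    class_names <- paste0("class", seq_len(C))
  }
  with_seed(spec$seed, {
    # centroids: scaled standard basis vectors, pairwise distance = separation
    centroids <- matrix(0, C, Fnum,
                        dimnames = list(class_names, num_cols))
    if (spec$separation > 0) {
      for (c in seq_len(C)) {
        centroids[c, c] <- spec$separation / sqrt(2)
      }
    }
    y <- rep(seq_len(C), counts)
    n <- spec$n
    Xnum <- centroids[y, , drop = FALSE] +
      matrix(rnorm(n * Fnum, sd = spec$noise_sd), n, Fnum)
    d <- as.data.frame(Xnum)
    names(d) <- num_cols
    for (col in cat_cols) {
      lev <- schema$levels[[col]] %||% c("A", "B")
      k <- length(lev)
      vals <- character(n)
      for (c in seq_len(C)) {
        w <- rep(1, k)
        w[((c - 1L) %% k) + 1L] <- 1 + spec$cat_signal
        idx <- which(y == c)
        vals[idx] <- sample(lev, length(idx), replace = TRUE,
                            prob = w / sum(w))
      }
      d[[col]] <- vals
    }
    d <- d[, schema$feature_names]
    d[[schema$label_column]] <- class_names[y]
    # shuffle row order so class blocks are not contiguous
    ord <- sample.int(n)
    d <- d[ord, , drop = FALSE]
    rownames(d) <- NULL
    # inject missing feature cells (non-mandatory columns only)
    cand_cols <- setdiff(schema$feature_names, schema$mandatory)
    n_cells <- round(spec$missing_rate * n * length(cand_cols))
    if (n_cells > 0) {
      cell_id <- sample.int(n * length(cand_cols), n_cells)
      ri <- ((cell_id - 1L) %% n) + 1L
      ci <- ((cell_id - 1L) %/% n) + 1L
      for (k in seq_len(n_cells)) {
        d[ri[k], cand_cols[ci[k]]] <- NA
      }
    }
    # inject missing labels
    n_mlab <- round(spec$missing_label_rate * n)
    if (n_mlab > 0) {
      d[sample.int(n, n_mlab), schema$label_column] <- NA
    }
    # append exact duplicate rows
    n_dup <- round(spec$duplicate_rate * n)
    if (n_dup > 0) {
      d <- rbind(d, d[sample.int(n, n_dup), , drop = FALSE])
      rownames(d) <- NULL
    }
    list(
      cohort = raw_cohort(d, schema),
      truth = list(injected_duplicates = n_dup,
                   injected_missing_cells = n_cells,
                   injected_missing_labels = n_mlab,
                   class_centroids = centroids,
                   class_counts = stats::setNames(counts, class_names))
    )
  })
}
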