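test_that("load_cohort reads a CSV verbatim and validates the header", {
  d <- data.frame(age = c(30, 41, 55), bp = c(120, 130, 110),
                  label = c("Red", "Green", "Green"))
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(d, f, row.names = FALSE)
  rc <- load_cohort(f, "custom")
  expect_s3_class(rc, "raw_cohort")
  expect_equal(nrow(rc$data), 3L)
  expect_equal(rc$data$age, d$age)
  expect_identical(rc$schema$label_column, "label")

  # empty file is a schema error
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(), f2)
  expect_error(load_cohort(f2), "empty")

  # duplicated header name is a schema error
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b,a", "1,2,3"), f3)
  expect_error(load_cohort(f3), "duplicated header")

  expect_error(load_cohort("/nonexistent/file.csv"), "cannot read")
})

test_that("missing-value encodings NA/NaN/empty are recognized", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y,label", "1,,Red", "NA,2,Green", "NaN,3,Red"), f)
  rc <- load_cohort(f, "custom")
  expect_true(is.na(rc$data$y[1]))
  expect_true(is.na(rc$data$x[2]))
  expect_true(is.na(rc$data$x[3]))
})

test_that("cleaning removes duplicates, missing labels and mandatory gaps", {
  d <- data.frame(x = c(1, 1, 2, 3, 4), g = c("M", "M", "F", NA, "F"),
                  label = c("a", "a", NA, "b", "b"))
  schema <- list(schema_id = "custom", feature_names = c("x", "g"),
                 categorical = "g", label_column = "label",
                 mandatory = "g", levels = list())
  rc <- raw_cohort(d, schema)
  out <- drop_duplicates_and_nulls(rc)
  # row2 = duplicate of row1; row3 missing label; row4 missing gender
  expect_equal(nrow(out$data), 2L)
  lg <- out$log[[1]]
  expect_equal(lg$duplicates_removed, 1L)
  expect_equal(lg$missing_label_removed, 1L)
  expect_equal(lg$missing_mandatory_removed, 1L)
  # count conservation
  expect_equal(lg$rows_in,
               lg$rows_out + lg$duplicates_removed +
                 lg$missing_label_removed + lg$missing_mandatory_removed)
})

test_that("cleaning matches a brute-force row filter on a random cohort", {
  set.seed(7)
  d <- data.frame(x = sample(1:4, 10, TRUE), y = sample(1:2, 10, TRUE),
                  label = sample(c("a", "b"), 10, TRUE))
  d[c(3, 8), ] <- d[c(1, 2), ]          # 2 duplicates
  d$label[5] <- NA                      # 1 missing label
  rc <- toy_cohort(d)
  out <- drop_duplicates_and_nulls(rc)
  # independent oracle: row-by-row filter
  seen <- character()
  keep <- logical(nrow(d))
  for (i in seq_len(nrow(d))) {
    key <- paste(d[i, ], collapse = "|")
    if (!(key %in% seen) && !is.na(d$label[i])) keep[i] <- TRUE
    seen <- c(seen, key)
  }
  expect_equal(out$data, d[keep, ], ignore_attr = TRUE)
})

test_that("mode imputation fills with the column mode, smallest on ties", {
  d <- data.frame(a = c("a", "a", "b", NA),
                  b = c(1, 2, NA, NA),
                  label = c("x", "x", "y", "y"))
  rc <- toy_cohort(d)
  rc$schema$categorical <- "a"
  out <- impute_mode(rc)
  expect_equal(out$data$a, c("a", "a", "b", "a"))
  # tie between 1 and 2 -> smallest value
  expect_equal(out$data$b, c(1, 2, 1, 1))

  d2 <- data.frame(a = c(NA_real_, NA_real_), label = c("x", "y"))
  expect_error(impute_mode(toy_cohort(d2)), "no observed values")
})

test_that("imputation matches an independent frequency count on a 5x3 table", {
  set.seed(11)
  d <- data.frame(a = sample(1:3, 5, TRUE), b = sample(1:3, 5, TRUE),
                  c = sample(1:3, 5, TRUE))
  d$label <- "z"
  miss <- cbind(c(1, 3, 5), c(1, 2, 3))
  for (k in 1:3) d[miss[k, 1], miss[k, 2]] <- NA
  out <- impute_mode(toy_cohort(d))
  for (k in 1:3) {
    col <- d[[miss[k, 2]]]
    tab <- table(col[!is.na(col)])
    expected <- min(as.numeric(names(tab)[tab == max(tab)]))
    expect_equal(out$data[miss[k, 1], miss[k, 2]], expected)
  }
  expect_false(anyNA(out$data))
})

test_that("categorical encoding is lexicographic, bijective and invertible", {
  d <- data.frame(res = c("Urban", "Rural", "Urban"),
                  smoke = c("never smoked", "smoke", "Unknown"),
                  label = c("Red", "Green", "Red"))
  schema <- list(schema_id = "custom", feature_names = c("res", "smoke"),
                 categorical = c("res", "smoke"), label_column = "label",
                 mandatory = character(), levels = list())
  rc <- raw_cohort(d, schema)
  out <- encode_categoricals(rc)
  expect_equal(out$data$res, c(1L, 0L, 1L))  # Rural=0, Urban=1
  expect_equal(unname(out$encoders$smoke),
               0:2)
  expect_equal(names(sort(out$encoders$smoke)),
               sort(c("never smoked", "smoke", "Unknown")))
  # round trip
  expect_equal(decode_categorical(out$data$res, out$encoders$res), d$res)
  expect_equal(decode_categorical(out$data$smoke, out$encoders$smoke),
               d$smoke)
  # 4 categories -> a bijection onto 0..3
  d4 <- data.frame(s = c("a", "d", "b", "c"), label = letters[1:4])
  s4 <- list(schema_id = "custom", feature_names = "s", categorical = "s",
             label_column = "label", mandatory = character(),
             levels = list())
  e4 <- encode_categoricals(raw_cohort(d4, s4))
  expect_setequal(e4$data$s, 0:3)
})

test_that("min-max scaling maps to [0,1] with constant columns at 0", {
  expect_equal(minmax_scale(cbind(c(2, 4, 6))), cbind(c(0, 0.5, 1)))
  expect_equal(minmax_scale(cbind(c(5, 5))), cbind(c(0, 0)))
  set.seed(3)
  X <- matrix(rnorm(40), 10, 4)
  S <- minmax_scale(X)
  expect_equal(unname(apply(S, 2, min)), rep(0, 4))
  expect_equal(unname(apply(S, 2, max)), rep(1, 4))
})

test_that("full preprocessing composes the steps in workflow order", {
  gen <- generate_cohort(cohort_spec(n = 100, missing_rate = 0,
                                     missing_label_rate = 0,
                                     duplicate_rate = 0, seed = 5))
  pc <- preprocess_cohort(gen$cohort,
                          preprocess_config(balance = balance_config("none")))
  expect_s3_class(pc, "prepared_cohort")
  expect_equal(nrow(pc$X), 100L)
  expect_true(all(pc$X >= 0 & pc$X <= 1))
  expect_false(anyNA(pc$X))
  expect_equal(sort(unique(pc$y)), 0:3)
  expect_equal(length(pc$class_names), 4L)
  acts <- vapply(pc$log, `[[`, "", "action")
  expect_equal(acts, c("drop_duplicates_and_nulls", "impute_mode",
                       "encode_categoricals", "balance_classes",
                       "minmax_scale"))
})

test_that("preprocessing is idempotent on already-prepared data", {
  gen <- generate_cohort(cohort_spec(n = 150, seed = 2))
  pc <- preprocess_cohort(gen$cohort)
  # wrap the prepared matrix back into a raw cohort and preprocess again
  d <- as.data.frame(pc$X)
  names(d) <- pc$feature_names
  d$label <- as.character(pc$y)
  pc2 <- preprocess_cohort(toy_cohort(d),
                           preprocess_config(balance = balance_config("none")))
  expect_lt(max(abs(pc2$X - pc$X)), 1e-12)
  expect_equal(pc2$y, pc$y)
})

test_that("preprocessing is deterministic for identical input and config", {
  gen <- generate_cohort(cohort_spec(n = 120, seed = 9))
  a <- preprocess_cohort(gen$cohort)
  b <- preprocess_cohort(gen$cohort)
  expect_identical(a$X, b$X)
  expect_identical(a$y, b$y)
})

test_that("prepared cohorts serialize to CSV + JSON log", {
  gen <- generate_cohort(cohort_spec(n = 60, seed = 4))
  pc <- preprocess_cohort(gen$cohort,
                          preprocess_config(balance = balance_config("none")))
  dir <- withr::local_tempdir()
  write_prepared(pc, dir)
  feat <- read.csv(file.path(dir, "features.csv"), check.names = FALSE)
  lab <- read.csv(file.path(dir, "labels.csv"))
  expect_equal(dim(feat), dim(pc$X))
  expect_equal(lab$y, pc$y)
  lg <- jsonlite::read_json(file.path(dir, "log.json"))
  expect_equal(length(lg), length(pc$log))
})

test_that("schema files round-trip through YAML", {
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(feature_names = c("a", "b"), label_column = "y",
                        categorical = "b", mandatory = "a"), f)
  s <- read_schema(f)
  expect_equal(s$feature_names, c("a", "b"))
  expect_equal(s$categorical, "b")
  expect_error(read_schema("/nonexistent.yaml"), "not found")
})
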