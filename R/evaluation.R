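#' Stratified train / test / validation node split
#'
#' Mirrors the tabular protocol: a \code{test_frac} share of the labeled
#' nodes goes to the test set, then a \code{val_of_test} share of the test
#' set is re-assigned to validation; the remainder trains. Splitting is
#' stratified by class (largest-remainder apportionment, per-class
#' proportions within 1) and deterministic under \code{seed}. For n = 1000
#' and the defaults this yields 700 / 300 -> 210 test + 90 validation.
#'
#' @param y integer class labels (NA = unlabeled, excluded from all masks).
#' @param test_frac fraction of labeled nodes in the test set (default 0.3).
#' @param val_of_test fraction of the test set moved to validation
#'   (default 0.3).
#' @param stratified stratify by class (default TRUE).
#' @param seed integer seed.
#' @return an object of class \code{split_masks}: list of logical vectors
#'   \code{train}, \code{validation}, \code{test} (pairwise disjoint, union
#'   = labeled nodes) plus the fractions and seed.
#' @export
make_split <- function(y, test_frac = 0.3, val_of_test = 0.3,
                       stratified = TRUE, seed = 1L) {
  stopifnot(test_frac > 0, test_frac < 1, val_of_test >= 0,
            val_of_test < 1)
  n <- length(y)
  labeled <- which(!is.na(y))
  with_seed(seed, {
    if (stratified) {
      classes <- sort(unique(y[labeled]))
      if (any(table(y[labeled]) < 2L)) {
        stop2("split error: a class has fewer than 2 labeled members")
      }
      by_class <- lapply(classes, function(cl) {
        idx <- labeled[y[labeled] == cl]
        idx[sample.int(length(idx))]
      })
      sizes <- lengths(by_class)
      n_test_tot <- round(test_frac * length(labeled))
      take_test <- apportion(sizes, n_test_tot)
      test_all <- unlist(mapply(function(idx, k) head(idx, k),
                                by_class, take_test, SIMPLIFY = FALSE),
                         use.names = FALSE)
      train <- setdiff(labeled, test_all)
      # validation: val_of_test of the test set, stratified again
      n_val_tot <- round(val_of_test * length(test_all))
      test_by_class <- mapply(function(idx, k) head(idx, k),
                              by_class, take_test, SIMPLIFY = FALSE)
      take_val <- apportion(pmax(lengths(test_by_class), 1e-9), n_val_tot)
      val <- unlist(mapply(function(idx, k) head(idx, k),
                           test_by_class, take_val, SIMPLIFY = FALSE),
                    use.names = FALSE)
      test <- setdiff(test_all, val)
    } else {
      perm <- labeled[sample.int(length(labeled))]
      n_test_tot <- round(test_frac * length(labeled))
      test_all <- head(perm, n_test_tot)
      train <- setdiff(labeled, test_all)
      n_val_tot <- round(val_of_test * length(test_all))
      val <- head(test_all, n_val_tot)
      test <- setdiff(test_all, val)
    }
    mk <- function(idx) {
      v <- logical(n)
      v[idx] <- TRUE
      v
    }
    structure(list(train = mk(train), validation = mk(val),
                   test = mk(test),
                   fractions = c(test = test_frac,
                                 val_of_test = val_of_test),
                   stratified = stratified, seed = seed),
              class = "split_masks")
  })
}

#' @export
print.split_masks <- function(x, ...) {
  cat("Split masks: train", sum(x$train), "/ validation",
      sum(x$validation), "/ test", sum(x$test),
      if (x$stratified) "(stratified)" else "", "\n")
  invisible(x)
}

#' Classification accuracy
#'
#' @param pred,true equal-length vectors of predicted and true classes.
#' @return fraction of matches in \code{[0, 1]}.
#' @export
accuracy <- function(pred, true) {
  if (length(pred) != length(true)) stop2("length mismatch")
  mean(pred == true)
}

#' Confusion matrix of class counts
#'
#' @param pred,true equal-length integer class vectors (codes 0..C-1).
#' @param C number of classes (default inferred).
#' @return C x C integer matrix; rows = true class, columns = predicted.
#' @export
confusion_counts <- function(pred, true, C = NULL) {
  if (length(pred) != length(true)) stop2("length mismatch")
  C <- C %||% (max(c(pred, true)) + 1L)
  lv <- seq_len(C) - 1L
  table(true = factor(true, levels = lv),
        predicted = factor(pred, levels = lv))
}

per_class_metrics <- function(cm) {
  cm <- unclass(cm)
  tp <- diag(cm)
  prec <- tp / pmax(colSums(cm), 1)
  rec <- tp / pmax(rowSums(cm), 1)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  data.frame(class = rownames(cm), precision = prec, recall = rec,
             f1 = f1, support = rowSums(cm), row.names = NULL)
}

experiment_report <- function(kind, config, stats, acc, cm, seed) {
  pcm <- per_class_metrics(cm)
  structure(list(
    kind = kind,
    config = config,
    network = stats,
    accuracy = acc,
    confusion = cm,
    per_class = pcm,
    macro_f1 = mean(pcm$f1),
    seed = seed,
    hash = fnv1a(as.character(config_string(config)))
  ), class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Experiment report [", x$kind, "] (hash ", x$hash, ")\n", sep = "")
  if (!is.null(x$network)) print(x$network, row.names = FALSE)
  cat("accuracy:", paste(names(x$accuracy), round(x$accuracy, 4),
                         sep = "=", collapse = " "), "\n")
  cat("macro F1:", round(x$macro_f1, 4), "\n")
  invisible(x)
}

#' Run one end-to-end graph classification experiment
#'
#' Pipeline: preprocess the cohort (unless already prepared), build the
#' thresholded similarity graph, split the nodes, fit the GNN, and evaluate
#' on the held-out test nodes.
#'
#' By default class balancing happens before graph construction and hence
#' before the split, matching the preprocessing workflow; this lets
#' synthetic minority rows share information with test nodes and is
#' optimistic. Set \code{leakage_safe = TRUE} to split first and apply SMOTE
#' to training rows only (synthetic rows join the graph as extra training
#' nodes).
#'
#' @param cohort a [raw_cohort()] or \code{prepared_cohort}.
#' @param metric a [metric_spec()].
#' @param arch architecture family (see [make_model()]), or a
#'   \code{gnn_model}.
#' @param preprocess_cfg a [preprocess_config()].
#' @param seed seed shared by split and training.
#' @param leakage_safe split before balancing (see above).
#' @param ... further arguments to [triage_gnn()] (e.g. \code{epochs}).
#' @return an \code{experiment_report} with network statistics, per-split
#'   accuracy, the test confusion matrix and per-class precision/recall,
#'   plus the fit in attribute \code{"fit"}.
#' @export
run_experiment <- function(cohort, metric, arch = "sage5",
                           preprocess_cfg = preprocess_config(),
                           seed = 1L, leakage_safe = FALSE, ...) {
  if (leakage_safe) {
    pc0 <- if (inherits(cohort, "prepared_cohort")) cohort else {
      cfg0 <- preprocess_cfg
      cfg0$balance <- balance_config("none")
      preprocess_cohort(cohort, cfg0)
    }
    masks <- make_split(pc0$y, seed = seed)
    tr <- which(masks$train)
    bal <- balance_classes(pc0$X[tr, , drop = FALSE], pc0$y[tr],
                           preprocess_cfg$balance)
    n_extra <- nrow(bal$X) - length(tr)
    pc <- pc0
    if (n_extra > 0) {
      pc$X <- rbind(pc0$X, bal$X[-seq_along(tr), , drop = FALSE])
      pc$y <- c(pc0$y, bal$y[-seq_along(tr)])
      grow <- function(m) c(m, rep(FALSE, n_extra))
      masks$train <- c(masks$train, rep(TRUE, n_extra))
      masks$validation <- grow(masks$validation)
      masks$test <- grow(masks$test)
    }
  } else {
    pc <- if (inherits(cohort, "prepared_cohort")) cohort
          else preprocess_cohort(cohort, preprocess_cfg)
    masks <- make_split(pc$y, seed = seed)
  }
  g <- build_graph(pc, metric)
  fit <- if (inherits(arch, "gnn_model")) {
    triage_gnn(g, model = arch, masks = masks, seed = seed, ...)
  } else {
    triage_gnn(g, family = arch, masks = masks, seed = seed, ...)
  }
  test_idx <- which(masks$test)
  pred <- predict(fit)
  cm <- confusion_counts(pred[test_idx], g$y[test_idx], C = fit$model$C)
  cfg <- list(metric = metric$name, p = metric$p,
              threshold = metric$threshold,
              arch = if (is.character(arch)) arch else arch$family,
              leakage_safe = leakage_safe, seed = seed,
              train = fit$config)
  rep <- experiment_report("graph", cfg, network_stats(g), fit$accuracy,
                           cm, seed)
  attr(rep, "fit") <- fit
  rep
}

#' Threshold and architecture sensitivity analysis
#'
#' Runs one experiment per (metric, threshold, architecture) combination on
#' a shared prepared cohort and split seed, and tabulates test accuracy
#' against the threshold for each metric, alongside the SVM and KNN tabular
#' baselines trained on the same features and split.
#'
#' @param cohort a [raw_cohort()] or \code{prepared_cohort}.
#' @param grids named list: metric name -> threshold vector. Minkowski
#'   entries may be named \code{"minkowski"} with \code{p} supplied, or
#'   \code{"minkowski_p<k>"} to encode the order in the name.
#' @param archs architecture families to evaluate.
#' @param p Minkowski order for plain \code{"minkowski"} entries.
#' @param preprocess_cfg a [preprocess_config()].
#' @param seed shared split/training seed.
#' @param baselines include SVM/KNN tabular baselines (default TRUE).
#' @param ... further arguments to [triage_gnn()].
#' @return an object of class \code{sensitivity_analysis}: list with
#'   \code{reports}, \code{table} (metric, p, threshold, arch,
#'   test_accuracy) and \code{baselines}.
#' @export
sensitivity_analysis <- function(cohort,
                                 grids = list(cosine = c(0.98, 0.95, 0.94,
                                                         0.92, 0.90)),
                                 archs = c("gcn5", "gatv2", "sage5"),
                                 p = 10,
                                 preprocess_cfg = preprocess_config(),
                                 seed = 1L, baselines = TRUE, ...) {
  stopifnot(length(grids) > 0, all(lengths(grids) > 0))
  pc <- if (inherits(cohort, "prepared_cohort")) cohort
        else preprocess_cohort(cohort, preprocess_cfg)
  reports <- list()
  rows <- list()
  for (mname in names(grids)) {
    base_name <- sub("_p[0-9.]+$", "", mname)
    pp <- if (grepl("_p[0-9.]+$", mname)) {
      as.numeric(sub("^.*_p", "", mname))
    } else if (base_name == "minkowski") p else NULL
    for (th in grids[[mname]]) {
      ms <- metric_spec(base_name, threshold = th, p = pp)
      for (a in archs) {
        rep <- run_experiment(pc, ms, arch = a, seed = seed, ...)
        key <- paste(mname, th, a, sep = "|")
        reports[[key]] <- rep
        rows[[key]] <- data.frame(metric = base_name,
                                  p = pp %||% NA_real_, threshold = th,
                                  arch = a,
                                  test_accuracy =
                                    unname(rep$accuracy["test"]))
      }
    }
  }
  bl <- NULL
  if (baselines) {
    bl <- tabular_baselines(pc, seed = seed)
    for (b in bl) {
      rows[[paste0("baseline|", b$config$arch)]] <-
        data.frame(metric = "tabular", p = NA_real_, threshold = NA_real_,
                   arch = b$config$arch,
                   test_accuracy = unname(b$accuracy["test"]))
    }
  }
  structure(list(reports = reports,
                 table = do.call(rbind, c(unname(rows),
                                          list(make.row.names = FALSE))),
                 baselines = bl),
            class = "sensitivity_analysis")
}

#' @export
print.sensitivity_analysis <- function(x, ...) {
  cat("Sensitivity analysis:", length(x$reports), "graph experiments\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Plot accuracy against threshold per metric
#'
#' One panel per metric; one line per architecture; dashed horizontal lines
#' mark the tabular baselines.
#'
#' @param x a \code{sensitivity_analysis}; @param ... unused.
#' @export
plot.sensitivity_analysis <- function(x, ...) {
  tab <- x$table[x$table$metric != "tabular", ]
  mets <- unique(tab$metric)
  archs <- unique(tab$arch)
  op <- graphics::par(mfrow = c(1, max(1, length(mets))),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  bl <- x$table[x$table$metric == "tabular", ]
  for (m in mets) {
    sub <- tab[tab$metric == m, ]
    ths <- sort(unique(sub$threshold))
    M <- sapply(archs, function(a) {
      sa <- sub[sub$arch == a, ]
      sa$test_accuracy[match(ths, sa$threshold)]
    })
    graphics::matplot(ths, M, type = "b", pch = 19, lty = 1,
                      col = seq_along(archs), xlab = "threshold",
                      ylab = "test accuracy", main = m,
                      ylim = range(x$table$test_accuracy, na.rm = TRUE))
    if (nrow(bl)) {
      graphics::abline(h = bl$test_accuracy, lty = 2,
                       col = "grey40")
    }
    graphics::legend("bottomleft", archs, col = seq_along(archs),
                     lty = 1, pch = 19, bty = "n", cex = 0.8)
  }
  invisible(x)
}

#' Ablation variant descriptor
#'
#' @param removed_layers subset of \code{c(2, 3, 4)}: GraphSAGE layers to
#'   remove.
#' @param hidden_width width of the remaining hidden layers (8 or 64 in the
#'   standard grid).
#' @return a list of class \code{ablation_variant}.
#' @export
ablation_variant <- function(removed_layers, hidden_width) {
  stopifnot(all(removed_layers %in% 2:4), is_count(hidden_width))
  structure(list(removed_layers = sort(as.integer(removed_layers)),
                 hidden_width = as.integer(hidden_width)),
            class = "ablation_variant")
}

#' The standard 8-variant ablation grid
#'
#' Four removal patterns (layer 2, layer 3, layer 4, layers 2-4) crossed
#' with hidden widths 8 and 64.
#'
#' @return list of 8 [ablation_variant()]s.
#' @export
ablation_variants <- function() {
  pats <- list(2L, 3L, 4L, 2:4)
  out <- list()
  for (w in c(8L, 64L)) {
    for (pp in pats) {
      out[[length(out) + 1L]] <- ablation_variant(pp, w)
    }
  }
  out
}

#' GraphSAGE layer-ablation study
#'
#' Fits the five-layer GraphSAGE base model and each ablation variant on the
#' same graph and split, reporting test accuracy, parameter count and the
#' (re-chained) dimension sequence of every variant.
#'
#' @param graph a [patient_graph()] (typically the cosine-0.95 graph).
#' @param variants list of [ablation_variant()]s (default the 8-variant
#'   grid).
#' @param seed shared split/training seed.
#' @param ... further arguments to [triage_gnn()] (e.g. reduced
#'   \code{epochs}).
#' @return an object of class \code{ablation_study}: list with
#'   \code{reports} (base first) and \code{table}.
#' @export
ablation_study <- function(graph, variants = ablation_variants(),
                           seed = 1L, ...) {
  stopifnot(inherits(graph, "patient_graph"))
  Fdim <- ncol(graph$X)
  C <- max(graph$y, na.rm = TRUE) + 1L
  masks <- make_split(graph$y, seed = seed)
  fit_one <- function(model, tag) {
    fit <- triage_gnn(graph, model = model, masks = masks, seed = seed,
                      ...)
    test_idx <- which(masks$test)
    pred <- predict(fit)
    cm <- confusion_counts(pred[test_idx], graph$y[test_idx], C = C)
    cfg <- list(arch = tag, removed = model$removed_layers %||% integer(),
                width = model$hidden_width %||% NA_integer_, seed = seed)
    rep <- experiment_report("ablation", cfg, network_stats(graph),
                             fit$accuracy, cm, seed)
    attr(rep, "fit") <- fit
    rep
  }
  reports <- list(base = fit_one(make_model("sage5", Fdim, C, seed = seed),
                                 "sage5"))
  rows <- list(data.frame(variant = "base", removed = "none", width = NA,
                          n_params = n_params(attr(reports$base, "fit")),
                          test_accuracy =
                            unname(reports$base$accuracy["test"])))
  for (v in variants) {
    tag <- paste0("-L", paste(v$removed_layers, collapse = ""),
                  "_w", v$hidden_width)
    model <- make_sage_variant(Fdim, C, v$removed_layers, v$hidden_width,
                               seed = seed)
    reports[[tag]] <- fit_one(model, tag)
    rows[[length(rows) + 1L]] <-
      data.frame(variant = tag,
                 removed = paste(v$removed_layers, collapse = ","),
                 width = v$hidden_width, n_params = n_params(model),
                 test_accuracy = unname(reports[[tag]]$accuracy["test"]))
  }
  structure(list(reports = reports,
                 table = do.call(rbind, c(rows,
                                          list(make.row.names = FALSE)))),
            class = "ablation_study")
}

#' @export
print.ablation_study <- function(x, ...) {
  cat("GraphSAGE ablation study\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' SVM and KNN baselines on the tabular features
#'
#' Trains a radial-kernel SVM and a k-nearest-neighbour classifier on the
#' same prepared feature matrix and split protocol used for the graph
#' models, for a like-for-like comparison of graph versus tabular
#' classification.
#'
#' @param pc a \code{prepared_cohort} (or list with \code{X}, \code{y}).
#' @param seed split seed (shared with graph experiments).
#' @param masks optional [make_split()] masks (overrides \code{seed}).
#' @param knn_k neighbours for KNN (default 5).
#' @param ... passed to [e1071::svm()].
#' @return list of two \code{experiment_report}s named \code{svm},
#'   \code{knn}.
#' @export
tabular_baselines <- function(pc, seed = 1L, masks = NULL, knn_k = 5L,
                              ...) {
  X <- as.matrix(pc$X)
  y <- pc$y
  masks <- masks %||% make_split(y, seed = seed)
  tr <- which(masks$train)
  te <- which(masks$test)
  C <- max(y, na.rm = TRUE) + 1L
  ytr <- factor(y[tr], levels = seq_len(C) - 1L)
  sv <- e1071::svm(X[tr, , drop = FALSE], ytr, kernel = "radial", ...)
  pred_sv <- as.integer(as.character(predict(sv, X[te, , drop = FALSE])))
  kn <- with_seed(seed,
    as.integer(as.character(class::knn(X[tr, , drop = FALSE],
                                       X[te, , drop = FALSE],
                                       ytr, k = knn_k))))
  mk <- function(pred, name, extra = list()) {
    cm <- confusion_counts(pred, y[te], C = C)
    acc_tr <- NA_real_
    experiment_report("tabular",
                      c(list(arch = name, seed = seed), extra),
                      NULL,
                      c(train = acc_tr, validation = NA_real_,
                        test = accuracy(pred, y[te])),
                      cm, seed)
  }
  list(svm = mk(pred_sv, "svm", list(kernel = "radial")),
       knn = mk(kn, "knn", list(k = knn_k)))
}
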