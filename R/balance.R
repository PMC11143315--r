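#' Class-balancing configuration
#'
#' @param method \code{"smote"} (oversample minority classes by SMOTE
#'   interpolation), \code{"smote_undersample"} (SMOTE minority classes up to
#'   the median class size and randomly undersample classes above it), or
#'   \code{"none"}.
#' @param k_neighbors number of same-class nearest neighbours a SMOTE
#'   interpolation partner is drawn from (default 5, the canonical SMOTE
#'   setting).
#' @param target \code{"equalize"} (bring every class to the majority count;
#'   for \code{smote_undersample}, to the median count) or a ratio in
#'   \code{(0, 1]} giving the minimum minority/majority class ratio.
#' @param seed integer seed controlling neighbour choice and interpolation.
#' @return a list of class \code{balance_config}.
#' @export
balance_config <- function(method = c("smote", "none", "smote_undersample"),
                           k_neighbors = 5L, target = "equalize",
                           seed = 0L) {
  method <- match.arg(method)
  stopifnot(is_count(k_neighbors))
  if (is.numeric(target)) {
    stopifnot(target > 0, target <= 1)
  } else stopifnot(identical(target, "equalize"))
  structure(list(method = method, k_neighbors = as.integer(k_neighbors),
                 target = target, seed = as.integer(seed)),
            class = "balance_config")
}

# k nearest same-class neighbours of each row of M (excluding itself),
# Euclidean; returns an n_c x k index matrix into M's rows.
knn_index <- function(M, k) {
  D <- as.matrix(dist(M))
  diag(D) <- Inf
  idx <- apply(D, 1L, function(r) order(r)[seq_len(k)])
  # apply returns a vector when k = 1; keep rows = points, cols = neighbours
  if (k == 1L) matrix(idx, ncol = 1L) else t(idx)
}

# SMOTE for one class: synthesize m rows from class rows M (n_c x F).
smote_class <- function(M, m, k) {
  n_c <- nrow(M)
  if (n_c < k + 1L) {
    stop2("balance error: class with ", n_c,
          " members is too small for k_neighbors = ", k)
  }
  nn <- knn_index(M, k)
  seed_idx <- ((seq_len(m) - 1L) %% n_c) + 1L
  nn_pick <- nn[cbind(seed_idx, sample.int(k, m, replace = TRUE))]
  u <- runif(m)
  synth <- M[seed_idx, , drop = FALSE] +
    u * (M[nn_pick, , drop = FALSE] - M[seed_idx, , drop = FALSE])
  list(synth = synth, seed_idx = seed_idx, nn_idx = nn_pick, u = u)
}

#' Balance class counts by SMOTE oversampling
#'
#' Synthetic minority samples are convex combinations
#' \eqn{x_i + u (x_{nn} - x_i)}, \eqn{u \in [0,1]}, of a minority row and one
#' of its \code{k_neighbors} nearest same-class neighbours (Euclidean).
#' Original rows are always preserved. With
#' \code{method = "smote_undersample"}, classes above the median class size
#' are randomly undersampled to it and classes below are SMOTE-oversampled
#' to it. Deterministic under \code{cfg$seed}.
#'
#' @param X numeric feature matrix (rows = patients).
#' @param y integer or factor class labels, length \code{nrow(X)}.
#' @param cfg a [balance_config()].
#' @return list with the balanced \code{X}, \code{y}, and \code{info}, a
#'   data.frame recording for every synthetic row its class, the row index of
#'   its seed and neighbour within the original \code{X}, and the
#'   interpolation weight \code{u}.
#' @export
balance_classes <- function(X, y, cfg = balance_config()) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  if (cfg$method == "none") {
    return(list(X = X, y = y,
                info = data.frame(class = integer(), seed_row = integer(),
                                  nn_row = integer(), u = numeric())))
  }
  with_seed(cfg$seed, {
    counts <- table(y)
    classes <- names(counts)
    keep_idx <- seq_len(nrow(X))
    target_n <- if (cfg$method == "smote_undersample") {
      as.integer(ceiling(median(counts)))
    } else if (identical(cfg$target, "equalize")) {
      max(counts)
    } else {
      as.integer(ceiling(cfg$target * max(counts)))
    }
    if (cfg$method == "smote_undersample") {
      drop <- integer()
      for (cl in classes) {
        idx <- which(y == cl)
        if (length(idx) > target_n) {
          drop <- c(drop, sample(idx, length(idx) - target_n))
        }
      }
      if (length(drop)) keep_idx <- setdiff(keep_idx, drop)
    }
    Xb <- X[keep_idx, , drop = FALSE]
    yb <- y[keep_idx]
    synth_rows <- list()
    synth_y <- list()
    info <- list()
    for (cl in classes) {
      idx <- which(yb == cl)
      need <- target_n - length(idx)
      if (need > 0L) {
        sm <- smote_class(Xb[idx, , drop = FALSE], need, cfg$k_neighbors)
        synth_rows[[cl]] <- sm$synth
        yv <- yb[idx[1L]]
        synth_y[[cl]] <- rep(yv, need)
        info[[cl]] <- data.frame(
          class = rep(as.character(yv), need),
          seed_row = keep_idx[idx[sm$seed_idx]],
          nn_row = keep_idx[idx[sm$nn_idx]],
          u = sm$u)
      }
    }
    X_out <- rbind(Xb, do.call(rbind, unname(synth_rows)))
    y_out <- c(yb, unlist(unname(synth_y), use.names = FALSE))
    rownames(X_out) <- NULL
    list(X = X_out, y = y_out,
         info = if (length(info)) do.call(rbind, c(unname(info), list(make.row.names = FALSE)))
                else data.frame(class = integer(), seed_row = integer(),
                                nn_row = integer(), u = numeric()))
  })
}
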