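#' Similarity / distance metric specification
#'
#' A patient-similarity network connects two patients when their feature
#' vectors pass a threshold predicate: for similarity metrics (cosine) the
#' value must \emph{exceed} the threshold, for distance metrics (euclidean,
#' manhattan, minkowski) it must be \emph{lower} than the threshold. Both
#' inequalities are strict.
#'
#' @param name one of \code{"cosine"}, \code{"euclidean"},
#'   \code{"manhattan"}, \code{"minkowski"}.
#' @param threshold edge threshold; in \code{[-1, 1]} for cosine,
#'   non-negative for distances.
#' @param p Minkowski order (\eqn{\ge 1}); required iff
#'   \code{name = "minkowski"}.
#' @return a list of class \code{metric_spec} with a derived
#'   \code{direction} field (\code{"similarity"} or \code{"distance"}).
#' @export
metric_spec <- function(name = c("cosine", "euclidean", "manhattan",
                                 "minkowski"),
                        threshold, p = NULL) {
  name <- match.arg(name)
  if (name == "minkowski") {
    if (is.null(p) || !is.numeric(p) || p < 1) {
      stop2("minkowski requires p >= 1")
    }
  } else if (!is.null(p)) {
    stop2("p is only meaningful for the minkowski metric")
  }
  direction <- if (name == "cosine") "similarity" else "distance"
  if (direction == "similarity") {
    stopifnot(threshold >= -1, threshold <= 1)
  } else {
    stopifnot(threshold >= 0)
  }
  structure(list(name = name, threshold = threshold, p = p,
                 direction = direction), class = "metric_spec")
}

# Metric values of rows a..b of X against all rows; cosine uses normalized
# rows (Xn); distances use the C++ Minkowski kernel with the metric's order.
metric_order <- function(metric) {
  switch(metric$name, manhattan = 1, euclidean = 2, minkowski = metric$p,
         cosine = NA_real_)
}

#' Full pairwise metric matrix
#'
#' Computes the symmetric n x n matrix of metric values between all row
#' pairs of \code{X}. The diagonal holds the self-value (1 for cosine, 0 for
#' distances). Minkowski uses \eqn{(\sum_k |x_k - y_k|^p)^{1/p}}.
#'
#' @param X numeric matrix with no missing values.
#' @param metric a [metric_spec()] (its threshold is ignored here).
#' @return symmetric numeric matrix.
#' @export
pairwise_values <- function(X, metric) {
  X <- as.matrix(X)
  if (anyNA(X)) stop2("X must not contain missing values")
  if (metric$name == "cosine") {
    nrm <- sqrt(rowSums(X^2))
    if (any(nrm == 0)) {
      stop2("metric error: zero-norm row(s) under cosine: ",
            paste(which(nrm == 0), collapse = ", "))
    }
    Xn <- X / nrm
    V <- Xn %*% t(Xn)
    V[V > 1] <- 1
    V[V < -1] <- -1
    diag(V) <- 1
  } else {
    V <- minkowski_block(X, X, metric_order(metric))
    diag(V) <- 0
  }
  V
}

edge_predicate <- function(values, metric) {
  if (metric$direction == "similarity") values > metric$threshold
  else values < metric$threshold
}

edge_weight <- function(values, metric) {
  if (metric$direction == "similarity") values else 1 / (1 + values)
}

#' Construct a patient graph object
#'
#' Low-level constructor; [build_graph()] is the usual entry point. Edges
#' are unordered pairs \code{i < j} with no self-loops or duplicates.
#'
#' @param X n x F node feature matrix.
#' @param y length-n integer node labels in \code{0..C-1} (NA allowed for
#'   unlabeled nodes).
#' @param edges 2-column integer matrix of node index pairs.
#' @param weights numeric edge weights, one per edge.
#' @param metric the [metric_spec()] that generated the graph (or NULL).
#' @param class_names optional character vector of class names.
#' @return an object of class \code{patient_graph}.
#' @export
patient_graph <- function(X, y, edges, weights = NULL, metric = NULL,
                          class_names = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges)) {
    if (any(edges[, 1L] == edges[, 2L])) stop2("self-loops are not allowed")
    swap <- edges[, 1L] > edges[, 2L]
    edges[swap, ] <- edges[swap, 2:1]
    key <- (edges[, 1L] - 1) * as.double(n) + edges[, 2L]
    if (anyDuplicated(key)) stop2("duplicate edges are not allowed")
    ord <- order(key)
    edges <- edges[ord, , drop = FALSE]
    weights <- if (!is.null(weights)) weights[ord] else rep(1, nrow(edges))
  } else {
    edges <- matrix(integer(), ncol = 2L)
    weights <- numeric()
  }
  structure(list(X = X, y = as.integer(y), edges = edges,
                 weights = weights, metric = metric, n = n,
                 class_names = class_names),
            class = "patient_graph")
}

#' Build a thresholded patient-similarity network
#'
#' Every patient is a node; an edge connects two patients when the metric
#' value between their feature vectors passes the threshold predicate
#' strictly (similarity: value > threshold; distance: value < threshold).
#' Edge weights store the raw cosine similarity, or \code{1/(1 + d)} for
#' distance metrics. Pairwise values are computed in row blocks so memory
#' stays O(block x n).
#'
#' @param pc a \code{prepared_cohort} (or any list with \code{X}, \code{y},
#'   and optionally \code{class_names}).
#' @param metric a [metric_spec()].
#' @param block_size rows per pairwise block.
#' @return a [patient_graph()].
#' @export
#' @examples
#' gen <- generate_cohort(cohort_spec(n = 120, seed = 3))
#' pc <- preprocess_cohort(gen$cohort)
#' g <- build_graph(pc, metric_spec("cosine", threshold = 0.95))
#' network_stats(g)
build_graph <- function(pc, metric, block_size = 1024L) {
  X <- as.matrix(pc$X)
  if (anyNA(X)) stop2("node features must not contain missing values")
  n <- nrow(X)
  p <- metric_order(metric)
  if (metric$name == "cosine") {
    nrm <- sqrt(rowSums(X^2))
    if (any(nrm == 0)) {
      stop2("metric error: zero-norm row(s) under cosine: ",
            paste(which(nrm == 0), collapse = ", "))
    }
    Xn <- X / nrm
  }
  edge_i <- list(); edge_j <- list(); edge_w <- list(); nb <- 0L
  for (a in seq(1L, n, by = block_size)) {
    b <- min(a + block_size - 1L, n)
    V <- if (metric$name == "cosine") {
      Xn[a:b, , drop = FALSE] %*% t(Xn)
    } else {
      minkowski_block(X[a:b, , drop = FALSE], X, p)
    }
    P <- edge_predicate(V, metric)
    # upper triangle only: j > global row index
    ii <- row(P) + (a - 1L)
    jj <- col(P)
    keep <- P & (jj > ii)
    if (any(keep)) {
      nb <- nb + 1L
      edge_i[[nb]] <- ii[keep]
      edge_j[[nb]] <- jj[keep]
      edge_w[[nb]] <- edge_weight(V[keep], metric)
    }
  }
  patient_graph(X, pc$y,
                cbind(unlist(edge_i, use.names = FALSE),
                      unlist(edge_j, use.names = FALSE)),
                unlist(edge_w, use.names = FALSE),
                metric = metric, class_names = pc$class_names)
}

#' Network statistics of a patient graph
#'
#' @param g a [patient_graph()].
#' @return one-row data.frame: \code{metric}, \code{p}, \code{threshold},
#'   \code{n_nodes}, \code{n_edges}, \code{n_isolated} (degree-0 nodes).
#' @export
network_stats <- function(g) {
  stopifnot(inherits(g, "patient_graph"))
  deg <- tabulate(c(g$edges[, 1L], g$edges[, 2L]), nbins = g$n)
  data.frame(
    metric = if (!is.null(g$metric)) g$metric$name else NA_character_,
    p = if (!is.null(g$metric)) g$metric$p %||% NA_real_ else NA_real_,
    threshold = if (!is.null(g$metric)) g$metric$threshold else NA_real_,
    n_nodes = g$n,
    n_edges = nrow(g$edges),
    n_isolated = sum(deg == 0L)
  )
}

#' @export
print.patient_graph <- function(x, ...) {
  s <- network_stats(x)
  cat("Patient-similarity network:", s$n_nodes, "nodes,", s$n_edges,
      "edges,", s$n_isolated, "isolated\n")
  if (!is.null(x$metric)) {
    cat("  metric:", x$metric$name,
        if (!is.null(x$metric$p)) paste0("(p=", x$metric$p, ")") else "",
        " threshold:", x$metric$threshold, "\n")
  }
  invisible(x)
}

#' Network statistics across a threshold grid
#'
#' Computes edge and isolated-node counts for every threshold in one
#' pairwise pass over the data (the pairwise values are computed once per
#' row block and reused across thresholds).
#'
#' @param pc a \code{prepared_cohort} (or list with \code{X}, \code{y}).
#' @param name metric name (see [metric_spec()]).
#' @param thresholds non-empty numeric vector.
#' @param p Minkowski order, if applicable.
#' @param block_size rows per pairwise block.
#' @return data.frame with one row per threshold (same columns as
#'   [network_stats()]).
#' @export
threshold_sweep <- function(pc, name, thresholds, p = NULL,
                            block_size = 1024L) {
  if (length(thresholds) == 0L) stop2("thresholds must be non-empty")
  X <- as.matrix(pc$X)
  n <- nrow(X)
  metric0 <- metric_spec(name, threshold = thresholds[1L], p = p)
  po <- metric_order(metric0)
  if (metric0$name == "cosine") {
    nrm <- sqrt(rowSums(X^2))
    if (any(nrm == 0)) stop2("metric error: zero-norm row(s) under cosine")
    Xn <- X / nrm
  }
  Tn <- length(thresholds)
  deg <- matrix(0L, n, Tn)
  n_edges <- numeric(Tn)
  for (a in seq(1L, n, by = block_size)) {
    b <- min(a + block_size - 1L, n)
    V <- if (metric0$name == "cosine") {
      Xn[a:b, , drop = FALSE] %*% t(Xn)
    } else {
      minkowski_block(X[a:b, , drop = FALSE], X, po)
    }
    self <- cbind(seq_len(b - a + 1L), a:b)  # diagonal entries of the block
    for (t in seq_len(Tn)) {
      P <- if (metric0$direction == "similarity") V > thresholds[t]
           else V < thresholds[t]
      P[self] <- FALSE
      rs <- rowSums(P)
      deg[a:b, t] <- deg[a:b, t] + as.integer(rs)
      n_edges[t] <- n_edges[t] + sum(rs)
    }
  }
  data.frame(metric = name, p = p %||% NA_real_, threshold = thresholds,
             n_nodes = n, n_edges = n_edges / 2,
             n_isolated = colSums(deg == 0L))
}

#' Convert a patient graph to an igraph object
#'
#' Nodes carry their class label (attribute \code{label_code}); edges carry
#' the similarity weight.
#'
#' @param g a [patient_graph()].
#' @return an undirected \code{igraph} graph.
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "patient_graph"))
  ig <- igraph::make_empty_graph(n = g$n, directed = FALSE)
  if (nrow(g$edges)) {
    ig <- igraph::add_edges(ig, t(g$edges), weight = g$weights)
  }
  igraph::V(ig)$label_code <- g$y
  ig
}

#' Write a patient graph as a whitespace edge list
#'
#' One line per edge: \code{i j weight} (1-based node indices).
#'
#' @param g a [patient_graph()]; @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_edgelist <- function(g, path) {
  stopifnot(inherits(g, "patient_graph"))
  write.table(data.frame(i = g$edges[, 1L], j = g$edges[, 2L],
                         weight = g$weights),
              path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a patient graph in GraphML format
#'
#' @param g a [patient_graph()]; @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_graphml <- function(g, path) {
  igraph::write_graph(as_igraph(g), path, format = "graphml")
  invisible(path)
}

#' Write the node table (id, label, features) as CSV
#'
#' @param g a [patient_graph()]; @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_node_table <- function(g, path) {
  stopifnot(inherits(g, "patient_graph"))
  d <- data.frame(id = seq_len(g$n), label = g$y)
  d <- cbind(d, as.data.frame(g$X))
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}
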