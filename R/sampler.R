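# Adjacency list (neighbors of each node) from an undirected edge matrix.
adjacency_list <- function(edges, n) {
  if (nrow(edges) == 0L) return(rep(list(integer()), n))
  src <- c(edges[, 1L], edges[, 2L])
  dst <- c(edges[, 2L], edges[, 1L])
  unname(split(dst, factor(src, levels = seq_len(n))))
}

#' Neighbor-sampled mini-batches for GraphSAGE training
#'
#' Partitions the training nodes into \code{ceiling(n_train / batch_size)}
#' seed sets and, for each, grows a subgraph by sampling at most
#' \code{fanout} neighbours per node per hop for \code{hops} hops. Every
#' training node is a seed in exactly one batch.
#'
#' @param graph a [patient_graph()].
#' @param batch_size seed nodes per batch (default 3000).
#' @param fanout maximum sampled neighbours per node per hop (default 10).
#' @param hops number of sampling hops (default 5, matching the five-layer
#'   GraphSAGE model).
#' @param train_nodes integer node ids to partition (default: all nodes).
#' @param seed optional seed; \code{NULL} uses the current RNG stream (as
#'   during training, where the epoch stream makes resampling
#'   deterministic).
#' @param adj optional precomputed adjacency list (internal use; avoids
#'   rebuilding it every epoch).
#' @return list of batches; each batch is a list with \code{seeds} and
#'   \code{nodes} (original node ids, seeds first), \code{seed_local}
#'   (positions of seeds in \code{nodes}), \code{edges_local} (2-column
#'   matrix of sampled undirected edges in local indexing), and
#'   \code{hop_sizes} (nodes added per hop).
#' @export
sample_neighborhoods <- function(graph, batch_size = 3000L, fanout = 10L,
                                 hops = 5L, train_nodes = NULL,
                                 seed = NULL, adj = NULL) {
  stopifnot(inherits(graph, "patient_graph"),
            is_count(batch_size), is_count(fanout), is_count(hops))
  n <- graph$n
  train_nodes <- train_nodes %||% seq_len(n)
  if (batch_size > length(train_nodes)) batch_size <- length(train_nodes)
  adj <- adj %||% adjacency_list(graph$edges, n)
  run <- function() {
    perm <- sample(train_nodes)
    starts <- seq(1L, length(perm), by = batch_size)
    lapply(starts, function(s) {
      seeds <- perm[s:min(s + batch_size - 1L, length(perm))]
      visited <- logical(n)
      visited[seeds] <- TRUE
      order_added <- seeds
      hop_sizes <- integer(hops)
      es <- vector("list", hops)
      frontier <- seeds
      for (hp in seq_len(hops)) {
        if (length(frontier) == 0L) break
        nbs <- lapply(adj[frontier], function(v) {
          if (length(v) > fanout) v[sample.int(length(v), fanout)] else v
        })
        lens <- lengths(nbs)
        srcs <- rep(frontier, lens)
        dsts <- unlist(nbs, use.names = FALSE)
        es[[hp]] <- cbind(srcs, dsts)
        fresh <- unique(dsts[!visited[dsts]])
        visited[fresh] <- TRUE
        order_added <- c(order_added, fresh)
        hop_sizes[hp] <- length(fresh)
        frontier <- fresh
      }
      E <- do.call(rbind, es)
      if (is.null(E)) E <- matrix(integer(), ncol = 2L)
      if (nrow(E)) {
        lo <- pmin(E[, 1L], E[, 2L])
        hi <- pmax(E[, 1L], E[, 2L])
        key <- (lo - 1) * as.double(n) + hi
        keep <- !duplicated(key)
        E <- cbind(lo[keep], hi[keep])
      }
      local_id <- integer(n)
      local_id[order_added] <- seq_along(order_added)
      list(seeds = seeds, nodes = order_added,
           seed_local = seq_along(seeds),
           edges_local = matrix(local_id[E], ncol = 2L),
           hop_sizes = hop_sizes)
    })
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
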