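glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -s, s), nin, nout)
}

new_layer <- function(type, in_dim, out_dim, aggr = NULL, heads = NULL,
                      dhead = NULL, act = FALSE, dropout_before = FALSE,
                      dropout_after = FALSE) {
  params <- switch(type,
    gcn = list(W = glorot(in_dim, out_dim), b = numeric(out_dim)),
    sage = {
      ps <- list(W_self = glorot(in_dim, out_dim),
                 W_neigh = glorot(in_dim, out_dim), b = numeric(out_dim))
      if (identical(aggr, "max")) {
        # max-pool aggregator: learned projection + ReLU before the
        # elementwise max (GraphSAGE pooling aggregator)
        ps$W_pool <- glorot(in_dim, in_dim)
        ps$b_pool <- numeric(in_dim)
      }
      ps
    },
    gatv2 = {
      hd <- heads * dhead
      list(W_l = glorot(in_dim, hd), W_r = glorot(in_dim, hd),
           a = runif(hd, -sqrt(6 / (hd + 1)), sqrt(6 / (hd + 1))),
           b = numeric(hd))
    },
    stop2("unknown layer type: ", type))
  list(type = type, in_dim = in_dim, out_dim = out_dim, aggr = aggr,
       heads = heads, dhead = dhead, act = act,
       dropout_before = dropout_before, dropout_after = dropout_after,
       params = params)
}

#' Construct a GNN node-classification model
#'
#' Four architecture families are available, all ending in a C-dimensional
#' logit layer and using ReLU after every non-final layer and dropout at
#' rate \code{dropout}:
#' \describe{
#'   \item{\code{"gcn5"}}{five graph-convolution layers
#'     (F,64),(64,64),(64,64),(64,64),(64,C); dropout after layers 2-4.}
#'   \item{\code{"gcn4"}}{four graph-convolution layers with hidden width 32;
#'     dropout after layers 2-3.}
#'   \item{\code{"gatv2"}}{two GATv2 attention layers: (F, 8) with 4
#'     attention heads (concatenated to 32), then (32, C); one dropout before
#'     each layer.}
#'   \item{\code{"sage5"}}{five GraphSAGE layers with hidden widths
#'     64, 32, 16, 8 then C; max-pool neighbour aggregation except the third
#'     layer which uses mean; dropout after the fourth layer.}
#' }
#'
#' @param family architecture family name.
#' @param F input feature dimension (number of node features).
#' @param C number of classes.
#' @param seed seed for Glorot-uniform parameter initialization.
#' @param dropout dropout rate (default 0.2).
#' @return an object of class \code{gnn_model}.
#' @export
#' @examples
#' m <- make_model("sage5", F = 16, C = 4)
#' architecture(m)
make_model <- function(family = c("gcn5", "gcn4", "gatv2", "sage5"),
                       F, C, seed = 1L, dropout = 0.2) {
  family <- match.arg(family)
  stopifnot(is_count(F), is_count(C))
  layers <- with_seed(seed, switch(family,
    gcn5 = {
      dims <- c(F, 64, 64, 64, 64, C)
      lapply(1:5, function(i) {
        new_layer("gcn", dims[i], dims[i + 1], act = i < 5,
                  dropout_after = i %in% 2:4)
      })
    },
    gcn4 = {
      dims <- c(F, 32, 32, 32, C)
      lapply(1:4, function(i) {
        new_layer("gcn", dims[i], dims[i + 1], act = i < 4,
                  dropout_after = i %in% 2:3)
      })
    },
    gatv2 = list(
      new_layer("gatv2", F, 32, heads = 4L, dhead = 8L, act = TRUE,
                dropout_before = TRUE),
      new_layer("gatv2", 32, C, heads = 1L, dhead = as.integer(C),
                dropout_before = TRUE)
    ),
    sage5 = {
      dims <- c(F, 64, 32, 16, 8, C)
      aggr <- c("max", "max", "mean", "max", "max")
      lapply(1:5, function(i) {
        new_layer("sage", dims[i], dims[i + 1], aggr = aggr[i],
                  act = i < 5, dropout_after = i == 4)
      })
    }
  ))
  structure(list(family = family, F = as.integer(F), C = as.integer(C),
                 layers = layers, dropout = dropout),
            class = "gnn_model")
}

#' Construct a GraphSAGE ablation variant
#'
#' Starts from the five-layer GraphSAGE architecture, removes the given
#' hidden layers (subset of positions 2-4) and sets every remaining hidden
#' dimension to \code{hidden_width}, re-chaining adjacent dimensions so the
#' model stays F -> width -> ... -> C. Aggregators are inherited from the
#' surviving base positions; dropout sits after the penultimate layer.
#'
#' @param F input feature dimension; @param C number of classes.
#' @param removed_layers integer subset of \code{c(2, 3, 4)}.
#' @param hidden_width width of every remaining hidden layer (8 or 64 in the
#'   ablation grid, any positive integer accepted).
#' @param seed initialization seed; @param dropout dropout rate.
#' @return a \code{gnn_model} with family \code{"sage_variant"}.
#' @export
make_sage_variant <- function(F, C, removed_layers = integer(),
                              hidden_width = 8L, seed = 1L, dropout = 0.2) {
  stopifnot(all(removed_layers %in% 2:4), is_count(hidden_width))
  keep <- setdiff(1:5, removed_layers)
  k <- length(keep)
  base_aggr <- c("max", "max", "mean", "max", "max")
  dims <- c(F, rep(hidden_width, k - 1L), C)
  layers <- with_seed(seed, lapply(seq_len(k), function(i) {
    new_layer("sage", dims[i], dims[i + 1], aggr = base_aggr[keep[i]],
              act = i < k, dropout_after = (i == k - 1L) && k > 1L)
  }))
  structure(list(family = "sage_variant", F = as.integer(F),
                 C = as.integer(C), layers = layers, dropout = dropout,
                 removed_layers = sort(removed_layers),
                 hidden_width = as.integer(hidden_width)),
            class = "gnn_model")
}

#' Architecture summary of a model
#'
#' @param model a \code{gnn_model} or \code{triage_gnn} fit.
#' @return data.frame with one row per layer: type, input and output
#'   dimension, heads, aggregator, and dropout placement.
#' @export
architecture <- function(model) {
  if (inherits(model, "triage_gnn")) model <- model$model
  stopifnot(inherits(model, "gnn_model"))
  do.call(rbind, lapply(seq_along(model$layers), function(i) {
    l <- model$layers[[i]]
    data.frame(layer = i, type = l$type, in_dim = l$in_dim,
               out_dim = l$out_dim,
               heads = l$heads %||% NA_integer_,
               aggr = l$aggr %||% NA_character_,
               relu = l$act,
               dropout_before = l$dropout_before,
               dropout_after = l$dropout_after)
  }))
}

#' Number of trainable parameters of a model
#'
#' @param model a \code{gnn_model} or \code{triage_gnn} fit.
#' @return integer count.
#' @export
n_params <- function(model) {
  if (inherits(model, "triage_gnn")) model <- model$model
  sum(vapply(model$layers,
             function(l) sum(vapply(l$params, length, 1L)), 1L))
}

#' @export
print.gnn_model <- function(x, ...) {
  cat("GNN model (", x$family, "): ", x$F, " features -> ", x$C,
      " classes, ", n_params(x), " parameters\n", sep = "")
  print(architecture(x), row.names = FALSE)
  invisible(x)
}
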