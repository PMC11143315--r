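adam_init <- function(layers) {
  lapply(layers, function(l) {
    lapply(l$params, function(p) list(m = p * 0, v = p * 0))
  })
}

# Clip gradients to a global L2 norm; stabilizes the first Adam steps.
clip_grads <- function(grads, max_norm) {
  if (!is.finite(max_norm)) return(grads)
  total <- sqrt(sum(vapply(grads, function(g) {
    sum(vapply(g, function(x) sum(x * x), 0))
  }, 0)))
  if (total <= max_norm) return(grads)
  s <- max_norm / total
  lapply(grads, function(g) lapply(g, `*`, s))
}

adam_step <- function(layers, grads, state, t, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in seq_along(layers)) {
    for (nm in names(layers[[l]]$params)) {
      g <- grads[[l]][[nm]] + weight_decay * layers[[l]]$params[[nm]]
      st <- state[[l]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      mh <- st$m / (1 - beta1^t)
      vh <- st$v / (1 - beta2^t)
      layers[[l]]$params[[nm]] <- layers[[l]]$params[[nm]] -
        lr * mh / (sqrt(vh) + eps)
      state[[l]][[nm]] <- st
    }
  }
  list(layers = layers, state = state)
}

masked_accuracy <- function(pred, y, mask_idx) {
  if (length(mask_idx) == 0L) return(NA_real_)
  mean(pred[mask_idx] == y[mask_idx])
}

#' Fit a GNN triage classifier on a patient-similarity network
#'
#' The main fitting function of the package. Trains one of the four GNN
#' architectures (see [make_model()]) to predict the node class (triage
#' severity code) by minimizing softmax cross-entropy on the training-mask
#' nodes with the Adam optimizer (weight decay 5e-4; learning rate 0.01, or
#' 0.005 for the attention model). GraphSAGE-family models train on
#' neighbor-sampled mini-batches (batch size 3000, fanout 10, one hop per
#' layer by default); the other families train full-graph. Training is
#' deterministic for fixed inputs and seed.
#'
#' @param graph a [patient_graph()] with labeled nodes.
#' @param family architecture family, or pass a ready \code{gnn_model} via
#'   \code{model}.
#' @param masks a \code{split_masks} object from [make_split()]; default
#'   splits the labeled nodes 70/30 with 30% of the test set as validation,
#'   stratified by class.
#' @param epochs training epochs; default 100 for neighbor-sampled
#'   GraphSAGE, 200 otherwise.
#' @param lr learning rate; \code{NULL} picks the family default.
#' @param weight_decay Adam weight decay (default 5e-4).
#' @param dropout dropout rate (default 0.2).
#' @param batch_size,fanout,hops neighbor-sampling parameters (GraphSAGE
#'   families only); \code{hops = NULL} uses one hop per layer.
#' @param batching \code{"auto"} (neighbor sampling for SAGE families, full
#'   graph otherwise), \code{"full"}, or \code{"neighbor"}.
#' @param patience early-stopping patience on validation accuracy;
#'   \code{Inf} disables early stopping. The returned parameters are those
#'   of the best validation epoch.
#' @param clip_norm clip gradients to this global L2 norm before each Adam
#'   step (\code{Inf} disables clipping).
#' @param eval_every compute split accuracies (and test early stopping)
#'   every this many epochs; the loss is recorded every epoch.
#' @param use_edge_weights propagate similarity edge weights through the
#'   GCN / mean-aggregation operators (default FALSE).
#' @param model optional pre-built \code{gnn_model} (overrides
#'   \code{family}).
#' @param seed integer seed controlling initialization, dropout, and
#'   neighbor sampling.
#' @param verbose print per-epoch progress.
#' @return an object of class \code{triage_gnn} with components
#'   \code{model}, \code{history} (per-epoch loss and split accuracies),
#'   \code{masks}, \code{config}, \code{graph}, and \code{accuracy}
#'   (train/validation/test). Methods: \code{print}, \code{summary},
#'   \code{predict}, \code{plot}, \code{coef}, \code{fitted}.
#' @export
#' @examples
#' \donttest{
#' gen <- generate_cohort(cohort_spec(n = 300, separation = 6, seed = 1))
#' pc <- preprocess_cohort(gen$cohort)
#' g <- build_graph(pc, metric_spec("cosine", threshold = 0.9))
#' fit <- triage_gnn(g, "sage5", epochs = 30, seed = 1)
#' fit$accuracy
#' }
triage_gnn <- function(graph, family = c("sage5", "gcn5", "gcn4", "gatv2"),
                       masks = NULL, epochs = NULL, lr = NULL,
                       weight_decay = 5e-4, dropout = 0.2,
                       batch_size = 3000L, fanout = 10L, hops = NULL,
                       batching = c("auto", "full", "neighbor"),
                       patience = 20, clip_norm = 1, eval_every = 1L,
                       use_edge_weights = FALSE,
                       model = NULL, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(graph, "patient_graph"))
  batching <- match.arg(batching)
  y <- graph$y
  if (is.null(model)) {
    family <- match.arg(family)
    C <- max(y, na.rm = TRUE) + 1L
    model <- make_model(family, F = ncol(graph$X), C = C, seed = seed,
                        dropout = dropout)
  } else {
    stopifnot(inherits(model, "gnn_model"))
    family <- model$family
  }
  is_sage <- family %in% c("sage5", "sage_variant")
  if (batching == "auto") batching <- if (is_sage) "neighbor" else "full"
  lr <- lr %||% if (family == "gatv2") 0.005 else 0.01
  epochs <- epochs %||% if (batching == "neighbor") 100L else 200L
  hops <- hops %||% length(model$layers)
  masks <- masks %||% make_split(y, seed = seed)
  stopifnot(inherits(masks, "split_masks"))
  train_idx <- which(masks$train)
  val_idx <- which(masks$validation)
  test_idx <- which(masks$test)
  if (length(train_idx) == 0L) stop2("training mask is empty")

  ctx_full <- gnn_ctx(graph$X, graph$edges, graph$weights, use_edge_weights)
  adj <- if (batching == "neighbor") adjacency_list(graph$edges, graph$n)
  state <- adam_init(model$layers)
  tstep <- 0L
  hist <- vector("list", epochs)
  best <- list(val = -Inf, layers = model$layers, epoch = 0L)
  wait <- 0L

  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      if (batching == "neighbor") {
        batches <- sample_neighborhoods(graph, batch_size, fanout, hops,
                                        train_nodes = train_idx, adj = adj)
        ep_loss <- 0
        for (bt in batches) {
          Xs <- graph$X[bt$nodes, , drop = FALSE]
          ys <- y[bt$nodes]
          ctx <- gnn_ctx(Xs, bt$edges_local)
          fw <- model_forward(model, Xs, ctx, training = TRUE)
          ls <- ce_loss(fw$logits, ys, bt$seed_local)
          if (!is.finite(ls$loss)) {
            stop2("training error: non-finite loss at epoch ", ep)
          }
          grads <- clip_grads(model_backward(model, fw$caches,
                                             ls$dlogits, ctx), clip_norm)
          tstep <- tstep + 1L
          upd <- adam_step(model$layers, grads, state, tstep, lr,
                           weight_decay)
          model$layers <- upd$layers
          state <- upd$state
          ep_loss <- ep_loss + ls$loss * length(bt$seeds)
        }
        ep_loss <- ep_loss / length(train_idx)
      } else {
        fw <- model_forward(model, graph$X, ctx_full, training = TRUE)
        ls <- ce_loss(fw$logits, y, train_idx)
        if (!is.finite(ls$loss)) {
          stop2("training error: non-finite loss at epoch ", ep)
        }
        grads <- clip_grads(model_backward(model, fw$caches, ls$dlogits,
                                           ctx_full), clip_norm)
        tstep <- tstep + 1L
        upd <- adam_step(model$layers, grads, state, tstep, lr,
                         weight_decay)
        model$layers <- upd$layers
        state <- upd$state
        ep_loss <- ls$loss
      }
      do_eval <- ep %% eval_every == 0L || ep == epochs
      acc_tr <- acc_va <- acc_te <- NA_real_
      if (do_eval) {
        logits <- model_forward(model, graph$X, ctx_full,
                                training = FALSE)$logits
        pred <- max.col(logits, ties.method = "first") - 1L
        acc_tr <- masked_accuracy(pred, y, train_idx)
        acc_va <- masked_accuracy(pred, y, val_idx)
        acc_te <- masked_accuracy(pred, y, test_idx)
      }
      hist[[ep]] <- data.frame(epoch = ep, loss = ep_loss,
                               train_acc = acc_tr, val_acc = acc_va,
                               test_acc = acc_te)
      if (verbose && do_eval) {
        cat(sprintf("epoch %3d  loss %.4f  train %.3f  val %.3f\n",
                    ep, ep_loss, acc_tr, acc_va))
      }
      if (do_eval && length(val_idx) && is.finite(patience)) {
        if (acc_va > best$val) {
          best <- list(val = acc_va, layers = model$layers, epoch = ep)
          wait <- 0L
        } else {
          wait <- wait + eval_every
          if (wait > patience) break
        }
      }
    }
  })
  if (is.finite(best$val) && best$val > -Inf && length(val_idx) &&
      is.finite(patience)) {
    model$layers <- best$layers
  }
  history <- do.call(rbind, hist[!vapply(hist, is.null, TRUE)])
  logits <- model_forward(model, graph$X, ctx_full,
                          training = FALSE)$logits
  pred <- max.col(logits, ties.method = "first") - 1L
  structure(list(
    model = model,
    family = family,
    history = history,
    masks = masks,
    graph = graph,
    config = list(family = family, epochs = epochs, lr = lr,
                  weight_decay = weight_decay, dropout = dropout,
                  batching = batching, batch_size = batch_size,
                  fanout = fanout, hops = hops, patience = patience,
                  clip_norm = clip_norm, eval_every = eval_every,
                  use_edge_weights = use_edge_weights, seed = seed),
    accuracy = c(train = masked_accuracy(pred, y, train_idx),
                 validation = masked_accuracy(pred, y, val_idx),
                 test = masked_accuracy(pred, y, test_idx)),
    class_names = graph$class_names,
    call = match.call()
  ), class = "triage_gnn")
}

#' @export
print.triage_gnn <- function(x, ...) {
  cat("GNN triage classifier (", x$family, ")\n", sep = "")
  cat("  graph:", x$graph$n, "nodes,", nrow(x$graph$edges), "edges\n")
  cat("  epochs run:", nrow(x$history), " final loss:",
      signif(x$history$loss[nrow(x$history)], 4), "\n")
  acc <- round(x$accuracy, 4)
  cat("  accuracy  train:", acc["train"], " validation:",
      acc["validation"], " test:", acc["test"], "\n")
  invisible(x)
}

#' @export
summary.triage_gnn <- function(object, ...) {
  test_idx <- which(object$masks$test)
  pred <- predict(object)
  cm <- confusion_counts(pred[test_idx], object$graph$y[test_idx],
                         C = object$model$C)
  out <- list(family = object$family,
              architecture = architecture(object$model),
              n_params = n_params(object$model),
              accuracy = object$accuracy,
              confusion = cm,
              per_class = per_class_metrics(cm),
              epochs = nrow(object$history))
  class(out) <- "summary.triage_gnn"
  out
}

#' @export
print.summary.triage_gnn <- function(x, ...) {
  cat("GNN triage classifier (", x$family, "), ", x$n_params,
      " parameters, ", x$epochs, " epochs\n", sep = "")
  print(x$architecture, row.names = FALSE)
  cat("\nAccuracy:\n")
  print(round(x$accuracy, 4))
  cat("\nTest confusion matrix (rows = true class):\n")
  print(x$confusion)
  cat("\nPer-class test metrics:\n")
  print(round(x$per_class, 4))
  invisible(x)
}

#' Predict triage classes for graph nodes
#'
#' Runs the trained model in inference mode. Because the architectures are
#' inductive, \code{newgraph} may contain nodes unseen during training (for
#' example the training graph extended with a new patient).
#'
#' @param object a \code{triage_gnn} fit.
#' @param newgraph a [patient_graph()]; default is the training graph.
#' @param nodes node ids to predict (default all).
#' @param type \code{"class"} (integer codes, ties broken toward the
#'   smallest class index), \code{"label"} (class names), \code{"prob"}
#'   (softmax probabilities) or \code{"logits"}.
#' @param ... unused.
#' @return integer vector, character vector, or numeric matrix per
#'   \code{type}.
#' @export
predict.triage_gnn <- function(object, newgraph = NULL, nodes = NULL,
                               type = c("class", "label", "prob", "logits"),
                               ...) {
  type <- match.arg(type)
  g <- newgraph %||% object$graph
  logits <- gnn_forward(object, g)
  nodes <- nodes %||% seq_len(g$n)
  if (any(nodes < 1L | nodes > g$n)) {
    stop2("index error: unknown node id(s): ",
          paste(nodes[nodes < 1L | nodes > g$n], collapse = ", "))
  }
  logits <- logits[nodes, , drop = FALSE]
  if (type == "logits") return(logits)
  if (type == "prob") {
    P <- exp(logits - apply(logits, 1L, max))
    return(P / rowSums(P))
  }
  cls <- max.col(logits, ties.method = "first") - 1L
  if (type == "label" && !is.null(object$class_names)) {
    return(object$class_names[cls + 1L])
  }
  cls
}

#' @export
fitted.triage_gnn <- function(object, ...) predict(object)

#' @export
coef.triage_gnn <- function(object, ...) {
  stats::setNames(lapply(object$model$layers, `[[`, "params"),
                  paste0("layer", seq_along(object$model$layers)))
}

#' Plot training curves of a fitted GNN
#'
#' Left axis: training loss; right panel: split accuracies per epoch.
#'
#' @param x a \code{triage_gnn} fit; @param ... passed to
#'   \code{plot.default}.
#' @export
plot.triage_gnn <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(h$epoch, h$loss, type = "l", xlab = "epoch", ylab = "training loss",
       main = x$family, ...)
  graphics::matplot(h$epoch, cbind(h$train_acc, h$val_acc, h$test_acc),
                    type = "l", lty = 1, col = c(1, 2, 4),
                    xlab = "epoch", ylab = "accuracy", main = "accuracy")
  graphics::legend("bottomright", c("train", "validation", "test"),
                   col = c(1, 2, 4), lty = 1, bty = "n")
  invisible(x)
}
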