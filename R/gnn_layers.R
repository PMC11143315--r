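# Message-passing context for one (sub)graph: sparse operators and edge
# index vectors shared by all layers.
#   A_hat : D^-1/2 (A + I) D^-1/2  (GCN propagation, symmetric)
#   A_mean: row-normalized A       (SAGE mean aggregation, no self-loops)
#   src/dst: directed edge lists (both directions of each undirected edge)
#   gat_src/gat_dst: src/dst plus self-loops (GATv2 attends to itself)
gnn_ctx <- function(X, edges, weights = NULL, use_weights = FALSE) {
  n <- nrow(X)
  if (is.null(dim(edges)) || nrow(edges) == 0L) {
    src <- integer(); dst <- integer(); w <- numeric()
  } else {
    src <- c(edges[, 1L], edges[, 2L])
    dst <- c(edges[, 2L], edges[, 1L])
    w <- if (use_weights && !is.null(weights)) rep(weights, 2L)
         else rep(1, length(src))
  }
  A <- Matrix::sparseMatrix(i = dst, j = src, x = w, dims = c(n, n))
  deg_hat <- Matrix::rowSums(A) + 1
  Dm <- Matrix::Diagonal(n, 1 / sqrt(deg_hat))
  A_hat <- Dm %*% (A + Matrix::Diagonal(n)) %*% Dm
  deg <- Matrix::rowSums(A)
  inv <- ifelse(deg > 0, 1 / deg, 0)
  A_mean <- Matrix::Diagonal(n, inv) %*% A
  list(n = n, src = src, dst = dst,
       gat_src = c(src, seq_len(n)), gat_dst = c(dst, seq_len(n)),
       A_hat = A_hat, A_mean = A_mean)
}

relu <- function(x) (x > 0) * x

layer_fwd <- function(lay, H, ctx) {
  p <- lay$params
  switch(lay$type,
    gcn = {
      M <- as.matrix(ctx$A_hat %*% H)
      out <- M %*% p$W
      out <- sweep(out, 2L, p$b, `+`)
      list(out = out, cache = list(M = M))
    },
    sage = {
      if (lay$aggr == "mean") {
        agg <- as.matrix(ctx$A_mean %*% H)
        cache <- list(H = H, agg = agg)
      } else {
        pre <- sweep(H %*% p$W_pool, 2L, p$b_pool, `+`)
        pm <- pre > 0
        P <- pre * pm
        mx <- edge_max_fwd(ctx$src, ctx$dst, P, ctx$n)
        agg <- mx$out
        cache <- list(H = H, agg = agg, argmax = mx$argmax, pmask = pm)
      }
      out <- H %*% p$W_self + agg %*% p$W_neigh
      out <- sweep(out, 2L, p$b, `+`)
      list(out = out, cache = cache)
    },
    gatv2 = {
      h <- lay$heads; dh <- lay$dhead; hd <- h * dh
      src <- ctx$gat_src; dst <- ctx$gat_dst; n <- ctx$n
      gl <- H %*% p$W_l
      gr <- H %*% p$W_r
      Z <- gl[dst, , drop = FALSE] + gr[src, , drop = FALSE]
      neg <- Z < 0
      ZL <- Z
      ZL[neg] <- 0.2 * Z[neg]             # LeakyReLU, slope 0.2
      SA <- ZL * matrix(p$a, nrow(ZL), hd, byrow = TRUE)
      S <- matrix(0, nrow(ZL), h)
      for (k in seq_len(h)) {
        cols <- ((k - 1L) * dh + 1L):(k * dh)
        S[, k] <- rowSums(SA[, cols, drop = FALSE])
      }
      Mx <- seg_max_mat(S, dst, n)
      Ee <- exp(S - Mx[dst, , drop = FALSE])
      den <- seg_sum_mat(Ee, dst, n)
      alpha <- Ee / den[dst, , drop = FALSE]
      rep_idx <- rep(seq_len(h), each = dh)
      Af <- alpha[, rep_idx, drop = FALSE]
      V <- gr[src, , drop = FALSE]
      out <- seg_sum_mat(Af * V, dst, n)
      out <- sweep(out, 2L, p$b, `+`)
      list(out = out,
           cache = list(H = H, gr = gr, ZL = ZL, neg = neg,
                        alpha = alpha, Af = Af, V = V,
                        rep_idx = rep_idx))
    })
}

layer_bwd <- function(lay, cache, dout, ctx) {
  p <- lay$params
  switch(lay$type,
    gcn = {
      dW <- crossprod(cache$M, dout)
      db <- colSums(dout)
      dM <- dout %*% t(p$W)
      dH <- as.matrix(ctx$A_hat %*% dM)   # A_hat is symmetric
      list(dH = dH, grads = list(W = dW, b = db))
    },
    sage = {
      dWs <- crossprod(cache$H, dout)
      dWn <- crossprod(cache$agg, dout)
      db <- colSums(dout)
      dH <- dout %*% t(p$W_self)
      dAgg <- dout %*% t(p$W_neigh)
      if (lay$aggr == "mean") {
        dH <- dH + as.matrix(Matrix::crossprod(ctx$A_mean, dAgg))
        grads <- list(W_self = dWs, W_neigh = dWn, b = db)
      } else {
        dP <- edge_max_bwd(cache$argmax, dAgg, ctx$n) * cache$pmask
        grads <- list(W_self = dWs, W_neigh = dWn, b = db,
                      W_pool = crossprod(cache$H, dP),
                      b_pool = colSums(dP))
        dH <- dH + dP %*% t(p$W_pool)
      }
      list(dH = dH, grads = grads)
    },
    gatv2 = {
      h <- lay$heads; dh <- lay$dhead; hd <- h * dh
      src <- ctx$gat_src; dst <- ctx$gat_dst; n <- ctx$n
      doutE <- dout[dst, , drop = FALSE]
      dgr <- seg_sum_mat(cache$Af * doutE, src, n)
      dalpha_full <- doutE * cache$V
      dalpha <- matrix(0, nrow(dalpha_full), h)
      for (k in seq_len(h)) {
        cols <- ((k - 1L) * dh + 1L):(k * dh)
        dalpha[, k] <- rowSums(dalpha_full[, cols, drop = FALSE])
      }
      t1 <- cache$alpha * dalpha
      ssum <- seg_sum_mat(t1, dst, n)
      dS <- t1 - cache$alpha * ssum[dst, , drop = FALSE]
      dSf <- dS[, cache$rep_idx, drop = FALSE]
      da <- colSums(dSf * cache$ZL)
      dZ <- dSf * matrix(p$a, nrow(dSf), hd, byrow = TRUE)
      dZ[cache$neg] <- 0.2 * dZ[cache$neg]
      dgl <- seg_sum_mat(dZ, dst, n)
      dgr <- dgr + seg_sum_mat(dZ, src, n)
      dW_l <- crossprod(cache$H, dgl)
      dW_r <- crossprod(cache$H, dgr)
      db <- colSums(dout)
      dH <- dgl %*% t(p$W_l) + dgr %*% t(p$W_r)
      list(dH = dH, grads = list(W_l = dW_l, W_r = dW_r, a = da, b = db))
    })
}

# Full forward pass. In training mode dropout masks are drawn from the
# current RNG stream and cached for the backward pass.
model_forward <- function(model, X, ctx, training = FALSE) {
  H <- as.matrix(X)
  rate <- model$dropout
  caches <- vector("list", length(model$layers))
  for (l in seq_along(model$layers)) {
    lay <- model$layers[[l]]
    mb <- NULL
    if (training && lay$dropout_before && rate > 0) {
      mb <- (matrix(runif(length(H)), nrow(H)) >= rate) / (1 - rate)
      H <- H * mb
    }
    fw <- layer_fwd(lay, H, ctx)
    H <- fw$out
    rmask <- NULL
    if (lay$act) {
      rmask <- H > 0
      H <- H * rmask
    }
    ma <- NULL
    if (training && lay$dropout_after && rate > 0) {
      ma <- (matrix(runif(length(H)), nrow(H)) >= rate) / (1 - rate)
      H <- H * ma
    }
    caches[[l]] <- list(layer = fw$cache, rmask = rmask,
                        drop_before = mb, drop_after = ma)
  }
  list(logits = H, caches = caches)
}

# Backward pass; returns per-layer gradient lists parallel to model$layers.
model_backward <- function(model, caches, dlogits, ctx) {
  dH <- dlogits
  grads <- vector("list", length(model$layers))
  for (l in rev(seq_along(model$layers))) {
    cc <- caches[[l]]
    if (!is.null(cc$drop_after)) dH <- dH * cc$drop_after
    if (!is.null(cc$rmask)) dH <- dH * cc$rmask
    bw <- layer_bwd(model$layers[[l]], cc$layer, dH, ctx)
    dH <- bw$dH
    if (!is.null(cc$drop_before)) dH <- dH * cc$drop_before
    grads[[l]] <- bw$grads
  }
  grads
}

# Softmax cross-entropy averaged over `idx`; returns loss and d(loss)/d(logits).
ce_loss <- function(logits, y, idx) {
  L <- logits[idx, , drop = FALSE]
  yy <- y[idx] + 1L
  m <- apply(L, 1L, max)
  P <- exp(L - m)
  P <- P / rowSums(P)
  eps <- 1e-12
  loss <- -mean(log(P[cbind(seq_along(idx), yy)] + eps))
  G <- P
  G[cbind(seq_along(idx), yy)] <- G[cbind(seq_along(idx), yy)] - 1
  dlogits <- matrix(0, nrow(logits), ncol(logits))
  dlogits[idx, ] <- G / length(idx)
  list(loss = loss, dlogits = dlogits)
}

#' Forward pass of a GNN model over a patient graph
#'
#' Runs the model in inference mode (dropout inactive, deterministic) and
#' returns one row of class logits per node.
#'
#' @param model a \code{gnn_model} or a \code{triage_gnn} fit.
#' @param graph a [patient_graph()] whose feature width matches the model.
#' @param use_edge_weights propagate edge weights through the GCN/mean
#'   aggregation operators (default FALSE: message passing is unweighted).
#' @return n x C numeric logit matrix.
#' @export
gnn_forward <- function(model, graph, use_edge_weights = FALSE) {
  if (inherits(model, "triage_gnn")) {
    use_edge_weights <- model$config$use_edge_weights
    model <- model$model
  }
  stopifnot(inherits(model, "gnn_model"), inherits(graph, "patient_graph"))
  if (ncol(graph$X) != model$F) {
    stop2("shape error: graph has ", ncol(graph$X),
          " features but model expects ", model$F)
  }
  ctx <- gnn_ctx(graph$X, graph$edges, graph$weights, use_edge_weights)
  model_forward(model, graph$X, ctx, training = FALSE)$logits
}
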