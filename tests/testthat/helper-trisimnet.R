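# Shared fixtures, built in code at test time.

# Naive double-loop pairwise metric oracle, independent of the package's
# block/crossprod implementation.
naive_pairwise <- function(X, name, p = NULL) {
  n <- nrow(X)
  V <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      xi <- X[i, ]; xj <- X[j, ]
      V[i, j] <- switch(name,
        cosine = sum(xi * xj) / (sqrt(sum(xi^2)) * sqrt(sum(xj^2))),
        euclidean = sqrt(sum((xi - xj)^2)),
        manhattan = sum(abs(xi - xj)),
        minkowski = sum(abs(xi - xj)^p)^(1 / p))
    }
  }
  if (name == "cosine") diag(V) <- 1 else diag(V) <- 0
  V
}

# A small random patient graph for model-level tests.
random_graph <- function(n = 30, Fd = 6, C = 4, p_edge = 0.2, seed = 1) {
  set.seed(seed)
  X <- matrix(runif(n * Fd), n, Fd)
  y <- sample(0:(C - 1), n, replace = TRUE)
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < p_edge
  patient_graph(X, y, pairs[keep, , drop = FALSE],
                weights = runif(sum(keep)))
}

# A tiny raw cohort with a custom fully-numeric schema.
toy_cohort <- function(d) {
  schema <- list(schema_id = "custom",
                 feature_names = setdiff(names(d), "label"),
                 categorical = character(), label_column = "label",
                 mandatory = character(), levels = list())
  raw_cohort(d, schema)
}

# Evaluate loss/gradients of a model on a graph (training disabled).
model_loss_grads <- function(model, g, idx = seq_len(g$n)) {
  ctx <- trisimnet:::gnn_ctx(g$X, g$edges)
  fw <- trisimnet:::model_forward(model, g$X, ctx, training = FALSE)
  ls <- trisimnet:::ce_loss(fw$logits, g$y, idx)
  grads <- trisimnet:::model_backward(model, fw$caches, ls$dlogits, ctx)
  list(loss = ls$loss, grads = grads, logits = fw$logits)
}
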