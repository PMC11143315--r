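test_that("architecture specs match the declared layer dimensions", {
  a5 <- architecture(make_model("gcn5", 16, 4))
  expect_equal(a5$in_dim, c(16, 64, 64, 64, 64))
  expect_equal(a5$out_dim, c(64, 64, 64, 64, 4))
  expect_equal(sum(a5$dropout_after), 3)        # after layers 2-4
  expect_equal(a5$relu, c(rep(TRUE, 4), FALSE))

  a4 <- architecture(make_model("gcn4", 16, 4))
  expect_equal(a4$in_dim, c(16, 32, 32, 32))
  expect_equal(a4$out_dim, c(32, 32, 32, 4))
  expect_equal(sum(a4$dropout_after), 2)

  ag <- architecture(make_model("gatv2", 16, 4))
  expect_equal(ag$heads, c(4, 1))
  expect_equal(ag$in_dim, c(16, 32))            # 8 per head x 4 heads
  expect_equal(ag$out_dim, c(32, 4))
  expect_true(all(ag$dropout_before))

  as <- architecture(make_model("sage5", 16, 4))
  expect_equal(as$in_dim, c(16, 64, 32, 16, 8))
  expect_equal(as$out_dim, c(64, 32, 16, 8, 4))
  expect_equal(as$aggr, c("max", "max", "mean", "max", "max"))
  expect_equal(which(as$dropout_after), 4L)
})

test_that("dimension chaining holds at arbitrary (F, C)", {
  for (Fd in c(3, 10, 25)) {
    for (C in c(2, 5)) {
      for (fam in c("gcn5", "gcn4", "gatv2", "sage5")) {
        a <- architecture(make_model(fam, Fd, C))
        expect_equal(a$in_dim[1], Fd)
        expect_equal(a$out_dim[nrow(a)], C)
        if (nrow(a) > 1) {
          expect_equal(a$in_dim[-1], a$out_dim[-nrow(a)])
        }
      }
    }
  }
})

test_that("forward returns n x C logits and rejects feature mismatch", {
  g <- random_graph(n = 20, Fd = 6, C = 4, seed = 50)
  for (fam in c("gcn5", "gcn4", "gatv2", "sage5")) {
    m <- make_model(fam, 6, 4, seed = 2)
    logits <- gnn_forward(m, g)
    expect_equal(dim(logits), c(20L, 4L))
    expect_true(all(is.finite(logits)))
  }
  m16 <- make_model("gcn5", 16, 4)
  expect_error(gnn_forward(m16, g), "shape error")
})

test_that("inference is deterministic and equivariant under permutation", {
  g <- random_graph(n = 50, Fd = 8, C = 4, p_edge = 0.15, seed = 51)
  set.seed(52)
  perm <- sample(g$n)
  inv <- order(perm)
  gp <- patient_graph(g$X[perm, ], g$y[perm],
                      cbind(inv[g$edges[, 1]], inv[g$edges[, 2]]))
  for (fam in c("gcn5", "gcn4", "gatv2", "sage5")) {
    m <- make_model(fam, 8, 4, seed = 3)
    l1 <- gnn_forward(m, g)
    l1b <- gnn_forward(m, g)
    expect_identical(l1, l1b)            # deterministic in inference mode
    l2 <- gnn_forward(m, gp)
    expect_lt(max(abs(l2 - l1[perm, ])), 1e-5)
  }
})

test_that("analytic gradients match finite differences for every family", {
  g <- random_graph(n = 12, Fd = 5, C = 3, p_edge = 0.3, seed = 53)
  for (fam in c("gcn5", "gcn4", "gatv2", "sage5")) {
    m <- make_model(fam, 5, 3, seed = 7, dropout = 0)
    base <- model_loss_grads(m, g)
    set.seed(54)
    for (l in seq_along(m$layers)) {
      for (nm in names(m$layers[[l]]$params)) {
        P <- m$layers[[l]]$params[[nm]]
        for (k in sample(length(P), min(4, length(P)))) {
          eps <- 1e-5
          m2 <- m
          m2$layers[[l]]$params[[nm]][k] <- P[k] + eps
          lp <- model_loss_grads(m2, g)$loss
          m2$layers[[l]]$params[[nm]][k] <- P[k] - eps
          lm <- model_loss_grads(m2, g)$loss
          num <- (lp - lm) / (2 * eps)
          expect_lt(abs(num - base$grads[[l]][[nm]][k]) / max(1, abs(num)),
                    1e-6)
        }
      }
    }
  }
})

test_that("isolated nodes depend only on their own features (gcn/sage)", {
  X <- matrix(runif(40), 10, 4)
  y <- rep(0:1, 5)
  edges <- rbind(c(1, 2), c(2, 3), c(4, 5))   # nodes 6..10 isolated
  g <- patient_graph(X, y, edges)
  g1 <- patient_graph(X[7, , drop = FALSE], y[7],
                      matrix(integer(), ncol = 2))
  for (fam in c("gcn5", "sage5")) {
    m <- make_model(fam, 4, 2, seed = 5)
    full <- gnn_forward(m, g)
    solo <- gnn_forward(m, g1)
    expect_lt(max(abs(full[7, ] - solo[1, ])), 1e-10)
  }
})

test_that("neighbor sampler partitions training nodes into capped batches", {
  # sparse ring + chords so sampling is cheap at 15000 train nodes
  n <- 15000L
  edges <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
  extra <- cbind(sample(n, 20000, TRUE), sample(n, 20000, TRUE))
  extra <- extra[extra[, 1] != extra[, 2], ]
  key <- paste(pmin(extra[, 1], extra[, 2]), pmax(extra[, 1], extra[, 2]))
  extra <- extra[!duplicated(key), ]
  ring_key <- paste(pmin(edges[, 1], edges[, 2]),
                    pmax(edges[, 1], edges[, 2]))
  extra <- extra[!(paste(pmin(extra[, 1], extra[, 2]),
                         pmax(extra[, 1], extra[, 2])) %in% ring_key), ]
  g <- patient_graph(matrix(runif(n * 2), n, 2),
                     sample(0:3, n, TRUE), rbind(edges, extra))
  batches <- sample_neighborhoods(g, batch_size = 3000, fanout = 10,
                                  hops = 5, seed = 9)
  expect_length(batches, 5L)
  seeds <- unlist(lapply(batches, `[[`, "seeds"))
  expect_equal(sort(seeds), seq_len(n))        # partition, no repeats
  expect_equal(anyDuplicated(seeds), 0L)
})

test_that("per-hop fanout never exceeds the cap (star graph)", {
  n <- 16L
  star <- cbind(rep(1L, 15), 2:16)
  g <- patient_graph(matrix(runif(n * 2), n, 2), rep(0:1, 8), star)
  batches <- sample_neighborhoods(g, batch_size = 1, fanout = 10, hops = 1,
                                  train_nodes = 1L, seed = 4)
  bt <- batches[[1]]
  # center has 15 neighbours; only 10 may be sampled
  expect_lte(nrow(bt$edges_local), 10L)
  expect_equal(bt$hop_sizes[1], 10L)
})

test_that("training reduces loss on separable data and is seed-reproducible", {
  gen <- generate_cohort(cohort_spec(n = 250, separation = 6,
                                     duplicate_rate = 0, missing_rate = 0,
                                     missing_label_rate = 0, seed = 55))
  pc <- preprocess_cohort(gen$cohort)
  g <- build_graph(pc, metric_spec("cosine", 0.9))
  fit1 <- triage_gnn(g, "sage5", epochs = 25, seed = 8, patience = Inf)
  fit2 <- triage_gnn(g, "sage5", epochs = 25, seed = 8, patience = Inf)
  expect_identical(fit1$history$loss, fit2$history$loss)
  expect_identical(coef(fit1), coef(fit2))
  h <- fit1$history$loss
  expect_lt(median(tail(h, 10)), median(head(h, 10)))
})

test_that("predictions are argmax with ties toward the smallest class", {
  g <- random_graph(n = 24, Fd = 4, C = 4, seed = 56)
  fit <- triage_gnn(g, "gcn4", epochs = 2, seed = 1, patience = Inf)
  logits <- predict(fit, type = "logits")
  cls <- predict(fit, type = "class")
  expect_equal(cls, max.col(logits, ties.method = "first") - 1L)
  # direct tie-break check on the documented rule
  expect_equal(max.col(rbind(c(1, 1, 0, 0)), ties.method = "first") - 1L,
               0L)
  expect_error(predict(fit, nodes = 99L), "index error")
})

test_that("a new node added after training receives a prediction", {
  gen <- generate_cohort(cohort_spec(n = 150, separation = 6, seed = 57))
  pc <- preprocess_cohort(gen$cohort)
  g <- build_graph(pc, metric_spec("cosine", 0.9))
  fit <- triage_gnn(g, "sage5", epochs = 10, seed = 2, patience = Inf)
  # extend the graph with a copy of node 1 connected like node 1
  Xn <- rbind(g$X, g$X[1, ])
  nb <- g$edges[g$edges[, 1] == 1L, 2L]
  new_edges <- rbind(g$edges, cbind(nb, g$n + 1L), c(1L, g$n + 1L))
  g2 <- patient_graph(Xn, c(g$y, NA), new_edges)
  p <- predict(fit, newgraph = g2, nodes = g$n + 1L)
  expect_true(p %in% 0:3)
})

test_that("untrained models predict at chance on balanced labels", {
  gen <- generate_cohort(cohort_spec(n = 200, separation = 0,
                                     cat_signal = 0,
                                     class_proportions = rep(0.25, 4),
                                     duplicate_rate = 0, missing_rate = 0,
                                     missing_label_rate = 0, seed = 58))
  pc <- preprocess_cohort(gen$cohort,
                          preprocess_config(balance = balance_config("none")))
  g <- build_graph(pc, metric_spec("cosine", 0.95))
  m <- make_model("gcn5", ncol(g$X), 4, seed = 6)
  pred <- max.col(gnn_forward(m, g), ties.method = "first") - 1L
  acc <- mean(pred == g$y)
  # untrained accuracy within binomial 4-sigma of 1/C
  expect_lt(abs(acc - 0.25), 4 * sqrt(0.25 * 0.75 / 200))
})

test_that("non-finite losses raise a training error", {
  g <- random_graph(n = 10, Fd = 4, C = 3, seed = 59)
  m <- make_model("gcn4", 4, 3, seed = 1)
  # poison the parameters so the forward pass overflows
  m$layers[[1]]$params$W[] <- 1e308
  expect_error(triage_gnn(g, model = m, epochs = 2, seed = 1,
                          patience = Inf),
               "training error")
})

test_that("sage ablation variants re-chain dimensions consistently", {
  for (w in c(8L, 64L)) {
    for (rem in list(2L, 3L, 4L, 2:4)) {
      m <- make_sage_variant(16, 4, rem, w)
      a <- architecture(m)
      expect_equal(nrow(a), 5L - length(rem))
      expect_equal(a$in_dim[1], 16)
      expect_equal(a$out_dim[nrow(a)], 4)
      if (nrow(a) > 1) expect_equal(a$in_dim[-1], a$out_dim[-nrow(a)])
    }
  }
  # removing layers 2-4 leaves a 2-layer model F -> width -> C
  m2 <- make_sage_variant(16, 4, 2:4, 64)
  a2 <- architecture(m2)
  expect_equal(a2$out_dim, c(64, 4))
  # at fixed width, removing more layers means fewer parameters
  expect_lt(n_params(make_sage_variant(16, 4, 2:4, 8)),
            n_params(make_sage_variant(16, 4, 2L, 8)))
  expect_error(make_sage_variant(16, 4, c(1L, 2L), 8), "removed_layers")
})
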