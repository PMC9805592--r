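test_that("graph convolution matches hand arithmetic and passes through isolated nodes", {
  # single node, no edges, identity self-weight, zero bias -> ReLU(input)
  X <- matrix(c(-1, 0.5, 2), 1, 3)
  out <- graph_convolution(X, matrix(integer(0), 0, 2), numeric(0),
                           Ws = diag(3), Wn = diag(3))
  expect_equal(out, pmax(X, 0))

  # two nodes, one edge with strength 1, hand-set 1x1 weights:
  # h'_1 = ReLU(2*h1 + 3*h2), h'_2 = ReLU(2*h2 + 3*h1)
  X <- matrix(c(1, -2), 2, 1)
  out <- graph_convolution(X, matrix(c(1L, 2L), 1, 2), 1,
                           Ws = matrix(2), Wn = matrix(3))
  expect_equal(as.numeric(out), c(max(2 * 1 + 3 * -2, 0),
                                  max(2 * -2 + 3 * 1, 0)))

  # edge strength scales the neighbour term
  out <- graph_convolution(X, matrix(c(1L, 2L), 1, 2), 0.5,
                           Ws = matrix(0), Wn = matrix(2))
  expect_equal(as.numeric(out), c(0, 1))   # ReLU(0.5*2*(-2))=0; ReLU(0.5*2*1)=1

  expect_error(graph_convolution(X, matrix(c(1L, 2L), 1, 2), 1,
                                 Ws = diag(3), Wn = diag(3)),
               class = "grappi_usage_error")
})

test_that("analytic gradients agree with finite differences", {
  fx <- fixture_graphs(n_graphs = 3, seed = 60)
  g <- fx$graphs[[1]]
  pg <- grappi:::prepare_graph(g)
  eps <- 1e-6

  for (task in c("regression", "classification")) {
    cfg <- ginet_config(n_features = ncol(g$node_features), hidden = 5,
                        fc = 7, task = task, seed = 3)
    m <- ginet(cfg)
    y <- if (task == "regression") 0.4 else 1L
    w <- if (task == "classification") c("0" = 0.25, "1" = 0.75)
    fw <- grappi:::ginet_forward_prepared(m$params, pg, cache = TRUE)
    bl <- grappi:::batch_loss(list(fw$out), y, task, w)
    gr <- grappi:::ginet_backward(m$params, pg, fw, bl$douts[[1]])
    loss_at <- function(theta)
      grappi:::batch_loss(list(grappi:::ginet_forward_prepared(theta, pg)),
                          y, task, w)$loss
    worst <- 0
    for (ly in names(m$params)) for (pn in names(m$params[[ly]])) {
      len <- length(m$params[[ly]][[pn]])
      for (i in unique(pmin(c(1, len %/% 2, len), len))) {
        th <- m$params
        th[[ly]][[pn]][i] <- th[[ly]][[pn]][i] + eps
        lp <- loss_at(th)
        th[[ly]][[pn]][i] <- th[[ly]][[pn]][i] - 2 * eps
        lm <- loss_at(th)
        num <- (lp - lm) / (2 * eps)
        ana <- gr[[ly]][[pn]][i]
        worst <- max(worst, abs(num - ana) / max(1e-6, abs(num) + abs(ana)))
      }
    }
    expect_lt(worst, 1e-4)
  }
})

test_that("GINet output is invariant to node permutation and deterministic", {
  fx <- fixture_graphs(n_graphs = 6, seed = 61)
  g1 <- fx$graphs[[1]]
  cfg <- ginet_config(n_features = ncol(g1$node_features), seed = 5)
  m <- ginet(cfg)
  set.seed(62)
  for (g in fx$graphs) {
    out <- ginet_forward(m, g)
    perm <- sample(nrow(g$nodes))
    expect_lt(max(abs(ginet_forward(m, permute_graph(g, perm)) - out)), 1e-6)
  }
  m2 <- ginet(cfg)   # same seed -> identical init -> identical outputs
  expect_identical(ginet_forward(m, g1), ginet_forward(m2, g1))
})

test_that("a graph with zero internal edges is still scored", {
  s <- toy_structure(list(list(chain = "A", resno = 1, xyz = c(0, 0, 0)),
                          list(chain = "B", resno = 1, xyz = c(6, 0, 0))))
  g <- featurize(build_graph(s), s,
                 config = graph_config(features = c("type", "charge",
                                                    "polarity")))
  expect_equal(nrow(g$internal_edges), 0)
  m <- ginet(ginet_config(n_features = ncol(g$node_features), seed = 1))
  expect_true(is.finite(ginet_forward(m, g)))
})

test_that("prediction batching, probabilities and feature checks behave", {
  fx <- fixture_graphs(n_graphs = 6, seed = 63)
  gs <- fx$graphs
  F <- ncol(gs[[1]]$node_features)
  mc <- ginet(ginet_config(n_features = F, task = "classification", seed = 2))
  p <- ginet_predict(mc, gs)
  expect_equal(unname(rowSums(p)), rep(1, length(gs)), tolerance = 1e-6)
  # single-graph and batched inference agree
  p1 <- ginet_predict(mc, gs[1])
  expect_equal(unname(p1[1, ]), unname(p[1, ]), tolerance = 1e-9)
  expect_equal(nrow(ginet_predict(mc, list())), 0)

  mr <- ginet(ginet_config(n_features = F, seed = 2))
  expect_length(ginet_predict(mr, list()), 0)

  bad <- ginet(ginet_config(n_features = F + 1, seed = 2))
  expect_error(ginet_predict(bad, gs), "width mismatch",
               class = "grappi_feature_mismatch")
})

test_that("training memorizes a small set and selects the best eval epoch", {
  fx <- fixture_graphs(n_graphs = 12, seed = 64, levels = c(0, 2, 5, 8))
  gs <- fx$graphs[seq_len(10)]
  y <- vapply(names(gs), function(id) fnat(fx$decoys$structures[[id]], fx$ref),
              numeric(1))
  m <- ginet(ginet_config(n_features = ncol(gs[[1]]$node_features), seed = 6))
  tc <- train_config(epochs = 250, batch_size = 10, lr = 0.01, scale = TRUE,
                     seed = 6)
  tr <- ginet_train(m, gs, y, gs, y, tc)
  expect_lt(tail(tr$history$train_loss, 1), 1e-3)
  expect_lte(min(tr$history$eval_loss), tr$history$eval_loss[1])
  expect_equal(tr$best_epoch, which.min(tr$history$eval_loss))
})

test_that("training recovers a linear function of mean node features", {
  fx <- fixture_graphs(n_graphs = 40, seed = 65, levels = c(0, 1, 2, 4, 6))
  gs <- fx$graphs
  # synthetic target: linear in the mean node feature vector
  set.seed(66)
  beta <- rnorm(ncol(gs[[1]]$node_features), sd = 0.3)
  y <- vapply(gs, function(g) sum(colMeans(g$node_features) * beta),
              numeric(1))
  y <- as.numeric(scale(y))
  m <- ginet(ginet_config(n_features = length(beta), seed = 7))
  tc <- train_config(epochs = 50, batch_size = 16, lr = 0.01, scale = TRUE,
                     seed = 7)
  tr <- ginet_train(m, gs, y, gs, y, tc)
  expect_lt(tail(tr$history$train_loss, 1), 0.1 * var(y))
})

test_that("classification separates linearly separable graph classes", {
  fx <- fixture_graphs(n_graphs = 40, seed = 67, levels = c(0, 8))
  gs <- fx$graphs
  y <- as.integer(vapply(names(gs), function(id)
    fx$decoys$manifest$level[fx$decoys$manifest$id == id], numeric(1)) > 4)
  m <- ginet(ginet_config(n_features = ncol(gs[[1]]$node_features),
                          task = "classification", seed = 8))
  tc <- train_config(epochs = 60, batch_size = 16, lr = 0.01, scale = TRUE,
                     seed = 8)
  tr <- ginet_train(m, gs, y, gs, y, tc)
  pred <- as.integer(ginet_predict(tr, gs)[, 2] > 0.5)
  expect_gte(mean(pred == y), 0.9)
})

test_that("k-fold duplication of the minority class equals class weight k", {
  fx <- fixture_graphs(n_graphs = 8, seed = 68, levels = c(0, 8))
  gs <- fx$graphs[seq_len(5)]
  y <- c(0L, 0L, 0L, 0L, 1L)
  k <- 3
  cfg <- ginet_config(n_features = ncol(gs[[1]]$node_features),
                      task = "classification", seed = 9)
  # route A: minority example duplicated k times, uniform weights
  gsA <- c(gs, gs[c(5, 5)]); yA <- c(y, 1L, 1L)
  mA <- ginet_train(ginet(cfg), gsA, yA, gsA, yA,
                    train_config(epochs = 1, batch_size = 16, seed = 1))
  # route B: weight k on the minority class
  mB <- ginet_train(ginet(cfg), gs, y, gs, y,
                    train_config(epochs = 1, batch_size = 16,
                                 class_weights = c("0" = 1, "1" = k),
                                 seed = 1))
  expect_equal(mA$params, mB$params, tolerance = 1e-8)
})

test_that("checkpoints round-trip and refuse mismatched features", {
  fx <- fixture_graphs(n_graphs = 3, seed = 69)
  gs <- fx$graphs
  m <- ginet(ginet_config(n_features = ncol(gs[[1]]$node_features), seed = 4),
             feature_names = gs[[1]]$feature_names)
  path <- tempfile(fileext = ".ckpt")
  ginet_save(m, path)
  m2 <- ginet_load(path)
  expect_identical(ginet_predict(m2, gs), ginet_predict(m, gs))
  g_bad <- gs[[1]]
  colnames(g_bad$node_features)[1] <- "other"
  expect_error(ginet_predict(m2, list(g_bad)), "name mismatch",
               class = "grappi_feature_mismatch")
})
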