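#' @title GINet: two-branch graph interaction network
#' @description A graph network for interface graphs with two parallel
#'   message-passing branches: one convolving over internal (same-chain)
#'   edges, one over external (cross-chain) edges. Each branch applies two
#'   edge-strength-weighted graph convolution layers with ReLU activations;
#'   each branch is then flattened by the per-feature mean over nodes, the two
#'   vectors concatenated, and two fully connected layers produce a scalar
#'   (regression) or class logits (classification). Because message passing
#'   only uses graph connectivity and features that are themselves invariant,
#'   the output is invariant to node ordering and to rigid transforms of the
#'   input coordinates. Training uses Adam with MSE (regression) or optionally
#'   class-weighted cross-entropy (classification).
#' @name network
NULL

#' GINet architecture configuration
#'
#' @param n_features Node feature count F of the graphs to be consumed.
#' @param hidden Width of each graph convolution layer (default 16).
#' @param fc Width of the first fully connected layer (default 128).
#' @param task `"regression"` (scalar output) or `"classification"`.
#' @param n_classes Output classes for classification (default 2).
#' @param seed Integer seed controlling parameter initialization.
#' @return A `grappi_ginet_config` list.
#' @export
ginet_config <- function(n_features, hidden = 16L, fc = 128L,
                         task = c("regression", "classification"),
                         n_classes = 2L, seed = 1L) {
  task <- match.arg(task)
  stopifnot(n_features > 0, hidden > 0, fc > 0, n_classes >= 2)
  structure(list(n_features = as.integer(n_features),
                 hidden = as.integer(hidden), fc = as.integer(fc),
                 task = task,
                 n_out = if (task == "regression") 1L else as.integer(n_classes),
                 seed = as.integer(seed)),
            class = "grappi_ginet_config")
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Initialize a GINet model
#'
#' @param config A [ginet_config()].
#' @param feature_names Optional character vector recorded in the model;
#'   scoring refuses graphs whose feature columns do not match.
#' @return A `grappi_ginet` model.
#' @export
ginet <- function(config, feature_names = NULL) {
  set.seed(config$seed)
  F <- config$n_features; h <- config$hidden
  conv <- function(n_in) list(Ws = glorot(n_in, h), Wn = glorot(n_in, h),
                              b = numeric(h))
  params <- list(int1 = conv(F), int2 = conv(h),
                 ext1 = conv(F), ext2 = conv(h),
                 fc1 = list(W = glorot(2L * h, config$fc),
                            b = numeric(config$fc)),
                 fc2 = list(W = glorot(config$fc, config$n_out),
                            b = numeric(config$n_out)))
  structure(list(params = params, config = config,
                 feature_names = feature_names, scaling = NULL),
            class = "grappi_ginet")
}

#' @export
print.grappi_ginet <- function(x, ...) {
  cat(sprintf("<grappi_ginet> task=%s  F=%d  hidden=%d  fc=%d  out=%d\n",
              x$config$task, x$config$n_features, x$config$hidden,
              x$config$fc, x$config$n_out))
  invisible(x)
}

# weighted symmetric adjacency from an i<j edge list (no self loops)
edge_adjacency <- function(n, edges, weights) {
  A <- matrix(0, n, n)
  if (nrow(edges)) {
    A[edges] <- weights
    A[edges[, 2:1, drop = FALSE]] <- weights
  }
  A
}

#' One edge-weighted graph convolution
#'
#' Node update h'_i = ReLU(W_self h_i + sum over neighbours j of
#' e_ij W_nbr h_j + b). Nodes without edges in the given edge set pass
#' through the self term only. Equivariant to node permutation.
#'
#' @param X n x F node feature matrix.
#' @param edges m x 2 integer matrix of undirected edges (1-based, i < j).
#' @param weights Length-m positive edge strengths.
#' @param Ws,Wn F x H self and neighbour weight matrices.
#' @param b Length-H bias.
#' @return n x H updated node feature matrix.
#' @export
graph_convolution <- function(X, edges, weights, Ws, Wn, b = numeric(ncol(Ws))) {
  if (ncol(X) != nrow(Ws) || ncol(X) != nrow(Wn))
    grappi_stop("feature dimension mismatch in graph convolution",
                "grappi_usage_error")
  A <- edge_adjacency(nrow(X), edges, weights)
  Z <- X %*% Ws + A %*% (X %*% Wn)
  pmax(sweep(Z, 2, b, "+"), 0)
}

# prepared representation: feature matrix + dense weighted adjacencies
prepare_graph <- function(graph, scaling = NULL) {
  if (is.null(graph$node_features))
    grappi_stop(paste0("graph not featurized: ", graph$id),
                "grappi_usage_error")
  X <- graph$node_features
  if (!is.null(scaling)) {
    rng <- scaling$max - scaling$min
    rng[rng == 0] <- 1
    X <- sweep(sweep(X, 2, scaling$min), 2, rng, "/")
  }
  wi <- graph$internal_edge_feat %||% edge_strength(graph$internal_dist)
  we <- graph$external_edge_feat %||% edge_strength(graph$external_dist)
  n <- nrow(X)
  list(id = graph$id, X = X,
       A_int = edge_adjacency(n, graph$internal_edges, wi),
       A_ext = edge_adjacency(n, graph$external_edges, we))
}

relu <- function(x) pmax(x, 0)

ginet_forward_prepared <- function(params, pg, cache = FALSE) {
  branch <- function(A, l1, l2) {
    Z1 <- sweep(pg$X %*% l1$Ws + A %*% (pg$X %*% l1$Wn), 2, l1$b, "+")
    H1 <- relu(Z1)
    Z2 <- sweep(H1 %*% l2$Ws + A %*% (H1 %*% l2$Wn), 2, l2$b, "+")
    H2 <- relu(Z2)
    list(Z1 = Z1, H1 = H1, Z2 = Z2, H2 = H2, p = colMeans(H2))
  }
  bi <- branch(pg$A_int, params$int1, params$int2)
  be <- branch(pg$A_ext, params$ext1, params$ext2)
  u <- c(bi$p, be$p)
  a1 <- as.numeric(u %*% params$fc1$W) + params$fc1$b
  f1 <- relu(a1)
  out <- as.numeric(f1 %*% params$fc2$W) + params$fc2$b
  if (!cache) return(out)
  list(out = out, u = u, a1 = a1, f1 = f1, int = bi, ext = be)
}

# analytic gradients for one graph given d(loss)/d(out); returns a list with
# the same skeleton as params
ginet_backward <- function(params, pg, fw, dout) {
  dout <- matrix(dout, 1)
  dW2 <- t(matrix(fw$f1, ncol = 1) %*% dout)
  gfc2 <- list(W = t(dW2), b = as.numeric(dout))
  df1 <- as.numeric(dout %*% t(params$fc2$W))
  da1 <- df1 * (fw$a1 > 0)
  gfc1 <- list(W = matrix(fw$u, ncol = 1) %*% matrix(da1, 1),
               b = da1)
  du <- as.numeric(matrix(da1, 1) %*% t(params$fc1$W))
  h <- length(fw$int$p)
  branch_grad <- function(A, l1, l2, bc, dp) {
    n <- nrow(pg$X)
    dH2 <- matrix(rep(dp / n, each = n), n)
    dZ2 <- dH2 * (bc$Z2 > 0)
    AH1 <- A %*% bc$H1
    g2 <- list(Ws = t(bc$H1) %*% dZ2, Wn = t(AH1) %*% dZ2,
               b = colSums(dZ2))
    dH1 <- dZ2 %*% t(l2$Ws) + A %*% (dZ2 %*% t(l2$Wn))
    dZ1 <- dH1 * (bc$Z1 > 0)
    AX <- A %*% pg$X
    g1 <- list(Ws = t(pg$X) %*% dZ1, Wn = t(AX) %*% dZ1,
               b = colSums(dZ1))
    list(g1 = g1, g2 = g2)
  }
  gi <- branch_grad(pg$A_int, params$int1, params$int2, fw$int, du[seq_len(h)])
  ge <- branch_grad(pg$A_ext, params$ext1, params$ext2, fw$ext, du[h + seq_len(h)])
  list(int1 = gi$g1, int2 = gi$g2, ext1 = ge$g1, ext2 = ge$g2,
       fc1 = gfc1, fc2 = gfc2)
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# loss and per-graph dout for a batch of forward outputs
batch_loss <- function(outs, y, task, weights = NULL) {
  B <- length(outs)
  if (task == "regression") {
    pred <- vapply(outs, `[`, numeric(1), 1)
    list(loss = mean((pred - y)^2),
         douts = lapply(seq_len(B), function(g) 2 * (pred[g] - y[g]) / B))
  } else {
    K <- length(outs[[1]])
    w <- if (is.null(weights)) rep(1, B) else unname(weights[as.character(y)])
    sw <- sum(w)
    probs <- lapply(outs, softmax)
    ll <- vapply(seq_len(B), function(g) -log(max(probs[[g]][y[g] + 1L], 1e-12)),
                 numeric(1))
    douts <- lapply(seq_len(B), function(g) {
      d <- probs[[g]]
      d[y[g] + 1L] <- d[y[g] + 1L] - 1
      w[g] * d / sw
    })
    list(loss = sum(w * ll) / sw, douts = douts)
  }
}

#' Forward pass of a GINet on one interface graph
#'
#' @param model A `grappi_ginet`.
#' @param graph A featurized `grappi_graph`.
#' @return Numeric vector: length 1 (regression) or class logits.
#' @export
ginet_forward <- function(model, graph) {
  check_features(model, list(graph))
  ginet_forward_prepared(model$params, prepare_graph(graph, model$scaling))
}

check_features <- function(model, graphs) {
  for (g in graphs) {
    if (is.null(g$node_features))
      grappi_stop(paste0("graph not featurized: ", g$id), "grappi_usage_error")
    if (ncol(g$node_features) != model$config$n_features)
      grappi_stop(sprintf(
        "feature width mismatch for graph '%s': model expects %d, graph has %d",
        g$id, model$config$n_features, ncol(g$node_features)),
        "grappi_feature_mismatch")
    if (!is.null(model$feature_names) && length(model$feature_names) &&
        !is.null(colnames(g$node_features)) &&
        !identical(colnames(g$node_features), model$feature_names))
      grappi_stop(paste0("feature name mismatch for graph: ", g$id),
                  "grappi_feature_mismatch")
  }
  invisible(TRUE)
}

#' Training configuration
#'
#' Defaults follow the reference protocol for docking-model scoring: Adam,
#' learning rate 0.001, batches of 128 shuffled graphs, 20 epochs (use 50 for
#' the classification application).
#'
#' @param epochs Training epochs.
#' @param batch_size Graphs per batch.
#' @param lr Adam learning rate.
#' @param class_weights `NULL` (uniform), `"auto"` (inverse class frequency
#'   via [class_weights()]) or a named numeric vector; classification only.
#' @param scale If `TRUE`, min-max scale node features using training-set
#'   statistics (stored in the model and re-applied at prediction time).
#' @param seed Seed for shuffling.
#' @return A `grappi_train_config` list.
#' @export
train_config <- function(epochs = 20L, batch_size = 128L, lr = 0.001,
                         class_weights = NULL, scale = FALSE, seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, lr > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 class_weights = class_weights, scale = isTRUE(scale),
                 seed = as.integer(seed)),
            class = "grappi_train_config")
}

#' Train a GINet
#'
#' Minimizes MSE (regression) or cross-entropy with optional class weights
#' (classification) with Adam over shuffled batches. The returned model
#' carries the parameters achieving the minimum evaluation-set loss across
#' epochs, plus the full per-epoch loss trace.
#'
#' @param model A `grappi_ginet` from [ginet()].
#' @param train_graphs,eval_graphs Lists of featurized `grappi_graph`.
#' @param train_targets,eval_targets Numeric targets (regression) or integer
#'   class labels in 0..K-1 (classification), aligned with the graph lists.
#' @param config A [train_config()].
#' @return The trained model, with `history` (data.frame epoch/train_loss/
#'   eval_loss) and `best_epoch` fields.
#' @export
ginet_train <- function(model, train_graphs, train_targets,
                        eval_graphs, eval_targets,
                        config = train_config()) {
  if (!length(train_graphs) || !length(eval_graphs))
    grappi_stop("empty training or evaluation set", "grappi_usage_error")
  stopifnot(length(train_graphs) == length(train_targets),
            length(eval_graphs) == length(eval_targets))
  check_features(model, train_graphs)
  check_features(model, eval_graphs)
  task <- model$config$task
  if (task == "classification") {
    train_targets <- as.integer(train_targets)
    eval_targets <- as.integer(eval_targets)
    if (any(train_targets < 0 | train_targets >= model$config$n_out))
      grappi_stop("class labels must lie in 0..K-1", "grappi_usage_error")
  }
  cw <- config$class_weights
  if (identical(cw, "auto")) cw <- class_weights(train_targets)

  if (config$scale) {
    allX <- do.call(rbind, lapply(train_graphs, function(g) g$node_features))
    model$scaling <- list(min = apply(allX, 2, min), max = apply(allX, 2, max))
  }
  ptr <- lapply(train_graphs, prepare_graph, scaling = model$scaling)
  pev <- lapply(eval_graphs, prepare_graph, scaling = model$scaling)

  theta <- model$params
  skel <- rapply(theta, function(x) x * 0, how = "replace")
  madam <- skel; vadam <- skel
  t_step <- 0L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8

  add_lists <- function(a, b) mapply(function(x, y) {
    if (is.list(x)) add_lists(x, y) else x + y
  }, a, b, SIMPLIFY = FALSE)

  eval_loss <- function(pgs, y) {
    outs <- lapply(pgs, function(pg) ginet_forward_prepared(theta, pg))
    batch_loss(outs, y, task, cw)$loss
  }

  set.seed(config$seed)
  n <- length(ptr)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        eval_loss = numeric(0))
  best <- list(loss = Inf, params = theta, epoch = 0L)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0
    for (bt in batches) {
      fws <- lapply(ptr[bt], function(pg)
        ginet_forward_prepared(theta, pg, cache = TRUE))
      outs <- lapply(fws, `[[`, "out")
      bl <- batch_loss(outs, train_targets[bt], task, cw)
      if (!is.finite(bl$loss))
        grappi_stop(sprintf("non-finite loss at epoch %d; try a lower lr",
                            epoch), "grappi_train_error")
      ep_loss <- ep_loss + bl$loss * length(bt)
      grad <- NULL
      for (g in seq_along(bt)) {
        gg <- ginet_backward(theta, ptr[[bt[g]]], fws[[g]], bl$douts[[g]])
        grad <- if (is.null(grad)) gg else add_lists(grad, gg)
      }
      t_step <- t_step + 1L
      upd <- function(p, g, m, v) {
        if (is.list(p)) return(mapply(upd, p, g, m, v, SIMPLIFY = FALSE))
        m <- b1 * m + (1 - b1) * g
        v <- b2 * v + (1 - b2) * g^2
        mh <- m / (1 - b1^t_step)
        vh <- v / (1 - b2^t_step)
        list(p = p - config$lr * mh / (sqrt(vh) + eps), m = m, v = v)
      }
      res <- mapply(upd, theta, grad, madam, vadam, SIMPLIFY = FALSE)
      theta <- lapply(res, function(layer) lapply(layer, `[[`, "p"))
      madam <- lapply(res, function(layer) lapply(layer, `[[`, "m"))
      vadam <- lapply(res, function(layer) lapply(layer, `[[`, "v"))
    }
    ev <- eval_loss(pev, eval_targets)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = ep_loss / n,
                                         eval_loss = ev))
    if (ev < best$loss) best <- list(loss = ev, params = theta, epoch = epoch)
  }
  model$params <- best$params
  model$history <- history
  model$best_epoch <- best$epoch
  model$class_weights_used <- cw
  model
}

#' Score graphs with a trained GINet
#'
#' @param model A `grappi_ginet`.
#' @param graphs List of featurized `grappi_graph` (may be empty).
#' @return Regression: numeric vector of scores. Classification: matrix of
#'   class probabilities (rows sum to 1), one row per graph.
#' @export
ginet_predict <- function(model, graphs) {
  if (!length(graphs)) {
    return(if (model$config$task == "regression") numeric(0)
           else matrix(numeric(0), 0, model$config$n_out))
  }
  check_features(model, graphs)
  outs <- lapply(graphs, function(g)
    ginet_forward_prepared(model$params, prepare_graph(g, model$scaling)))
  if (model$config$task == "regression") {
    vapply(outs, `[`, numeric(1), 1)
  } else {
    p <- do.call(rbind, lapply(outs, softmax))
    colnames(p) <- paste0("class_", seq_len(ncol(p)) - 1L)
    p
  }
}

#' @export
predict.grappi_ginet <- function(object, newdata, ...) {
  ginet_predict(object, newdata)
}

#' Save / load a GINet checkpoint
#'
#' A single-file serialized parameter set together with the architecture
#' config, the feature column names and any feature scaling statistics.
#' Loading a checkpoint and scoring graphs whose feature columns do not match
#' raises an error.
#'
#' @param model A `grappi_ginet`.
#' @param path Checkpoint path.
#' @return `ginet_save` invisibly returns `path`; `ginet_load` the model.
#' @export
ginet_save <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname ginet_save
#' @export
ginet_load <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "grappi_ginet"))
    grappi_stop("not a GINet checkpoint", "grappi_io_error")
  m
}
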