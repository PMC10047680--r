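#' Configuration for the graph convolutional network
#'
#' Defaults follow the model's stated configuration: two 16-unit hidden
#' layers with dropouts 0.005 and 0.4 applied to the respective layer
#' inputs, softmax output over 2 classes, adaptive-moment optimiser.
#'
#' @param hidden_layers integer vector of hidden widths (default `c(16, 16)`).
#' @param dropouts dropout rate per hidden layer (default `c(0.005, 0.4)`).
#' @param n_classes number of classes (default 2).
#' @param seed integer seed.
#' @param epochs training epochs (default 200).
#' @param learning_rate Adam learning rate (default 0.01).
#' @param weight_decay L2 penalty on the first-layer weights (default 5e-4).
#' @return A list of class `gcn_config`.
#' @export
gcn_config <- function(hidden_layers = c(16L, 16L), dropouts = c(0.005, 0.4),
                       n_classes = 2L, seed = 1L, epochs = 200L,
                       learning_rate = 0.01, weight_decay = 5e-4) {
  assert_that(length(dropouts) == length(hidden_layers),
              "dropouts length must equal hidden_layers length")
  assert_that(all(dropouts >= 0 & dropouts < 1), "dropouts must lie in [0, 1)")
  structure(list(hidden_layers = as.integer(hidden_layers),
                 dropouts = dropouts, n_classes = as.integer(n_classes),
                 seed = as.integer(seed), epochs = as.integer(epochs),
                 learning_rate = learning_rate, weight_decay = weight_decay),
            class = "gcn_config")
}

#' Symmetrically normalised adjacency
#'
#' Adds self-loops and normalises: with A-bar = A + I and D-bar its degree
#' matrix, returns D-bar^(-1/2) A-bar D-bar^(-1/2), whose (i, j) entry is
#' A-bar_ij / sqrt((d_i + 1)(d_j + 1)).
#'
#' @param A binary symmetric adjacency matrix with zero diagonal.
#' @return The normalised N x N matrix.
#' @export
normalize_adjacency <- function(A) {
  A <- as.matrix(A)
  assert_that(isTRUE(all.equal(A, t(A))), "adjacency must be symmetric")
  assert_that(all(diag(A) == 0), "adjacency must have a zero diagonal (self-loops are added here)")
  Abar <- A + diag(nrow(A))
  dinv <- 1 / sqrt(rowSums(Abar))
  Abar * outer(dinv, dinv)
}

# Forward pass; returns activations and pre-activations per layer.
gcn_layers_forward <- function(A_hat, X, weights, cfg, training = FALSE,
                               dropout_masks = NULL) {
  H <- X
  acts <- list(H)
  pre <- list()
  masks <- list()
  n_hidden <- length(cfg$hidden_layers)
  for (l in seq_len(n_hidden + 1L)) {
    Hin <- H
    if (l <= n_hidden && training && cfg$dropouts[l] > 0) {
      m <- dropout_masks[[l]] %||%
        matrix(stats::runif(length(Hin)) >= cfg$dropouts[l], nrow(Hin), ncol(Hin))
      masks[[l]] <- m
      Hin <- Hin * m / (1 - cfg$dropouts[l])
    }
    Z <- A_hat %*% (Hin %*% weights[[l]])
    pre[[l]] <- Z
    H <- if (l <= n_hidden) relu(Z) else Z
    acts[[l + 1L]] <- H
  }
  list(logits = H, probs = softmax_rows(H), acts = acts, pre = pre, masks = masks)
}

#' GCN forward pass
#'
#' Propagation per layer: `H^k = ReLU(A_hat %*% H^(k-1) %*% W^(k-1))`, with
#' layer dropout on hidden inputs when `training = TRUE`; the final layer is
#' linear followed by row-wise softmax, so every row of the result sums to 1.
#'
#' @param A_hat a [normalize_adjacency()] result.
#' @param X N x F node-feature matrix.
#' @param weights list of weight matrices (one per hidden layer plus the
#'   output layer).
#' @param cfg a [gcn_config()].
#' @param training apply dropout.
#' @return N x n_classes matrix of class probabilities.
#' @export
gcn_forward <- function(A_hat, X, weights, cfg = gcn_config(), training = FALSE) {
  assert_that(nrow(X) == nrow(A_hat), "X and A_hat disagree on node count")
  gcn_layers_forward(A_hat, X, weights, cfg, training = training)$probs
}

#' Fit a GCN on a population graph
#'
#' Full-batch gradient training of the semi-supervised node classifier:
#' cross-entropy on the training-mask nodes, symmetric-limit uniform
#' (Glorot) initialisation, adaptive-moment optimiser with L2 weight decay
#' on the first layer, all seeded.
#'
#' @param graph a [population_graph()].
#' @param cfg a [gcn_config()].
#' @return An object of class `gcn_fit` with `weights`, `cfg`, the
#'   normalised adjacency and a per-epoch training-log tibble.
#' @export
gcn_fit <- function(graph, cfg = gcn_config()) {
  assert_that(inherits(graph, "population_graph"), "graph must be a population_graph")
  y <- graph$labels[graph$train_mask]
  assert_that(length(unique(y)) >= 2,
              "training mask must contain at least one node of each class")
  A_hat <- normalize_adjacency(graph$adjacency)
  X <- graph$node_features
  n <- nrow(X)
  sizes <- c(ncol(X), cfg$hidden_layers, cfg$n_classes)
  train_idx <- which(graph$train_mask)
  Yhot <- matrix(0, n, cfg$n_classes)
  Yhot[cbind(train_idx, graph$labels[train_idx] + 1L)] <- 1
  n_train <- length(train_idx)
  log_rows <- vector("list", cfg$epochs)
  with_seed(derive_seed(cfg$seed, "gcn"), {
    weights <- lapply(seq_len(length(sizes) - 1L),
                      function(l) glorot_uniform(sizes[l], sizes[l + 1L]))
    opt <- vector("list", length(weights))
    for (ep in seq_len(cfg$epochs)) {
      fw <- gcn_layers_forward(A_hat, X, weights, cfg, training = TRUE)
      p_train <- fw$probs[train_idx, , drop = FALSE]
      loss <- -mean(log(rowSums(p_train * Yhot[train_idx, , drop = FALSE]) + 1e-12)) +
        cfg$weight_decay * sum(weights[[1]]^2) / 2
      assert_that(is.finite(loss), "GCN training diverged at epoch %d", ep)
      acc <- mean(max.col(p_train, ties.method = "first") - 1L == graph$labels[train_idx])
      log_rows[[ep]] <- tibble::tibble(epoch = ep, loss = loss, accuracy = acc)
      # backward
      dZ <- (fw$probs - Yhot)
      dZ[-train_idx, ] <- 0
      dZ <- dZ / n_train
      grads <- vector("list", length(weights))
      n_hidden <- length(cfg$hidden_layers)
      for (l in rev(seq_along(weights))) {
        if (l <= n_hidden) dZ <- dZ * (fw$pre[[l]] > 0)   # through ReLU of layer l
        Hin <- fw$acts[[l]]                               # input to layer l
        if (l <= n_hidden && cfg$dropouts[l] > 0) {
          Hin <- Hin * fw$masks[[l]] / (1 - cfg$dropouts[l])
        }
        AtdZ <- crossprod(A_hat, dZ)   # A_hat symmetric, but keep it general
        grads[[l]] <- crossprod(Hin, AtdZ)
        if (l > 1L) {
          dHm <- AtdZ %*% t(weights[[l]])                 # wrt layer-l masked input
          if (l <= n_hidden && cfg$dropouts[l] > 0) {
            dHm <- dHm * fw$masks[[l]] / (1 - cfg$dropouts[l])
          }
          dZ <- dHm                                       # wrt act of layer l-1
        }
      }
      grads[[1]] <- grads[[1]] + cfg$weight_decay * weights[[1]]
      for (l in seq_along(weights)) {
        st <- adam_step(weights[[l]], grads[[l]], opt[[l]], cfg$learning_rate)
        weights[[l]] <- st$w
        opt[[l]] <- st$state
      }
    }
    structure(list(weights = weights, cfg = cfg, A_hat = A_hat,
                   log = do.call(rbind, log_rows)),
              class = "gcn_fit")
  })
}

#' @export
print.gcn_fit <- function(x, ...) {
  cat(sprintf("<gcn_fit> layers %s; final train loss %.4g, accuracy %.3f\n",
              paste(vapply(x$weights, ncol, 0L), collapse = " -> "),
              tail(x$log$loss, 1), tail(x$log$accuracy, 1)))
  invisible(x)
}

#' Predict node classes with a fitted GCN
#'
#' Deterministic forward pass (dropout off); argmax with ties broken toward
#' the lower class index.
#'
#' @param fit a [gcn_fit()] result.
#' @param graph the [population_graph()] to predict on.
#' @return List with `labels` (integer vector) and `probs` (N x n_classes).
#' @export
gcn_predict <- function(fit, graph) {
  A_hat <- normalize_adjacency(graph$adjacency)
  probs <- gcn_forward(A_hat, graph$node_features, fit$weights, fit$cfg,
                       training = FALSE)
  list(labels = max.col(probs, ties.method = "first") - 1L, probs = probs)
}

#' Tidy a GCN training log
#'
#' @param x a `gcn_fit`.
#' @param ... unused.
#' @return The per-epoch tibble of training loss and accuracy.
#' @method tidy gcn_fit
#' @export
tidy.gcn_fit <- function(x, ...) x$log

#' Glance at a fitted GCN
#'
#' @param x a `gcn_fit`.
#' @param ... unused.
#' @return One-row tibble of architecture and final training metrics.
#' @method glance gcn_fit
#' @export
glance.gcn_fit <- function(x, ...) {
  tibble::tibble(n_layers = length(x$weights),
                 hidden = paste(x$cfg$hidden_layers, collapse = ","),
                 epochs = x$cfg$epochs,
                 final_loss = tail(x$log$loss, 1),
                 final_train_accuracy = tail(x$log$accuracy, 1))
}

#' Plot a GCN training log
#'
#' @param object a `gcn_fit`.
#' @param ... unused.
#' @return A ggplot of loss and training accuracy against epoch.
#' @method autoplot gcn_fit
#' @export
autoplot.gcn_fit <- function(object, ...) {
  d <- object$log
  long <- rbind(tibble::tibble(epoch = d$epoch, metric = "loss", value = d$loss),
                tibble::tibble(epoch = d$epoch, metric = "train accuracy", value = d$accuracy))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL)
}
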