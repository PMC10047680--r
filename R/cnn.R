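#' Configuration for the multichannel 3D CNN node encoder
#'
#' Architecture: a first convolution block, then `repeated_blocks` blocks
#' whose filter counts start at 32 and double each block (32, 64, 128, 256
#' for the default 4), each block being convolution (3x3x3, same padding) +
#' ReLU + batch normalisation + max pooling (2x2x2, valid), followed by
#' global average pooling, a dense layer (default 1024 units, ReLU) whose
#' activations are the node features, dropout, and a 2-class softmax head.
#'
#' @param input_shape integer vector (x, y, z, channels).
#' @param first_block_filters filters in the first block (default 16).
#' @param repeated_blocks number of doubling blocks after the first
#'   (default 4).
#' @param dense_units width of the node-feature dense layer (default 1024).
#' @param dropout dropout rate before the softmax head (default 0.5).
#' @param seed integer seed for weight initialisation and dropout.
#' @param epochs training epochs (default 30).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @return A list of class `cnn_config`.
#' @export
cnn_config <- function(input_shape, first_block_filters = 16L,
                       repeated_blocks = 4L, dense_units = 1024L,
                       dropout = 0.5, seed = 1L, epochs = 30L,
                       learning_rate = 1e-3) {
  assert_that(length(input_shape) == 4 && all(input_shape >= 1),
              "input_shape must be (x, y, z, channels)")
  assert_that(repeated_blocks >= 1, "repeated_blocks must be >= 1")
  assert_that(dropout >= 0 && dropout < 1, "dropout must lie in [0, 1)")
  filters <- c(first_block_filters, 32L * 2L^(seq_len(repeated_blocks) - 1L))
  structure(list(input_shape = as.integer(input_shape),
                 filters = as.integer(filters),
                 dense_units = as.integer(dense_units),
                 dropout = dropout, seed = as.integer(seed),
                 epochs = as.integer(epochs), learning_rate = learning_rate),
            class = "cnn_config")
}

# --- low-level layers (feature maps are 4D arrays (x, y, z, channels)) -------

conv_offsets <- function() {
  as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
}

# im2col for a 3x3x3 same-padded convolution: returns nvox x (27 * C) matrix;
# column block o holds the C channels at offset o (dx fastest offset order).
im2col3 <- function(x) {
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L, d[2] + 2L, d[3] + 2L, d[4]))
  xp[1L + seq_len(d[1]), 1L + seq_len(d[2]), 1L + seq_len(d[3]), ] <- x
  offs <- conv_offsets()
  nvox <- prod(d[1:3])
  P <- matrix(0, nvox, 27L * d[4])
  for (o in seq_len(27L)) {
    sl <- xp[offs[o, 1] + 1L + seq_len(d[1]),
             offs[o, 2] + 1L + seq_len(d[2]),
             offs[o, 3] + 1L + seq_len(d[3]), , drop = FALSE]
    P[, (o - 1L) * d[4] + seq_len(d[4])] <- matrix(sl, nvox, d[4])
  }
  P
}

# Scatter a patch-gradient matrix back onto the input grid (adjoint of im2col3).
col2im3 <- function(dP, d) {
  xp <- array(0, c(d[1] + 2L, d[2] + 2L, d[3] + 2L, d[4]))
  offs <- conv_offsets()
  for (o in seq_len(27L)) {
    blk <- array(dP[, (o - 1L) * d[4] + seq_len(d[4])], c(d[1:3], d[4]))
    ix <- offs[o, 1] + 1L + seq_len(d[1])
    iy <- offs[o, 2] + 1L + seq_len(d[2])
    iz <- offs[o, 3] + 1L + seq_len(d[3])
    xp[ix, iy, iz, ] <- xp[ix, iy, iz, , drop = FALSE] + blk
  }
  xp[1L + seq_len(d[1]), 1L + seq_len(d[2]), 1L + seq_len(d[3]), , drop = FALSE]
}

conv3d_forward <- function(x, W, b) {
  d <- dim(x)
  P <- im2col3(x)
  Y <- sweep(P %*% W, 2, b, "+")
  list(out = array(Y, c(d[1:3], ncol(W))), P = P)
}

# 2x2x2 valid max pooling; odd trailing voxels are cropped.
maxpool3 <- function(x) {
  d <- dim(x)
  d2 <- d[1:3] %/% 2L
  assert_that(all(d2 >= 1), "spatial dims %s too small for 2x2x2 pooling",
              paste(d[1:3], collapse = "x"))
  xc <- x[seq_len(2L * d2[1]), seq_len(2L * d2[2]), seq_len(2L * d2[3]), , drop = FALSE]
  dim(xc) <- c(2L, d2[1], 2L, d2[2], 2L, d2[3], d[4])
  xr <- aperm(xc, c(1, 3, 5, 2, 4, 6, 7))
  m <- matrix(xr, 8L, prod(d2) * d[4])
  best <- m[1, ]
  idx <- rep(1L, ncol(m))
  for (r in 2:8) {
    hit <- m[r, ] > best
    best[hit] <- m[r, hit]
    idx[hit] <- r
  }
  list(out = array(best, c(d2, d[4])), argmax = idx, in_dim = d)
}

maxpool3_backward <- function(dout, cache) {
  d <- cache$in_dim
  d2 <- d[1:3] %/% 2L
  m <- matrix(0, 8L, prod(d2) * d[4])
  m[cbind(cache$argmax, seq_len(ncol(m)))] <- as.vector(dout)
  xr <- array(m, c(2L, 2L, 2L, d2, d[4]))
  xc <- aperm(xr, c(1, 4, 2, 5, 3, 6, 7))
  dx <- array(0, d)
  dx[seq_len(2L * d2[1]), seq_len(2L * d2[2]), seq_len(2L * d2[3]), ] <-
    array(xc, c(2L * d2, d[4]))
  dx
}

# Batch normalisation over (batch x voxels) per channel. `xs` is a list of
# 4D arrays with equal dims.
bn_forward <- function(xs, gamma, beta, eps = 1e-5, training = TRUE,
                       running = NULL, momentum = 0.9) {
  d <- dim(xs[[1]])
  C <- d[4]
  nvox <- prod(d[1:3])
  B <- length(xs)
  M <- do.call(rbind, lapply(xs, function(a) matrix(a, nvox, C)))
  if (training) {
    mu <- colMeans(M)
    va <- colMeans(M^2) - mu^2
  } else {
    mu <- running$mean
    va <- running$var
  }
  xhat <- sweep(sweep(M, 2, mu), 2, sqrt(va + eps), "/")
  out_m <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  outs <- lapply(seq_len(B), function(s) {
    array(out_m[(s - 1L) * nvox + seq_len(nvox), , drop = FALSE], d)
  })
  new_running <- if (training) {
    if (is.null(running)) list(mean = mu, var = va)
    else list(mean = momentum * running$mean + (1 - momentum) * mu,
              var = momentum * running$var + (1 - momentum) * va)
  } else running
  list(out = outs, cache = list(xhat = xhat, mu = mu, va = va, eps = eps, d = d, B = B),
       running = new_running)
}

bn_backward <- function(douts, cache, gamma) {
  d <- cache$d
  nvox <- prod(d[1:3])
  C <- d[4]
  dM <- do.call(rbind, lapply(douts, function(a) matrix(a, nvox, C)))
  n <- nrow(dM)
  xhat <- cache$xhat
  istd <- 1 / sqrt(cache$va + cache$eps)
  dgamma <- colSums(dM * xhat)
  dbeta <- colSums(dM)
  dxhat <- sweep(dM, 2, gamma, "*")
  dx <- sweep(dxhat - matrix(colMeans(dxhat), n, C, byrow = TRUE) -
              sweep(xhat, 2, colMeans(dxhat * xhat), "*"),
              2, istd, "*")
  dxs <- lapply(seq_len(cache$B), function(s) {
    array(dx[(s - 1L) * nvox + seq_len(nvox), , drop = FALSE], d)
  })
  list(dxs = dxs, dgamma = dgamma, dbeta = dbeta)
}

# --- model -------------------------------------------------------------------

#' Build the multichannel 3D CNN
#'
#' Initialises seeded weights and derives the per-layer output shapes,
#' erroring if any pooling stage would exhaust a spatial axis.
#'
#' @param cfg a [cnn_config()].
#' @return An object of class `cnn_model` with `params`, `cfg` and a
#'   `shapes` tibble listing every layer's output shape.
#' @export
cnn_build <- function(cfg) {
  d <- cfg$input_shape
  shapes <- list(tibble::tibble(layer = "input", shape = paste(d, collapse = "x")))
  spatial <- d[1:3]
  c_in <- d[4]
  params <- list(blocks = list())
  with_seed(derive_seed(cfg$seed, "cnn_init"), {
    for (bi in seq_along(cfg$filters)) {
      f <- cfg$filters[bi]
      params$blocks[[bi]] <- list(
        W = glorot_uniform(27L * c_in, f),
        b = rep(0, f),
        gamma = rep(1, f),
        beta = rep(0, f),
        running = NULL
      )
      shapes[[length(shapes) + 1L]] <- tibble::tibble(
        layer = sprintf("block%d_conv(%d)", bi, f),
        shape = paste(c(spatial, f), collapse = "x"))
      assert_that(all(spatial >= 2),
                  "input too small: pooling stage %d needs spatial dims >= 2, has %s",
                  bi, paste(spatial, collapse = "x"))
      spatial <- spatial %/% 2L
      shapes[[length(shapes) + 1L]] <- tibble::tibble(
        layer = sprintf("block%d_pool", bi),
        shape = paste(c(spatial, f), collapse = "x"))
      c_in <- f
    }
    params$dense1 <- list(W = glorot_uniform(c_in, cfg$dense_units),
                          b = rep(0, cfg$dense_units))
    params$dense2 <- list(W = glorot_uniform(cfg$dense_units, 2L), b = rep(0, 2L))
  })
  shapes[[length(shapes) + 1L]] <- tibble::tibble(layer = "global_avg_pool",
                                                  shape = as.character(c_in))
  shapes[[length(shapes) + 1L]] <- tibble::tibble(layer = "dense_features",
                                                  shape = as.character(cfg$dense_units))
  shapes[[length(shapes) + 1L]] <- tibble::tibble(layer = "softmax", shape = "2")
  structure(list(cfg = cfg, params = params, shapes = do.call(rbind, shapes),
                 log = NULL),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model> %d blocks (filters %s), dense %d\n",
              length(x$cfg$filters), paste(x$cfg$filters, collapse = ","),
              x$cfg$dense_units))
  print(as.data.frame(x$shapes), row.names = FALSE)
  invisible(x)
}

# Forward pass over a batch (list of 4D arrays). Returns activations and
# caches; `training` switches batch-norm statistics and dropout.
cnn_forward <- function(params, xs, cfg, training = FALSE, dropout_mask = NULL) {
  B <- length(xs)
  caches <- list(blocks = list())
  cur <- xs
  for (bi in seq_along(params$blocks)) {
    blk <- params$blocks[[bi]]
    convs <- lapply(cur, conv3d_forward, W = blk$W, b = blk$b)
    z <- lapply(convs, `[[`, "out")
    a <- lapply(z, relu)
    bn <- bn_forward(a, blk$gamma, blk$beta, training = training,
                     running = blk$running)
    pools <- lapply(bn$out, maxpool3)
    caches$blocks[[bi]] <- list(P = lapply(convs, `[[`, "P"),
                                relu_in = z, bn = bn$cache,
                                pools = pools, running = bn$running)
    cur <- lapply(pools, `[[`, "out")
  }
  G <- do.call(rbind, lapply(cur, function(a) {
    d <- dim(a)
    colMeans(matrix(a, prod(d[1:3]), d[4]))
  }))
  H_pre <- sweep(G %*% params$dense1$W, 2, params$dense1$b, "+")
  H <- relu(H_pre)
  Hd <- H
  if (training && cfg$dropout > 0) {
    if (is.null(dropout_mask)) {
      dropout_mask <- matrix(stats::runif(length(H)) >= cfg$dropout, nrow(H), ncol(H))
    }
    Hd <- H * dropout_mask / (1 - cfg$dropout)
  }
  logits <- sweep(Hd %*% params$dense2$W, 2, params$dense2$b, "+")
  probs <- softmax_rows(logits)
  list(probs = probs, features = H,
       caches = c(caches, list(G = G, H_pre = H_pre, H = H, Hd = Hd,
                               dropout_mask = dropout_mask,
                               pooled_dims = lapply(cur, dim))))
}

#' Train the CNN on labelled summary stacks
#'
#' Full-batch supervised training with binary cross-entropy, an
#' adaptive-moment optimiser and seeded initialisation/dropout, so runs are
#' reproducible under a fixed seed and single-threaded execution.
#'
#' @param model a [cnn_build()] result.
#' @param stacks list of [summary_stack()] objects (or 4D arrays), one per
#'   subject, all with the model's input shape.
#' @param labels integer vector in \{0, 1\}.
#' @return The trained `cnn_model`, with a training-log tibble in `$log`.
#' @export
cnn_train <- function(model, stacks, labels) {
  cfg <- model$cfg
  xs <- lapply(stacks, function(s) if (inherits(s, "summary_stack")) s$data else s)
  for (x in xs) {
    assert_that(all(dim(x) == cfg$input_shape),
                "stack shape %s does not match model input %s",
                paste(dim(x), collapse = "x"), paste(cfg$input_shape, collapse = "x"))
  }
  assert_that(length(labels) == length(xs), "one label per stack required")
  assert_that(all(labels %in% c(0L, 1L)), "labels must be 0/1")
  counts <- table(factor(labels, levels = c(0L, 1L)))
  assert_that(min(counts) >= 2, "need at least 2 subjects per class")
  params <- model$params
  B <- length(xs)
  Y <- cbind(1 - labels, labels)  # class 0, class 1 columns
  opt <- list()
  log_rows <- vector("list", cfg$epochs)
  with_seed(derive_seed(cfg$seed, "cnn_train"), {
    for (ep in seq_len(cfg$epochs)) {
      fw <- cnn_forward(params, xs, cfg, training = TRUE)
      loss <- -mean(log(rowSums(fw$probs * Y) + 1e-12))
      assert_that(is.finite(loss), "training diverged (non-finite loss) at epoch %d", ep)
      acc <- mean(max.col(fw$probs, ties.method = "first") - 1L == labels)
      log_rows[[ep]] <- tibble::tibble(epoch = ep, loss = loss, accuracy = acc)
      ca <- fw$caches
      # gradients: softmax + cross-entropy
      dlogits <- (fw$probs - Y) / B
      g_d2W <- crossprod(ca$Hd, dlogits)
      g_d2b <- colSums(dlogits)
      dHd <- dlogits %*% t(params$dense2$W)
      dH <- if (cfg$dropout > 0) dHd * ca$dropout_mask / (1 - cfg$dropout) else dHd
      dH[ca$H_pre <= 0] <- 0
      g_d1W <- crossprod(ca$G, dH)
      g_d1b <- colSums(dH)
      dG <- dH %*% t(params$dense1$W)
      # through global average pooling into per-subject arrays
      dcur <- lapply(seq_len(B), function(s) {
        d <- ca$pooled_dims[[s]]
        nvox <- prod(d[1:3])
        array(rep(dG[s, ], each = nvox) / nvox, d)
      })
      grads <- list(blocks = vector("list", length(params$blocks)))
      for (bi in rev(seq_along(params$blocks))) {
        bc <- ca$blocks[[bi]]
        dbn_out <- lapply(seq_len(B), function(s) maxpool3_backward(dcur[[s]], bc$pools[[s]]))
        bb <- bn_backward(dbn_out, bc$bn, params$blocks[[bi]]$gamma)
        da <- bb$dxs
        gW <- 0; gb <- 0
        dcur <- vector("list", B)
        for (s in seq_len(B)) {
          dz <- da[[s]]
          dz[bc$relu_in[[s]] <= 0] <- 0
          d <- dim(dz)
          dzm <- matrix(dz, prod(d[1:3]), d[4])
          gW <- gW + crossprod(bc$P[[s]], dzm)
          gb <- gb + colSums(dzm)
          dP <- dzm %*% t(params$blocks[[bi]]$W)
          in_c <- nrow(params$blocks[[bi]]$W) / 27L
          dcur[[s]] <- col2im3(dP, c(d[1:3], in_c))
        }
        grads$blocks[[bi]] <- list(W = gW, b = gb, gamma = bb$dgamma, beta = bb$dbeta)
        params$blocks[[bi]]$running <- bc$running
      }
      # Adam updates
      upd <- function(path, value, grad) {
        key <- paste(path, collapse = ".")
        st <- adam_step(value, grad, opt[[key]], cfg$learning_rate)
        opt[[key]] <<- st$state
        st$w
      }
      for (bi in seq_along(params$blocks)) {
        params$blocks[[bi]]$W <- upd(c("b", bi, "W"), params$blocks[[bi]]$W, grads$blocks[[bi]]$W)
        params$blocks[[bi]]$b <- upd(c("b", bi, "b"), params$blocks[[bi]]$b, grads$blocks[[bi]]$b)
        params$blocks[[bi]]$gamma <- upd(c("b", bi, "g"), params$blocks[[bi]]$gamma, grads$blocks[[bi]]$gamma)
        params$blocks[[bi]]$beta <- upd(c("b", bi, "be"), params$blocks[[bi]]$beta, grads$blocks[[bi]]$beta)
      }
      params$dense1$W <- upd(c("d1", "W"), params$dense1$W, g_d1W)
      params$dense1$b <- upd(c("d1", "b"), params$dense1$b, g_d1b)
      params$dense2$W <- upd(c("d2", "W"), params$dense2$W, g_d2W)
      params$dense2$b <- upd(c("d2", "b"), params$dense2$b, g_d2b)
    }
  })
  model$params <- params
  model$log <- do.call(rbind, log_rows)
  model
}

#' Encode subjects into node features with the CNN
#'
#' Runs the network in inference mode (batch-norm running statistics,
#' dropout off) and returns the post-ReLU activations of the dense feature
#' layer, one row per subject in input order.
#'
#' @param model a trained (or at least built) `cnn_model`.
#' @param stacks list of [summary_stack()] objects or 4D arrays.
#' @param subject_ids optional character vector of row names.
#' @return A `node_feature_matrix`: numeric subjects x dense_units matrix
#'   with attribute `subject_ids`.
#' @export
cnn_encode <- function(model, stacks, subject_ids = NULL) {
  cfg <- model$cfg
  xs <- lapply(stacks, function(s) if (inherits(s, "summary_stack")) s$data else s)
  for (x in xs) {
    assert_that(all(dim(x) == cfg$input_shape),
                "stack shape %s does not match model input %s (channel mismatch?)",
                paste(dim(x), collapse = "x"), paste(cfg$input_shape, collapse = "x"))
  }
  # fall back to batch statistics when the model was never trained
  trained <- !is.null(model$params$blocks[[1]]$running)
  fw <- cnn_forward(model$params, xs, cfg, training = !trained)
  out <- fw$features
  rownames(out) <- subject_ids %||% sprintf("sub-%03d", seq_along(xs))
  class(out) <- c("node_feature_matrix", class(out))
  out
}

#' Glance at a trained CNN
#'
#' @param x a `cnn_model`.
#' @param ... unused.
#' @return One-row tibble with architecture and final training metrics.
#' @method glance cnn_model
#' @export
glance.cnn_model <- function(x, ...) {
  tibble::tibble(n_blocks = length(x$cfg$filters),
                 last_block_filters = x$cfg$filters[length(x$cfg$filters)],
                 dense_units = x$cfg$dense_units,
                 final_loss = if (is.null(x$log)) NA_real_ else tail(x$log$loss, 1),
                 final_accuracy = if (is.null(x$log)) NA_real_ else tail(x$log$accuracy, 1))
}

#' Tidy a CNN training log
#'
#' @param x a `cnn_model` that has been trained.
#' @param ... unused.
#' @return The per-epoch tibble of loss and accuracy.
#' @method tidy cnn_model
#' @export
tidy.cnn_model <- function(x, ...) {
  assert_that(!is.null(x$log), "model has no training log; call cnn_train() first")
  x$log
}

#' Plot a CNN training log
#'
#' @param object a trained `cnn_model`.
#' @param ... unused.
#' @return A ggplot of loss and accuracy against epoch.
#' @method autoplot cnn_model
#' @export
autoplot.cnn_model <- function(object, ...) {
  d <- tidy.cnn_model(object)
  long <- rbind(tibble::tibble(epoch = d$epoch, metric = "loss", value = d$loss),
                tibble::tibble(epoch = d$epoch, metric = "accuracy", value = d$accuracy))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL)
}
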