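#' Fisher-score feature ranking
#'
#' Per feature j, with class sizes n_c, class means mu_cj, class variances
#' sigma2_cj (population, 1/n_c convention) and overall mean mu_j:
#' F_j = sum_c n_c (mu_cj - mu_j)^2 / sum_c n_c sigma2_cj.
#' Features with a zero denominator (constant within every class) score 0.
#' Ranking is by descending score; ties break by ascending feature index.
#'
#' @param X numeric subjects x features matrix without missing values.
#' @param y binary label vector (two distinct values, >= 2 subjects each).
#' @return An object of class `fisher_ranking` with `scores` (one per
#'   feature) and `order` (feature indices, best first).
#' @export
fisher_score <- function(X, y) {
  X <- as.matrix(X)
  assert_that(!anyNA(X), "X must not contain missing values")
  classes <- sort(unique(y))
  assert_that(length(classes) == 2, "y must contain exactly 2 classes, got %d", length(classes))
  for (cl in classes) {
    assert_that(sum(y == cl) >= 2, "class %s has fewer than 2 subjects", format(cl))
  }
  mu <- colMeans(X)
  num <- 0
  den <- 0
  for (cl in classes) {
    Xc <- X[y == cl, , drop = FALSE]
    nc <- nrow(Xc)
    mc <- colMeans(Xc)
    vc <- colMeans(Xc^2) - mc^2  # population variance
    num <- num + nc * (mc - mu)^2
    den <- den + nc * vc
  }
  scores <- ifelse(den > 0, num / den, 0)
  scores[!is.finite(scores)] <- 0
  structure(list(scores = scores,
                 order = order(-scores, seq_along(scores))),
            class = "fisher_ranking")
}

#' @export
print.fisher_ranking <- function(x, ...) {
  cat(sprintf("<fisher_ranking> %d features; top score %.4g (feature %d)\n",
              length(x$scores), x$scores[x$order[1]], x$order[1]))
  invisible(x)
}

#' Tidy a Fisher ranking
#'
#' @param x a `fisher_ranking`.
#' @param ... unused.
#' @return A tibble with columns feature (index), score, rank.
#' @method tidy fisher_ranking
#' @export
tidy.fisher_ranking <- function(x, ...) {
  tibble::tibble(feature = seq_along(x$scores),
                 score = x$scores,
                 rank = match(seq_along(x$scores), x$order))
}

#' Keep the top-k ranked feature columns
#'
#' @param ranking a [fisher_score()] result.
#' @param X the matrix the ranking was computed on (or one with matching
#'   columns).
#' @param k number of features to keep (default 2000).
#' @return List with `X` (columns reordered by rank, first k kept) and
#'   `kept` (original column indices, best first).
#' @export
select_top_k <- function(ranking, X, k = 2000L) {
  X <- as.matrix(X)
  assert_that(length(ranking$scores) == ncol(X),
              "ranking covers %d features but X has %d columns",
              length(ranking$scores), ncol(X))
  assert_that(k >= 1 && k <= ncol(X),
              "k must lie in [1, %d], got %d", ncol(X), k)
  kept <- ranking$order[seq_len(k)]
  list(X = X[, kept, drop = FALSE], kept = kept)
}

# --- stacked autoencoder -----------------------------------------------------

# Forward through a sigmoid MLP; returns list of activations per layer
# (A[[1]] = input).
mlp_forward <- function(X, layers) {
  A <- vector("list", length(layers) + 1L)
  A[[1]] <- X
  for (l in seq_along(layers)) {
    A[[l + 1L]] <- sigmoid(sweep(A[[l]] %*% layers[[l]]$W, 2, layers[[l]]$b, "+"))
  }
  A
}

# One Adam epoch of backprop for a sigmoid MLP with MSE loss against `target`.
# Returns updated layers/opt state and the epoch's loss (computed pre-update).
mlp_mse_epoch <- function(X, target, layers, opt, lr) {
  A <- mlp_forward(X, layers)
  out <- A[[length(A)]]
  n <- nrow(X)
  loss <- mean((out - target)^2)
  delta <- 2 * (out - target) / length(out)     # dL/d(out)
  for (l in rev(seq_along(layers))) {
    act <- A[[l + 1L]]
    dz <- delta * act * (1 - act)               # sigmoid'
    gW <- crossprod(A[[l]], dz)
    gb <- colSums(dz)
    delta <- dz %*% t(layers[[l]]$W)
    sW <- adam_step(layers[[l]]$W, gW, opt[[l]]$W, lr)
    sb <- adam_step(layers[[l]]$b, gb, opt[[l]]$b, lr)
    layers[[l]]$W <- sW$w; opt[[l]]$W <- sW$state
    layers[[l]]$b <- sb$w; opt[[l]]$b <- sb$state
  }
  list(layers = layers, opt = opt, loss = loss)
}

new_layer <- function(n_in, n_out) {
  list(W = glorot_uniform(n_in, n_out), b = rep(0, n_out))
}

#' Fit a stacked autoencoder for radiomic compression
#'
#' A 4-level stacked autoencoder compressing the selected radiomic features
#' (default 2000 -> 1024 -> 512 -> 256 -> 150) with sigmoid activations
#' throughout, so the 150-dimensional embedding is bounded in \[0, 1\] —
#' nonnegative, as the downstream sqrt-cosine similarity requires. Inputs
#' are min-max scaled per feature to \[0, 1\]. Training is greedy layer-wise
#' pretraining (each level learns to reconstruct its input) followed by
#' end-to-end fine-tuning of the full encoder-decoder, both minimising mean
#' squared reconstruction error with an adaptive-moment optimiser.
#'
#' @param X numeric subjects x features matrix (fit on training subjects
#'   only to avoid label leakage; encoding may then be applied to all).
#' @param hidden_sizes encoder layer widths; default `c(1024, 512, 256, 150)`.
#' @param seed integer seed; identical seeds give identical weights.
#' @param epochs_pretrain,epochs_finetune training epochs per phase.
#' @param learning_rate Adam learning rate.
#' @return An object of class `sae_model` with encoder/decoder weights,
#'   scaling parameters and a training log tibble.
#' @export
sae_fit <- function(X, hidden_sizes = c(1024L, 512L, 256L, 150L), seed = 1L,
                    epochs_pretrain = 200L, epochs_finetune = 200L,
                    learning_rate = 1e-3) {
  X <- as.matrix(X)
  assert_that(nrow(X) >= 8, "need at least 8 subjects to fit the autoencoder, got %d", nrow(X))
  assert_that(all(hidden_sizes >= 1), "hidden_sizes must be positive")
  mins <- apply(X, 2, min)
  rngs <- apply(X, 2, max) - mins
  Xs <- sweep(X, 2, mins)
  pos <- rngs > 0
  Xs[, pos] <- sweep(Xs[, pos, drop = FALSE], 2, rngs[pos], "/")
  sizes <- c(ncol(X), hidden_sizes)
  log_rows <- list()
  with_seed(seed, {
    encoder <- vector("list", length(hidden_sizes))
    decoder_parts <- vector("list", length(hidden_sizes))
    H <- Xs
    for (l in seq_along(hidden_sizes)) {
      enc <- new_layer(sizes[l], sizes[l + 1L])
      dec <- new_layer(sizes[l + 1L], sizes[l])
      layers <- list(enc, dec)
      opt <- list(list(W = NULL, b = NULL), list(W = NULL, b = NULL))
      for (ep in seq_len(epochs_pretrain)) {
        st <- mlp_mse_epoch(H, H, layers, opt, learning_rate)
        layers <- st$layers; opt <- st$opt
        if (!is.finite(st$loss)) {
          stop_arg("autoencoder pretraining diverged at level %d epoch %d; try a smaller learning_rate", l, ep)
        }
        log_rows[[length(log_rows) + 1L]] <-
          tibble::tibble(phase = "pretrain", level = l, epoch = ep, loss = st$loss)
      }
      encoder[[l]] <- layers[[1]]
      decoder_parts[[l]] <- layers[[2]]
      H <- mlp_forward(H, list(layers[[1]]))[[2]]
    }
    decoder <- rev(decoder_parts)
    all_layers <- c(encoder, decoder)
    opt <- rep(list(list(W = NULL, b = NULL)), length(all_layers))
    for (ep in seq_len(epochs_finetune)) {
      st <- mlp_mse_epoch(Xs, Xs, all_layers, opt, learning_rate)
      all_layers <- st$layers; opt <- st$opt
      if (!is.finite(st$loss)) {
        stop_arg("autoencoder fine-tuning diverged at epoch %d; try a smaller learning_rate", ep)
      }
      log_rows[[length(log_rows) + 1L]] <-
        tibble::tibble(phase = "finetune", level = NA_integer_, epoch = ep, loss = st$loss)
    }
    ne <- length(encoder)
    structure(list(encoder = all_layers[seq_len(ne)],
                   decoder = all_layers[ne + seq_len(ne)],
                   scaling = list(mins = mins, ranges = rngs),
                   sizes = sizes,
                   log = do.call(rbind, log_rows)),
              class = "sae_model")
  })
}

#' @export
print.sae_model <- function(x, ...) {
  cat(sprintf("<sae_model> encoder %s; final fine-tune loss %.4g\n",
              paste(x$sizes, collapse = " -> "),
              tail(x$log$loss[x$log$phase == "finetune"], 1)))
  invisible(x)
}

#' Encode subjects with a fitted stacked autoencoder
#'
#' Applies the stored min-max scaling and the encoder half of the model.
#' Outputs lie in \[0, 1\] (sigmoid embedding).
#'
#' @param model a [sae_fit()] result.
#' @param X matrix with the same feature columns the model was fitted on.
#' @return Numeric subjects x embedding matrix.
#' @export
sae_encode <- function(model, X) {
  X <- as.matrix(X)
  assert_that(ncol(X) == model$sizes[1],
              "X has %d columns but the model expects %d", ncol(X), model$sizes[1])
  Xs <- sweep(X, 2, model$scaling$mins)
  pos <- model$scaling$ranges > 0
  Xs[, pos] <- sweep(Xs[, pos, drop = FALSE], 2, model$scaling$ranges[pos], "/")
  A <- mlp_forward(Xs, model$encoder)
  A[[length(A)]]
}

#' Glance at a fitted stacked autoencoder
#'
#' @param x a `sae_model`.
#' @param ... unused.
#' @return One-row tibble with input width, embedding width and final losses.
#' @method glance sae_model
#' @export
glance.sae_model <- function(x, ...) {
  ft <- x$log$loss[x$log$phase == "finetune"]
  tibble::tibble(input_width = x$sizes[1],
                 embedding_width = x$sizes[length(x$sizes)],
                 n_levels = length(x$encoder),
                 first_finetune_loss = ft[1],
                 final_finetune_loss = ft[length(ft)])
}

#' Plot an autoencoder training log
#'
#' @param object a `sae_model`.
#' @param ... unused.
#' @return A ggplot of loss against epoch, faceted by phase/level.
#' @method autoplot sae_model
#' @export
autoplot.sae_model <- function(object, ...) {
  d <- object$log
  d$curve <- ifelse(d$phase == "pretrain", paste0("pretrain L", d$level), "finetune")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~curve, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = "reconstruction MSE")
}
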