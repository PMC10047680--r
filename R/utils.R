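# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_arg <- function(...) stop(sprintf(...), call. = FALSE)

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop_arg(...)
  invisible(TRUE)
}

# Run `expr` under a locally-seeded RNG without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Derive a child seed from a parent seed and a stage tag, staying < 2^31.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# Pearson correlation matrix of the columns of `x` (t x n), with columns of
# zero variance given correlation 0 against everything (including themselves).
safe_cor <- function(x) {
  n <- ncol(x)
  s <- apply(x, 2, stats::sd)
  ok <- s > 0
  r <- matrix(0, n, n)
  if (any(ok)) {
    z <- scale(x[, ok, drop = FALSE])
    r[ok, ok] <- crossprod(z) / (nrow(x) - 1)
  }
  r[!is.finite(r)] <- 0
  r
}

# Pairwise Pearson between matched columns of x and y (both t x n); 0 where
# either column is constant.
safe_cor_pairwise <- function(x, y) {
  sx <- apply(x, 2, stats::sd)
  sy <- apply(y, 2, stats::sd)
  cx <- sweep(x, 2, colMeans(x))
  cy <- sweep(y, 2, colMeans(y))
  num <- colSums(cx * cy)
  den <- (nrow(x) - 1) * sx * sy
  r <- ifelse(den > 0, num / den, 0)
  r[!is.finite(r)] <- 0
  r
}

# Row-wise softmax.
softmax_rows <- function(m) {
  m <- m - apply(m, 1, max)
  e <- exp(m)
  e / rowSums(e)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Glorot/Xavier symmetric-limit uniform initialisation.
glorot_uniform <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

# One Adam update; `state` carries m, v, t.
adam_step <- function(w, g, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.null(state)) state <- list(m = w * 0, v = w * 0, t = 0L)
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(w = w - lr * mhat / (sqrt(vhat) + eps), state = state)
}

# 6-connected (face) neighbour offsets.
face_offsets <- function() {
  rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
}

# Offsets for the 6/18/26 voxel neighbourhoods (excluding the centre).
neighbourhood_offsets <- function(k = c(26, 18, 6)) {
  k <- as.integer(k[1])
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  ord <- rowSums(abs(g))
  keep <- switch(as.character(k),
    "6" = ord == 1,
    "18" = ord <= 2,
    "26" = rep(TRUE, nrow(g)),
    stop_arg("neighbourhood must be one of 6, 18, 26, got %s", k)
  )
  unname(g[keep, , drop = FALSE])
}
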