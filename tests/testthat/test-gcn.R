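random_graph <- function(n, p = 0.4, seed = 4) {
  set.seed(seed)
  A <- matrix(rbinom(n * n, 1, p), n, n)
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  diag(A) <- 0
  A
}

test_that("adjacency normalisation matches the (d_i+1)(d_j+1) definition", {
  # no edges: every node self-normalises to the identity
  expect_identical(normalize_adjacency(matrix(0, 3, 3)), diag(3))
  # single edge between two nodes: all four entries 1/2
  A2 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(normalize_adjacency(A2), matrix(0.5, 2, 2), tolerance = 1e-15)
  # dense oracle on an 8-node graph
  A8 <- random_graph(8)
  Abar <- A8 + diag(8)
  Dm <- diag(1 / sqrt(rowSums(Abar)))
  expect_equal(normalize_adjacency(A8), Dm %*% Abar %*% Dm, tolerance = 1e-12)
  # elementwise form: entry (i,j) = Abar_ij / sqrt((d_i+1)(d_j+1))
  dvec <- rowSums(A8)
  ref <- Abar / sqrt(outer(dvec + 1, dvec + 1))
  expect_equal(normalize_adjacency(A8), ref, tolerance = 1e-12)
  expect_error(normalize_adjacency(diag(3)), "zero diagonal")
})

test_that("the forward pass equals a dense evaluation of the propagation rule", {
  A <- random_graph(8)
  Ah <- normalize_adjacency(A)
  set.seed(5)
  X <- matrix(rnorm(8 * 5), 8, 5)
  W <- list(matrix(rnorm(5 * 16) * 0.1, 5, 16),
            matrix(rnorm(16 * 16) * 0.1, 16, 16),
            matrix(rnorm(16 * 2) * 0.1, 16, 2))
  cfg <- gcn_config()
  P <- gcn_forward(Ah, X, W, cfg)
  H1 <- pmax(Ah %*% X %*% W[[1]], 0)
  H2 <- pmax(Ah %*% H1 %*% W[[2]], 0)
  Z <- Ah %*% H2 %*% W[[3]]
  Pe <- exp(Z - apply(Z, 1, max)); Pe <- Pe / rowSums(Pe)
  expect_equal(P, Pe, tolerance = 1e-10)
  expect_equal(rowSums(P), rep(1, 8), tolerance = 1e-12)
  # all-zero weights give the uniform prediction for every node
  W0 <- lapply(W, function(w) w * 0)
  expect_true(all(abs(gcn_forward(Ah, X, W0, cfg) - 0.5) < 1e-15))
  # with dropout off and fixed weights the forward pass is idempotent
  expect_identical(gcn_forward(Ah, X, W, cfg), gcn_forward(Ah, X, W, cfg))
})

test_that("semi-supervised training recovers a planted two-community graph", {
  g <- planted_partition()
  fit <- cached("gcn_fit_pp", gcn_fit(g, gcn_config(seed = 2)))
  pred <- gcn_predict(fit, g)
  acc <- mean(pred$labels[g$test_mask] == g$labels[g$test_mask])
  expect_gte(acc, 0.9)
  # smoothed descent over the first 10 epochs
  expect_lt(mean(fit$log$loss[8:10]), mean(fit$log$loss[1:3]))
  # determinism of the weight trajectory
  fit2 <- gcn_fit(g, gcn_config(seed = 2))
  expect_identical(fit$weights, fit2$weights)
  expect_identical(fit$log, fit2$log)
  expect_s3_class(glance(fit), "tbl_df")
  expect_error(gcn_fit(population_graph(g$node_features, g$adjacency, g$labels,
                                        g$labels == 1L & g$train_mask, g$test_mask),
                       gcn_config()), "each class")
})

test_that("an edgeless graph reduces the GCN to a per-node MLP", {
  set.seed(6)
  X <- matrix(rnorm(50), 10, 5)
  W <- list(matrix(rnorm(5 * 16) * 0.3, 5, 16),
            matrix(rnorm(16 * 16) * 0.3, 16, 16),
            matrix(rnorm(16 * 2) * 0.3, 16, 2))
  cfg <- gcn_config(dropouts = c(0, 0))
  P <- gcn_forward(normalize_adjacency(matrix(0, 10, 10)), X, W, cfg)
  H <- pmax(X %*% W[[1]], 0)
  H <- pmax(H %*% W[[2]], 0)
  Z <- H %*% W[[3]]
  Pe <- exp(Z - apply(Z, 1, max)); Pe <- Pe / rowSums(Pe)
  expect_equal(P, Pe, tolerance = 1e-12)
})

test_that("predictions are permutation-equivariant and break ties downward", {
  A <- random_graph(10, seed = 8)
  Ah <- normalize_adjacency(A)
  set.seed(9)
  X <- matrix(rnorm(10 * 4), 10, 4)
  W <- list(matrix(rnorm(4 * 16) * 0.2, 4, 16),
            matrix(rnorm(16 * 16) * 0.2, 16, 16),
            matrix(rnorm(16 * 2) * 0.2, 16, 2))
  cfg <- gcn_config(dropouts = c(0, 0))
  P <- gcn_forward(Ah, X, W, cfg)
  perm <- sample(10)
  Pp <- gcn_forward(normalize_adjacency(A[perm, perm]), X[perm, ], W, cfg)
  expect_equal(Pp, P[perm, ], tolerance = 1e-12)
  # zero weights -> exact ties -> class 0 (lower index)
  g <- population_graph(X, A, rep(c(0L, 1L), 5), rep(c(TRUE, FALSE), 5),
                        rep(c(FALSE, TRUE), 5))
  fake_fit <- structure(list(weights = lapply(W, function(w) w * 0),
                             cfg = cfg, A_hat = Ah,
                             log = tibble::tibble(epoch = 1L, loss = 0, accuracy = 0)),
                        class = "gcn_fit")
  pr <- gcn_predict(fake_fit, g)
  expect_true(all(pr$labels == 0L))
  expect_equal(rowSums(pr$probs), rep(1, 10), tolerance = 1e-12)
})
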