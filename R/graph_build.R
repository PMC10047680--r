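#' Improved sqrt-cosine (Hellinger-style) similarity
#'
#' For nonnegative vectors x, y:
#' `Sim(x, y) = sum_i sqrt(x_i * y_i) / (sqrt(sum_i x_i) * sqrt(sum_i y_i))`.
#' Values lie in \[0, 1\], with `Sim(x, x) = 1` and 0 for disjoint supports.
#' This is the Hellinger-affinity form of the similarity; `method =
#' "literal"` computes the plain-product variant
#' `sum(x*y) / (sum(x) * sum(y))` instead, for comparison.
#'
#' @param x,y nonnegative numeric vectors of equal length with positive sums.
#' @param method `"sqrt"` (default) or `"literal"`.
#' @return A similarity value.
#' @export
sqrt_cosine <- function(x, y, method = c("sqrt", "literal")) {
  method <- match.arg(method)
  assert_that(length(x) == length(y), "x and y must have equal length")
  assert_that(all(x >= 0) && all(y >= 0), "inputs must be elementwise nonnegative")
  sx <- sum(x); sy <- sum(y)
  assert_that(sx > 0 && sy > 0, "inputs must have positive sums")
  if (method == "sqrt") {
    sum(sqrt(x * y)) / (sqrt(sx) * sqrt(sy))
  } else {
    sum(x * y) / (sx * sy)
  }
}

#' Pairwise similarity matrix and edge threshold
#'
#' Computes S_ij = [sqrt_cosine()] between every pair of rows of the
#' embedding matrix, and the edge threshold tau = the minimum over rows of
#' the largest off-diagonal entry in that row. By construction every node
#' has at least one neighbour at threshold tau.
#'
#' @param E nonnegative subjects x features embedding matrix (N >= 2 rows).
#' @param method passed to [sqrt_cosine()].
#' @return An object of class `similarity_matrix` with `S` (N x N symmetric,
#'   unit diagonal) and `threshold`.
#' @export
similarity_matrix <- function(E, method = c("sqrt", "literal")) {
  method <- match.arg(method)
  E <- as.matrix(E)
  n <- nrow(E)
  assert_that(n >= 2, "need at least 2 subjects, got %d", n)
  assert_that(all(E >= 0), "embeddings must be elementwise nonnegative")
  sums <- rowSums(E)
  assert_that(all(sums > 0), "every embedding row must have a positive sum")
  if (method == "sqrt") {
    R <- sqrt(E)
    S <- (R %*% t(R)) / sqrt(outer(sums, sums))
  } else {
    S <- (E %*% t(E)) / outer(sums, sums)
  }
  S <- (S + t(S)) / 2  # enforce exact symmetry against rounding
  offdiag <- S
  diag(offdiag) <- -Inf
  row_max <- apply(offdiag, 1, max)
  structure(list(S = S, threshold = min(row_max)), class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d nodes, threshold %.4g\n",
              nrow(x$S), x$threshold))
  invisible(x)
}

#' Threshold a similarity matrix into a binary adjacency
#'
#' A_ij = 1 iff i != j and S_ij >= tau (ties at tau are kept, which
#' guarantees minimum degree >= 1). Optionally keeps S_ij as edge weights.
#'
#' @param sim a [similarity_matrix()].
#' @param weighted keep similarity values on edges instead of 1s.
#' @return Symmetric N x N adjacency matrix with zero diagonal.
#' @export
threshold_adjacency <- function(sim, weighted = FALSE) {
  assert_that(inherits(sim, "similarity_matrix"), "sim must be a similarity_matrix")
  A <- (sim$S >= sim$threshold) * 1
  diag(A) <- 0
  if (weighted) A <- A * sim$S
  A
}

#' Assemble a population graph
#'
#' Bundles the node-feature matrix (one row per subject, e.g. the CNN
#' features), the thresholded structural-similarity adjacency, labels and
#' train/test masks into the object the GCN consumes.
#'
#' @param node_features N x F numeric matrix.
#' @param adjacency N x N symmetric binary matrix with zero diagonal.
#' @param labels integer vector in \{0, 1\} (NA for unknown).
#' @param train_mask,test_mask disjoint logical N-vectors.
#' @return An object of class `population_graph`.
#' @export
population_graph <- function(node_features, adjacency, labels, train_mask, test_mask) {
  node_features <- as.matrix(node_features)
  n <- nrow(node_features)
  assert_that(all(dim(adjacency) == c(n, n)), "adjacency must be %d x %d", n, n)
  assert_that(isTRUE(all.equal(adjacency, t(adjacency))), "adjacency must be symmetric")
  assert_that(all(diag(adjacency) == 0), "adjacency must have a zero diagonal")
  assert_that(length(labels) == n && length(train_mask) == n && length(test_mask) == n,
              "labels and masks must have length %d", n)
  assert_that(!any(train_mask & test_mask), "train and test masks must be disjoint")
  structure(list(node_features = node_features, adjacency = adjacency,
                 labels = as.integer(labels),
                 train_mask = as.logical(train_mask),
                 test_mask = as.logical(test_mask)),
            class = "population_graph")
}

#' @export
print.population_graph <- function(x, ...) {
  cat(sprintf("<population_graph> %d nodes, %d features, %d edges, %d train / %d test\n",
              nrow(x$node_features), ncol(x$node_features),
              sum(x$adjacency > 0) / 2, sum(x$train_mask), sum(x$test_mask)))
  invisible(x)
}

#' Write graph edges as a TSV edge list
#'
#' @param sim a [similarity_matrix()].
#' @param path output TSV path (columns node_i, node_j, similarity), one row
#'   per thresholded edge with i < j.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(sim, path) {
  A <- threshold_adjacency(sim)
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  df <- data.frame(node_i = idx[, 1], node_j = idx[, 2],
                   similarity = sim$S[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
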