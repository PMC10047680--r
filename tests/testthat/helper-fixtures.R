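# Shared miniature fixtures and independent oracles, built once per run.

.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .cache)) assign(name, force(expr), envir = .cache)
  get(name, envir = .cache)
}

mini_fixture <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(grid_shape = c(12L, 14L, 12L), n_timepoints = 40L, tr_seconds = 2,
         n_regions_per_hemisphere = 3L, n_templates = 4L, seed = seed,
         noise_sd = 1, effect_size = 5),
    list(...))
  do.call(fixture_config, args)
}

# cohort with a strong, localized structural + functional class signal
mini_cohort <- function() {
  cached("mini_cohort", make_cohort(
    mini_fixture(seed = 11, n_timepoints = 20L),
    n_subjects = 16, n_affected_rois = 2L, functional_effect = 1.5))
}

mini_radiomics <- function() {
  cached("mini_radiomics", radiomics_matrix(mini_cohort()))
}

# --- independent oracles -----------------------------------------------------

# Kendall's W with mid-rank tie correction, straight from the definition.
oracle_kendall_w <- function(series) {
  K <- length(series)
  n <- length(series[[1]])
  R <- sapply(series, rank)
  Ri <- rowSums(R)
  S <- sum((Ri - mean(Ri))^2)
  Tj <- sum(sapply(series, function(x) { tt <- table(x); sum(tt^3 - tt) }))
  denom <- K^2 * (n^3 - n) - K * Tj
  if (denom <= 0) 0 else 12 * S / denom
}

# ReHo oracle at one voxel: gather in-grid neighbour series, apply the W
# definition above.
oracle_reho_at <- function(vol, i, j, k, nbhd = 26) {
  offs <- rbind(c(0, 0, 0), asdgraph:::neighbourhood_offsets(nbhd))
  d <- dim(vol$data)[1:3]
  series <- list()
  for (o in seq_len(nrow(offs))) {
    p <- c(i, j, k) + offs[o, ]
    if (all(p >= 1 & p <= d)) {
      series[[length(series) + 1L]] <- vol$data[p[1], p[2], p[3], ]
    }
  }
  oracle_kendall_w(series)
}

# Single-sided DFT amplitudes by explicit summation (no fft()).
oracle_amplitudes <- function(x) {
  n <- length(x)
  t <- 0:(n - 1)
  sapply(seq_len(n %/% 2), function(k) {
    2 * Mod(sum(x * exp(-2i * pi * k * t / n))) / n
  })
}

oracle_detrend <- function(x) {
  n <- length(x)
  X <- cbind(1, seq_len(n) - (n + 1) / 2)
  as.vector(x - X %*% solve(crossprod(X), crossprod(X, x)))
}

# LFCD oracle: breadth-first flood fill over the thresholded seed-correlation
# field with 6-connectivity.
oracle_lfcd_at <- function(vol, seed_idx, tau) {
  d <- dim(vol$data)[1:3]
  n <- prod(d)
  m <- t(matrix(vol$data, n, dim(vol$data)[4]))
  co <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3])))
  lin <- function(p) p[1] + (p[2] - 1) * d[1] + (p[3] - 1) * d[1] * d[2]
  seed_series <- m[, seed_idx]
  visited <- seed_idx
  frontier <- seed_idx
  offs <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  while (length(frontier) > 0) {
    cand <- integer()
    for (f in frontier) {
      for (o in seq_len(6)) {
        p <- co[f, ] + offs[o, ]
        if (all(p >= 1 & p <= d)) cand <- c(cand, lin(p))
      }
    }
    cand <- setdiff(unique(cand), visited)
    if (length(cand) == 0) break
    admit <- cand[sapply(cand, function(v) {
      r <- suppressWarnings(stats::cor(seed_series, m[, v]))
      !is.na(r) && r >= tau
    })]
    visited <- c(visited, admit)
    frontier <- admit
  }
  length(visited)
}

# Connected-component count of one label under 6-connectivity.
oracle_n_components <- function(lab, value) {
  idx <- which(lab == value)
  if (length(idx) == 0) return(0L)
  d <- dim(lab)
  co <- arrayInd(idx, d)
  rownames(co) <- as.character(idx)
  remaining <- idx
  ncomp <- 0L
  offs <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  lin <- function(p) p[1] + (p[2] - 1) * d[1] + (p[3] - 1) * d[1] * d[2]
  while (length(remaining) > 0) {
    ncomp <- ncomp + 1L
    frontier <- remaining[1]
    remaining <- remaining[-1]
    while (length(frontier) > 0) {
      nxt <- integer()
      for (f in frontier) {
        p0 <- arrayInd(f, d)
        for (o in seq_len(6)) {
          p <- p0 + offs[o, ]
          if (all(p >= 1 & p <= d)) {
            v <- lin(as.vector(p))
            if (v %in% remaining) {
              nxt <- c(nxt, v)
              remaining <- setdiff(remaining, v)
            }
          }
        }
      }
      frontier <- unique(nxt)
    }
  }
  ncomp
}

# low-rank data for autoencoder experiments
low_rank_data <- function() {
  cached("sae_lowrank", {
    set.seed(21)
    n <- 40; p <- 64
    Z <- matrix(rnorm(n * 3), n, 3)
    W <- matrix(rnorm(3 * p), 3, p)
    Z %*% W + 0.05 * matrix(rnorm(n * p), n, p)
  })
}

# planted two-community population graph for the GCN
planted_partition <- function() {
  cached("planted_partition", {
    set.seed(5)
    n <- 60
    y <- rep(c(0L, 1L), each = 30)
    A <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      p <- if (y[i] == y[j]) 0.5 else 0.05
      A[i, j] <- A[j, i] <- rbinom(1, 1, p)
    }
    X <- cbind(y + rnorm(n, sd = 1.5), -y + rnorm(n, sd = 1.5),
               matrix(rnorm(n * 3), n, 3))
    train <- rep(FALSE, n); train[c(1:6, 31:36)] <- TRUE
    population_graph(X, A, y, train, !train)
  })
}

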