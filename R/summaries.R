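#' Configuration for rs-fMRI summary derivatives
#'
#' @param band_low_hz lower edge of the low-frequency band (Hz). Default 0.01,
#'   the standard lower edge for amplitude-of-low-frequency-fluctuation
#'   analyses.
#' @param band_high_hz upper edge of the low-frequency band (Hz), default 0.08.
#' @param full_band_high_hz upper edge of the full band used by fALFF (Hz),
#'   default 0.25.
#' @param corr_threshold correlation threshold for centrality/LFCD maps,
#'   default 0.25.
#' @param neighborhood voxel neighbourhood for ReHo: 6 (faces), 18
#'   (faces+edges) or 26 (full cube), default 26.
#' @param detrend remove a per-voxel linear trend before spectral operations.
#' @return A list of class `summary_config`.
#' @export
summary_config <- function(band_low_hz = 0.01, band_high_hz = 0.08,
                           full_band_high_hz = 0.25, corr_threshold = 0.25,
                           neighborhood = 26L, detrend = TRUE) {
  assert_that(band_low_hz >= 0 && band_low_hz < band_high_hz &&
              band_high_hz <= full_band_high_hz,
              "need 0 <= band_low_hz < band_high_hz <= full_band_high_hz")
  assert_that(corr_threshold > -1 && corr_threshold < 1,
              "corr_threshold must lie in (-1, 1)")
  assert_that(neighborhood %in% c(6L, 18L, 26L), "neighborhood must be 6, 18 or 26")
  structure(list(band_low_hz = band_low_hz, band_high_hz = band_high_hz,
                 full_band_high_hz = full_band_high_hz,
                 corr_threshold = corr_threshold,
                 neighborhood = as.integer(neighborhood),
                 detrend = isTRUE(detrend)),
            class = "summary_config")
}

# --- internal plumbing -------------------------------------------------------

# Flatten a volume to a t x nvox matrix.
vol_matrix <- function(vol) {
  d <- dim(vol$data)
  t(matrix(vol$data, prod(d[1:3]), d[4]))
}

# Linear voxel index of (i, j, k) given grid dims (1-based).
lin_index <- function(ijk, d) {
  ijk[, 1] + (ijk[, 2] - 1L) * d[1] + (ijk[, 3] - 1L) * d[1] * d[2]
}

# Coordinates (i, j, k) of all voxels in grid order.
grid_coords <- function(d) {
  as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3])))
}

# Remove per-column linear trend (intercept + slope).
detrend_linear <- function(m) {
  n <- nrow(m)
  x <- cbind(1, seq_len(n) - (n + 1) / 2)
  m - x %*% (solve(crossprod(x)) %*% crossprod(x, m))
}

# Single-sided amplitude spectrum of the columns of m: a_k = 2|X_k|/n for
# bins k = 1..floor(n/2), with frequencies k/(n*tr). Returns list(freq, amp).
amplitude_spectrum <- function(m, tr) {
  n <- nrow(m)
  ks <- seq_len(n %/% 2)
  f <- stats::mvfft(m)
  amp <- 2 * Mod(f[ks + 1L, , drop = FALSE]) / n
  list(freq = ks / (n * tr), amp = amp)
}

to_map <- function(values, mask_idx, d) {
  out <- array(0, d)
  out[mask_idx] <- values
  out
}

check_t <- function(vol, min_t, op) {
  nt <- dim(vol$data)[4]
  assert_that(nt >= min_t, "%s requires at least %d timepoints, got %d", op, min_t, nt)
  nt
}

# --- derivatives -------------------------------------------------------------

#' Regional homogeneity (ReHo)
#'
#' Kendall's coefficient of concordance W between each in-mask voxel's time
#' series and those of its in-mask neighbours (6, 18 or 26 neighbourhood).
#' With K series over n timepoints and rank sums R_i,
#' W = 12 * sum_i (R_i - mean(R))^2 / (K^2 (n^3 - n) - K * sum_j T_j), where
#' T_j = sum over tie groups of series j of (t^3 - t) is the standard
#' mid-rank tie correction. Voxels whose denominator is nonpositive (all
#' series constant) report 0. Out-of-mask voxels report 0.
#'
#' @param vol a [volume4d()] with at least 3 timepoints.
#' @param cfg a [summary_config()].
#' @return A 3D array of W values in \[0, 1\].
#' @export
reho <- function(vol, cfg = summary_config()) {
  nt <- check_t(vol, 3L, "reho")
  d <- dim(vol$data)[1:3]
  mask <- volume_mask(vol)
  m <- vol_matrix(vol)
  nv <- prod(d)
  ranks <- apply(m, 2, rank)                    # mid-ranks, nt x nvox
  tie_sum <- apply(m, 2, function(x) {
    tt <- table(x)
    sum(tt^3 - tt)
  })
  offs <- rbind(c(0L, 0L, 0L), neighbourhood_offsets(cfg$neighborhood))
  co <- grid_coords(d)
  in_mask <- as.vector(mask)
  Rsum <- matrix(0, nt, nv)
  K <- numeric(nv)
  Tsum <- numeric(nv)
  for (o in seq_len(nrow(offs))) {
    nb <- sweep(co, 2, offs[o, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    idx <- rep(NA_integer_, nv)
    idx[ok] <- lin_index(nb[ok, , drop = FALSE], d)
    ok[ok] <- in_mask[idx[ok]]
    v <- which(ok & in_mask)
    Rsum[, v] <- Rsum[, v] + ranks[, idx[v], drop = FALSE]
    K[v] <- K[v] + 1
    Tsum[v] <- Tsum[v] + tie_sum[idx[v]]
  }
  S <- colSums(Rsum^2) - nt * colMeans(Rsum)^2
  denom <- K^2 * (nt^3 - nt) - K * Tsum
  W <- ifelse(denom > 0, 12 * S / denom, 0)
  W[!in_mask] <- 0
  array(pmin(pmax(W, 0), 1), d)
}

# Resolve the DFT bins of a band; error (naming the resolvable band) if empty.
band_bins <- function(freq, lo, hi, what) {
  bins <- which(freq >= lo & freq <= hi)
  assert_that(length(bins) > 0,
              "%s band [%g, %g] Hz contains no DFT bin; resolvable band is [%g, %g] Hz with spacing %g Hz",
              what, lo, hi, freq[1], freq[length(freq)], freq[1])
  bins
}

#' Amplitude of low-frequency fluctuations (ALFF)
#'
#' Per voxel: optional linear detrend, discrete Fourier transform, and the
#' mean single-sided amplitude (square root of spectral power, scaled so a
#' bin-aligned sinusoid of amplitude A reports A) over the bins with
#' `band_low_hz <= f <= band_high_hz`. The DC bin is excluded.
#'
#' @inheritParams reho
#' @return A 3D array of ALFF values (0 outside the mask).
#' @export
alff <- function(vol, cfg = summary_config()) {
  check_t(vol, 8L, "alff")
  d <- dim(vol$data)[1:3]
  mask <- volume_mask(vol)
  mi <- which(as.vector(mask))
  m <- vol_matrix(vol)[, mi, drop = FALSE]
  if (cfg$detrend) m <- detrend_linear(m)
  sp <- amplitude_spectrum(m, vol$tr_seconds)
  bins <- band_bins(sp$freq, cfg$band_low_hz, cfg$band_high_hz, "ALFF")
  to_map(colMeans(sp$amp[bins, , drop = FALSE]), mi, d)
}

#' Fractional amplitude of low-frequency fluctuations (fALFF)
#'
#' Ratio of summed amplitudes in the low-frequency band to summed amplitudes
#' over the full band `0 < f <= full_band_high_hz`; 0 where the denominator
#' is 0 (e.g. a constant series).
#'
#' @inheritParams reho
#' @return A 3D array of fALFF values in \[0, 1\].
#' @export
falff <- function(vol, cfg = summary_config()) {
  check_t(vol, 8L, "falff")
  d <- dim(vol$data)[1:3]
  mask <- volume_mask(vol)
  mi <- which(as.vector(mask))
  m <- vol_matrix(vol)[, mi, drop = FALSE]
  if (cfg$detrend) m <- detrend_linear(m)
  sp <- amplitude_spectrum(m, vol$tr_seconds)
  bins <- band_bins(sp$freq, cfg$band_low_hz, cfg$band_high_hz, "fALFF")
  full <- band_bins(sp$freq, sp$freq[1], cfg$full_band_high_hz, "fALFF full")
  num <- colSums(sp$amp[bins, , drop = FALSE])
  den <- colSums(sp$amp[full, , drop = FALSE])
  to_map(ifelse(den > 0, num / den, 0), mi, d)
}

# Thresholded correlation structure over in-mask voxels; shared by the
# centrality maps.
mask_cor <- function(vol, min_vox = 2L) {
  check_t(vol, 3L, "centrality")
  d <- dim(vol$data)[1:3]
  mask <- volume_mask(vol)
  mi <- which(as.vector(mask))
  assert_that(length(mi) >= min_vox, "need at least %d in-mask voxels", min_vox)
  r <- safe_cor(vol_matrix(vol)[, mi, drop = FALSE])
  list(r = r, mask_idx = mi, d = d)
}

#' Degree centrality (binarized or weighted)
#'
#' Pearson correlation between each in-mask voxel's series and every other
#' in-mask voxel's. Binarized: the count of correlations `>= corr_threshold`
#' (self excluded). Weighted: the sum of those correlation values.
#' Correlations with a constant series are defined as 0.
#'
#' @inheritParams reho
#' @param weighted sum suprathreshold correlations instead of counting them.
#' @return A 3D array (integer-valued when `weighted = FALSE`).
#' @export
degree_centrality <- function(vol, cfg = summary_config(), weighted = FALSE) {
  mc <- mask_cor(vol)
  r <- mc$r
  diag(r) <- NA
  hits <- r >= cfg$corr_threshold
  val <- if (weighted) rowSums(r * hits, na.rm = TRUE) else rowSums(hits, na.rm = TRUE)
  to_map(val, mc$mask_idx, mc$d)
}

#' Eigenvector centrality (binarized or weighted)
#'
#' Builds the thresholded voxel-by-voxel similarity matrix (binarized:
#' `1(r >= corr_threshold)`; weighted: suprathreshold correlations rescaled
#' to `(1 + r) / 2` so entries are nonnegative), zero diagonal, and returns
#' each voxel's component of the leading eigenvector (nonnegative, unit
#' Euclidean norm) computed by power iteration.
#'
#' @inheritParams degree_centrality
#' @param max_iter,tol power-iteration limits.
#' @return A 3D array whose in-mask entries form a unit-norm vector.
#' @export
eigenvector_centrality <- function(vol, cfg = summary_config(), weighted = FALSE,
                                   max_iter = 1000L, tol = 1e-10) {
  mc <- mask_cor(vol)
  r <- mc$r
  hits <- r >= cfg$corr_threshold
  B <- if (weighted) ((1 + r) / 2) * hits else hits * 1
  diag(B) <- 0
  n <- nrow(B)
  assert_that(sum(B) > 0, "thresholded similarity matrix has no edges; eigenvector centrality undefined")
  v <- rep(1 / sqrt(n), n)
  converged <- FALSE
  residual <- Inf
  for (it in seq_len(max_iter)) {
    w <- as.vector(B %*% v)
    nw <- sqrt(sum(w^2))
    if (nw == 0) stop_arg("power iteration collapsed to the zero vector")
    w <- w / nw
    residual <- sqrt(sum((w - v)^2))
    v <- w
    if (residual < tol) { converged <- TRUE; break }
  }
  assert_that(converged,
              "power iteration did not converge in %d iterations (residual %.3g)",
              max_iter, residual)
  to_map(abs(v), mc$mask_idx, mc$d)
}

#' Local functional connectivity density (LFCD)
#'
#' For each in-mask seed voxel, grows a face-adjacent (6-connectivity)
#' cluster from the seed, admitting neighbours whose Pearson correlation
#' with the *seed* series is `>= corr_threshold`. LFCD is the cluster size
#' including the seed.
#'
#' @inheritParams reho
#' @return A 3D array of cluster sizes (>= 1 in-mask, 0 outside).
#' @export
lfcd <- function(vol, cfg = summary_config()) {
  nt <- check_t(vol, 3L, "lfcd")
  d <- dim(vol$data)[1:3]
  mask <- volume_mask(vol)
  in_mask <- as.vector(mask)
  m <- vol_matrix(vol)
  sds <- apply(m, 2, stats::sd)
  z <- sweep(m, 2, colMeans(m))
  ok_sd <- sds > 0
  z[, ok_sd] <- sweep(z[, ok_sd, drop = FALSE], 2, sds[ok_sd], "/")
  z[, !ok_sd] <- 0
  offs <- face_offsets()
  co <- grid_coords(d)
  nv <- prod(d)
  # precompute face-neighbour linear indices (NA outside grid)
  nb_idx <- matrix(NA_integer_, nv, nrow(offs))
  for (o in seq_len(nrow(offs))) {
    nb <- sweep(co, 2, offs[o, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb_idx[ok, o] <- lin_index(nb[ok, , drop = FALSE], d)
  }
  out <- numeric(nv)
  seeds <- which(in_mask)
  for (s in seeds) {
    zs <- z[, s]
    visited <- s
    frontier <- s
    while (length(frontier) > 0) {
      cand <- unique(stats::na.omit(as.vector(nb_idx[frontier, ])))
      cand <- setdiff(cand[in_mask[cand]], visited)
      if (length(cand) == 0) break
      r <- as.vector(crossprod(zs, z[, cand, drop = FALSE])) / (nt - 1)
      admit <- cand[r >= cfg$corr_threshold]
      visited <- c(visited, admit)
      frontier <- admit
    }
    out[s] <- length(visited)
  }
  array(out, d)
}

#' Voxel-mirrored homotopic connectivity (VMHC)
#'
#' Pearson correlation between each voxel's series and the series of its
#' mirror voxel across the first (left-right) axis: (i, y, z) pairs with
#' (Nx + 1 - i, y, z). Voxels whose mirror partner (or themselves) are out
#' of mask report 0.
#'
#' @inheritParams reho
#' @return A 3D array of correlations in \[-1, 1\].
#' @export
vmhc <- function(vol, cfg = summary_config()) {
  nt <- check_t(vol, 3L, "vmhc")
  d <- dim(vol$data)[1:3]
  mask <- volume_mask(vol)
  in_mask <- as.vector(mask)
  co <- grid_coords(d)
  mirror <- cbind(d[1] + 1L - co[, 1], co[, 2], co[, 3])
  midx <- lin_index(mirror, d)
  m <- vol_matrix(vol)
  r <- safe_cor_pairwise(m, m[, midx, drop = FALSE])
  r[!in_mask | !in_mask[midx]] <- 0
  array(r, d)
}

#' Dual regression against group spatial templates
#'
#' Stage 1 (spatial regression): each timepoint's in-mask image is
#' least-squares regressed on the template vectors, giving a subject-specific
#' time course per template. Stage 2 (temporal regression): each voxel's
#' series is regressed on those time courses, giving one subject-specific
#' spatial map per template.
#'
#' @param vol a [volume4d()] with more timepoints than templates.
#' @param templates list of 3D arrays on the volume's spatial grid.
#' @return A [summary_stack()] with one channel per template
#'   (`dr_01`, `dr_02`, ...).
#' @export
dual_regression <- function(vol, templates) {
  d <- dim(vol$data)[1:3]
  S <- length(templates)
  assert_that(S >= 1, "need at least one template")
  for (s in seq_len(S)) {
    assert_that(all(dim(templates[[s]]) == d),
                "template %d grid does not match the volume", s)
  }
  nt <- dim(vol$data)[4]
  assert_that(nt > S, "need more timepoints (%d) than templates (%d)", nt, S)
  mask <- volume_mask(vol)
  mi <- which(as.vector(mask))
  D <- vapply(templates, function(tp) as.vector(tp)[mi], numeric(length(mi)))
  qr1 <- qr(D)
  assert_that(qr1$rank == S, "stage 1 (spatial regression) design is rank-deficient")
  Y <- t(vol_matrix(vol)[, mi, drop = FALSE])          # nvox x t
  TC <- t(qr.coef(qr1, Y))                             # t x S time courses
  qr2 <- qr(TC)
  assert_that(qr2$rank == S, "stage 2 (temporal regression) design is rank-deficient")
  B <- qr.coef(qr2, t(Y))                              # S x nvox coefficients
  maps <- array(0, c(d, S))
  for (s in seq_len(S)) {
    m3 <- array(0, d)
    m3[mi] <- B[s, ]
    maps[, , , s] <- m3
  }
  out <- summary_stack(maps, sprintf("dr_%02d", seq_len(S)))
  attr(out, "timecourses") <- TC
  out
}

#' Compute the full summary-derivative stack for one subject
#'
#' Produces the stacked 4D channel volume used as CNN input: ReHo, ALFF,
#' fALFF, binarized and weighted degree centrality, binarized and weighted
#' eigenvector centrality, LFCD, VMHC, then the dual-regression maps (one
#' per template) — 19 channels with the default 10 templates.
#'
#' @inheritParams dual_regression
#' @param cfg a [summary_config()].
#' @return A [summary_stack()] with channels in the documented fixed order.
#' @export
compute_all_summaries <- function(vol, templates = list(), cfg = summary_config()) {
  maps <- list(
    reho = reho(vol, cfg),
    alff = alff(vol, cfg),
    falff = falff(vol, cfg),
    dc_bin = degree_centrality(vol, cfg, weighted = FALSE),
    dc_weighted = degree_centrality(vol, cfg, weighted = TRUE),
    ec_bin = eigenvector_centrality(vol, cfg, weighted = FALSE),
    ec_weighted = eigenvector_centrality(vol, cfg, weighted = TRUE),
    lfcd = lfcd(vol, cfg),
    vmhc = vmhc(vol, cfg)
  )
  if (length(templates) > 0) {
    dr <- dual_regression(vol, templates)
    stack_channels(c(maps, list(dr)), names = c(names(maps), dr$channel_names))
  } else {
    stack_channels(maps, names = names(maps))
  }
}
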