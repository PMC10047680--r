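#' Configuration for per-ROI radiomic feature extraction
#'
#' @param wavelet_family analysis wavelet; `"db4"` (the 8-tap Daubechies
#'   filter) is the default and currently the built-in choice.
#' @param boundary_mode signal extension at the volume edges: `"symmetric"`
#'   (half-sample reflection) or `"periodic"`.
#' @param glcm_levels number of grey levels for co-occurrence and histogram
#'   discretization (default 32).
#' @param glcm_offsets integer matrix of 3D offsets (one per row); defaults to
#'   the 13 unique distance-1 direction offsets (unique up to sign).
#' @param discretization `"fixed_bin_count"` (equal-width bins spanning the
#'   ROI min-max; shift/scale invariant) or `"fixed_bin_width"`.
#' @param bin_width bin width when `discretization = "fixed_bin_width"`.
#' @param voxel_volume physical voxel volume used by the total-energy
#'   feature (default 1).
#' @return A list of class `radiomics_config`.
#' @export
radiomics_config <- function(wavelet_family = "db4",
                             boundary_mode = c("symmetric", "periodic"),
                             glcm_levels = 32L,
                             glcm_offsets = NULL,
                             discretization = c("fixed_bin_count", "fixed_bin_width"),
                             bin_width = 1,
                             voxel_volume = 1) {
  boundary_mode <- match.arg(boundary_mode)
  discretization <- match.arg(discretization)
  assert_that(identical(wavelet_family, "db4"),
              "only the 8-tap Daubechies filter ('db4') is built in")
  assert_that(glcm_levels >= 2, "glcm_levels must be >= 2")
  if (is.null(glcm_offsets)) glcm_offsets <- unique_direction_offsets()
  assert_that(is.matrix(glcm_offsets) && ncol(glcm_offsets) == 3 &&
              all(rowSums(abs(glcm_offsets)) > 0),
              "glcm_offsets must be a matrix of nonzero 3D integer offsets")
  # reject duplicate or antiparallel offsets (the symmetric GLCM counts both)
  keys <- apply(glcm_offsets, 1, paste, collapse = ",")
  anti <- apply(-glcm_offsets, 1, paste, collapse = ",")
  assert_that(!anyDuplicated(keys) && !any(anti %in% keys),
              "glcm_offsets must be distinct and pairwise non-antiparallel")
  structure(list(wavelet_family = wavelet_family, boundary_mode = boundary_mode,
                 glcm_levels = as.integer(glcm_levels), glcm_offsets = glcm_offsets,
                 discretization = discretization, bin_width = bin_width,
                 voxel_volume = voxel_volume),
            class = "radiomics_config")
}

# The 13 distance-1 3D direction offsets, unique up to sign.
unique_direction_offsets <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  keep <- g[, 1] > 0 | (g[, 1] == 0 & g[, 2] > 0) | (g[, 1] == 0 & g[, 2] == 0 & g[, 3] > 0)
  unname(g[keep, , drop = FALSE])
}

# 8-tap Daubechies (db4) analysis filters, standard published coefficients.
db4_filters <- function() {
  lo <- c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
          -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
          0.7148465705529157, 0.2303778133088965)
  hi <- rev(lo) * (-1)^(seq_along(lo))  # quadrature mirror: g_k = (-1)^k h_{L-1-k}
  list(lo = lo, hi = hi)
}

# Filter every 1D fibre of `x` along `axis` with `h` (undecimated, same
# length). Boundary: "periodic" wraps; "symmetric" reflects half-sample.
axis_filter <- function(x, h, axis, boundary) {
  d <- dim(x)
  n <- d[axis]
  L <- length(h)
  pad <- L - 1L
  idx_ext <- seq.int(1L - pad, n)  # output j uses inputs j-pad .. j (causal taps)
  ext_map <- function(i) {
    if (boundary == "periodic") {
      ((i - 1L) %% n) + 1L
    } else {
      # half-sample symmetric reflection: ... 2 1 | 1 2 ... n | n n-1 ...
      j <- i
      repeat {
        j <- ifelse(j < 1L, 1L - j, j)
        j <- ifelse(j > n, 2L * n + 1L - j, j)
        if (all(j >= 1L & j <= n)) break
      }
      j
    }
  }
  perm <- c(axis, setdiff(seq_along(d), axis))
  xp <- aperm(x, perm)
  dp <- dim(xp)
  m <- matrix(xp, dp[1], prod(dp[-1]))
  out <- matrix(0, n, ncol(m))
  # y_j = sum_k h_k * x_{j - (k-1)} with boundary extension
  for (k in seq_len(L)) {
    src <- ext_map(seq_len(n) - (k - 1L))
    out <- out + h[k] * m[src, , drop = FALSE]
  }
  res <- array(out, dp)
  aperm(res, order(perm))
}

#' Level-1 undecimated 3D wavelet sub-bands
#'
#' Separable level-1 stationary (undecimated) wavelet decomposition: the
#' low-pass and high-pass analysis filters are applied along each axis in all
#' 2^3 combinations, producing 8 sub-bands named by the filter per axis
#' (`LLL` ... `HHH`, first letter = first axis). Every sub-band keeps the
#' input grid shape, so ROI masks apply unchanged. Filters are scaled by
#' 1/sqrt(2) per axis so that, with periodic boundaries, the 8 sub-band
#' energies sum to the input energy (tight-frame normalisation).
#'
#' @param vol 3D numeric array.
#' @param cfg a [radiomics_config()].
#' @return Named list of 8 arrays (`LLL`, `LLH`, `LHL`, `LHH`, `HLL`, `HLH`,
#'   `HHL`, `HHH`), each the shape of `vol`.
#' @export
wavelet_subbands <- function(vol, cfg = radiomics_config()) {
  assert_that(is.array(vol) && length(dim(vol)) == 3L, "vol must be a 3D array")
  f <- db4_filters()
  L <- length(f$lo)
  assert_that(all(dim(vol) >= L),
              "every spatial dim must be >= the filter length (%d), got %s",
              L, paste(dim(vol), collapse = "x"))
  lo <- f$lo / sqrt(2)
  hi <- f$hi / sqrt(2)
  bands <- list()
  # share the axis-1/axis-2 partial results across sub-bands
  part1 <- list(L = axis_filter(vol, lo, 1L, cfg$boundary_mode),
                H = axis_filter(vol, hi, 1L, cfg$boundary_mode))
  for (a1 in c("L", "H")) {
    part2 <- list(L = axis_filter(part1[[a1]], lo, 2L, cfg$boundary_mode),
                  H = axis_filter(part1[[a1]], hi, 2L, cfg$boundary_mode))
    for (a2 in c("L", "H")) {
      for (a3 in c("L", "H")) {
        h3 <- if (a3 == "L") lo else hi
        bands[[paste0(a1, a2, a3)]] <- axis_filter(part2[[a2]], h3, 3L, cfg$boundary_mode)
      }
    }
  }
  bands[subband_names()]
}

subband_names <- function() {
  c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")
}

first_order_names <- function() {
  c("energy", "total_energy", "entropy", "minimum", "percentile10",
    "percentile90", "maximum", "mean", "median", "iqr", "range",
    "mad", "rmad", "rms", "sd", "skewness", "kurtosis", "variance",
    "uniformity")
}

glcm_names <- function() {
  c("autocorrelation", "joint_average", "cluster_prominence", "cluster_shade",
    "cluster_tendency", "contrast", "correlation", "difference_average",
    "difference_entropy", "difference_variance", "joint_energy",
    "joint_entropy", "imc1", "imc2", "idm", "idmn", "id", "idn",
    "inverse_variance", "maximum_probability", "sum_entropy", "sum_squares")
}

# Discretize intensities to 1..levels.
discretize_levels <- function(x, cfg) {
  if (cfg$discretization == "fixed_bin_count") {
    rng <- range(x)
    if (rng[2] == rng[1]) return(rep(1L, length(x)))
    lv <- floor((x - rng[1]) / (rng[2] - rng[1]) * cfg$glcm_levels) + 1L
    pmin(lv, cfg$glcm_levels)
  } else {
    as.integer(floor((x - min(x)) / cfg$bin_width) + 1L)
  }
}

#' First-order (histogram) radiomic features
#'
#' The standard 19-feature first-order set over the intensities of one ROI:
#' energy, total energy, (histogram) entropy, minimum, 10th and 90th
#' percentiles, maximum, mean, median, interquartile range, range, mean
#' absolute deviation, robust mean absolute deviation (10-90 percentile
#' subset), root mean square, standard deviation, skewness, kurtosis
#' (non-excess), variance and uniformity. Moments use the population (1/N)
#' convention; entropy/uniformity use the configured discretization.
#'
#' @param values numeric vector of ROI voxel intensities (nonempty).
#' @param cfg a [radiomics_config()].
#' @return Named numeric vector of length 19.
#' @export
first_order_features <- function(values, cfg = radiomics_config()) {
  assert_that(length(values) >= 1, "ROI has no voxels")
  x <- as.numeric(values)
  n <- length(x)
  eps <- 2.2e-16
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  q <- stats::quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE, type = 7)
  sub <- x[x >= q[1] & x <= q[5]]
  lv <- discretize_levels(x, cfg)
  p <- tabulate(lv, nbins = max(lv)) / n
  p <- p[p > 0]
  out <- c(
    energy = sum(x^2),
    total_energy = cfg$voxel_volume * sum(x^2),
    entropy = -sum(p * log2(p + eps)),
    minimum = min(x),
    percentile10 = q[1],
    percentile90 = q[5],
    maximum = max(x),
    mean = mu,
    median = q[3],
    iqr = q[4] - q[2],
    range = max(x) - min(x),
    mad = mean(abs(x - mu)),
    rmad = if (length(sub) > 0) mean(abs(sub - mean(sub))) else 0,
    rms = sqrt(mean(x^2)),
    sd = sqrt(m2),
    skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    variance = m2,
    uniformity = sum(p^2)
  )
  out[first_order_names()]
}

# Accumulate the symmetric co-occurrence matrix for one offset within a ROI.
glcm_matrix_offset <- function(lv_arr, roi, off, levels) {
  d <- dim(lv_arr)
  sx <- seq_len(d[1]) ; sy <- seq_len(d[2]) ; sz <- seq_len(d[3])
  ax <- sx[sx + off[1] >= 1 & sx + off[1] <= d[1]]
  ay <- sy[sy + off[2] >= 1 & sy + off[2] <= d[2]]
  az <- sz[sz + off[3] >= 1 & sz + off[3] <= d[3]]
  if (length(ax) == 0 || length(ay) == 0 || length(az) == 0) return(NULL)
  a <- lv_arr[ax, ay, az, drop = FALSE]
  b <- lv_arr[ax + off[1], ay + off[2], az + off[3], drop = FALSE]
  ra <- roi[ax, ay, az, drop = FALSE]
  rb <- roi[ax + off[1], ay + off[2], az + off[3], drop = FALSE]
  ok <- ra & rb
  if (!any(ok)) return(NULL)
  ia <- a[ok]; ib <- b[ok]
  counts <- tabulate((ia - 1L) * levels + ib, nbins = levels * levels) +
            tabulate((ib - 1L) * levels + ia, nbins = levels * levels)
  matrix(counts, levels, levels, byrow = TRUE)
}

glcm_features_from_p <- function(P) {
  eps <- 2.2e-16
  L <- nrow(P)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  px <- rowSums(P)
  py <- colSums(P)
  mux <- sum(seq_len(L) * px)
  muy <- sum(seq_len(L) * py)
  sigx <- sqrt(sum((seq_len(L) - mux)^2 * px))
  sigy <- sqrt(sum((seq_len(L) - muy)^2 * py))
  # diagonal (difference) and cross-diagonal (sum) distributions
  k_diff <- 0:(L - 1)
  p_diff <- vapply(k_diff, function(k) sum(P[abs(i - j) == k]), 0)
  k_sum <- 2:(2 * L)
  p_sum <- vapply(k_sum, function(k) sum(P[(i + j) == k]), 0)
  da <- sum(k_diff * p_diff)
  hx <- -sum(px[px > 0] * log2(px[px > 0] + eps))
  hy <- -sum(py[py > 0] * log2(py[py > 0] + eps))
  hxy <- -sum(P[P > 0] * log2(P[P > 0] + eps))
  pxy <- outer(px, py)
  hxy1 <- -sum(P * log2(pxy + eps))
  hxy2 <- -sum(pxy * log2(pxy + eps))
  corr <- if (sigx * sigy > 0) (sum(i * j * P) - mux * muy) / (sigx * sigy) else 1
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - hxy)), 0))
  out <- c(
    autocorrelation = sum(i * j * P),
    joint_average = sum(i * P),
    cluster_prominence = sum((i + j - mux - muy)^4 * P),
    cluster_shade = sum((i + j - mux - muy)^3 * P),
    cluster_tendency = sum((i + j - mux - muy)^2 * P),
    contrast = sum((i - j)^2 * P),
    correlation = corr,
    difference_average = da,
    difference_entropy = -sum(p_diff[p_diff > 0] * log2(p_diff[p_diff > 0] + eps)),
    difference_variance = sum((k_diff - da)^2 * p_diff),
    joint_energy = sum(P^2),
    joint_entropy = hxy,
    imc1 = imc1,
    imc2 = imc2,
    idm = sum(P / (1 + (i - j)^2)),
    idmn = sum(P / (1 + ((i - j) / L)^2)),
    id = sum(P / (1 + abs(i - j))),
    idn = sum(P / (1 + abs(i - j) / L)),
    inverse_variance = sum(P[i != j] / (i - j)[i != j]^2),
    maximum_probability = max(P),
    sum_entropy = -sum(p_sum[p_sum > 0] * log2(p_sum[p_sum > 0] + eps)),
    sum_squares = sum((i - mux)^2 * P)
  )
  out[glcm_names()]
}

#' Grey-level co-occurrence (GLCM) radiomic features
#'
#' Discretizes the ROI intensities to `glcm_levels` grey levels, accumulates
#' a symmetric co-occurrence matrix per spatial offset (in-ROI voxel pairs
#' only), normalises each, computes the standard 22-feature GLCM set per
#' offset, and averages the feature values over offsets that have at least
#' one valid pair.
#'
#' @param values 3D numeric array (e.g. one wavelet sub-band).
#' @param roi_mask logical 3D array selecting the ROI.
#' @param cfg a [radiomics_config()].
#' @return Named numeric vector of length 22.
#' @export
glcm_features <- function(values, roi_mask, cfg = radiomics_config()) {
  assert_that(all(dim(values) == dim(roi_mask)), "values and roi_mask dims differ")
  nvox <- sum(roi_mask)
  assert_that(nvox >= 2, "ROI needs at least 2 voxels for co-occurrence, got %d", nvox)
  # crop to the ROI bounding box for speed
  w <- which(roi_mask, arr.ind = TRUE)
  rr <- apply(w, 2, range)
  vb <- values[rr[1, 1]:rr[2, 1], rr[1, 2]:rr[2, 2], rr[1, 3]:rr[2, 3], drop = FALSE]
  mb <- roi_mask[rr[1, 1]:rr[2, 1], rr[1, 2]:rr[2, 2], rr[1, 3]:rr[2, 3], drop = FALSE]
  lv <- array(1L, dim(vb))
  lv[mb] <- discretize_levels(vb[mb], cfg)
  levels <- max(lv[mb])
  feats <- NULL
  n_used <- 0L
  for (o in seq_len(nrow(cfg$glcm_offsets))) {
    cm <- glcm_matrix_offset(lv, mb, cfg$glcm_offsets[o, ], levels)
    if (is.null(cm)) next
    P <- cm / sum(cm)
    fo <- glcm_features_from_p(P)
    feats <- if (is.null(feats)) fo else feats + fo
    n_used <- n_used + 1L
  }
  assert_that(n_used > 0, "ROI has no valid co-occurrence pairs for any offset")
  feats / n_used
}

#' Extract the per-subject radiomic feature vector
#'
#' For every atlas ROI and each of the 8 level-1 wavelet sub-bands, computes
#' the 19 first-order and 22 GLCM features, i.e. 328 features per ROI and
#' `328 * n_rois` per subject (48,544 for a 148-region atlas). Ordering is
#' deterministic: ROI (ascending id), then sub-band (`LLL` ... `HHH`), then
#' feature (first-order set followed by GLCM set).
#'
#' @param vol 3D structural volume.
#' @param atlas a [labelmap()] on the same grid.
#' @param cfg a [radiomics_config()].
#' @return An object of class `radiomic_vector`: list with `values` (numeric)
#'   and `index` (tibble with columns roi_id, subband, feature).
#' @export
extract_subject <- function(vol, atlas, cfg = radiomics_config()) {
  assert_that(all(dim(vol) == dim(atlas$data)), "atlas grid does not match the volume")
  bands <- wavelet_subbands(vol, cfg)
  rois <- atlas$region_ids
  nfo <- length(first_order_names())
  ngl <- length(glcm_names())
  per_band <- nfo + ngl
  values <- numeric(length(rois) * 8L * per_band)
  at <- 0L
  roi_masks <- lapply(rois, function(r) atlas$data == r)
  for (ri in seq_along(rois)) {
    m <- roi_masks[[ri]]
    assert_that(any(m), "ROI %d is empty in the atlas", rois[ri])
    for (b in seq_len(8L)) {
      band <- bands[[b]]
      fo <- first_order_features(band[m], cfg)
      gl <- glcm_features(band, m, cfg)
      values[at + seq_len(per_band)] <- c(fo, gl)
      at <- at + per_band
    }
  }
  index <- tibble::tibble(
    roi_id = rep(rois, each = 8L * per_band),
    subband = rep(rep(subband_names(), each = per_band), times = length(rois)),
    feature = rep(c(first_order_names(), glcm_names()), times = length(rois) * 8L)
  )
  structure(list(values = values, index = index), class = "radiomic_vector")
}

#' @export
print.radiomic_vector <- function(x, ...) {
  cat(sprintf("<radiomic_vector> %d values (%d ROIs x %d sub-bands x %d features)\n",
              length(x$values), length(unique(x$index$roi_id)),
              length(unique(x$index$subband)), length(unique(x$index$feature))))
  invisible(x)
}

#' Tidy a radiomic vector into a long tibble
#'
#' @param x a `radiomic_vector`.
#' @param ... unused.
#' @return A tibble with columns roi_id, subband, feature, value.
#' @method tidy radiomic_vector
#' @export
tidy.radiomic_vector <- function(x, ...) {
  out <- x$index
  out$value <- x$values
  out
}

#' Radiomic feature matrix for a cohort
#'
#' Runs [extract_subject()] for every subject and binds the vectors into a
#' subjects x features matrix (features in the deterministic per-subject
#' order, shared across subjects).
#'
#' @param cohort a [make_cohort()] result (or any list of subjects with an
#'   `smri` field) plus an atlas.
#' @param cfg a [radiomics_config()].
#' @return List with `X` (matrix), `index` (feature index tibble) and
#'   `subject_ids`.
#' @export
radiomics_matrix <- function(cohort, cfg = radiomics_config()) {
  vecs <- lapply(cohort$subjects, function(s) extract_subject(s$smri, cohort$atlas, cfg))
  X <- do.call(rbind, lapply(vecs, `[[`, "values"))
  rownames(X) <- vapply(cohort$subjects, `[[`, "", "id")
  list(X = X, index = vecs[[1]]$index, subject_ids = rownames(X))
}
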