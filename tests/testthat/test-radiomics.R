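test_that("wavelet sub-bands conserve energy and annihilate constants", {
  set.seed(1)
  x <- array(rnorm(10 * 12 * 11), c(10, 12, 11))
  sb <- wavelet_subbands(x, radiomics_config(boundary_mode = "periodic"))
  expect_identical(names(sb), c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH"))
  for (b in sb) expect_identical(dim(b), dim(x))
  # tight-frame Parseval identity under periodic extension
  expect_equal(sum(sapply(sb, function(b) sum(b^2))), sum(x^2),
               tolerance = 1e-8)
  # any sub-band with a high-pass axis vanishes on a constant image
  for (mode in c("symmetric", "periodic")) {
    sbc <- wavelet_subbands(array(5, c(9, 9, 9)), radiomics_config(boundary_mode = mode))
    expect_lt(max(sapply(sbc[-1], function(b) max(abs(b)))), 1e-10)
  }
  expect_error(wavelet_subbands(array(0, c(4, 9, 9))), "filter length")
})

test_that("first-order features match direct formulas", {
  x <- 1:8
  fo <- first_order_features(x)
  expect_length(fo, 19L)
  expect_equal(fo[["energy"]], 204)
  expect_equal(fo[["mean"]], 4.5)
  expect_equal(fo[["range"]], 7)
  # every feature against an independently coded formula
  q <- quantile(x, c(.10, .25, .50, .75, .90), names = FALSE)
  sub <- x[x >= q[1] & x <= q[5]]
  m2 <- mean((x - mean(x))^2)
  direct <- c(energy = sum(x^2), total_energy = sum(x^2),
              minimum = 1, percentile10 = q[1], percentile90 = q[5], maximum = 8,
              mean = 4.5, median = q[3], iqr = q[4] - q[2], range = 7,
              mad = mean(abs(x - 4.5)), rmad = mean(abs(sub - mean(sub))),
              rms = sqrt(mean(x^2)), sd = sqrt(m2),
              skewness = mean((x - 4.5)^3) / m2^1.5,
              kurtosis = mean((x - 4.5)^4) / m2^2, variance = m2)
  for (nm in names(direct)) expect_equal(fo[[nm]], direct[[nm]], tolerance = 1e-12)
  # degenerate (constant) distribution
  foc <- first_order_features(rep(3, 10))
  expect_equal(foc[["variance"]], 0)
  expect_equal(foc[["range"]], 0)
  expect_equal(foc[["entropy"]], 0, tolerance = 1e-12)
  expect_equal(foc[["uniformity"]], 1)
  expect_error(first_order_features(numeric(0)), "no voxels")
})

test_that("GLCM counts match hand enumeration and are shift-invariant", {
  cfg2 <- radiomics_config(glcm_levels = 2L, glcm_offsets = matrix(c(1L, 0L, 0L), 1))
  strip <- array(c(1, 1, 2, 2), c(4, 1, 1))
  g <- glcm_features(strip, array(TRUE, c(4, 1, 1)), cfg2)
  expect_length(g, 22L)
  # pairs (1,1),(1,2),(2,2); symmetric counts (2,1,1,2)/6
  P <- matrix(c(2, 1, 1, 2) / 6, 2, 2)
  i <- matrix(1:2, 2, 2); j <- t(i)
  expect_equal(g[["maximum_probability"]], max(P))
  expect_equal(g[["contrast"]], sum((i - j)^2 * P))
  expect_equal(g[["joint_entropy"]], -sum(P * log2(P)), tolerance = 1e-12)
  expect_equal(g[["joint_energy"]], sum(P^2))
  expect_equal(g[["autocorrelation"]], sum(i * j * P))
  expect_equal(g[["inverse_variance"]], sum(P[i != j]), tolerance = 1e-12)
  # constant ROI: a single co-occurrence cell
  gc <- glcm_features(array(7, c(3, 3, 3)), array(TRUE, c(3, 3, 3)),
                      radiomics_config())
  expect_equal(gc[["maximum_probability"]], 1)
  expect_equal(gc[["contrast"]], 0)
  expect_equal(gc[["joint_entropy"]], 0, tolerance = 1e-12)
  # fixed-bin-count discretization ignores global intensity shifts
  expect_equal(glcm_features(strip + 100, array(TRUE, c(4, 1, 1)), cfg2), g,
               tolerance = 1e-12)
  expect_error(glcm_features(strip, array(c(TRUE, rep(FALSE, 3)), c(4, 1, 1)), cfg2),
               "at least 2")
})

test_that("per-subject extraction yields 328 features per ROI in stable order", {
  co <- mini_cohort()
  rv <- cached("rv_subject1", extract_subject(co$subjects[[1]]$smri, co$atlas))
  n_rois <- length(co$atlas$region_ids)
  expect_length(rv$values, 328L * n_rois)
  expect_true(all(is.finite(rv$values)))
  expect_false(anyDuplicated(rv$index) > 0)
  # a 1-region atlas gives exactly 328 values covering 8 sub-bands x 41 names
  lab1 <- labelmap(array(1L, c(10, 10, 10)))
  rv1 <- extract_subject(array(rnorm(1000), c(10, 10, 10)), lab1)
  expect_length(rv1$values, 328L)
  expect_identical(length(unique(rv1$index$subband)), 8L)
  expect_identical(length(unique(rv1$index$feature)), 41L)
  # deterministic ordering: roi, then sub-band, then feature
  expect_identical(rv$index$roi_id[1:656], rep(co$atlas$region_ids[1:2], each = 328L))
  expect_identical(rv$index$subband[1:82], rep(c("LLL", "LLH"), each = 41L))
  # tidy() exposes the long table
  td <- tidy(rv)
  expect_identical(nrow(td), length(rv$values))
  expect_identical(td$value, rv$values)
})

test_that("ROI features depend only on voxels that can reach the ROI", {
  # perturbing voxels beyond the wavelet filter reach leaves a ROI unchanged
  set.seed(4)
  vol <- array(rnorm(18 * 10 * 10), c(18, 10, 10))
  lab <- array(0L, c(18, 10, 10))
  lab[1:4, , ] <- 1L
  lab[15:18, , ] <- 2L
  atlas <- labelmap(lab)
  base <- extract_subject(vol, atlas)
  vol2 <- vol
  vol2[15:18, , ] <- vol2[15:18, , ] + 50  # far from ROI 1 (filter length 8)
  pert <- extract_subject(vol2, atlas)
  roi1 <- base$index$roi_id == 1L
  expect_equal(pert$values[roi1], base$values[roi1], tolerance = 1e-10)
  expect_false(isTRUE(all.equal(pert$values[!roi1], base$values[!roi1])))
})

test_that("a planted shift shows up only in ROIs within filter reach", {
  # two ROIs separated by more than the 8-tap filter support; the class
  # shift is planted in ROI 1 only
  lab <- array(0L, c(20, 10, 10))
  lab[1:4, , ] <- 1L
  lab[17:20, , ] <- 2L
  atlas <- labelmap(lab)
  set.seed(31)
  y <- rep(c(0L, 1L), each = 6)
  X <- t(sapply(y, function(cl) {
    v <- array(rnorm(2000, mean = 100), c(20, 10, 10))
    if (cl == 1L) v[1:4, , ] <- v[1:4, , ] + 5
    extract_subject(v, atlas)$values
  }))
  idx <- extract_subject(array(rnorm(2000), c(20, 10, 10)), atlas)$index
  pick <- which(idx$subband == "LLL" & idx$feature == "mean")
  contrast <- sapply(pick, function(j) abs(mean(X[y == 1, j]) - mean(X[y == 0, j])))
  expect_gt(contrast[idx$roi_id[pick] == 1L], 10 * contrast[idx$roi_id[pick] == 2L])
})

test_that("the cohort feature matrix has the documented shape", {
  rm <- mini_radiomics()
  expect_identical(dim(rm$X), c(16L, 328L * 6L))
  expect_identical(rm$subject_ids, sprintf("sub-%03d", 1:16))
  expect_true(all(is.finite(rm$X)))
})
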