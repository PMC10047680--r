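noise_vol <- function() {
  cached("noise_vol_8", make_rsfmri(
    fixture_config(grid_shape = c(8, 8, 8), n_timepoints = 40L, seed = 3),
    "white_noise"))
}

test_that("ReHo matches the tie-corrected Kendall-W oracle", {
  v <- noise_vol()
  cfg <- summary_config()
  w <- reho(v, cfg)
  expect_true(all(w >= 0 & w <= 1))
  for (p in list(c(3, 4, 5), c(1, 1, 1), c(8, 5, 2))) {
    expect_equal(w[p[1], p[2], p[3]], oracle_reho_at(v, p[1], p[2], p[3]),
                 tolerance = 1e-12)
  }
  # a constant series in the neighbourhood engages the tie correction
  vc <- v
  vc$data[4, 4, 4, ] <- 7
  vc$mask <- array(TRUE, dim(vc$data)[1:3])
  wc <- reho(vc, cfg)
  expect_equal(wc[4, 5, 4], oracle_reho_at(vc, 4, 5, 4), tolerance = 1e-12)
  # perfect concordance: identical series in a homogeneous block
  vh <- make_rsfmri(fixture_config(grid_shape = c(6, 6, 6), n_timepoints = 20L,
                                   seed = 6, noise_sd = 0),
                    "locally_homogeneous", block_size = 6L)
  expect_equal(reho(vh, cfg)[3, 3, 3], 1, tolerance = 1e-12)
  # K independent series at the 6-neighbourhood: W near 1/K
  w6 <- reho(v, summary_config(neighborhood = 6L))
  expect_lt(abs(w6[4, 4, 4] - 1 / 7), 0.15)
  expect_error(reho(volume4d(array(1:16, c(2, 2, 2, 2)))), "timepoints")
})

test_that("ALFF and fALFF match the explicit DFT oracle", {
  v <- noise_vol()
  cfg <- summary_config()
  a <- alff(v, cfg)
  fa <- falff(v, cfg)
  n <- dim(v$data)[4]
  f <- seq_len(n %/% 2) / (n * v$tr_seconds)
  band <- f >= cfg$band_low_hz & f <= cfg$band_high_hz
  full <- f <= cfg$full_band_high_hz
  for (p in list(c(2, 2, 2), c(7, 3, 6))) {
    amp <- oracle_amplitudes(oracle_detrend(v$data[p[1], p[2], p[3], ]))
    expect_equal(a[p[1], p[2], p[3]], mean(amp[band]), tolerance = 1e-10)
    expect_equal(fa[p[1], p[2], p[3]], sum(amp[band]) / sum(amp[full]),
                 tolerance = 1e-10)
  }
  # zero signal and linear scaling
  z <- volume4d(array(0, c(3, 3, 3, 16)), tr_seconds = 2,
                mask = array(TRUE, c(3, 3, 3)))
  expect_true(all(alff(z, cfg) == 0))
  expect_true(all(falff(z, cfg) == 0))
  v3 <- v
  v3$data <- 3 * v3$data
  v3$mask <- array(TRUE, dim(v$data)[1:3])
  expect_equal(alff(v3, cfg), 3 * a, tolerance = 1e-10)
  # unresolvable band names the resolvable one
  short <- volume4d(array(rnorm(8 * 8), c(2, 2, 2, 8)), tr_seconds = 2)
  expect_error(alff(short, summary_config(band_low_hz = 0.011, band_high_hz = 0.02)),
               "resolvable")
})

test_that("pure tones land entirely in (or out of) the low-frequency band", {
  cfg <- summary_config(detrend = FALSE)  # the planted tone has no trend
  vin <- make_rsfmri(fixture_config(grid_shape = c(5, 5, 5), n_timepoints = 100L,
                                    tr_seconds = 2, planted_freq_hz = 0.05, seed = 2),
                     "pure_tone")
  fa_in <- falff(vin, cfg)
  expect_gte(min(fa_in), 0.99)
  # per-voxel ALFF equals the oracle mean band amplitude
  a_in <- alff(vin, cfg)
  amp <- oracle_amplitudes(vin$data[2, 3, 4, ])
  f <- seq_len(50) / 200
  expect_equal(a_in[2, 3, 4], mean(amp[f >= 0.01 & f <= 0.08]), tolerance = 1e-10)
  # a tone above the band but inside the full band
  vout <- make_rsfmri(fixture_config(grid_shape = c(5, 5, 5), n_timepoints = 100L,
                                     tr_seconds = 2, planted_freq_hz = 0.15, seed = 2),
                      "pure_tone")
  expect_lte(max(falff(vout, cfg)), 0.01)
})

test_that("degree centrality matches the all-pairs correlation oracle", {
  v <- cached("noise_vol_4", make_rsfmri(
    fixture_config(grid_shape = c(4, 4, 4), n_timepoints = 30L, seed = 5),
    "white_noise"))
  cfg <- summary_config()
  m <- t(matrix(v$data, 64, 30))
  R <- stats::cor(m)
  diag(R) <- NA
  expect_equal(as.vector(degree_centrality(v, cfg)),
               rowSums(R >= cfg$corr_threshold, na.rm = TRUE), tolerance = 1e-12)
  expect_equal(as.vector(degree_centrality(v, cfg, weighted = TRUE)),
               rowSums(R * (R >= cfg$corr_threshold), na.rm = TRUE), tolerance = 1e-12)
  # binarized map is integer-valued
  expect_true(all(degree_centrality(v, cfg) %% 1 == 0))
  # threshold near 1 on noise leaves nothing
  expect_true(all(degree_centrality(v, summary_config(corr_threshold = 0.999)) == 0))
  # perfect correlation inside a homogeneous block
  vh <- make_rsfmri(fixture_config(grid_shape = c(6, 6, 6), n_timepoints = 40L,
                                   seed = 7, noise_sd = 0),
                    "locally_homogeneous", block_size = 3L)
  dch <- degree_centrality(vh, summary_config(corr_threshold = 0.9))
  expect_true(all(dch == 26))
  # invariance to per-voxel positive affine rescaling of the series
  v2 <- v
  scl <- array(runif(64, 0.5, 2), c(4, 4, 4))
  off <- array(rnorm(64), c(4, 4, 4))
  v2$data <- sweep(sweep(v$data, 1:3, scl, "*"), 1:3, off, "+")
  v2$mask <- array(TRUE, c(4, 4, 4))
  expect_equal(degree_centrality(v2, cfg), degree_centrality(v, cfg), tolerance = 1e-9)
})

test_that("eigenvector centrality matches a dense eigensolver", {
  v <- cached("noise_vol_4", make_rsfmri(
    fixture_config(grid_shape = c(4, 4, 4), n_timepoints = 30L, seed = 5),
    "white_noise"))
  cfg <- summary_config()
  m <- t(matrix(v$data, 64, 30))
  R <- stats::cor(m)
  for (wt in c(FALSE, TRUE)) {
    B <- if (wt) ((1 + R) / 2) * (R >= cfg$corr_threshold) else (R >= cfg$corr_threshold) * 1
    diag(B) <- 0
    lead <- abs(eigen(B, symmetric = TRUE)$vectors[, 1])
    ec <- eigenvector_centrality(v, cfg, weighted = wt)
    expect_equal(as.vector(ec), lead, tolerance = 1e-8)
    expect_equal(sum(ec^2), 1, tolerance = 1e-10)
  }
  # identical series everywhere -> uniform eigenvector
  base <- rnorm(20)
  ve <- volume4d(array(rep(base, each = 27), c(3, 3, 3, 20)), tr_seconds = 2)
  expect_equal(as.vector(eigenvector_centrality(ve, cfg)),
               rep(1 / sqrt(27), 27), tolerance = 1e-9)
})

test_that("LFCD grows face-connected clusters from each seed", {
  v <- cached("noise_vol_4", make_rsfmri(
    fixture_config(grid_shape = c(4, 4, 4), n_timepoints = 30L, seed = 5),
    "white_noise"))
  cfg <- summary_config()
  lf <- lfcd(v, cfg)
  for (seed_idx in c(1L, 22L, 64L)) {
    expect_identical(as.vector(lf)[seed_idx],
                     as.numeric(oracle_lfcd_at(v, seed_idx, cfg$corr_threshold)))
  }
  # threshold 1 on noisy data: every seed keeps only itself
  expect_true(all(lfcd(v, summary_config(corr_threshold = 0.9999)) == 1))
  # homogeneous 3x3x3 blocks at long series: every voxel reports its block size
  vh <- make_rsfmri(fixture_config(grid_shape = c(6, 6, 6), n_timepoints = 200L,
                                   seed = 8, noise_sd = 0),
                    "locally_homogeneous", block_size = 3L)
  expect_true(all(lfcd(vh, summary_config(corr_threshold = 0.9)) == 27))
})

test_that("VMHC equals flip-and-correlate and detects planted (anti)symmetry", {
  v <- noise_vol()
  cfg <- summary_config()
  vm <- vmhc(v, cfg)
  d <- dim(v$data)
  m <- t(matrix(v$data, prod(d[1:3]), d[4]))
  flip <- t(matrix(v$data[d[1]:1, , , ], prod(d[1:3]), d[4]))
  ref <- sapply(seq_len(prod(d[1:3])), function(i) stats::cor(m[, i], flip[, i]))
  expect_equal(as.vector(vm), ref, tolerance = 1e-12)
  # exact mirror symmetry -> 1 everywhere
  vs <- make_rsfmri(mini_fixture(seed = 5), "mirror_symmetric")
  expect_true(all(abs(vmhc(vs, cfg) - 1) < 1e-12))
  # negate one hemisphere -> -1 everywhere
  va <- vs
  va$data[7:12, , , ] <- -va$data[7:12, , , ]
  expect_true(all(abs(vmhc(va, cfg) + 1) < 1e-12))
})

test_that("dual regression recovers planted maps and matches least squares", {
  cfg0 <- fixture_config(grid_shape = c(6, 6, 6), n_timepoints = 50L, seed = 6,
                         noise_sd = 0, n_templates = 4L)
  vx <- make_rsfmri(cfg0, "template_mixture")
  dr <- dual_regression(vx, vx$planted$templates)
  expect_identical(dr$channel_names, sprintf("dr_%02d", 1:4))
  expect_equal(attr(dr, "timecourses"), vx$planted$timecourses, tolerance = 1e-9)
  for (s in 1:4) {
    expect_equal(dr$data[, , , s], vx$planted$templates[[s]], tolerance = 1e-9)
  }
  # with noise: per-voxel coefficients equal the normal-equations solution
  cfgn <- fixture_config(grid_shape = c(6, 6, 6), n_timepoints = 50L, seed = 7,
                         noise_sd = 0.5, n_templates = 4L)
  vn <- make_rsfmri(cfgn, "template_mixture")
  drn <- dual_regression(vn, vn$planted$templates)
  TC <- attr(drn, "timecourses")
  Y <- t(asdgraph:::vol_matrix(vn))
  B <- solve(crossprod(TC), crossprod(TC, t(Y)))
  got <- matrix(drn$data, prod(dim(vn$data)[1:3]), 4)
  expect_equal(got, t(B), tolerance = 1e-8, ignore_attr = TRUE)
  # 10 templates -> 10 channels
  v10 <- make_rsfmri(mini_fixture(seed = 8, n_templates = 10L), "white_noise")
  tpl10 <- make_templates(mini_fixture(seed = 8, n_templates = 10L))
  expect_identical(dim(dual_regression(v10, tpl10)$data)[4], 10L)
  # rank-deficient design names the failing stage
  dup <- vx$planted$templates
  dup[[2]] <- dup[[1]]
  expect_error(dual_regression(vx, dup), "stage 1")
})

test_that("the full stack has 19 named channels in a stable order", {
  cfg <- mini_fixture(seed = 9, n_templates = 10L,
                      grid_shape = c(8, 9, 8), n_timepoints = 40L)
  v <- make_rsfmri(cfg, "white_noise")
  tpl <- make_templates(cfg)
  st <- compute_all_summaries(v, tpl)
  expect_identical(dim(st$data)[4], 19L)
  expect_identical(st$channel_names,
                   c("reho", "alff", "falff", "dc_bin", "dc_weighted",
                     "ec_bin", "ec_weighted", "lfcd", "vmhc",
                     sprintf("dr_%02d", 1:10)))
  st2 <- compute_all_summaries(v, tpl)
  expect_identical(st$data, st2$data)
  # without templates the nine voxelwise maps remain
  expect_identical(dim(compute_all_summaries(v)$data)[4], 9L)
})

test_that("derivatives transform consistently under a first-axis flip", {
  v <- cached("noise_vol_4", make_rsfmri(
    fixture_config(grid_shape = c(4, 4, 4), n_timepoints = 30L, seed = 5),
    "white_noise"))
  cfg <- summary_config()
  vf <- volume4d(v$data[4:1, , , ], tr_seconds = v$tr_seconds,
                 mask = array(TRUE, c(4, 4, 4)))
  flip <- function(m) m[4:1, , ]
  expect_equal(reho(vf, cfg), flip(reho(v, cfg)), tolerance = 1e-12)
  expect_equal(alff(vf, cfg), flip(alff(v, cfg)), tolerance = 1e-12)
  expect_equal(degree_centrality(vf, cfg), flip(degree_centrality(v, cfg)),
               tolerance = 1e-12)
  expect_equal(lfcd(vf, cfg), flip(lfcd(v, cfg)), tolerance = 1e-12)
  expect_equal(vmhc(vf, cfg), flip(vmhc(v, cfg)), tolerance = 1e-12)
  # ALFF/degree centrality are invariant under arbitrary voxel relabelling
  perm <- sample(64)
  mp <- matrix(v$data, 64, 30)[perm, ]
  vp <- volume4d(array(mp, c(4, 4, 4, 30)), tr_seconds = 2,
                 mask = array(TRUE, c(4, 4, 4)))
  expect_equal(as.vector(alff(vp, cfg)), as.vector(alff(v, cfg))[perm],
               tolerance = 1e-12)
  expect_equal(as.vector(degree_centrality(vp, cfg)),
               as.vector(degree_centrality(v, cfg))[perm], tolerance = 1e-12)
})
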