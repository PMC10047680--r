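test_that("atlas has mirrored, contiguous regions with the expected label count", {
  at <- make_atlas(fixture_config(seed = 3))  # default 74 per hemisphere
  expect_length(at$region_ids, 148L)

  cfg <- fixture_config(grid_shape = c(12, 12, 12), n_regions_per_hemisphere = 3L, seed = 2)
  at3 <- make_atlas(cfg)
  expect_length(at3$region_ids, 6L)
  # each label forms exactly one 6-connected component
  for (r in at3$region_ids) {
    expect_identical(oracle_n_components(at3$data, r), 1L)
  }
  # region k on the left mirrors region k + n on the right
  d <- dim(at3$data)
  for (i in seq_len(d[1] %/% 2)) {
    l <- at3$data[i, , ]
    r <- at3$data[d[1] + 1L - i, , ]
    expect_true(all(r[l > 0] == l[l > 0] + 3L))
  }
  # minimal case: one region per hemisphere
  at1 <- make_atlas(fixture_config(grid_shape = c(6, 6, 6), n_regions_per_hemisphere = 1L))
  expect_identical(at1$region_ids, c(1L, 2L))
  # impossible sizing errors out
  expect_error(make_atlas(fixture_config(grid_shape = c(2, 2, 2),
                                         n_regions_per_hemisphere = 50L)),
               "too small")
})

test_that("planted rs-fMRI structures are directly checkable", {
  cfg <- mini_fixture(seed = 5)
  # mirror symmetry is exact by construction
  vm <- make_rsfmri(cfg, "mirror_symmetric")
  expect_identical(vm$data, vm$data[dim(vm$data)[1]:1, , , ])
  # pure tone: all non-DC spectral energy in the planted bin (explicit DFT)
  vt <- make_rsfmri(fixture_config(grid_shape = c(5, 5, 5), n_timepoints = 200L,
                                   tr_seconds = 2, planted_freq_hz = 0.05, seed = 4),
                    "pure_tone")
  expect_identical(vt$planted$bin, 20L)
  for (v in list(c(1, 1, 1), c(3, 4, 5))) {
    amp <- oracle_amplitudes(vt$data[v[1], v[2], v[3], ])
    expect_gt(amp[vt$planted$bin] / sum(amp), 1 - 1e-8)
  }
  # white noise is deterministic under a fixed seed
  w1 <- make_rsfmri(cfg, "white_noise")
  w2 <- make_rsfmri(cfg, "white_noise")
  expect_identical(w1$data, w2$data)
  # locally homogeneous: voxels in one block share the latent series exactly
  # at zero noise
  vh <- make_rsfmri(mini_fixture(seed = 6, noise_sd = 0), "locally_homogeneous",
                    block_size = 3L)
  b <- vh$planted$block_id
  same_block <- which(b == b[2, 2, 2], arr.ind = TRUE)
  ref <- vh$data[2, 2, 2, ]
  for (r in seq_len(nrow(same_block))) {
    expect_identical(vh$data[same_block[r, 1], same_block[r, 2], same_block[r, 3], ], ref)
  }
  # template mixture reproduces maps %*% timecourses exactly at zero noise
  vx <- make_rsfmri(mini_fixture(seed = 7, noise_sd = 0), "template_mixture")
  recon <- Reduce(`+`, lapply(seq_along(vx$planted$templates), function(s) {
    outer(as.vector(vx$planted$templates[[s]]), vx$planted$timecourses[, s])
  }))
  expect_equal(as.vector(vx$data), as.vector(recon), tolerance = 1e-12)
  expect_error(make_rsfmri(cfg, "no_such_structure"))
})

test_that("group templates are disjoint, unit-norm and counted correctly", {
  tpl <- make_templates(mini_fixture(n_templates = 10L))
  expect_length(tpl, 10L)
  for (m in tpl) expect_equal(sum(m^2), 1, tolerance = 1e-12)
  for (i in 1:9) for (j in (i + 1):10) {
    expect_identical(sum(tpl[[i]] * tpl[[j]]), 0)
  }
  one <- make_templates(mini_fixture(n_templates = 1L))
  expect_length(one, 1L)
  expect_equal(sum(one[[1]]^2), 1, tolerance = 1e-12)
})

test_that("cohorts have exact class balance, planted shifts and reproducibility", {
  cfg <- mini_fixture(seed = 9, n_timepoints = 12L)
  co <- make_cohort(cfg, 20, class_balance = 0.5, n_affected_rois = 2L)
  expect_identical(sum(co$labels == 1L), 10L)
  expect_identical(sum(co$labels == 0L), 10L)
  # planted structural shift: affected-ROI class contrast exceeds unaffected
  roi_mean <- function(s, r) mean(s$smri[co$atlas$data == r])
  contrast <- sapply(co$atlas$region_ids, function(r) {
    m <- sapply(co$subjects, roi_mean, r = r)
    abs(mean(m[co$labels == 1]) - mean(m[co$labels == 0]))
  })
  aff <- co$atlas$region_ids %in% co$affected_rois
  expect_gt(min(contrast[aff]), max(contrast[!aff]))
  # determinism: identical config => bit-identical volumes and labels
  co2 <- make_cohort(cfg, 20, class_balance = 0.5, n_affected_rois = 2L)
  expect_identical(co$labels, co2$labels)
  expect_identical(co$subjects[[1]]$smri, co2$subjects[[1]]$smri)
  expect_identical(co$subjects[[5]]$fmri$data, co2$subjects[[5]]$fmri$data)
  # null construction: zero effect size leaves no systematic contrast
  co0 <- make_cohort(mini_fixture(seed = 10, n_timepoints = 12L, effect_size = 0),
                     12, n_affected_rois = 2L)
  p <- sapply(co0$affected_rois, function(r) {
    m <- sapply(co0$subjects, roi_mean, r = r)
    stats::t.test(m[co0$labels == 1], m[co0$labels == 0])$p.value
  })
  expect_gt(min(p), 0.01)
})

test_that("cohort round-trips to disk as NIfTI plus subject table", {
  dir <- withr::local_tempdir()
  co <- make_cohort(mini_fixture(seed = 12, n_timepoints = 6L), 4)
  write_cohort(co, dir, split = c("train", "train", "test", "test"))
  expect_true(file.exists(file.path(dir, "atlas.nii.gz")))
  tab <- utils::read.delim(file.path(dir, "subjects.tsv"))
  expect_identical(nrow(tab), 4L)
  expect_identical(tab$label, co$labels)
  back <- read_volume(file.path(dir, "sub-001_fmri.nii.gz"))
  expect_equal(back$data, co$subjects[[1]]$fmri$data, tolerance = 1e-6)
  expect_equal(back$tr_seconds, 2)
})
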