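#' Configuration for the synthetic-data generators
#'
#' Defines the study conditions every fixture generator works under: the voxel
#' grid (default 61 x 73 x 61, the shape of a standard-space fMRI volume),
#' the number of timepoints and repetition time, the parcellation size
#' (74 regions per hemisphere, a Destrieux-style cortical atlas), the number
#' of group spatial templates (10, as produced by a group ICA), the noise
#' level, the frequency of planted oscillations and the structural class
#' effect size.
#'
#' The first array axis is the left-right axis: mirroring maps voxel i to
#' Nx + 1 - i (no centre voxel on even-length axes).
#'
#' @param grid_shape integer vector of 3 positive voxel counts.
#' @param n_timepoints number of fMRI timepoints (>= 2).
#' @param tr_seconds repetition time in seconds.
#' @param n_regions_per_hemisphere atlas regions per hemisphere (default 74).
#' @param n_templates number of group spatial maps (default 10).
#' @param seed integer seed; identical seeds give bit-identical fixtures.
#' @param noise_sd standard deviation of additive noise.
#' @param planted_freq_hz frequency of planted oscillations; must lie below
#'   the Nyquist frequency 1/(2 * tr_seconds).
#' @param effect_size class-1 shift (intensity units) added to structural
#'   features in designated regions.
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(grid_shape = c(61L, 73L, 61L),
                           n_timepoints = 150L,
                           tr_seconds = 2,
                           n_regions_per_hemisphere = 74L,
                           n_templates = 10L,
                           seed = 1L,
                           noise_sd = 1,
                           planted_freq_hz = 0.05,
                           effect_size = 5) {
  assert_that(length(grid_shape) == 3 && all(grid_shape >= 1) &&
              all(grid_shape == round(grid_shape)), "grid_shape must be 3 positive integers")
  assert_that(n_timepoints >= 2, "n_timepoints must be >= 2")
  assert_that(tr_seconds > 0, "tr_seconds must be positive")
  assert_that(n_regions_per_hemisphere >= 1, "n_regions_per_hemisphere must be >= 1")
  assert_that(n_templates >= 1, "n_templates must be >= 1")
  assert_that(noise_sd >= 0, "noise_sd must be nonnegative")
  assert_that(planted_freq_hz > 0 && planted_freq_hz < 1 / (2 * tr_seconds),
              "planted_freq_hz must lie in (0, Nyquist) = (0, %.4g)", 1 / (2 * tr_seconds))
  structure(list(grid_shape = as.integer(grid_shape),
                 n_timepoints = as.integer(n_timepoints),
                 tr_seconds = tr_seconds,
                 n_regions_per_hemisphere = as.integer(n_regions_per_hemisphere),
                 n_templates = as.integer(n_templates),
                 seed = as.integer(seed),
                 noise_sd = noise_sd,
                 planted_freq_hz = planted_freq_hz,
                 effect_size = effect_size),
            class = "fixture_config")
}

# Split 1..n into k near-equal contiguous chunks (each nonempty).
split_chunks <- function(n, k) {
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  Map(seq.int, starts, ends)
}

# Choose a tiling (a, b, c) of a box of dims `dims` into >= n tiles, each
# nonempty, with minimal waste, then most cubical tiles. Deterministic.
choose_tiling <- function(dims, n) {
  best <- NULL
  for (a in seq_len(min(dims[1], n))) {
    for (b in seq_len(min(dims[2], ceiling(n / a)))) {
      cc <- ceiling(n / (a * b))
      if (cc > dims[3]) next
      waste <- a * b * cc - n
      shape <- c(dims[1] / a, dims[2] / b, dims[3] / cc)
      balance <- max(shape) / min(shape)
      cand <- list(a = a, b = b, c = cc, waste = waste, balance = balance)
      if (is.null(best) || waste < best$waste ||
          (waste == best$waste && balance < best$balance)) {
        best <- cand
      }
    }
  }
  best
}

#' Generate a mirrored synthetic cortical parcellation
#'
#' Builds a labelmap with `n_regions_per_hemisphere` spatially contiguous
#' box-shaped regions tiling the left hemisphere (first-axis indices
#' 1..floor(Nx/2)) and their mirror images in the right hemisphere. Region k
#' on the left mirrors region k + n on the right across the first axis. With
#' the default 74 regions per hemisphere this emulates the 148-region
#' Destrieux cortical parcellation.
#'
#' @param config a [fixture_config()].
#' @return A [labelmap()] with exactly `2 * n_regions_per_hemisphere`
#'   distinct nonzero labels.
#' @export
make_atlas <- function(config) {
  d <- config$grid_shape
  n <- config$n_regions_per_hemisphere
  lx <- d[1] %/% 2L
  assert_that(lx >= 1, "grid first axis too small to host two hemispheres")
  tiling <- choose_tiling(c(lx, d[2], d[3]), n)
  assert_that(!is.null(tiling),
              "grid %s too small to allocate %d contiguous regions per hemisphere",
              paste(d, collapse = "x"), n)
  cx <- split_chunks(lx, tiling$a)
  cy <- split_chunks(d[2], tiling$b)
  cz <- split_chunks(d[3], tiling$c)
  lab <- array(0L, d)
  id <- 0L
  done <- FALSE
  for (k in seq_along(cz)) {
    for (j in seq_along(cy)) {
      for (i in seq_along(cx)) {
        id <- id + 1L
        if (id > n) { done <- TRUE; break }
        lab[cx[[i]], cy[[j]], cz[[k]]] <- id
        # mirror image on the right hemisphere gets label id + n
        lab[d[1] + 1L - cx[[i]], cy[[j]], cz[[k]]] <- id + n
      }
      if (done) break
    }
    if (done) break
  }
  labelmap(lab)
}

#' Generate a synthetic rs-fMRI volume with planted structure
#'
#' Each structure plants one statistical property that a summary derivative
#' should detect, so every derivative can be validated directly:
#'
#' * `mirror_symmetric`: the series at (i, y, z) equals the series at its
#'   first-axis mirror exactly (VMHC = 1 everywhere).
#' * `locally_homogeneous`: the grid is tiled into contiguous blocks; all
#'   voxels of a block share one latent series plus independent noise
#'   (high ReHo / degree centrality / LFCD inside blocks).
#' * `template_mixture`: data = sum_s map_s * timecourse_s + noise with known
#'   spatial maps and timecourses (exact dual-regression recovery at zero
#'   noise). Maps/timecourses are attached as `$planted`.
#' * `white_noise`: i.i.d. Gaussian noise.
#' * `pure_tone`: every voxel is a sinusoid at `planted_freq_hz`, snapped to
#'   the nearest DFT bin so all non-DC spectral energy sits in one bin
#'   (ALFF/fALFF oracles).
#'
#' @param config a [fixture_config()].
#' @param structure one of `"mirror_symmetric"`, `"locally_homogeneous"`,
#'   `"template_mixture"`, `"white_noise"`, `"pure_tone"`.
#' @param block_size edge length of the homogeneous blocks (voxels).
#' @return A [volume4d()]; for structures with latent components, a
#'   `$planted` list describes them.
#' @export
make_rsfmri <- function(config, structure = c("mirror_symmetric", "locally_homogeneous",
                                              "template_mixture", "white_noise", "pure_tone"),
                        block_size = 3L) {
  structure_tag <- match.arg(structure)
  d <- config$grid_shape
  nt <- config$n_timepoints
  nvox <- prod(d)
  vol <- with_seed(derive_seed(config$seed, paste0("rsfmri_", structure_tag)), {
    planted <- NULL
    data <- switch(structure_tag,
      white_noise = array(stats::rnorm(nvox * nt), c(d, nt)),
      mirror_symmetric = {
        a <- array(stats::rnorm(nvox * nt, sd = max(config$noise_sd, 1)), c(d, nt))
        half <- seq_len(ceiling(d[1] / 2))
        for (i in half) a[d[1] + 1L - i, , , ] <- a[i, , , ]
        a
      },
      locally_homogeneous = {
        bx <- split_chunks(d[1], max(1L, d[1] %/% block_size))
        by <- split_chunks(d[2], max(1L, d[2] %/% block_size))
        bz <- split_chunks(d[3], max(1L, d[3] %/% block_size))
        block_id <- array(0L, d)
        id <- 0L
        for (k in seq_along(bz)) for (j in seq_along(by)) for (i in seq_along(bx)) {
          id <- id + 1L
          block_id[bx[[i]], by[[j]], bz[[k]]] <- id
        }
        latents <- matrix(stats::rnorm(id * nt), nt, id)
        a <- array(0, c(d, nt))
        flat <- as.vector(block_id)
        m <- t(latents[, flat, drop = FALSE])  # nvox x nt
        if (config$noise_sd > 0) m <- m + stats::rnorm(length(m), sd = config$noise_sd)
        a[] <- m
        planted <- list(block_id = block_id, latents = latents)
        a
      },
      template_mixture = {
        tpl <- make_templates(config)
        tc <- matrix(stats::rnorm(nt * length(tpl)), nt, length(tpl))
        a <- array(0, c(d, nt))
        m <- matrix(0, nvox, nt)
        for (s in seq_along(tpl)) m <- m + outer(as.vector(tpl[[s]]), tc[, s])
        if (config$noise_sd > 0) m <- m + stats::rnorm(length(m), sd = config$noise_sd)
        a[] <- m
        planted <- list(templates = tpl, timecourses = tc)
        a
      },
      pure_tone = {
        k <- round(config$planted_freq_hz * nt * config$tr_seconds)
        k <- max(1L, min(as.integer(k), nt %/% 2L))
        amp <- stats::runif(nvox, 0.5, 1.5)
        phase <- stats::runif(nvox, 0, 2 * pi)
        tgrid <- seq_len(nt) - 1L
        m <- outer(seq_len(nvox), tgrid, function(v, t) amp[v] * sin(2 * pi * k * t / nt + phase[v]))
        a <- array(0, c(d, nt))
        a[] <- m
        planted <- list(bin = k, freq_hz = k / (nt * config$tr_seconds), amplitude = amp)
        a
      }
    )
    v <- volume4d(data, tr_seconds = config$tr_seconds,
                  mask = array(TRUE, d))
    v$planted <- planted
    v
  })
  vol
}

#' Generate disjoint unit-norm group spatial templates
#'
#' Emulates the group spatial maps a group ICA would supply: `n_templates`
#' nonnegative 3D maps with pairwise disjoint supports (hence exactly
#' orthogonal), each scaled to unit Euclidean norm. The grid is tiled into
#' contiguous boxes, one per template.
#'
#' @param config a [fixture_config()].
#' @return A list of `n_templates` 3D arrays.
#' @export
make_templates <- function(config) {
  d <- config$grid_shape
  s <- config$n_templates
  tiling <- choose_tiling(d, s)
  assert_that(!is.null(tiling), "grid too small for %d disjoint templates", s)
  cx <- split_chunks(d[1], tiling$a)
  cy <- split_chunks(d[2], tiling$b)
  cz <- split_chunks(d[3], tiling$c)
  with_seed(derive_seed(config$seed, "templates"), {
    out <- vector("list", s)
    id <- 0L
    for (k in seq_along(cz)) for (j in seq_along(cy)) for (i in seq_along(cx)) {
      id <- id + 1L
      if (id > s) break
      m <- array(0, d)
      vals <- abs(stats::rnorm(length(cx[[i]]) * length(cy[[j]]) * length(cz[[k]]))) + 0.1
      m[cx[[i]], cy[[j]], cz[[k]]] <- vals
      out[[id]] <- m / sqrt(sum(m^2))
    }
    out
  })
}

#' Generate a labelled synthetic cohort
#'
#' Produces, per subject, an sMRI-like 3D intensity volume parcellated by
#' [make_atlas()] and an rs-fMRI 4D volume, plus a diagnostic label in
#' \{0, 1\}. Class 1 subjects have their per-ROI mean intensity shifted by
#' `effect_size` in `n_affected_rois` designated regions (the structural
#' class signal that drives Fisher ranking and the population graph).
#' Optionally, a functional class signal modulates the amplitude of a planted
#' oscillation inside the affected regions by `1 + functional_effect` for
#' class 1 (detectable by ALFF and the CNN stream).
#'
#' @param config a [fixture_config()].
#' @param n_subjects number of subjects (>= 4).
#' @param class_balance proportion of class-1 subjects in (0, 1).
#' @param n_affected_rois number of designated discriminative regions.
#' @param functional_effect relative amplitude increase of the planted
#'   oscillation in affected regions for class 1 (0 = no functional signal).
#' @return A list of class `cohort` with elements `subjects` (list of
#'   `list(id, smri, fmri, label)`), `labels` (integer vector), `atlas`,
#'   `affected_rois` and `config`.
#' @export
make_cohort <- function(config, n_subjects, class_balance = 0.5,
                        n_affected_rois = 10L, functional_effect = 0) {
  assert_that(n_subjects >= 4, "n_subjects must be >= 4")
  assert_that(class_balance > 0 && class_balance < 1, "class_balance must be in (0,1)")
  atlas <- make_atlas(config)
  n_rois <- length(atlas$region_ids)
  n_affected_rois <- min(n_affected_rois, n_rois)
  affected <- atlas$region_ids[seq_len(n_affected_rois)]
  d <- config$grid_shape
  nt <- config$n_timepoints
  with_seed(derive_seed(config$seed, "cohort"), {
    n_pos <- round(n_subjects * class_balance)
    labels <- as.integer(sample(c(rep(1L, n_pos), rep(0L, n_subjects - n_pos))))
    roi_base <- stats::runif(n_rois, 80, 120)  # cohort-level per-ROI mean intensity
    lab_flat <- as.vector(atlas$data)
    in_roi <- lab_flat > 0L
    roi_index <- match(lab_flat[in_roi], atlas$region_ids)
    affected_mask_flat <- lab_flat %in% affected
    k_bin <- max(1L, min(as.integer(round(config$planted_freq_hz * nt * config$tr_seconds)), nt %/% 2L))
    tone <- sin(2 * pi * k_bin * (seq_len(nt) - 1L) / nt)
    subjects <- vector("list", n_subjects)
    for (s in seq_len(n_subjects)) {
      y <- labels[s]
      # structural volume: cohort ROI means + subject-level ROI variation +
      # voxel noise + class shift in affected regions
      roi_mean_s <- roi_base + stats::rnorm(n_rois, sd = config$noise_sd)
      if (y == 1L) {
        roi_mean_s[match(affected, atlas$region_ids)] <-
          roi_mean_s[match(affected, atlas$region_ids)] + config$effect_size
      }
      sm <- numeric(length(lab_flat))
      sm[in_roi] <- roi_mean_s[roi_index]
      sm <- sm + stats::rnorm(length(sm), sd = max(config$noise_sd, 1e-3))
      smri <- array(sm, d)
      # functional volume: white noise + planted oscillation in affected
      # regions whose amplitude carries the (optional) functional class signal
      fm <- matrix(stats::rnorm(prod(d) * nt, sd = max(config$noise_sd, 1e-3)), prod(d), nt)
      amp <- 1 + functional_effect * y
      fm[affected_mask_flat, ] <- fm[affected_mask_flat, , drop = FALSE] +
        matrix(tone * amp, nrow = sum(affected_mask_flat), ncol = nt, byrow = TRUE)
      fd <- array(0, c(d, nt))
      fd[] <- fm
      fmri <- volume4d(fd, tr_seconds = config$tr_seconds, mask = array(TRUE, d))
      subjects[[s]] <- list(id = sprintf("sub-%03d", s), smri = smri,
                            fmri = fmri, label = y)
    }
    structure(list(subjects = subjects, labels = labels, atlas = atlas,
                   affected_rois = affected, config = config),
              class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects (%d class 1 / %d class 0), %d-region atlas\n",
              length(x$subjects), sum(x$labels == 1), sum(x$labels == 0),
              length(x$atlas$region_ids)))
  invisible(x)
}

#' Write a cohort to disk as NIfTI volumes and a subject table
#'
#' Writes one sMRI and one fMRI NIfTI per subject, the atlas labelmap, a
#' tab-separated subject table (subject_id, label, split) and a key-value
#' manifest recording the generator parameters.
#'
#' @param cohort a [make_cohort()] result.
#' @param dir output directory (created if needed).
#' @param split optional character vector of split assignments per subject
#'   (e.g. "train"/"test"); defaults to "unassigned".
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, split = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(cohort$subjects)
  if (is.null(split)) split <- rep("unassigned", n)
  write_volume(cohort$atlas, file.path(dir, "atlas.nii.gz"))
  ids <- vapply(cohort$subjects, `[[`, "", "id")
  for (s in seq_len(n)) {
    write_volume(array(cohort$subjects[[s]]$smri, dim(cohort$subjects[[s]]$smri)),
                 file.path(dir, paste0(ids[s], "_smri.nii.gz")))
    write_volume(cohort$subjects[[s]]$fmri, file.path(dir, paste0(ids[s], "_fmri.nii.gz")))
  }
  tab <- data.frame(subject_id = ids, label = cohort$labels, split = split)
  utils::write.table(tab, file.path(dir, "subjects.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- cohort$config
  manifest <- c(
    sprintf("grid_shape=%s", paste(cfg$grid_shape, collapse = "x")),
    sprintf("n_timepoints=%d", cfg$n_timepoints),
    sprintf("tr_seconds=%g", cfg$tr_seconds),
    sprintf("n_regions_per_hemisphere=%d", cfg$n_regions_per_hemisphere),
    sprintf("n_templates=%d", cfg$n_templates),
    sprintf("seed=%d", cfg$seed),
    sprintf("noise_sd=%g", cfg$noise_sd),
    sprintf("planted_freq_hz=%g", cfg$planted_freq_hz),
    sprintf("effect_size=%g", cfg$effect_size)
  )
  writeLines(manifest, file.path(dir, "manifest.cfg"))
  invisible(dir)
}
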