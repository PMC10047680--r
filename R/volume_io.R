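#' Construct a 4D functional volume
#'
#' A `volume4d` is the package's container for a resting-state fMRI run: a 4D
#' numeric array indexed (x, y, z, t), the repetition time in seconds, and an
#' optional 3D logical brain mask. 3D arrays are promoted to a single
#' timepoint. The first array axis is the left-right axis used for mirroring.
#'
#' @param data numeric 3D or 4D array.
#' @param tr_seconds repetition time in seconds (positive).
#' @param mask optional logical 3D array matching the spatial grid. When
#'   absent, operations default to voxels with nonzero temporal variance.
#' @return An object of class `volume4d`.
#' @export
volume4d <- function(data, tr_seconds = 2, mask = NULL) {
  assert_that(is.array(data) && length(dim(data)) %in% c(3L, 4L),
              "data must be a 3D or 4D array, got %s dims", length(dim(data)))
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  assert_that(is.numeric(tr_seconds) && length(tr_seconds) == 1 && tr_seconds > 0,
              "tr_seconds must be a single positive number")
  n_bad <- sum(!is.finite(data))
  assert_that(n_bad == 0, "volume contains %d non-finite voxel values", n_bad)
  if (!is.null(mask)) {
    assert_that(is.logical(mask) && length(dim(mask)) == 3L &&
                all(dim(mask) == dim(data)[1:3]),
                "mask must be a logical 3D array matching the spatial grid")
  }
  structure(list(data = data, tr_seconds = tr_seconds, mask = mask),
            class = "volume4d")
}

#' @export
print.volume4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume4d> %d x %d x %d voxels, %d timepoints, TR %.3g s\n",
              d[1], d[2], d[3], d[4], x$tr_seconds))
  invisible(x)
}

#' @export
dim.volume4d <- function(x) dim(x$data)

# Mask to use for a volume: explicit mask, else nonzero temporal variance
# (all-TRUE for single-timepoint volumes with any nonzero voxel variance
# undefined -> treat every finite voxel as in-mask).
volume_mask <- function(vol) {
  if (!is.null(vol$mask)) return(vol$mask)
  d <- dim(vol$data)
  if (d[4] < 2L) {
    return(array(TRUE, d[1:3]))
  }
  m2 <- matrix(vol$data, prod(d[1:3]), d[4])
  v <- rowSums((m2 - rowMeans(m2))^2)
  array(v > 0, d[1:3])
}

#' Construct an ROI labelmap
#'
#' A `labelmap` assigns each voxel a nonnegative integer region id; 0 is
#' background. `region_ids` is always the sorted set of distinct nonzero
#' labels actually present.
#'
#' @param data integer-valued 3D array with nonnegative entries.
#' @return An object of class `labelmap` with fields `data` and `region_ids`.
#' @export
labelmap <- function(data) {
  assert_that(is.array(data) && length(dim(data)) == 3L,
              "labelmap data must be a 3D array")
  assert_that(all(data >= 0) && all(data == round(data)),
              "labelmap values must be nonnegative integers")
  storage.mode(data) <- "integer"
  ids <- sort(unique(data[data > 0L]))
  structure(list(data = data, region_ids = as.integer(ids)), class = "labelmap")
}

#' @export
print.labelmap <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<labelmap> %d x %d x %d voxels, %d regions\n",
              d[1], d[2], d[3], length(x$region_ids)))
  invisible(x)
}

#' Stack 3D maps (or stacks) on the channel axis
#'
#' Implements the pipeline's channel convention: summary derivatives are 3D
#' maps which are concatenated along a fourth (channel) axis, in argument
#' order, to form a `summary_stack`. Stacking the ten dual-regression maps
#' with an ALFF map yields an 11-channel stack; the full derivative set (9
#' voxelwise maps + 10 dual-regression maps) yields 19 channels.
#'
#' @param volumes list of 3D arrays and/or `summary_stack` objects sharing one
#'   spatial grid.
#' @param names character vector of channel names, one per resulting channel.
#'   May be omitted when every element of `volumes` is a named
#'   `summary_stack`/3D map.
#' @return A `summary_stack`: list with 4D `data` (x, y, z, channel) and
#'   `channel_names`.
#' @export
stack_channels <- function(volumes, names = NULL) {
  assert_that(is.list(volumes) && length(volumes) >= 1, "volumes must be a nonempty list")
  pieces <- list()
  cnames <- character()
  for (i in seq_along(volumes)) {
    v <- volumes[[i]]
    if (inherits(v, "summary_stack")) {
      pieces[[length(pieces) + 1L]] <- v$data
      cnames <- c(cnames, v$channel_names)
    } else if (is.array(v) && length(dim(v)) == 3L) {
      a <- v
      dim(a) <- c(dim(v), 1L)
      pieces[[length(pieces) + 1L]] <- a
      nm <- base::names(volumes)[i]
      cnames <- c(cnames, if (!is.null(nm) && nzchar(nm)) nm else sprintf("channel_%d", i))
    } else if (is.array(v) && length(dim(v)) == 4L) {
      pieces[[length(pieces) + 1L]] <- v
      cnames <- c(cnames, sprintf("channel_%d_%d", i, seq_len(dim(v)[4])))
    } else {
      stop_arg("element %d of volumes is not a 3D map or summary_stack", i)
    }
  }
  grids <- vapply(pieces, function(p) paste(dim(p)[1:3], collapse = "x"), "")
  assert_that(length(unique(grids)) == 1,
              "all volumes must share one spatial grid, got: %s",
              paste(unique(grids), collapse = ", "))
  data <- array(0, c(dim(pieces[[1]])[1:3], sum(vapply(pieces, function(p) dim(p)[4], 0))))
  at <- 0L
  for (p in pieces) {
    k <- dim(p)[4]
    data[, , , at + seq_len(k)] <- p
    at <- at + k
  }
  if (!is.null(names)) {
    assert_that(length(names) == dim(data)[4],
                "names has length %d but the stack has %d channels",
                length(names), dim(data)[4])
    cnames <- names
  }
  summary_stack(data, cnames)
}

#' Construct a summary stack
#'
#' @param data 4D numeric array (x, y, z, channel).
#' @param channel_names character vector, one name per channel.
#' @return An object of class `summary_stack`.
#' @export
summary_stack <- function(data, channel_names) {
  assert_that(is.array(data) && length(dim(data)) == 4L, "data must be a 4D array")
  assert_that(length(channel_names) == dim(data)[4],
              "channel count %d does not match channel_names length %d",
              dim(data)[4], length(channel_names))
  structure(list(data = data, channel_names = as.character(channel_names)),
            class = "summary_stack")
}

#' @export
print.summary_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<summary_stack> %d x %d x %d voxels, %d channels\n", d[1], d[2], d[3], d[4]))
  cat(" channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' Read a NIfTI volume
#'
#' Reads a NIfTI-1 file into a [volume4d()]. 3D images are promoted to 4D
#' with one timepoint. The repetition time is taken from the header's fourth
#' pixdim unless overridden.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param tr_seconds optional TR override (seconds).
#' @return A `volume4d`.
#' @export
read_volume <- function(path, tr_seconds = NULL) {
  assert_that(file.exists(path), "file not found: %s", path)
  img <- RNifti::readNifti(path)
  data <- array(as.numeric(img), dim(img))  # plain array, no NIfTI attributes
  nd <- length(dim(data))
  assert_that(nd %in% c(3L, 4L), "expected a 3D or 4D NIfTI, got %d dims", nd)
  if (is.null(tr_seconds)) {
    pd <- RNifti::pixdim(img)
    tr_seconds <- if (length(pd) >= 4 && is.finite(pd[4]) && pd[4] > 0) pd[4] else 1
  }
  n_bad <- sum(!is.finite(data))
  assert_that(n_bad == 0, "volume %s contains %d non-finite voxel values", path, n_bad)
  volume4d(data, tr_seconds = tr_seconds)
}

#' Write a volume, labelmap or stack to NIfTI
#'
#' @param x a `volume4d`, `labelmap`, `summary_stack` or plain 3D/4D array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly. For a `summary_stack` a sidecar text file
#'   `<path>.channels.txt` records the channel names, one per line.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "volume4d")) {
    img <- RNifti::asNifti(x$data)
    pd <- RNifti::pixdim(img)
    pd[4] <- x$tr_seconds
    RNifti::pixdim(img) <- pd
    RNifti::writeNifti(img, path)
  } else if (inherits(x, "labelmap")) {
    RNifti::writeNifti(RNifti::asNifti(x$data), path, datatype = "int32")
  } else if (inherits(x, "summary_stack")) {
    RNifti::writeNifti(RNifti::asNifti(x$data), path)
    writeLines(x$channel_names, paste0(path, ".channels.txt"))
  } else if (is.array(x)) {
    RNifti::writeNifti(RNifti::asNifti(x), path)
  } else {
    stop_arg("cannot write object of class %s", paste(class(x), collapse = "/"))
  }
  invisible(path)
}
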