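# Probe depth and volume per homolog from 3D z-stacks.
#
# Depth = number of optical sections containing segmented probe signal times
# the axial step (e.g. 10 of 17 sections at 0.13 um steps = 1.30 um).
# Volume = voxel count times pixel_size_xy^2 * z_step. Segmentation is a
# global threshold (Otsu by default) followed by the 26-connected component
# containing a seed voxel.

#' Z-stack acquisition geometry
#'
#' @param n_sections Number of optical sections.
#' @param z_step Axial step, micrometres (0.13 by default).
#' @param pixel_size_xy Lateral pixel size, micrometres.
#' @return An object of class `"zstack_geometry"`.
#' @export
zstack_geometry <- function(n_sections = 17L, z_step = 0.13,
                            pixel_size_xy = 0.04) {
  stopifnot(is_count(n_sections, 1), is_number(z_step), z_step > 0,
            is_number(pixel_size_xy), pixel_size_xy > 0)
  structure(list(n_sections = as.integer(n_sections), z_step = z_step,
                 pixel_size_xy = pixel_size_xy),
            class = "zstack_geometry")
}

# 26-connected flood fill from a seed voxel, vectorized frontier BFS.
#' @noRd
flood_fill_26 <- function(above, seed) {
  dims <- dim(above)
  offsets <- as.matrix(expand.grid(ds = -1:1, dr = -1:1, dc = -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, , drop = FALSE]
  visited <- array(FALSE, dims)
  visited[seed[1], seed[2], seed[3]] <- TRUE
  frontier <- matrix(seed, 1, 3)
  while (nrow(frontier) > 0) {
    nb <- frontier[rep(seq_len(nrow(frontier)), each = nrow(offsets)), ,
                   drop = FALSE] +
      offsets[rep(seq_len(nrow(offsets)), times = nrow(frontier)), ,
              drop = FALSE]
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
      nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    nb <- unique(nb[ok, , drop = FALSE])
    keep <- above[nb] & !visited[nb]
    nb <- nb[keep, , drop = FALSE]
    visited[nb] <- TRUE
    frontier <- nb
  }
  visited
}

#' Segment the probe signal in a z-stack
#'
#' Thresholds the whole stack (Otsu on the intensity histogram, or
#' background + `background_k * sqrt(background)` with the background taken
#' as the stack median) and keeps the 26-connected component containing the
#' seed voxel.
#'
#' @param zstack 3D array `[section, row, col]`.
#' @param seed_point `(section, row, col)` voxel inside the target spot.
#' @param threshold_method `"otsu"` or `"background"`.
#' @param background_k Multiplier for the background method.
#' @return Logical 3D mask of the same shape.
#' @export
segment_probe_3d <- function(zstack, seed_point,
                             threshold_method = c("otsu", "background"),
                             background_k = 3) {
  threshold_method <- match.arg(threshold_method)
  stopifnot(length(dim(zstack)) == 3L, length(seed_point) == 3L)
  seed <- as.integer(round(seed_point))
  dims <- dim(zstack)
  if (any(seed < 1L) || any(seed > dims)) {
    fishda_stop("seed point outside the stack", "fishda_error_seed")
  }
  rng <- range(zstack)
  if (rng[2] <= rng[1]) {
    fishda_stop("constant stack: nothing to segment", "fishda_error_no_signal")
  }
  thr <- switch(threshold_method,
    otsu = {
      norm <- (zstack - rng[1]) / (rng[2] - rng[1])
      t01 <- EBImage::otsu(matrix(norm, nrow = dims[1] * dims[2]),
                           range = c(0, 1))
      rng[1] + t01 * (rng[2] - rng[1])
    },
    background = {
      bg <- stats::median(zstack)
      bg + background_k * sqrt(max(bg, 0))
    }
  )
  above <- zstack > thr
  if (mean(above) > 0.25) {
    fishda_stop("threshold does not separate a foreground: no distinct probe signal in the stack",
                "fishda_error_no_signal")
  }
  if (!above[seed[1], seed[2], seed[3]]) {
    fishda_stop("seed voxel below threshold: no signal at seed",
                "fishda_error_seed")
  }
  flood_fill_26(above, seed)
}

#' Probe depth from a voxel mask
#'
#' Number of distinct sections containing at least one mask voxel, times the
#' axial step. With `contiguous = TRUE` only the longest contiguous run of
#' such sections is counted.
#'
#' @param mask Logical 3D array `[section, row, col]`.
#' @param geometry [zstack_geometry()].
#' @param contiguous Count only the longest contiguous section run.
#' @return List with `n_sections_with_signal` and `depth` (micrometres).
#' @export
probe_depth <- function(mask, geometry, contiguous = FALSE) {
  stopifnot(length(dim(mask)) == 3L, inherits(geometry, "zstack_geometry"))
  has <- apply(mask, 1, any)
  if (!any(has)) {
    fishda_stop("empty mask: no probe signal", "fishda_error_empty_mask")
  }
  n <- if (contiguous) {
    runs <- rle(has)
    max(runs$lengths[runs$values])
  } else {
    sum(has)
  }
  list(n_sections_with_signal = as.integer(n), depth = n * geometry$z_step)
}

#' Probe volume from a voxel mask
#'
#' `volume = n_voxels * pixel_size_xy^2 * z_step`, exactly.
#'
#' @param mask Logical 3D array.
#' @param geometry [zstack_geometry()].
#' @return List with `n_voxels` and `volume` (cubic micrometres).
#' @export
probe_volume <- function(mask, geometry) {
  stopifnot(length(dim(mask)) == 3L, inherits(geometry, "zstack_geometry"))
  n <- sum(mask)
  if (n == 0) {
    fishda_stop("empty mask: no probe signal", "fishda_error_empty_mask")
  }
  list(n_voxels = as.integer(n),
       volume = n * geometry$pixel_size_xy^2 * geometry$z_step)
}

#' Measure one homolog's probe depth and volume
#'
#' @param zstack 3D array.
#' @param seed_point `(section, row, col)` inside the spot.
#' @param geometry [zstack_geometry()].
#' @param homolog Label (`"A"` or `"B"`).
#' @param ... Passed to [segment_probe_3d()].
#' @return One-row data.frame: homolog, n_sections_with_signal, depth,
#'   n_voxels, volume.
#' @export
measure_probe_3d <- function(zstack, seed_point, geometry,
                             homolog = NA_character_, ...) {
  mask <- segment_probe_3d(zstack, seed_point, ...)
  d <- probe_depth(mask, geometry)
  v <- probe_volume(mask, geometry)
  data.frame(homolog = homolog,
             n_sections_with_signal = d$n_sections_with_signal,
             depth = d$depth, n_voxels = v$n_voxels, volume = v$volume,
             stringsAsFactors = FALSE)
}

#' Raw and normalized inter-homolog depth/volume differences
#'
#' Normalized differences use the same `|x_A - x_B| / (x_A + x_B)` form as
#' the intensity statistic.
#'
#' @param meas_A,meas_B One-row data.frames from [measure_probe_3d()].
#' @return List with raw_depth_difference, raw_volume_difference,
#'   normalized_depth_difference, normalized_volume_difference.
#' @export
compare_homolog_volumetrics <- function(meas_A, meas_B) {
  nd <- function(a, b) if (a + b > 0) abs(a - b) / (a + b) else 0
  list(
    raw_depth_difference = abs(meas_A$depth - meas_B$depth),
    raw_volume_difference = abs(meas_A$volume - meas_B$volume),
    normalized_depth_difference = nd(meas_A$depth, meas_B$depth),
    normalized_volume_difference = nd(meas_A$volume, meas_B$volume)
  )
}
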