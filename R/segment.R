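# Per-cell segmentation: locate the two homolog spots, run the GVF snake in
# a local window around each, and return image-frame contours.

#' Segmentation configuration
#'
#' Defaults assume Gaussian-like spots of lateral sigma `spot_sigma`. The
#' smoothing sigma defaults to `2.25 * spot_sigma`: for a Gaussian spot the
#' gradient ridge of the smoothed image lies at radius
#' `sqrt(spot_sigma^2 + smoothing_sigma^2)`, and this choice places it at
#' the radius enclosing ~95% of the spot's mass (`2.448 * spot_sigma`), so
#' the converged contour approximates the spot's photometric support.
#'
#' @param spot_sigma Expected lateral spot sigma, pixels.
#' @param smoothing_sigma Edge-map smoothing sigma, pixels.
#' @param binarize_fraction Edge-map binarization fraction (0 = gray-scale).
#' @param gvf_mu,gvf_max_iterations,gvf_tolerance,gvf_gamma GVF settings.
#' @param snake [snake_params()].
#' @param init_radius_factor Initial contour radius in units of `spot_sigma`.
#' @param n_vertices Snake vertex count.
#' @param peak_smoothing_sigma,peak_min_distance Peak-detection settings.
#' @param window_halfwidth Half-width of the per-spot analysis window,
#'   pixels; `NULL` derives it from the smoothing sigma.
#' @param annulus_width,dilate_radius Background annulus geometry.
#' @return An object of class `"seg_config"`.
#' @export
seg_config <- function(spot_sigma = 2,
                       smoothing_sigma = 2.25 * spot_sigma,
                       binarize_fraction = 0,
                       gvf_mu = 0.1, gvf_max_iterations = 500,
                       gvf_tolerance = 1e-4, gvf_gamma = 1,
                       snake = snake_params(),
                       init_radius_factor = 3, n_vertices = 64L,
                       peak_smoothing_sigma = 2, peak_min_distance = 10,
                       window_halfwidth = NULL,
                       annulus_width = 4, dilate_radius = 2) {
  if (is.null(window_halfwidth)) {
    sigma_e <- sqrt(spot_sigma^2 + smoothing_sigma^2)
    window_halfwidth <- ceiling(2.5 * sigma_e + 5)
  }
  structure(list(
    spot_sigma = spot_sigma, smoothing_sigma = smoothing_sigma,
    binarize_fraction = binarize_fraction,
    gvf_mu = gvf_mu, gvf_max_iterations = gvf_max_iterations,
    gvf_tolerance = gvf_tolerance, gvf_gamma = gvf_gamma,
    snake = snake, init_radius_factor = init_radius_factor,
    n_vertices = as.integer(n_vertices),
    peak_smoothing_sigma = peak_smoothing_sigma,
    peak_min_distance = peak_min_distance,
    window_halfwidth = as.integer(window_halfwidth),
    annulus_width = annulus_width, dilate_radius = dilate_radius
  ), class = "seg_config")
}

#' Segment one probe spot around a known center
#'
#' Crops a window around `center`, computes the edge map and GVF field
#' there, evolves a circular snake of radius
#' `init_radius_factor * spot_sigma`, and returns the contour in image
#' coordinates.
#'
#' @param probe_image Numeric matrix.
#' @param center `(row, col)` spot center (e.g. from [detect_probe_peaks()]).
#' @param config [seg_config()].
#' @return A [contour] in the full-image frame.
#' @export
segment_spot <- function(probe_image, center, config = seg_config()) {
  stopifnot(inherits(config, "seg_config"))
  h <- nrow(probe_image); w <- ncol(probe_image)
  hw <- config$window_halfwidth
  r0 <- max(1L, as.integer(round(center[1])) - hw)
  r1 <- min(h, as.integer(round(center[1])) + hw)
  c0 <- max(1L, as.integer(round(center[2])) - hw)
  c1 <- min(w, as.integer(round(center[2])) + hw)
  win <- probe_image[r0:r1, c0:c1, drop = FALSE]
  em <- compute_edge_map(win, config$smoothing_sigma, config$binarize_fraction)
  gvf <- compute_gvf(em, mu = config$gvf_mu,
                     max_iterations = config$gvf_max_iterations,
                     tolerance = config$gvf_tolerance, gamma = config$gvf_gamma)
  init <- initialize_contour(
    c(center[1] - r0 + 1, center[2] - c0 + 1),
    radius = config$init_radius_factor * config$spot_sigma,
    n_vertices = config$n_vertices
  )
  out <- evolve_snake(init, gvf, config$snake)
  contour(cbind(out$vertices[, 1] + r0 - 1, out$vertices[, 2] + c0 - 1),
          converged = out$converged)
}

#' Segment and measure one two-spot cell
#'
#' Full per-cell path: detect the two homolog peaks (labelled A/B in
#' lexicographic (row, col) order), segment each with the GVF snake, and
#' compute the background-corrected measurement.
#'
#' @param probe_image Numeric matrix (probe channel).
#' @param config [seg_config()].
#' @param cell_id,locus_id Identifiers for the measurement row.
#' @return List with `measurement` (one-row data.frame), `contours`
#'   (list of two [contour]s) and `peaks`.
#' @export
segment_and_measure_cell <- function(probe_image, config = seg_config(),
                                     cell_id = NA_character_,
                                     locus_id = NA_character_) {
  peaks <- detect_probe_peaks(probe_image, expected_count = 2L,
                              smoothing_sigma = config$peak_smoothing_sigma,
                              min_distance = config$peak_min_distance)
  contour_a <- segment_spot(probe_image, peaks[1, ], config)
  contour_b <- segment_spot(probe_image, peaks[2, ], config)
  meas <- measure_cell(probe_image, contour_a, contour_b,
                       annulus_width = config$annulus_width,
                       dilate_radius = config$dilate_radius,
                       cell_id = cell_id, locus_id = locus_id)
  list(measurement = meas, contours = list(A = contour_a, B = contour_b),
       peaks = peaks)
}
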