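# Background-corrected integrated probe intensities and the normalized
# inter-homolog difference statistic.
#
# The statistic is |I_A - I_B| / (I_A + I_B) on background-corrected
# integrated intensities: 0 means equal accessibility of the probe to both
# homologs, 1 means signal absent on one homolog. Background is estimated
# per spot from a local annulus (robust to uneven counterstain
# bleed-through), and negative background-corrected pixels are clipped at
# zero before summation so noise cannot drive the integral negative.

#' @noRd
dilate_mask <- function(mask, radius) {
  if (radius <= 0) return(mask)
  brush <- EBImage::makeBrush(2L * as.integer(ceiling(radius)) + 1L,
                              shape = "disc")
  EBImage::dilate(mask * 1, brush) > 0.5
}

#' Estimate local background around a contour
#'
#' Median pixel value in an annulus of width `annulus_width` outside the
#' contour dilated by `dilate_radius`. Pixels falling inside the (dilated)
#' partner contour are excluded; a fully excluded annulus is an error.
#'
#' @param image Numeric matrix.
#' @param contour The spot's [contour].
#' @param annulus_width Annulus width, pixels.
#' @param dilate_radius Gap between contour and annulus, pixels.
#' @param exclude Optional [contour] (or list of contours) whose dilated
#'   interiors are removed from the annulus (the partner spot).
#' @return Scalar background level (photons/pixel).
#' @export
estimate_background <- function(image, contour, annulus_width = 4,
                                dilate_radius = 2, exclude = NULL) {
  stopifnot(is.matrix(image), inherits(contour, "contour"),
            is_number(annulus_width), annulus_width >= 1)
  h <- nrow(image); w <- ncol(image)
  inner <- dilate_mask(polygon_mask(contour, h, w), dilate_radius)
  outer_m <- dilate_mask(inner, annulus_width)
  annulus <- outer_m & !inner
  if (!is.null(exclude)) {
    if (inherits(exclude, "contour")) exclude <- list(exclude)
    for (ex in exclude) {
      annulus <- annulus & !dilate_mask(polygon_mask(ex, h, w), dilate_radius)
    }
  }
  if (!any(annulus)) {
    fishda_stop("background annulus fully excluded: no pixels to estimate from",
                "fishda_error_background")
  }
  stats::median(image[annulus])
}

#' Integrated intensity inside a contour
#'
#' Sum of `pmax(value - background, 0)` over pixels whose centers fall
#' inside the contour.
#'
#' @param image Numeric matrix.
#' @param contour A simple, closed [contour].
#' @param background Scalar background level to subtract.
#' @return Integrated background-corrected intensity (photons).
#' @export
integrated_intensity <- function(image, contour, background = 0) {
  stopifnot(is.matrix(image), inherits(contour, "contour"),
            is_number(background))
  if (!polygon_is_simple(contour$vertices)) {
    fishda_stop("contour is not simple", "fishda_error_contour")
  }
  mask <- polygon_mask(contour, nrow(image), ncol(image))
  if (!any(mask)) {
    fishda_stop("contour encloses no pixel centers", "fishda_error_contour")
  }
  sum(pmax(image[mask] - background, 0))
}

#' Normalized inter-homolog intensity difference
#'
#' `|I_A - I_B| / (I_A + I_B)`, in `[0, 1]`. Both intensities zero is an
#' error (failed hybridization; the cell is excluded upstream).
#'
#' @param intensity_A,intensity_B Non-negative integrated intensities.
#' @return Dimensionless difference in `[0, 1]`.
#' @export
normalized_difference <- function(intensity_A, intensity_B) {
  stopifnot(is_number(intensity_A), is_number(intensity_B),
            intensity_A >= 0, intensity_B >= 0)
  total <- intensity_A + intensity_B
  if (total <= 0) {
    fishda_stop("both integrated intensities are zero: failed hybridization",
                "fishda_error_no_signal")
  }
  abs(intensity_A - intensity_B) / total
}

#' Measure one cell: intensities, normalized difference, weaker homolog
#'
#' @param probe_image Numeric matrix (probe channel, photons).
#' @param contour_A,contour_B Disjoint homolog contours (A, B).
#' @param annulus_width,dilate_radius Background annulus geometry, pixels.
#' @param cell_id,locus_id Identifiers carried into the result row.
#' @return One-row data.frame: cell_id, locus_id, intensity_A, intensity_B,
#'   normalized_difference, weaker_homolog.
#' @export
measure_cell <- function(probe_image, contour_A, contour_B,
                         annulus_width = 4, dilate_radius = 2,
                         cell_id = NA_character_, locus_id = NA_character_) {
  bg_a <- estimate_background(probe_image, contour_A, annulus_width,
                              dilate_radius, exclude = contour_B)
  bg_b <- estimate_background(probe_image, contour_B, annulus_width,
                              dilate_radius, exclude = contour_A)
  i_a <- integrated_intensity(probe_image, contour_A, bg_a)
  i_b <- integrated_intensity(probe_image, contour_B, bg_b)
  d <- normalized_difference(i_a, i_b)
  weaker <- if (d < 1e-12) "none" else if (i_a < i_b) "A" else "B"
  data.frame(
    cell_id = cell_id, locus_id = locus_id,
    intensity_A = i_a, intensity_B = i_b,
    normalized_difference = d, weaker_homolog = weaker,
    stringsAsFactors = FALSE
  )
}
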