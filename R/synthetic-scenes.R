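# Synthetic FISH scene generator.
#
# Renders paired homolog probe spots as Gaussian intensity profiles on a
# constant background, in 2D (epifluorescence-like, probe + counterstain
# channel) or as a 3D z-stack (SIM-like reconstructed optical sections).
# Every render returns a ground-truth record of the noise-free integrated
# spot intensities, the true normalized inter-homolog difference and, in 3D,
# the true axial section span and voxel count, so downstream segmentation
# and quantification can be scored against known truth.

#' Specify a synthetic two-spot FISH scene
#'
#' @param image_height,image_width Frame size in pixels.
#' @param pixel_size_xy Lateral pixel size, micrometres per pixel.
#' @param n_sections Number of optical sections for 3D rendering.
#' @param z_step Axial step between sections, micrometres.
#' @param background_level Constant background, photons per pixel.
#' @param spot_sigma_xy Lateral Gaussian sigma of each probe spot, pixels.
#' @param spot_sigma_z Axial Gaussian sigma, in sections (3D only).
#' @param amplitude_bright,amplitude_dim Peak amplitudes (photons) of the
#'   spots at positions 1 (homolog A) and 2 (homolog B) respectively. The
#'   names reflect the default DA configuration; [generate_cohort()] may
#'   place the dimmer amplitude on either homolog. Equal amplitudes model a
#'   locus with equal accessibility on both homologs.
#' @param spot_positions List of two numeric centers, `(row, col)` for 2D or
#'   `(section, row, col)` for 3D, in 1-based pixel/section coordinates.
#'   Position 1 is homolog A, position 2 homolog B.
#' @param noise_model `"none"`, `"poisson"`, or `"poisson_gaussian"`.
#' @param read_sigma Read-noise standard deviation (photons) added after the
#'   Poisson draw when `noise_model = "poisson_gaussian"`.
#' @param seed Integer seed; identical spec + seed gives bit-identical scenes.
#' @return An object of class `"scene_spec"`.
#' @export
scene_spec <- function(image_height = 64L, image_width = 64L,
                       pixel_size_xy = 0.1, n_sections = 17L, z_step = 0.13,
                       background_level = 10, spot_sigma_xy = 2,
                       spot_sigma_z = 1.5,
                       amplitude_bright = 200, amplitude_dim = 200,
                       spot_positions = list(c(32, 20), c(32, 44)),
                       noise_model = c("poisson", "none", "poisson_gaussian"),
                       read_sigma = 2, seed = NULL) {
  noise_model <- match.arg(noise_model)
  stopifnot(is_count(image_height, 1), is_count(image_width, 1),
            is_count(n_sections, 1), is_number(z_step), z_step > 0,
            is_number(pixel_size_xy), pixel_size_xy > 0,
            is_number(background_level), background_level >= 0,
            is_number(spot_sigma_xy), spot_sigma_xy > 0,
            is_number(spot_sigma_z), spot_sigma_z > 0,
            is_number(amplitude_bright), amplitude_bright >= 0,
            is_number(amplitude_dim), amplitude_dim >= 0,
            is.list(spot_positions), length(spot_positions) == 2L)
  for (p in spot_positions) {
    rc <- if (length(p) == 3L) p[2:3] else p
    if (length(p) < 2L || length(p) > 3L) {
      fishda_stop("spot positions must be (row, col) or (section, row, col)",
                  "fishda_error_scene")
    }
    if (rc[1] < 1 || rc[1] > image_height || rc[2] < 1 || rc[2] > image_width) {
      fishda_stop("spot center outside image bounds", "fishda_error_scene")
    }
    if (length(p) == 3L && (p[1] < 1 || p[1] > n_sections)) {
      fishda_stop("spot center outside stack bounds", "fishda_error_scene")
    }
  }
  structure(list(
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    pixel_size_xy = pixel_size_xy,
    n_sections = as.integer(n_sections), z_step = z_step,
    background_level = background_level,
    spot_sigma_xy = spot_sigma_xy, spot_sigma_z = spot_sigma_z,
    amplitude_bright = amplitude_bright, amplitude_dim = amplitude_dim,
    spot_positions = spot_positions,
    noise_model = noise_model, read_sigma = read_sigma,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "scene_spec")
}

#' @noRd
ground_truth <- function(i_a, i_b, span_a = NA_integer_, span_b = NA_integer_,
                         vox_a = NA_integer_, vox_b = NA_integer_) {
  total <- i_a + i_b
  d <- if (total > 0) abs(i_a - i_b) / total else NA_real_
  weaker <- if (!is.finite(d) || d < 1e-12) {
    "none"
  } else if (i_a < i_b) "A" else "B"
  structure(list(
    true_integrated_intensity_A = i_a,
    true_integrated_intensity_B = i_b,
    true_normalized_difference = d,
    weaker_homolog = weaker,
    true_section_span_A = span_a, true_section_span_B = span_b,
    true_voxel_count_A = vox_a, true_voxel_count_B = vox_b
  ), class = "ground_truth")
}

# Noise-free 2D Gaussian spot evaluated at pixel centers.
#' @noRd
gaussian_spot_2d <- function(nrow, ncol, center, amplitude, sigma) {
  dr2 <- (seq_len(nrow) - center[1])^2
  dc2 <- (seq_len(ncol) - center[2])^2
  amplitude * outer(exp(-dr2 / (2 * sigma^2)), exp(-dc2 / (2 * sigma^2)))
}

#' @noRd
apply_noise <- function(signal, spec) {
  switch(spec$noise_model,
    none = signal,
    poisson = {
      out <- stats::rpois(length(signal), lambda = as.vector(signal))
      array(as.numeric(out), dim = dim(signal))
    },
    poisson_gaussian = {
      out <- stats::rpois(length(signal), lambda = as.vector(signal)) +
        stats::rnorm(length(signal), sd = spec$read_sigma)
      array(pmax(out, 0), dim = dim(signal))
    }
  )
}

#' @noRd
check_spot_separation <- function(spec) {
  p1 <- spec$spot_positions[[1]]; p2 <- spec$spot_positions[[2]]
  rc1 <- if (length(p1) == 3L) p1[2:3] else p1
  rc2 <- if (length(p2) == 3L) p2[2:3] else p2
  if (sqrt(sum((rc1 - rc2)^2)) < 6 * spec$spot_sigma_xy) {
    fishda_stop(
      "spot centers closer than 6 sigma: overlapping signals are unusable for paired quantification",
      "fishda_error_overlap")
  }
}

#' Render a 2D two-channel metaphase scene
#'
#' The probe channel carries the two homolog spots as isotropic Gaussians of
#' the specified sigma and amplitudes over a constant background; the
#' counterstain channel holds a pair of filled ellipses standing in for the
#' chromosomes (not quantified). Ground truth records the noise-free
#' integrated (pixel-summed) spot intensities.
#'
#' @param spec A [scene_spec()].
#' @return List with `probe_image`, `counterstain_image` (matrices, photons)
#'   and `truth` (a ground-truth record).
#' @export
render_scene_2d <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  check_spot_separation(spec)
  h <- spec$image_height; w <- spec$image_width
  pos <- lapply(spec$spot_positions, function(p) if (length(p) == 3L) p[2:3] else p)
  spot_a <- gaussian_spot_2d(h, w, pos[[1]], spec$amplitude_bright, spec$spot_sigma_xy)
  spot_b <- gaussian_spot_2d(h, w, pos[[2]], spec$amplitude_dim, spec$spot_sigma_xy)
  clean <- spec$background_level + spot_a + spot_b
  probe <- with_seed(spec$seed, apply_noise(clean, spec))

  counterstain <- matrix(spec$background_level, h, w)
  for (p in pos) {
    rr <- outer((seq_len(h) - p[1])^2 / (6 * spec$spot_sigma_xy)^2,
                (seq_len(w) - p[2])^2 / (2.5 * spec$spot_sigma_xy)^2, "+")
    counterstain[rr <= 1] <- counterstain[rr <= 1] + spec$background_level * 5
  }

  list(probe_image = probe, counterstain_image = counterstain,
       truth = ground_truth(sum(spot_a), sum(spot_b)))
}

#' Render a 3D z-stack of paired probe spots
#'
#' Spots are separable 3D Gaussians (lateral sigma `spot_sigma_xy`, axial
#' sigma `spot_sigma_z` in sections). Ground truth additionally records, per
#' homolog, the axial section span and voxel count above the generator's own
#' signal threshold, `3 * sqrt(background_level)` over background: a voxel is
#' true signal when its noise-free spot value exceeds that, and a section is
#' in the span when it contains at least one such voxel.
#'
#' @param spec A [scene_spec()] whose `spot_positions` are
#'   `(section, row, col)` triples.
#' @return List with `zstack` (array `[section, row, col]`) and `truth`.
#' @export
render_scene_3d <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  if (spec$spot_sigma_z >= spec$n_sections) {
    fishda_stop("spot_sigma_z >= n_sections: axial extent unresolvable in this stack",
                "fishda_error_axial")
  }
  check_spot_separation(spec)
  h <- spec$image_height; w <- spec$image_width; ns <- spec$n_sections
  pos <- lapply(spec$spot_positions, function(p) {
    if (length(p) != 3L) c((ns + 1) / 2, p) else p
  })
  render_spot <- function(p, amplitude) {
    gz <- exp(-(seq_len(ns) - p[1])^2 / (2 * spec$spot_sigma_z^2))
    plane <- gaussian_spot_2d(h, w, p[2:3], amplitude, spec$spot_sigma_xy)
    out <- array(0, dim = c(ns, h, w))
    for (s in seq_len(ns)) out[s, , ] <- gz[s] * plane
    out
  }
  spot_a <- render_spot(pos[[1]], spec$amplitude_bright)
  spot_b <- render_spot(pos[[2]], spec$amplitude_dim)
  clean <- spec$background_level + spot_a + spot_b
  zstack <- with_seed(spec$seed, apply_noise(clean, spec))

  thr <- 3 * sqrt(spec$background_level)
  span <- function(spot) {
    sig <- spot > thr
    sum(apply(sig, 1, any))
  }
  truth <- ground_truth(
    sum(spot_a), sum(spot_b),
    span_a = span(spot_a), span_b = span(spot_b),
    vox_a = sum(spot_a > thr), vox_b = sum(spot_b > thr)
  )
  list(zstack = zstack, truth = truth)
}

#' Axial sigma giving a target true section span
#'
#' Bisects `spot_sigma_z` until the noise-free generator truth span of
#' homolog A equals `target_sections` under the supplied template. The truth
#' span is monotone in the axial sigma, so bisection converges; spans of
#' even parity need a spot center between sections (e.g. 8.5 in a 17-section
#' stack), odd spans an on-section center.
#'
#' @param spec_template A [scene_spec()] with 3D spot positions; its
#'   `spot_sigma_z` is ignored.
#' @param target_sections Desired number of sections in the truth span.
#' @return The calibrated axial sigma (sections).
#' @export
axial_sigma_for_span <- function(spec_template, target_sections) {
  stopifnot(inherits(spec_template, "scene_spec"),
            is_count(target_sections, 1),
            target_sections <= spec_template$n_sections)
  span_at <- function(sz) {
    sp <- spec_template
    sp$spot_sigma_z <- sz
    sp$noise_model <- "none"
    render_scene_3d(sp)$truth$true_section_span_A
  }
  lo <- 0.05
  hi <- spec_template$n_sections - 0.01
  if (span_at(hi) < target_sections || span_at(lo) > target_sections) {
    fishda_stop("target span unreachable under this template",
                "fishda_error_axial")
  }
  for (i in 1:50) {
    mid <- (lo + hi) / 2
    if (span_at(mid) < target_sections) lo <- mid else hi <- mid
  }
  if (span_at(hi) != target_sections) {
    fishda_stop("target span unreachable under this template (parity of the spot center)",
                "fishda_error_axial")
  }
  hi
}
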