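# Gradient vector flow (GVF) external force field.
#
# The edge map is the gradient magnitude of the Gaussian-smoothed image
# (optionally binarized at a fraction of its maximum). GVF diffuses the edge
# map's gradient across the image, extending the capture range of the active
# contour far beyond the edge's immediate vicinity while agreeing with the
# plain gradient where edges are strong.

# Gaussian smoothing with a kernel clipped to the image size (windows near
# the frame border can be smaller than the default kernel support).
#' @noRd
gaussian_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  m <- min(dim(img))
  if (r > m) r <- m - ((m + 1L) %% 2L)  # largest odd size that fits
  if (r < 3L) return(img)
  EBImage::gblur(img, sigma = sigma, radius = r, boundary = "replicate")
}

# Central-difference gradients with replicate-edge boundaries.
# Returns d/drow and d/dcol components.
#' @noRd
image_gradient <- function(img) {
  h <- nrow(img); w <- ncol(img)
  up <- img[c(1L, seq_len(h - 1L)), , drop = FALSE]
  dn <- img[c(seq_len(h)[-1L], h), , drop = FALSE]
  lf <- img[, c(1L, seq_len(w - 1L)), drop = FALSE]
  rt <- img[, c(seq_len(w)[-1L], w), drop = FALSE]
  list(dr = (dn - up) / 2, dc = (rt - lf) / 2)
}

# 5-point Laplacian with replicate-edge boundaries.
#' @noRd
image_laplacian <- function(img) {
  h <- nrow(img); w <- ncol(img)
  img[c(1L, seq_len(h - 1L)), ] + img[c(seq_len(h)[-1L], h), ] +
    img[, c(1L, seq_len(w - 1L))] + img[, c(seq_len(w)[-1L], w)] - 4 * img
}

#' Compute an edge map from a gray-scale image
#'
#' Gradient magnitude of the Gaussian-smoothed image, normalized to
#' `[0, 1]`. With `binarize_fraction > 0` the map is thresholded at that
#' fraction of its maximum to yield a binary variant.
#'
#' @param image Finite, non-negative numeric matrix.
#' @param smoothing_sigma Gaussian smoothing sigma in pixels (0 = none).
#' @param binarize_fraction Threshold as a fraction of the maximum gradient
#'   magnitude; 0 keeps the gray-scale map (default).
#' @return An object of class `"edge_map"` with element `values`.
#' @export
compute_edge_map <- function(image, smoothing_sigma = 1, binarize_fraction = 0) {
  stopifnot(is.matrix(image), all(is.finite(image)), all(image >= 0),
            is_number(smoothing_sigma), smoothing_sigma >= 0,
            is_number(binarize_fraction),
            binarize_fraction >= 0, binarize_fraction < 1)
  sm <- gaussian_smooth(image, smoothing_sigma)
  g <- image_gradient(sm)
  mag <- sqrt(g$dr^2 + g$dc^2)
  mx <- max(mag)
  # a locally-constant (smoothed) image carries no edges; guard against
  # normalizing the FFT-level ripple of the smoothing filter
  if (mx <= 1e-8 * max(max(abs(sm)), 1)) {
    values <- mag * 0
  } else {
    values <- mag / mx
    if (binarize_fraction > 0) {
      values <- (values >= binarize_fraction) * 1
    }
  }
  structure(list(values = values, smoothing_sigma = smoothing_sigma,
                 binarize_fraction = binarize_fraction),
            class = "edge_map")
}

#' Compute the gradient vector flow field of an edge map
#'
#' Iterates the explicit diffusion update
#' `u <- u + gamma * (mu * lap(u) - (u - f_c) * (f_r^2 + f_c^2))` (and
#' analogously for `v`) from the initial field `(f_c, f_r)`, where
#' `(f_r, f_c)` are the edge-map gradients, until the RMS Euler-equation
#' residual drops below `tolerance` or `max_iterations` is reached. The time
#' step must satisfy `gamma * mu <= 1/4` for stability on the unit grid.
#'
#' @param edge_map An [compute_edge_map()] result (or plain matrix).
#' @param mu Regularization weight (> 0): larger values give a smoother,
#'   farther-reaching field.
#' @param max_iterations Iteration cap.
#' @param tolerance Convergence tolerance on the RMS residual.
#' @param gamma Explicit time step.
#' @return An object of class `"gvf_field"` with components `u` (col/x
#'   component), `v` (row/y component), `converged`, `final_residual`,
#'   `n_iterations`.
#' @export
compute_gvf <- function(edge_map, mu = 0.1, max_iterations = 500,
                        tolerance = 1e-4, gamma = 1) {
  f <- if (inherits(edge_map, "edge_map")) edge_map$values else edge_map
  stopifnot(is.matrix(f), is_number(mu), mu > 0, is_number(gamma), gamma > 0,
            is_count(max_iterations, 1))
  if (gamma * mu > 0.25) {
    fishda_stop("gamma * mu > 1/4: diffusion step unstable on the unit grid",
                "fishda_error_gvf_step")
  }
  g <- image_gradient(f)
  fr <- g$dr; fc <- g$dc
  mag <- fr^2 + fc^2
  u <- fc; v <- fr
  it <- 0L
  resid <- Inf
  while (it < max_iterations) {
    ru <- mu * image_laplacian(u) - (u - fc) * mag
    rv <- mu * image_laplacian(v) - (v - fr) * mag
    resid <- sqrt(mean(ru^2 + rv^2))
    if (!is.finite(resid)) {
      fishda_stop("GVF iteration diverged: time step too large for given mu",
                  "fishda_error_gvf_diverged")
    }
    if (resid < tolerance) break
    u <- u + gamma * ru
    v <- v + gamma * rv
    it <- it + 1L
  }
  structure(list(u = u, v = v, mu = mu, n_iterations = it,
                 final_residual = resid,
                 converged = resid < tolerance),
            class = "gvf_field")
}

#' Euler-equation residual of a GVF field
#'
#' Independently evaluates `mu * lap(u) - (u - f_c) * (f_r^2 + f_c^2)` (and
#' the v analogue) on the given field and edge map, returning the RMS over
#' both components. At the GVF energy minimum this is zero.
#'
#' @param gvf A [compute_gvf()] result.
#' @param edge_map The edge map the field was computed from.
#' @param mu Regularization weight used.
#' @return RMS residual (scalar).
#' @export
gvf_residual <- function(gvf, edge_map, mu = gvf$mu) {
  f <- if (inherits(edge_map, "edge_map")) edge_map$values else edge_map
  g <- image_gradient(f)
  mag <- g$dr^2 + g$dc^2
  ru <- mu * image_laplacian(gvf$u) - (gvf$u - g$dc) * mag
  rv <- mu * image_laplacian(gvf$v) - (gvf$v - g$dr) * mag
  sqrt(mean(ru^2 + rv^2))
}
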