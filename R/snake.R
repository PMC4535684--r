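# Active contour (snake) evolution under internal smoothness forces and the
# GVF external force, plus probe peak detection and contour initialization.

#' Detect probe signal peaks
#'
#' Local maxima of the Gaussian-smoothed image above a robust background
#' threshold (median + 3 MAD), ranked by height and greedily kept with a
#' minimum mutual distance. Equal heights break ties toward smaller
#' (row, col) in lexicographic order.
#'
#' @param probe_image Numeric matrix.
#' @param expected_count Number of peaks that must be found (>= 1).
#' @param smoothing_sigma Smoothing before maxima detection, pixels.
#' @param min_distance Minimum distance between accepted peaks, pixels.
#' @return Integer matrix `(row, col)` with `expected_count` rows.
#' @export
detect_probe_peaks <- function(probe_image, expected_count = 2L,
                               smoothing_sigma = 2, min_distance = 10) {
  stopifnot(is.matrix(probe_image), is_count(expected_count, 1))
  sm <- gaussian_smooth(probe_image, smoothing_sigma)
  h <- nrow(sm); w <- ncol(sm)
  # 5 MAD above the median: above the maxima of smoothed background noise
  # on frames this size, while far below any real spot peak
  thr <- stats::median(sm) + 5 * stats::mad(sm)
  # 8-neighborhood maximum via shifted copies (replicate edges)
  shift <- function(m, dr, dc) {
    ri <- pmin(pmax(seq_len(h) + dr, 1L), h)
    ci <- pmin(pmax(seq_len(w) + dc, 1L), w)
    m[ri, ci, drop = FALSE]
  }
  nmax <- sm
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nmax <- pmax(nmax, shift(sm, dr, dc))
  }
  keep <- sm >= nmax & sm > thr
  # border pixels have degenerate (clamped) neighborhoods and cannot anchor
  # a contour; exclude them from candidacy
  keep[c(1L, h), ] <- FALSE
  keep[, c(1L, w)] <- FALSE
  cand <- which(keep, arr.ind = TRUE)
  if (nrow(cand) == 0L) {
    fishda_stop("no local maxima above background: hybridization failure",
                "fishda_error_peaks")
  }
  vals <- sm[cand]
  ord <- order(-vals, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  kept <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    if (nrow(kept) == 0L ||
        all(sqrt((kept[, 1] - p[1])^2 + (kept[, 2] - p[2])^2) >= min_distance)) {
      kept <- rbind(kept, p)
      if (nrow(kept) == expected_count) break
    }
  }
  if (nrow(kept) < expected_count) {
    fishda_stop(sprintf(
      "found %d peak(s) above background, expected %d: hybridization failure",
      nrow(kept), expected_count), "fishda_error_peaks")
  }
  dimnames(kept) <- list(NULL, c("row", "col"))
  # stable homolog labelling: order kept peaks lexicographically by (row, col)
  kept[order(kept[, 1], kept[, 2]), , drop = FALSE]
}

#' Initialize a circular contour
#'
#' Regular polygon approximating a circle, traversed counter-clockwise.
#'
#' @param center `(row, col)` center.
#' @param radius Circle radius in pixels (> 0).
#' @param n_vertices Number of vertices (>= 8).
#' @return A [contour].
#' @export
initialize_contour <- function(center, radius, n_vertices = 64L) {
  stopifnot(length(center) == 2L, all(is.finite(center)))
  if (!is_number(radius) || radius <= 0) {
    fishda_stop("radius must be positive", "fishda_error_contour")
  }
  if (!is_count(n_vertices, 8)) {
    fishda_stop("n_vertices must be at least 8", "fishda_error_contour")
  }
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[seq_len(n_vertices)]
  contour(cbind(row = center[1] + radius * sin(theta),
                col = center[2] + radius * cos(theta)))
}

#' Snake evolution parameters
#'
#' @param alpha Tension (first-derivative) weight.
#' @param beta Rigidity (second-derivative) weight.
#' @param gamma Time step (> 0).
#' @param kappa External (GVF) force weight.
#' @param max_iterations Iteration cap.
#' @param convergence_tol Mean vertex displacement (pixels) below which the
#'   contour is declared converged.
#' @return An object of class `"snake_params"`.
#' @export
snake_params <- function(alpha = 0.1, beta = 0.1, gamma = 1, kappa = 2,
                         max_iterations = 400L, convergence_tol = 0.02) {
  stopifnot(is_number(alpha), alpha >= 0, is_number(beta), beta >= 0,
            is_number(gamma), gamma > 0, is_number(kappa), kappa >= 0,
            is_count(max_iterations, 1), is_number(convergence_tol),
            convergence_tol > 0)
  structure(list(alpha = alpha, beta = beta, gamma = gamma, kappa = kappa,
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol),
            class = "snake_params")
}

# Cyclic pentadiagonal internal-energy matrix for n vertices.
#' @noRd
snake_internal_matrix <- function(n, alpha, beta) {
  idx <- function(k) ((seq_len(n) - 1L + k) %% n) + 1L
  A <- matrix(0, n, n)
  main <- 2 * alpha + 6 * beta
  off1 <- -alpha - 4 * beta
  off2 <- beta
  for (i in seq_len(n)) {
    A[i, i] <- main
    A[i, idx(1L)[i]] <- A[i, idx(1L)[i]] + off1
    A[i, idx(-1L)[i]] <- A[i, idx(-1L)[i]] + off1
    A[i, idx(2L)[i]] <- A[i, idx(2L)[i]] + off2
    A[i, idx(-2L)[i]] <- A[i, idx(-2L)[i]] + off2
  }
  A
}

# Bilinear sampling of a field at continuous (row, col) points,
# clamped to the image frame.
#' @noRd
bilinear_sample <- function(field, rows, cols) {
  h <- nrow(field); w <- ncol(field)
  r <- pmin(pmax(rows, 1), h)
  c <- pmin(pmax(cols, 1), w)
  r0 <- pmin(floor(r), h - 1L); c0 <- pmin(floor(c), w - 1L)
  fr <- r - r0; fc <- c - c0
  f00 <- field[cbind(r0, c0)]
  f10 <- field[cbind(r0 + 1L, c0)]
  f01 <- field[cbind(r0, c0 + 1L)]
  f11 <- field[cbind(r0 + 1L, c0 + 1L)]
  f00 * (1 - fr) * (1 - fc) + f10 * fr * (1 - fc) +
    f01 * (1 - fr) * fc + f11 * fr * fc
}

#' Evolve a snake under a GVF external force
#'
#' Semi-implicit iteration: the internal tension/rigidity system is solved
#' implicitly through the cyclic pentadiagonal matrix, while the external
#' force `kappa * (u, v)` is sampled at the vertices by bilinear
#' interpolation. Vertices are re-sampled to uniform arc length every
#' iteration. Iteration stops when the mean vertex displacement falls below
#' `convergence_tol`; a contour that fails to converge is returned with
#' `converged = FALSE`. A self-intersecting output signals a degenerate
#' segmentation and raises an error.
#'
#' @param init Initial [contour].
#' @param gvf A [compute_gvf()] field sharing the image frame.
#' @param params [snake_params()].
#' @return The final [contour] with a `converged` flag.
#' @export
evolve_snake <- function(init, gvf, params = snake_params()) {
  stopifnot(inherits(init, "contour"), inherits(gvf, "gvf_field"),
            inherits(params, "snake_params"))
  v <- init$vertices
  n <- nrow(v)
  A <- snake_internal_matrix(n, params$alpha, params$beta)
  M <- solve(diag(n) + params$gamma * A)
  converged <- FALSE
  for (it in seq_len(params$max_iterations)) {
    fu <- bilinear_sample(gvf$u, v[, 1], v[, 2])  # col/x component
    fv <- bilinear_sample(gvf$v, v[, 1], v[, 2])  # row/y component
    new_r <- M %*% (v[, 1] + params$gamma * params$kappa * fv)
    new_c <- M %*% (v[, 2] + params$gamma * params$kappa * fu)
    disp <- mean(sqrt((new_r - v[, 1])^2 + (new_c - v[, 2])^2))
    v <- resample_closed(cbind(new_r, new_c), n)
    if (disp < params$convergence_tol) {
      converged <- TRUE
      break
    }
  }
  if (!polygon_is_simple(v)) {
    fishda_stop("snake output self-intersects: degenerate segmentation",
                "fishda_error_snake_degenerate")
  }
  contour(v, converged = converged)
}
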