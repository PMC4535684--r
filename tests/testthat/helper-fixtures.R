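# Shared fixtures and independent oracles for the test suite.

# Filled disk of given value over zero background, anti-alias-free.
make_disk_image <- function(nrow, ncol, center, radius, value = 5,
                            background = 0) {
  d2 <- outer((seq_len(nrow) - center[1])^2, (seq_len(ncol) - center[2])^2, "+")
  img <- matrix(background, nrow, ncol)
  img[d2 <= radius^2] <- background + value
  img
}

# Independent brute-force finite-difference gradient magnitude
# (central differences, replicate edges) -- oracle for the edge map.
oracle_gradient_magnitude <- function(img) {
  h <- nrow(img); w <- ncol(img)
  gr <- matrix(0, h, w); gc <- matrix(0, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    gr[r, c] <- (img[min(r + 1, h), c] - img[max(r - 1, 1), c]) / 2
    gc[r, c] <- (img[r, min(c + 1, w)] - img[r, max(c - 1, 1)]) / 2
  }
  sqrt(gr^2 + gc^2)
}

# Independent GVF Euler-equation residual: loops, not the package's
# vectorized shifts.
oracle_gvf_residual <- function(u, v, f, mu) {
  h <- nrow(f); w <- ncol(f)
  gr <- matrix(0, h, w); gc <- matrix(0, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    gr[r, c] <- (f[min(r + 1, h), c] - f[max(r - 1, 1), c]) / 2
    gc[r, c] <- (f[r, min(c + 1, w)] - f[r, max(c - 1, 1)]) / 2
  }
  mag <- gr^2 + gc^2
  lap <- function(m) {
    out <- matrix(0, h, w)
    for (r in seq_len(h)) for (c in seq_len(w)) {
      out[r, c] <- m[max(r - 1, 1), c] + m[min(r + 1, h), c] +
        m[r, max(c - 1, 1)] + m[r, min(c + 1, w)] - 4 * m[r, c]
    }
    out
  }
  ru <- mu * lap(u) - (u - gc) * mag
  rv <- mu * lap(v) - (v - gr) * mag
  sqrt(mean(ru^2 + rv^2))
}

# 90-degree clockwise rotation of a matrix and the matching point map:
# pixel (r, c) in the original lands at (c, H + 1 - r).
rot90_cw <- function(m) t(m)[, nrow(m):1, drop = FALSE]
rot90_cw_points <- function(pts, h) cbind(pts[, 2], h + 1 - pts[, 1])
rot90_cw_points_inv <- function(pts, h) cbind(h + 1 - pts[, 2], pts[, 1])

# Default two-spot DA scene used across modules.
da_scene_spec <- function(amplitude_bright = 300, amplitude_dim = 100,
                          seed = 1L, noise_model = "poisson", ...) {
  scene_spec(amplitude_bright = amplitude_bright,
             amplitude_dim = amplitude_dim, seed = seed,
             noise_model = noise_model, ...)
}

# Build a per-cell measurement frame directly from cohort ground truth
# (statistic-level path: bypasses imaging).
measurements_from_truth <- function(truth, locus_id = "locus") {
  data.frame(
    cell_id = truth$cell_id, locus_id = locus_id,
    intensity_A = NA_real_, intensity_B = NA_real_,
    normalized_difference = truth$d_true,
    weaker_homolog = truth$weaker_true,
    stringsAsFactors = FALSE
  )
}
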