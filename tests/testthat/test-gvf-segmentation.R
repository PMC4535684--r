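# Edge map, GVF field, peak detection and snake evolution.

test_that("constant image yields an all-zero edge map", {
  em <- compute_edge_map(matrix(7, 32, 32), smoothing_sigma = 1)
  expect_true(all(em$values == 0))
})

test_that("edge map matches a brute-force gradient oracle on a step edge", {
  img <- matrix(0, 32, 32)
  img[, 17:32] <- 10
  em <- compute_edge_map(img, smoothing_sigma = 0)
  oracle <- oracle_gradient_magnitude(img)
  expect_equal(em$values, oracle / max(oracle), tolerance = 1e-12)
  # maximal response in the column band about the step, symmetric around it
  col_mean <- colMeans(em$values)
  expect_true(which.max(col_mean) %in% c(16L, 17L))
  expect_equal(col_mean[16], col_mean[17], tolerance = 1e-12)
})

test_that("disk edge map peaks on a ring of the disk radius", {
  img <- make_disk_image(64, 64, c(32, 32), radius = 10, value = 20)
  em <- compute_edge_map(img, smoothing_sigma = 1)
  peak_px <- which(em$values > 0.8 * max(em$values), arr.ind = TRUE)
  radii <- sqrt((peak_px[, 1] - 32)^2 + (peak_px[, 2] - 32)^2)
  expect_true(all(abs(radii - 10) <= 1.5))
})

test_that("binarized edge map is 0/1 at the stated fraction of maximum", {
  img <- make_disk_image(32, 32, c(16, 16), radius = 6, value = 10)
  em <- compute_edge_map(img, smoothing_sigma = 1, binarize_fraction = 0.5)
  expect_true(all(em$values %in% c(0, 1)))
  gray <- compute_edge_map(img, smoothing_sigma = 1)
  expect_identical(em$values == 1, unname(gray$values >= 0.5))
})

test_that("zero edge map gives the zero GVF field immediately", {
  gvf <- compute_gvf(matrix(0, 16, 16))
  expect_true(all(gvf$u == 0) && all(gvf$v == 0))
  expect_true(gvf$converged)
})

test_that("converged GVF field satisfies the Euler equation per an independent oracle", {
  img <- make_disk_image(40, 40, c(20, 20), radius = 8, value = 10)
  em <- compute_edge_map(img, smoothing_sigma = 1)
  tol <- 1e-4
  gvf <- compute_gvf(em, mu = 0.1, max_iterations = 5000, tolerance = tol)
  expect_true(gvf$converged)
  resid <- oracle_gvf_residual(gvf$u, gvf$v, em$values, mu = 0.1)
  expect_lt(resid, tol)
  # field points toward the edge ring along a radial line outside the disk
  rows <- 20; cols <- 31:38  # right of the ring at col 28
  expect_true(all(gvf$u[rows, cols] < 0))
})

test_that("GVF extends the capture range far beyond the plain gradient", {
  img <- make_disk_image(64, 64, c(32, 32), radius = 8, value = 10)
  em <- compute_edge_map(img, smoothing_sigma = 1)
  gvf <- compute_gvf(em, mu = 0.2, max_iterations = 3000, tolerance = 1e-5)
  # probe point 10 px outside the ring
  probe <- c(32, 32 + 8 + 10)
  gvf_mag <- sqrt(gvf$u[probe[1], probe[2]]^2 + gvf$v[probe[1], probe[2]]^2)
  g <- fishda:::image_gradient(em$values)
  grad_mag <- sqrt(g$dr[probe[1], probe[2]]^2 + g$dc[probe[1], probe[2]]^2)
  peak <- max(sqrt(gvf$u^2 + gvf$v^2))
  expect_gt(gvf_mag, 1e-3 * peak)
  expect_lt(grad_mag, 1e-8)
})

test_that("unstable GVF time step is rejected", {
  expect_error(compute_gvf(matrix(0, 8, 8), mu = 0.3, gamma = 1),
               class = "fishda_error_gvf_step")
})

test_that("peak detection recovers well-separated Gaussian centers within 1 px", {
  spec <- da_scene_spec(seed = 5L)
  sc <- render_scene_2d(spec)
  peaks <- detect_probe_peaks(sc$probe_image, 2)
  expect_lt(sqrt(sum((peaks[1, ] - c(32, 20))^2)), 1.01)
  expect_lt(sqrt(sum((peaks[2, ] - c(32, 44))^2)), 1.01)
})

test_that("peak detection errors on flat images and missing spots", {
  expect_error(detect_probe_peaks(matrix(3, 32, 32), 2),
               class = "fishda_error_peaks")
  one_spot <- render_scene_2d(scene_spec(amplitude_bright = 200,
                                         amplitude_dim = 0, seed = 2L))
  expect_error(detect_probe_peaks(one_spot$probe_image, 2),
               class = "fishda_error_peaks")
})

test_that("initial contour is a regular circle with the stated radius", {
  ctr <- initialize_contour(c(10, 12), radius = 5, n_vertices = 32)
  d <- sqrt((ctr$vertices[, 1] - 10)^2 + (ctr$vertices[, 2] - 12)^2)
  expect_true(all(abs(d - 5) < 1e-9))
  # polygon area vs pi r^2, within the inscribed-polygon deficit
  deficit <- 1 - (32 / (2 * pi)) * sin(2 * pi / 32)
  expect_equal(polygon_area(ctr$vertices), pi * 25 * (1 - deficit),
               tolerance = 1e-9)
  expect_error(initialize_contour(c(1, 1), 5, n_vertices = 7),
               class = "fishda_error_contour")
  expect_error(initialize_contour(c(1, 1), 0, n_vertices = 16),
               class = "fishda_error_contour")
})

test_that("snake initialized on a disk's edge ring stays there", {
  img <- make_disk_image(64, 64, c(32, 32), radius = 10, value = 20)
  em <- compute_edge_map(img, smoothing_sigma = 1)
  gvf <- compute_gvf(em, max_iterations = 2000, tolerance = 1e-5)
  init <- initialize_contour(c(32, 32), radius = 10)
  out <- evolve_snake(init, gvf, snake_params(alpha = 0.05, beta = 0.05,
                                              kappa = 2))
  d <- sqrt((out$vertices[, 1] - 32)^2 + (out$vertices[, 2] - 32)^2)
  expect_true(all(abs(d - 10) < 0.5))
})

test_that("snake from 1.5x the disk radius recovers the disk area within 10%", {
  img <- make_disk_image(64, 64, c(32, 32), radius = 10, value = 20)
  em <- compute_edge_map(img, smoothing_sigma = 1)
  gvf <- compute_gvf(em, max_iterations = 2000, tolerance = 1e-5)
  init <- initialize_contour(c(32, 32), radius = 15)
  out <- evolve_snake(init, gvf, snake_params())
  expect_lt(abs(polygon_area(out$vertices) - pi * 100) / (pi * 100), 0.10)
})

test_that("with no external force the snake shrinks monotonically", {
  gvf0 <- compute_gvf(matrix(0, 64, 64))
  params <- snake_params(alpha = 0.2, beta = 0, kappa = 0,
                         max_iterations = 1, convergence_tol = 1e-9)
  v <- initialize_contour(c(32, 32), radius = 15)
  per <- fishda:::polygon_perimeter(v$vertices)
  for (i in 1:20) {
    v <- tryCatch(evolve_snake(v, gvf0, params), fishda_error = function(e) NULL)
    if (is.null(v)) break
    p2 <- fishda:::polygon_perimeter(v$vertices)
    expect_lt(p2, per)
    per <- p2
  }
})

test_that("segmentation recovers spot support and center over many noisy spots", {
  # 25 cells = 50 spots at SNR >= 10; contour area within 15% of the
  # 95%-mass area, centroid within 1 px of the true center
  sigma <- 2
  target_area <- pi * (sigma * sqrt(2 * log(20)))^2
  cfg <- seg_config(spot_sigma = sigma)
  n_bad_area <- 0
  for (i in 1:25) {
    spec <- da_scene_spec(amplitude_bright = 300, amplitude_dim = 150,
                          seed = 100L + i)
    sc <- render_scene_2d(spec)
    for (center in spec$spot_positions) {
      ctr <- segment_spot(sc$probe_image, center, cfg)
      area <- polygon_area(ctr$vertices)
      if (abs(area - target_area) / target_area > 0.15) {
        n_bad_area <- n_bad_area + 1
      }
      expect_lt(sqrt(sum((fishda:::polygon_centroid(ctr$vertices) - center)^2)), 1)
    }
  }
  expect_identical(n_bad_area, 0)
})

test_that("rotating the image by 90 degrees rotates the contour correspondingly", {
  spec <- da_scene_spec(seed = 9L)
  sc <- render_scene_2d(spec)
  cfg <- seg_config(spot_sigma = 2)
  h <- nrow(sc$probe_image)
  center <- c(32, 20)
  ctr <- segment_spot(sc$probe_image, center, cfg)
  rot <- rot90_cw(sc$probe_image)
  ctr_rot <- segment_spot(rot, rot90_cw_points(rbind(center), h), cfg)
  back <- rot90_cw_points_inv(ctr_rot$vertices, h)
  # compare vertex sets via nearest-neighbour distance (resampling may
  # shift vertices along the curve)
  dmat <- sqrt(outer(back[, 1], ctr$vertices[, 1], "-")^2 +
                 outer(back[, 2], ctr$vertices[, 2], "-")^2)
  expect_lt(max(apply(dmat, 1, min)), 0.5)
  expect_lt(max(apply(dmat, 2, min)), 0.5)
})
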