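# Synthetic scene generator: analytic integrals, noise statistics,
# ground-truth bookkeeping, determinism.

test_that("noise-free spot integral matches the closed-form Gaussian integral", {
  # pixel sum of A * exp(-r^2 / 2 sigma^2) vs 2 * pi * A * sigma^2,
  # frame extends far beyond 5 sigma on each side
  for (case in list(c(A = 100, sigma = 2), c(A = 250, sigma = 3))) {
    spec <- scene_spec(image_height = 96, image_width = 96,
                       spot_sigma_xy = case[["sigma"]],
                       amplitude_bright = case[["A"]],
                       amplitude_dim = case[["A"]],
                       spot_positions = list(c(48, 26), c(48, 70)),
                       noise_model = "none")
    sc <- render_scene_2d(spec)
    closed_form <- 2 * pi * case[["A"]] * case[["sigma"]]^2
    expect_lt(abs(sc$truth$true_integrated_intensity_A - closed_form) /
                closed_form, 0.005)
    # rendered pixel sum (background removed) agrees too
    rendered <- sum(sc$probe_image - spec$background_level) / 2
    expect_lt(abs(rendered - closed_form) / closed_form, 0.005)
  }
})

test_that("symmetric amplitudes give zero truth difference and no weaker homolog", {
  sc <- render_scene_2d(scene_spec(amplitude_bright = 150, amplitude_dim = 150,
                                   noise_model = "none"))
  expect_identical(sc$truth$true_normalized_difference, 0)
  expect_identical(sc$truth$weaker_homolog, "none")
})

test_that("identical spec and seed render bit-identical scenes in 2D and 3D", {
  spec <- da_scene_spec(seed = 17L)
  expect_identical(render_scene_2d(spec)$probe_image,
                   render_scene_2d(spec)$probe_image)
  spec3 <- scene_spec(spot_positions = list(c(9, 32, 20), c(9, 32, 44)),
                      seed = 17L)
  expect_identical(render_scene_3d(spec3)$zstack,
                   render_scene_3d(spec3)$zstack)
})

test_that("overlapping spot centers are rejected", {
  expect_error(
    render_scene_2d(scene_spec(spot_positions = list(c(32, 20), c(32, 28)))),
    class = "fishda_error_overlap")
})

test_that("Poisson noise has unit variance-to-mean ratio in background", {
  spec <- scene_spec(image_height = 24, image_width = 24,
                     spot_positions = list(c(4, 4), c(20, 20)),
                     spot_sigma_xy = 1, background_level = 10)
  # background-only corner, far from both spots
  vals <- sapply(seq_len(200), function(i) {
    s <- spec; s$seed <- 1000L + i
    render_scene_2d(s)$probe_image[10:14, 10:14]
  })
  ratio <- stats::var(as.vector(vals)) / mean(vals)
  expect_gt(ratio, 0.9)
  expect_lt(ratio, 1.1)
})

test_that("3D generator truth spans and voxel counts follow its threshold rule", {
  spec <- scene_spec(spot_positions = list(c(9, 32, 20), c(9, 32, 44)),
                     amplitude_bright = 300, amplitude_dim = 120,
                     spot_sigma_z = 1.5, noise_model = "none")
  z <- render_scene_3d(spec)
  # independent recomputation of the truth rule for homolog A
  thr <- 3 * sqrt(spec$background_level)
  gz <- exp(-(1:17 - 9)^2 / (2 * 1.5^2))
  plane <- 300 * exp(-outer((1:64 - 32)^2, (1:64 - 20)^2, "+") / (2 * 4))
  vox <- 0L; span <- 0L
  for (s in 1:17) {
    above <- gz[s] * plane > thr
    vox <- vox + sum(above)
    span <- span + any(above)
  }
  expect_identical(z$truth$true_section_span_A, as.integer(span))
  expect_identical(z$truth$true_voxel_count_A, as.integer(vox))

  # amplitude zero: all-background stack, spans zero
  z0 <- render_scene_3d(scene_spec(
    spot_positions = list(c(9, 32, 20), c(9, 32, 44)),
    amplitude_bright = 0, amplitude_dim = 0, noise_model = "none"))
  expect_identical(z0$truth$true_section_span_A, 0L)
  expect_identical(z0$truth$true_voxel_count_B, 0L)
})

test_that("unresolvable axial extent is rejected", {
  expect_error(
    render_scene_3d(scene_spec(n_sections = 5, spot_sigma_z = 5,
                               spot_positions = list(c(3, 32, 20), c(3, 32, 44)))),
    class = "fishda_error_axial")
})

test_that("cohort amplitudes follow the normalization algebra", {
  # fraction 1, constant d = 0.5, amplitude sum 200 -> every cell (150, 50)
  coh <- cohort_spec(n_cells = 10, fraction_da_cells = 1,
                     da_difference_distribution =
                       difference_distribution("constant", value = 0.5),
                     consistent_weaker_homolog = "B", seed = 3L)
  tmpl <- scene_spec(amplitude_bright = 100, amplitude_dim = 100)
  cd <- generate_cohort(coh, tmpl)
  expect_true(all(abs(cd$truth$amplitude_A - 150) < 1e-12))
  expect_true(all(abs(cd$truth$amplitude_B - 50) < 1e-12))
  expect_true(all(cd$truth$weaker_true == "B"))

  # fraction 0: all differences from the null distribution support
  coh0 <- cohort_spec(n_cells = 40, fraction_da_cells = 0,
                      null_difference_distribution =
                        difference_distribution("uniform", min = 0, max = 0.2),
                      seed = 4L)
  cd0 <- generate_cohort(coh0, tmpl)
  expect_true(all(cd0$truth$d_true <= 0.2))
  expect_true(all(!cd0$truth$is_da))
})

test_that("cohort draw mean sits within 3 SE of the distribution mean", {
  dist <- difference_distribution("uniform", min = 0.4, max = 0.9)
  coh <- cohort_spec(n_cells = 50, fraction_da_cells = 1,
                     da_difference_distribution = dist, seed = 11L)
  cd <- generate_cohort(coh, scene_spec())
  se <- sqrt((0.9 - 0.4)^2 / 12 / 50)
  expect_lt(abs(mean(cd$truth$d_true) - 0.65), 3 * se)
})

test_that("cohorts are reproducible from their seed", {
  coh <- cohort_spec(n_cells = 5, seed = 21L)
  a <- generate_cohort(coh, scene_spec())
  b <- generate_cohort(coh, scene_spec())
  expect_identical(a$truth, b$truth)
  expect_identical(render_scene_2d(a$cells[[3]])$probe_image,
                   render_scene_2d(b$cells[[3]])$probe_image)
})
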