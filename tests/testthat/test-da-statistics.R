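# DA calling statistics: per-cell scoring, locus summaries, pre/post
# comparisons and the generic tests.

test_that("two-proportion z matches frozen oracle values", {
  # equal proportions
  eq <- two_proportion_z(20, 40, 20, 40)
  expect_identical(eq$z, 0)
  expect_identical(eq$p, 1)
  # (35/50 vs 10/50): pool 0.45, se sqrt(0.2475 * 0.04), hand-computed
  zt <- two_proportion_z(35, 50, 10, 50)
  expect_equal(zt$z, 0.5 / sqrt(0.45 * 0.55 * (1 / 50 + 1 / 50)),
               tolerance = 1e-12)
  expect_equal(zt$z, 5.025189, tolerance = 1e-6)
  expect_equal(zt$p, 5.029056e-07, tolerance = 1e-5)
  # cross-check against the chi-square equivalence (prop.test, no correction)
  pt <- suppressWarnings(prop.test(c(35, 10), c(50, 50), correct = FALSE))
  expect_equal(zt$z^2, unname(pt$statistic), tolerance = 1e-10)
  expect_equal(zt$p, pt$p.value, tolerance = 1e-10)
  # extreme split: pool is 0.5, not degenerate
  zx <- two_proportion_z(0, 10, 10, 10)
  expect_false(zx$degenerate)
  expect_equal(zx$z, -1 / sqrt(0.25 * 0.2), tolerance = 1e-12)
})

test_that("two-proportion z is antisymmetric and degenerate pools are flagged", {
  set.seed(12)
  for (i in 1:20) {
    n1 <- sample(10:80, 1); n2 <- sample(10:80, 1)
    k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
    a <- two_proportion_z(k1, n1, k2, n2)
    b <- two_proportion_z(k2, n2, k1, n1)
    expect_equal(a$z, -b$z, tolerance = 1e-12)
    expect_equal(a$p, b$p, tolerance = 1e-12)
  }
  expect_true(two_proportion_z(0, 10, 0, 15)$degenerate)
  expect_true(two_proportion_z(10, 10, 15, 15)$degenerate)
})

test_that("two-proportion z null rejection rate agrees with binomial Monte Carlo", {
  set.seed(41)
  n <- 50
  k1 <- rbinom(2000, n, 0.5); k2 <- rbinom(2000, n, 0.5)
  rej <- mapply(function(a, b) two_proportion_z(a, n, b, n)$p < 0.05, k1, k2)
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})

test_that("per-cell DA scoring uses an inclusive threshold", {
  mk <- function(d) list(normalized_difference = d, weaker_homolog = "A")
  expect_true(score_cell_da(mk(0.5), 0.3)$da)
  expect_true(score_cell_da(mk(0.3), 0.3)$da)
  expect_false(score_cell_da(mk(0.1), 0.3)$da)
})

test_that("locus summary calls DA for a consistent high-fraction cohort", {
  cells <- data.frame(
    normalized_difference = c(rep(0.6, 40), rep(0.1, 10)),
    weaker_homolog = c(rep("A", 40), rep("B", 10)))
  res <- summarize_locus(cells, da_config(), "locus1")
  expect_identical(res$n_da_cells, 40L)
  expect_equal(res$da_fraction, 0.8)
  expect_identical(res$consistent_weaker_homolog, "A")
  # z against a 0.5 pseudo-cohort of equal size, hand-checked
  zt <- two_proportion_z(40, 50, 25, 50)
  expect_equal(res$z_vs_null, zt$z, tolerance = 1e-12)
  expect_lt(res$p_value, 0.05)
  expect_true(res$da_call)
})

test_that("locus summary withholds or refuses calls appropriately", {
  none <- data.frame(normalized_difference = rep(0.1, 50),
                     weaker_homolog = rep("A", 50))
  res0 <- summarize_locus(none, da_config())
  expect_equal(res0$da_fraction, 0)
  expect_false(res0$da_call)

  # 35/50 flagged but split 18/17: direction mixed, no call
  mixed <- data.frame(
    normalized_difference = c(rep(0.6, 35), rep(0.1, 15)),
    weaker_homolog = c(rep("A", 18), rep("B", 17), rep("A", 15)))
  resm <- summarize_locus(mixed, da_config())
  expect_identical(resm$consistent_weaker_homolog, "mixed")
  expect_false(resm$da_call)

  # below the cohort floor: underpowered, call withheld
  tiny <- data.frame(normalized_difference = rep(0.6, 5),
                     weaker_homolog = rep("A", 5))
  rest <- summarize_locus(tiny, da_config())
  expect_true(rest$underpowered)
  expect_true(is.na(rest$da_call))
})

test_that("pre/post comparison signs reductions negative and reports delta-mu", {
  pre <- data.frame(normalized_difference = c(rep(0.7, 42), rep(0.1, 8)),
                    weaker_homolog = c(rep("A", 42), rep("B", 8)))
  post <- data.frame(normalized_difference = c(rep(0.6, 6), rep(0.12, 44)),
                     weaker_homolog = c(rep("A", 6), rep("B", 44)))
  cmp <- compare_pre_post(pre, post, da_config(), "locus1")
  expect_lt(cmp$z_pre_post, -2)
  expect_true(cmp$significant_reduction)
  expect_gt(cmp$delta_mu_pre, cmp$delta_mu_post)
  expect_equal(cmp$delta_mu_pre, mean(pre$normalized_difference))
  expect_lt(cmp$t_p_value, 0.05)

  # identical cohorts: z = 0, no reduction, t = 0
  same <- compare_pre_post(pre, pre, da_config())
  expect_identical(same$z_pre_post, 0)
  expect_false(same$significant_reduction)
  expect_equal(same$t_statistic, 0)

  expect_error(compare_pre_post(pre, pre[1:3, ], da_config()),
               class = "fishda_error_cohort_floor")
})

test_that("pre/post reduction is detected reliably at the spec power point", {
  # truth DA fractions 0.85 pre vs 0.15 post, n = 50 each, 500 simulations
  set.seed(61)
  hits <- 0L
  for (i in 1:500) {
    k_pre <- rbinom(1, 50, 0.85)
    k_post <- rbinom(1, 50, 0.15)
    pre <- data.frame(
      normalized_difference = c(rep(0.7, k_pre), rep(0.1, 50 - k_pre)),
      weaker_homolog = rep("A", 50))
    post <- data.frame(
      normalized_difference = c(rep(0.7, k_post), rep(0.1, 50 - k_post)),
      weaker_homolog = rep("A", 50))
    cmp <- compare_pre_post(pre, post, da_config())
    hits <- hits + cmp$significant_reduction
  }
  expect_gt(hits / 500, 0.95)
})

test_that("locus-level calls recover the simulated regime from cohort truth", {
  # statistic-level end-to-end: cohorts built from generator truth
  tmpl <- scene_spec()
  errors_da <- 0L; errors_null <- 0L
  for (i in 1:200) {
    cd <- generate_cohort(cohort_spec(n_cells = 50, fraction_da_cells = 0.85,
                                      seed = 3000L + i), tmpl)
    res <- summarize_locus(measurements_from_truth(cd$truth), da_config())
    if (!isTRUE(res$da_call)) errors_da <- errors_da + 1L
    cd0 <- generate_cohort(cohort_spec(n_cells = 50, fraction_da_cells = 0.1,
                                       seed = 7000L + i), tmpl)
    res0 <- summarize_locus(measurements_from_truth(cd0$truth), da_config())
    if (isTRUE(res0$da_call)) errors_null <- errors_null + 1L
  }
  expect_lt(errors_da / 200, 0.05)
  expect_lt(errors_null / 200, 0.05)
})

test_that("Welch t matches the textbook oracle", {
  # {1,2,3} vs {4,5,6}: t = -3 / sqrt(2/3), Satterthwaite df = 4
  res <- welch_t_two_tailed(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(res$df, 4, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-12)

  same <- welch_t_two_tailed(c(2, 2, 2), c(2, 2, 2))
  expect_identical(same$t, 0)
  expect_identical(same$p, 1)
  expect_error(welch_t_two_tailed(1, c(1, 2)))
})

test_that("one-way ANOVA matches the hand-computed sum of squares", {
  # groups {1,2,3},{4,5,6},{7,8,9}: SSB = 54 (df 2), SSW = 6 (df 6), F = 27
  res <- one_way_anova(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(res$F, 27, tolerance = 1e-10)
  expect_identical(res$df_between, 2)
  expect_identical(res$df_within, 6)
  expect_equal(res$p, pf(27, 2, 6, lower.tail = FALSE), tolerance = 1e-12)

  same <- one_way_anova(list(c(1, 1), c(1, 1)))
  expect_identical(same$F, 0)
  expect_identical(same$p, 1)
  expect_error(one_way_anova(list(c(1, 2))))
})

test_that("Pearson r matches hand computation and handles edge cases", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_r(x, 2 * x + 1), 1, tolerance = 1e-12)
  expect_equal(pearson_r(x, -x), -1, tolerance = 1e-12)
  # hand-computed 5-point sample: cov terms sum 10, sx2 = 10, sy2 = 14.8
  y <- c(2, 1, 4, 3, 6)
  expect_equal(pearson_r(x, y), 10 / sqrt(10 * 14.8), tolerance = 1e-12)
  expect_error(pearson_r(x, rep(1, 5)), class = "fishda_error_variance")
})
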