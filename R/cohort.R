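# Cohorts of synthetic cells for one locus.
#
# A cohort mixes DA cells (large, directionally consistent inter-homolog
# asymmetry) with null cells (small asymmetry, random direction), emulating
# the per-locus metaphase-cell cohorts scored in practice. The per-cell true
# normalized difference d fixes the pair of peak amplitudes through
# (A_bright - A_dim) / (A_bright + A_dim) = d at a fixed amplitude sum.

#' Describe a distribution on [0, 1] for per-cell true differences
#'
#' Supported families: `"uniform"` (`min`, `max`), `"beta"` (`shape1`,
#' `shape2`) and `"constant"` (`value`).
#'
#' @param family Distribution family name.
#' @param ... Family parameters (see above).
#' @return An object of class `"difference_distribution"`.
#' @export
difference_distribution <- function(family = c("uniform", "beta", "constant"), ...) {
  family <- match.arg(family)
  pars <- list(...)
  d <- switch(family,
    uniform = {
      stopifnot(is_number(pars$min), is_number(pars$max),
                pars$min >= 0, pars$max <= 1, pars$min <= pars$max)
      list(family = "uniform", min = pars$min, max = pars$max)
    },
    beta = {
      stopifnot(is_number(pars$shape1), is_number(pars$shape2),
                pars$shape1 > 0, pars$shape2 > 0)
      list(family = "beta", shape1 = pars$shape1, shape2 = pars$shape2)
    },
    constant = {
      stopifnot(is_number(pars$value), pars$value >= 0, pars$value <= 1)
      list(family = "constant", value = pars$value)
    }
  )
  structure(d, class = "difference_distribution")
}

#' @noRd
draw_differences <- function(dist, n) {
  switch(dist$family,
    uniform = stats::runif(n, dist$min, dist$max),
    beta = stats::rbeta(n, dist$shape1, dist$shape2),
    constant = rep(dist$value, n)
  )
}

#' @noRd
distribution_mean <- function(dist) {
  switch(dist$family,
    uniform = (dist$min + dist$max) / 2,
    beta = dist$shape1 / (dist$shape1 + dist$shape2),
    constant = dist$value
  )
}

#' Specify a synthetic per-locus cell cohort
#'
#' @param n_cells Number of cells.
#' @param fraction_da_cells Proportion of cells drawn from the DA regime.
#' @param da_difference_distribution,null_difference_distribution
#'   [difference_distribution()] objects for the true normalized difference
#'   of DA and null cells respectively.
#' @param consistent_weaker_homolog `"A"` or `"B"`: the homolog carrying the
#'   dimmer spot in every DA cell (directional consistency).
#' @param seed Integer seed for the cohort draw and all per-cell renders.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_cells = 50L, fraction_da_cells = 0.85,
                        da_difference_distribution =
                          difference_distribution("uniform", min = 0.4, max = 0.9),
                        null_difference_distribution =
                          difference_distribution("uniform", min = 0, max = 0.2),
                        consistent_weaker_homolog = c("A", "B"),
                        seed = 1L) {
  consistent_weaker_homolog <- match.arg(consistent_weaker_homolog)
  stopifnot(is_count(n_cells, 1),
            is_number(fraction_da_cells),
            fraction_da_cells >= 0, fraction_da_cells <= 1,
            inherits(da_difference_distribution, "difference_distribution"),
            inherits(null_difference_distribution, "difference_distribution"))
  structure(list(
    n_cells = as.integer(n_cells),
    fraction_da_cells = fraction_da_cells,
    da_difference_distribution = da_difference_distribution,
    null_difference_distribution = null_difference_distribution,
    consistent_weaker_homolog = consistent_weaker_homolog,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Generate a cohort of synthetic cells with ground truth
#'
#' Each cell's true difference d is drawn from the DA or null distribution
#' according to `fraction_da_cells`; amplitudes are set to
#' `A_sum * (1 +/- d) / 2` where `A_sum` is the template's amplitude sum.
#' DA cells place the dim spot on `consistent_weaker_homolog`; null cells
#' assign the weaker side at random. Per-cell render seeds are drawn from the
#' cohort seed, so the whole cohort is reproducible.
#'
#' @param cohort A [cohort_spec()].
#' @param scene_template A [scene_spec()] providing geometry, background,
#'   spot sigma and the amplitude sum (`amplitude_bright + amplitude_dim`).
#' @return List with `cells` (list of per-cell `scene_spec`s) and `truth`
#'   (data.frame: cell_id, is_da, d_true, amplitude_A, amplitude_B,
#'   weaker_true, seed).
#' @export
generate_cohort <- function(cohort, scene_template) {
  stopifnot(inherits(cohort, "cohort_spec"),
            inherits(scene_template, "scene_spec"))
  n <- cohort$n_cells
  a_sum <- scene_template$amplitude_bright + scene_template$amplitude_dim
  draws <- with_seed(cohort$seed, {
    is_da <- stats::runif(n) < cohort$fraction_da_cells
    d <- numeric(n)
    d[is_da] <- draw_differences(cohort$da_difference_distribution, sum(is_da))
    d[!is_da] <- draw_differences(cohort$null_difference_distribution, sum(!is_da))
    weaker <- ifelse(is_da, cohort$consistent_weaker_homolog,
                     sample(c("A", "B"), n, replace = TRUE))
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    list(is_da = is_da, d = d, weaker = weaker, seeds = seeds)
  })
  amp_bright <- a_sum * (1 + draws$d) / 2
  amp_dim <- a_sum * (1 - draws$d) / 2
  amp_a <- ifelse(draws$weaker == "A", amp_dim, amp_bright)
  amp_b <- ifelse(draws$weaker == "A", amp_bright, amp_dim)

  cells <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- scene_template
    # homolog A sits at spot_positions[[1]]; amplitude_bright renders there
    sp$amplitude_bright <- amp_a[i]
    sp$amplitude_dim <- amp_b[i]
    sp$seed <- draws$seeds[i]
    cells[[i]] <- sp
  }
  truth <- data.frame(
    cell_id = sprintf("cell_%03d", seq_len(n)),
    is_da = draws$is_da,
    d_true = draws$d,
    amplitude_A = amp_a,
    amplitude_B = amp_b,
    weaker_true = ifelse(draws$d < 1e-12, "none", draws$weaker),
    seed = draws$seeds,
    stringsAsFactors = FALSE
  )
  list(cells = cells, truth = truth)
}
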