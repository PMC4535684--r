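# Locus-level DA calling and the statistical tests used around it.
#
# A cell "shows DA" when its normalized inter-homolog difference meets the
# per-cell threshold (default 0.3, which separates the reported DA-locus
# regime of the statistic, medians 0.53-1, from the equal/treated regime,
# 0.08-0.27). A locus is called DA when at least two thirds of scored cells
# show DA, the weaker homolog is directionally consistent, and the DA
# fraction differs significantly from the 0.5 null (two-proportion z-test).
# Pre/post-treatment comparisons use the same z-test signed so reductions
# are negative, with z < -2.0 declaring a significant reduction.

#' DA-calling configuration
#'
#' @param per_cell_threshold Normalized difference at or above which a cell
#'   is scored as showing DA.
#' @param min_cells Cohort floor below which a locus is marked underpowered
#'   and no call is made.
#' @param da_fraction_threshold Locus-level DA fraction criterion
#'   (inclusive); default exactly 2/3.
#' @param consistency_fraction Minimum share of flagged cells that must
#'   agree on the weaker homolog; otherwise direction is "mixed".
#' @param alpha Significance level.
#' @param null_proportion Null DA proportion for the single-locus test.
#' @param reduction_z Signed z cutoff declaring a significant pre/post
#'   reduction.
#' @return An object of class `"da_config"`.
#' @export
da_config <- function(per_cell_threshold = 0.3, min_cells = 10L,
                      da_fraction_threshold = 2 / 3,
                      consistency_fraction = 0.75, alpha = 0.05,
                      null_proportion = 0.5, reduction_z = -2.0) {
  stopifnot(is_number(per_cell_threshold), per_cell_threshold >= 0,
            is_count(min_cells, 1), is_number(da_fraction_threshold),
            is_number(consistency_fraction), is_number(alpha),
            alpha > 0, alpha < 1, is_number(null_proportion),
            null_proportion > 0, null_proportion < 1)
  structure(list(per_cell_threshold = per_cell_threshold,
                 min_cells = as.integer(min_cells),
                 da_fraction_threshold = da_fraction_threshold,
                 consistency_fraction = consistency_fraction,
                 alpha = alpha, null_proportion = null_proportion,
                 reduction_z = reduction_z),
            class = "da_config")
}

#' Two-proportion z-test (pooled variance)
#'
#' `z = (k1/n1 - k2/n2) / sqrt(p(1-p)(1/n1 + 1/n2))` with the pooled
#' estimate `p = (k1+k2)/(n1+n2)`; two-sided p from the standard normal.
#' A degenerate pool (`p` of 0 or 1) carries no evidence either way and is
#' returned as `z = 0` with `degenerate = TRUE`.
#'
#' @param k1,n1,k2,n2 Successes and sizes of the two cohorts; `k` may be
#'   fractional when testing against a hypothetical proportion.
#' @return List with `z`, `p`, `degenerate`.
#' @export
two_proportion_z <- function(k1, n1, k2, n2) {
  stopifnot(is_number(k1), is_number(n1), is_number(k2), is_number(n2),
            n1 > 0, n2 > 0, k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2)
  pool <- (k1 + k2) / (n1 + n2)
  if (pool <= 0 || pool >= 1) {
    return(list(z = 0, p = 1, degenerate = TRUE))
  }
  se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  z <- (k1 / n1 - k2 / n2) / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)), degenerate = FALSE)
}

#' Score one cell for DA
#'
#' @param measurement One-row data.frame from [measure_cell()] (or any list
#'   with `normalized_difference` and `weaker_homolog`).
#' @param per_cell_threshold Inclusive threshold on the normalized
#'   difference.
#' @return List with `da` (flag) and `weaker_homolog`.
#' @export
score_cell_da <- function(measurement, per_cell_threshold = 0.3) {
  d <- measurement$normalized_difference
  stopifnot(is_number(d), d >= 0, d <= 1)
  list(da = d >= per_cell_threshold,
       weaker_homolog = measurement$weaker_homolog)
}

#' Summarize a locus over its cell cohort
#'
#' Computes the DA fraction, the majority weaker-homolog direction among
#' flagged cells ("mixed" unless one side exceeds `consistency_fraction` of
#' them), a two-proportion z-test of the DA fraction against the null
#' proportion with an equal-size pseudo-cohort, and the locus DA call
#' (fraction >= 2/3, p < alpha, direction not mixed).
#'
#' @param cells data.frame of per-cell measurements with columns
#'   `normalized_difference` and `weaker_homolog`.
#' @param config [da_config()].
#' @param locus_id Identifier carried into the result.
#' @return An object of class `"locus_da_result"` (also a list):
#'   locus_id, n_cells, n_da_cells, da_fraction, consistent_weaker_homolog,
#'   z_vs_null, p_value, da_call, underpowered, delta_mu.
#' @export
summarize_locus <- function(cells, config = da_config(), locus_id = NA_character_) {
  stopifnot(is.data.frame(cells), inherits(config, "da_config"))
  n <- nrow(cells)
  flags <- cells$normalized_difference >= config$per_cell_threshold
  k <- sum(flags)
  frac <- if (n > 0) k / n else NA_real_
  weaker <- cells$weaker_homolog[flags]
  n_a <- sum(weaker == "A"); n_b <- sum(weaker == "B")
  direction <- if (k == 0) {
    "mixed"
  } else if (n_a > config$consistency_fraction * k) {
    "A"
  } else if (n_b > config$consistency_fraction * k) {
    "B"
  } else {
    "mixed"
  }
  underpowered <- n < config$min_cells
  zt <- two_proportion_z(k, n, config$null_proportion * n, n)
  call <- !underpowered &&
    frac >= config$da_fraction_threshold &&
    zt$p < config$alpha &&
    direction != "mixed"
  structure(list(
    locus_id = locus_id, n_cells = n, n_da_cells = k, da_fraction = frac,
    consistent_weaker_homolog = direction,
    z_vs_null = zt$z, p_value = zt$p,
    da_call = if (underpowered) NA else call,
    underpowered = underpowered,
    delta_mu = mean(cells$normalized_difference)
  ), class = "locus_da_result")
}

#' @export
print.locus_da_result <- function(x, ...) {
  cat(sprintf(
    "<locus_da_result> %s: %d/%d cells DA (%.1f%%), direction %s, z = %.2f, p = %.3g, call = %s\n",
    x$locus_id, x$n_da_cells, x$n_cells, 100 * x$da_fraction,
    x$consistent_weaker_homolog, x$z_vs_null, x$p_value,
    if (is.na(x$da_call)) "underpowered" else x$da_call))
  invisible(x)
}

#' Compare a locus pre- vs post-treatment
#'
#' Two-proportion z on the DA-cell counts, signed so that a reduction after
#' treatment is negative (`z < -2.0` declares significant reduction), plus
#' the group mean normalized differences (delta-mu) and a two-tailed Welch
#' t-test on the per-cell differences.
#'
#' @param pre_cells,post_cells Per-cell measurement data.frames.
#' @param config [da_config()].
#' @param locus_id Identifier.
#' @return An object of class `"treatment_comparison"` with fields pre,
#'   post, z_pre_post, p_pre_post, significant_reduction, delta_mu_pre,
#'   delta_mu_post, t_statistic, t_df, t_p_value.
#' @export
compare_pre_post <- function(pre_cells, post_cells, config = da_config(),
                             locus_id = NA_character_) {
  stopifnot(is.data.frame(pre_cells), is.data.frame(post_cells))
  if (nrow(pre_cells) < config$min_cells || nrow(post_cells) < config$min_cells) {
    fishda_stop("both cohorts must meet the cell-count floor",
                "fishda_error_cohort_floor")
  }
  pre <- summarize_locus(pre_cells, config, locus_id)
  post <- summarize_locus(post_cells, config, locus_id)
  # post as cohort 1 makes a post-treatment reduction negative
  zt <- two_proportion_z(post$n_da_cells, post$n_cells,
                         pre$n_da_cells, pre$n_cells)
  tt <- welch_t_two_tailed(pre_cells$normalized_difference,
                           post_cells$normalized_difference)
  structure(list(
    locus_id = locus_id, pre = pre, post = post,
    z_pre_post = zt$z, p_pre_post = zt$p,
    significant_reduction = zt$z < config$reduction_z,
    delta_mu_pre = pre$delta_mu, delta_mu_post = post$delta_mu,
    t_statistic = tt$t, t_df = tt$df, t_p_value = tt$p
  ), class = "treatment_comparison")
}

#' @export
print.treatment_comparison <- function(x, ...) {
  cat(sprintf(
    paste0("<treatment_comparison> %s: DA %.1f%% -> %.1f%%, z = %.2f ",
           "(significant reduction: %s); delta-mu %.3f -> %.3f, t = %.2f, p = %.3g\n"),
    x$locus_id, 100 * x$pre$da_fraction, 100 * x$post$da_fraction,
    x$z_pre_post, x$significant_reduction,
    x$delta_mu_pre, x$delta_mu_post, x$t_statistic, x$t_p_value))
  invisible(x)
}

#' Two-tailed Welch t-test
#'
#' Unequal-variance t with Satterthwaite degrees of freedom. Two constant,
#' equal samples return `t = 0, p = 1`.
#'
#' @param sample1,sample2 Numeric vectors, each of length >= 2.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t_two_tailed <- function(sample1, sample2) {
  stopifnot(is.numeric(sample1), is.numeric(sample2),
            length(sample1) >= 2, length(sample2) >= 2,
            all(is.finite(sample1)), all(is.finite(sample2)))
  v1 <- stats::var(sample1); v2 <- stats::var(sample2)
  if (v1 == 0 && v2 == 0) {
    if (mean(sample1) == mean(sample2)) {
      return(list(t = 0, df = length(sample1) + length(sample2) - 2, p = 1))
    }
    return(list(t = sign(mean(sample1) - mean(sample2)) * Inf,
                df = length(sample1) + length(sample2) - 2, p = 0))
  }
  ht <- stats::t.test(sample1, sample2, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Classical one-way ANOVA
#'
#' @param groups List of >= 2 numeric samples, each of length >= 2.
#' @return List with `F`, `df_between`, `df_within`, `p`.
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  lapply(groups, function(g) stopifnot(is.numeric(g), length(g) >= 2,
                                       all(is.finite(g))))
  values <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  df_b <- length(groups) - 1L
  df_w <- length(values) - length(groups)
  within_ss <- sum(vapply(groups, function(x) sum((x - mean(x))^2), 0))
  if (within_ss == 0) {
    means <- vapply(groups, mean, 0)
    if (max(means) == min(means)) {
      return(list(F = 0, df_between = df_b, df_within = df_w, p = 1))
    }
    return(list(F = Inf, df_between = df_b, df_within = df_w, p = 0))
  }
  ht <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(F = unname(ht$statistic), df_between = unname(ht$parameter[1]),
       df_within = unname(ht$parameter[2]), p = ht$p.value)
}

#' Pearson correlation
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return Sample correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            length(x) >= 3, all(is.finite(x)), all(is.finite(y)))
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    fishda_stop("zero variance: correlation undefined", "fishda_error_variance")
  }
  stats::cor(x, y)
}
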