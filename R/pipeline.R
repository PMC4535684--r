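# End-to-end pipeline over synthetic pre/post cohorts.
#
# simulate -> detect/segment -> quantify -> call DA, with every per-cell
# failure recorded once in a QC log (reason code) while the locus statistics
# are computed on the surviving cells. Identical config + seeds give
# byte-identical result tables.

#' Pipeline run configuration
#'
#' @param locus_id Locus label used in all outputs.
#' @param scene_template [scene_spec()] shared by all cells.
#' @param pre_cohort,post_cohort [cohort_spec()]s for the untreated and
#'   treated cohorts (`post_cohort = NULL` runs a single cohort).
#' @param seg [seg_config()].
#' @param da [da_config()].
#' @param output_dir Directory for result tables; `NULL` keeps results in
#'   memory only.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(locus_id = "locus", scene_template = scene_spec(),
                       pre_cohort = cohort_spec(seed = 1L),
                       post_cohort = NULL,
                       seg = seg_config(spot_sigma = scene_template$spot_sigma_xy),
                       da = da_config(), output_dir = NULL) {
  stopifnot(inherits(scene_template, "scene_spec"),
            inherits(pre_cohort, "cohort_spec"),
            is.null(post_cohort) || inherits(post_cohort, "cohort_spec"),
            inherits(seg, "seg_config"), inherits(da, "da_config"))
  structure(list(locus_id = locus_id, scene_template = scene_template,
                 pre_cohort = pre_cohort, post_cohort = post_cohort,
                 seg = seg, da = da, output_dir = output_dir),
            class = "run_config")
}

#' Process one simulated cohort: render, segment, quantify
#'
#' @param cohort_data Output of [generate_cohort()].
#' @param seg [seg_config()].
#' @param locus_id Locus label.
#' @param group Group label recorded in the measurement table.
#' @return List with `measurements` (data.frame of surviving cells), `qc`
#'   (data.frame cell_id, stage, reason for excluded cells) and `truth`.
#' @export
process_cohort <- function(cohort_data, seg = seg_config(),
                           locus_id = "locus", group = "pre") {
  meas_rows <- list()
  qc_rows <- list()
  for (i in seq_along(cohort_data$cells)) {
    cell_id <- cohort_data$truth$cell_id[i]
    scene <- render_scene_2d(cohort_data$cells[[i]])
    res <- tryCatch(
      segment_and_measure_cell(scene$probe_image, seg,
                               cell_id = cell_id, locus_id = locus_id),
      fishda_error = function(e) e
    )
    if (inherits(res, "fishda_error")) {
      qc_rows[[length(qc_rows) + 1L]] <- data.frame(
        cell_id = cell_id, stage = class(res)[1],
        reason = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      m <- res$measurement
      m$group <- group
      meas_rows[[length(meas_rows) + 1L]] <- m
    }
  }
  empty_meas <- data.frame(cell_id = character(), locus_id = character(),
                           intensity_A = numeric(), intensity_B = numeric(),
                           normalized_difference = numeric(),
                           weaker_homolog = character(), group = character(),
                           stringsAsFactors = FALSE)
  list(
    measurements = if (length(meas_rows)) do.call(rbind, meas_rows) else empty_meas,
    qc = if (length(qc_rows)) {
      do.call(rbind, qc_rows)
    } else {
      data.frame(cell_id = character(), stage = character(),
                 reason = character(), stringsAsFactors = FALSE)
    },
    truth = cohort_data$truth
  )
}

#' Run the full pipeline on a configuration
#'
#' @param config [run_config()].
#' @return List with `measurements`, `qc`, `locus_pre`, `locus_post`,
#'   `comparison` (NULL without a post cohort), `truth` and `report`
#'   (character vector). Tables are also written to `config$output_dir`
#'   when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  pre_data <- generate_cohort(config$pre_cohort, config$scene_template)
  pre <- process_cohort(pre_data, config$seg, config$locus_id, "pre")

  post <- NULL
  if (!is.null(config$post_cohort)) {
    post_data <- generate_cohort(config$post_cohort, config$scene_template)
    post <- process_cohort(post_data, config$seg, config$locus_id, "post")
  }

  measurements <- if (is.null(post)) {
    pre$measurements
  } else {
    rbind(pre$measurements, post$measurements)
  }
  qc <- if (is.null(post)) pre$qc else rbind(pre$qc, post$qc)

  locus_pre <- if (nrow(pre$measurements) > 0) {
    summarize_locus(pre$measurements, config$da, config$locus_id)
  } else {
    NULL
  }
  locus_post <- if (!is.null(post) && nrow(post$measurements) > 0) {
    summarize_locus(post$measurements, config$da, config$locus_id)
  } else {
    NULL
  }
  comparison <- if (!is.null(locus_pre) && !is.null(locus_post) &&
                    !locus_pre$underpowered && !locus_post$underpowered) {
    compare_pre_post(pre$measurements, post$measurements, config$da,
                     config$locus_id)
  } else {
    NULL
  }

  report <- c(
    sprintf("locus: %s", config$locus_id),
    sprintf("cells measured: %d (excluded by QC: %d)",
            nrow(measurements), nrow(qc)),
    if (!is.null(locus_pre)) sprintf(
      "pre:  %d/%d cells DA (%.1f%%), direction %s, z = %.3f, p = %.4g, call = %s",
      locus_pre$n_da_cells, locus_pre$n_cells, 100 * locus_pre$da_fraction,
      locus_pre$consistent_weaker_homolog, locus_pre$z_vs_null,
      locus_pre$p_value, format(locus_pre$da_call)),
    if (!is.null(locus_post)) sprintf(
      "post: %d/%d cells DA (%.1f%%), direction %s, z = %.3f, p = %.4g, call = %s",
      locus_post$n_da_cells, locus_post$n_cells, 100 * locus_post$da_fraction,
      locus_post$consistent_weaker_homolog, locus_post$z_vs_null,
      locus_post$p_value, format(locus_post$da_call)),
    if (!is.null(comparison)) sprintf(
      "pre/post: z = %.3f (significant reduction: %s), delta-mu %.3f -> %.3f, t = %.3f (p = %.4g)",
      comparison$z_pre_post, comparison$significant_reduction,
      comparison$delta_mu_pre, comparison$delta_mu_post,
      comparison$t_statistic, comparison$t_p_value),
    if (nrow(measurements) == 0) "warning: all cells failed QC; locus table empty"
  )

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(measurements, file.path(config$output_dir, "measurements.tsv"))
    write_tsv(qc, file.path(config$output_dir, "qc_log.tsv"))
    locus_df <- do.call(rbind, lapply(
      Filter(Negate(is.null), list(pre = locus_pre, post = locus_post)),
      function(l) data.frame(
        locus_id = l$locus_id, n_cells = l$n_cells, n_da_cells = l$n_da_cells,
        da_fraction = l$da_fraction,
        direction = l$consistent_weaker_homolog, z = l$z_vs_null,
        p = l$p_value, delta_mu = l$delta_mu,
        da_call = format(l$da_call), stringsAsFactors = FALSE)))
    if (!is.null(locus_df)) {
      locus_df <- cbind(group = rownames(locus_df), locus_df)
      rownames(locus_df) <- NULL
      write_tsv(locus_df, file.path(config$output_dir, "locus_results.tsv"))
    }
    writeLines(report, file.path(config$output_dir, "report.txt"))
    jsonlite::write_json(
      unclass_deep(list(locus_id = config$locus_id,
                        scene_template = config$scene_template,
                        pre_cohort = config$pre_cohort,
                        post_cohort = config$post_cohort,
                        seg = config$seg, da = config$da)),
      file.path(config$output_dir, "config.json"),
      auto_unbox = TRUE, digits = NA, null = "null")
  }

  list(measurements = measurements, qc = qc,
       locus_pre = locus_pre, locus_post = locus_post,
       comparison = comparison,
       truth = if (is.null(post)) pre$truth else
         rbind(cbind(pre$truth, group = "pre"),
               cbind(post$truth, group = "post")),
       report = report)
}
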