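#!/usr/bin/env Rscript
# Locus-level DA statistics on the quantified cohorts: per-locus DA fraction
# and call (two-thirds criterion, directional consistency, two-proportion z
# against the 0.5 null), the pre/post comparison (z signed so reductions are
# negative; z < -2 flags significant reduction), group mean differences
# (delta-mu) and the Welch t-test on per-cell differences. Reads
# results/measurements.tsv from 02_segment_quantify.R.

suppressMessages(library(fishda))
results_dir <- "results"
meas_path <- file.path(results_dir, "measurements.tsv")
if (!file.exists(meas_path)) {
  stop("run analysis/02_segment_quantify.R first (missing ", meas_path, ")")
}
measurements <- read_tsv(meas_path)
pre <- measurements[measurements$group == "pre", ]
post <- measurements[measurements$group == "post", ]

cfg <- da_config()
locus_pre <- summarize_locus(pre, cfg, "locus_sim")
locus_post <- summarize_locus(post, cfg, "locus_sim")
cmp <- compare_pre_post(pre, post, cfg, "locus_sim")

print(locus_pre)
print(locus_post)
print(cmp)

write_tsv(data.frame(
  locus_id = "locus_sim",
  n_pre = locus_pre$n_cells, frac_pre = locus_pre$da_fraction,
  n_post = locus_post$n_cells, frac_post = locus_post$da_fraction,
  z = cmp$z_pre_post, p = cmp$p_pre_post,
  delta_mu_pre = cmp$delta_mu_pre, delta_mu_post = cmp$delta_mu_post,
  t = cmp$t_statistic, p_t = cmp$t_p_value,
  significant_reduction = cmp$significant_reduction,
  call_pre = format(locus_pre$da_call), call_post = format(locus_post$da_call)),
  file.path(results_dir, "locus_comparison.tsv"))

# box plot of per-cell normalized differences, pre vs post
png(file.path(results_dir, "fig_intensity_ratios.png"), 600, 500)
boxplot(normalized_difference ~ group,
        data = transform(measurements,
                         group = factor(group, c("pre", "post"))),
        ylab = "normalized inter-homolog difference",
        main = "Per-cell intensity asymmetry, untreated vs treated")
abline(h = cfg$per_cell_threshold, lty = 2)
dev.off()

cat("locus comparison table and figure written to", results_dir, "\n")
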