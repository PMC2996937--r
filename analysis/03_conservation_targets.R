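#!/usr/bin/env Rscript
# Stage 3: conservation and target-site conservation of the novel
# candidates — mean per-base conservation against the composition-matched
# intron/intergenic background, seed families, the binomial excess/deficit
# test against scrambled-seed controls, motif rank scores, and the
# family-proportion simulations. Writes tables under results/03_targets/.

suppressPackageStartupMessages(library(smallmir))

out <- "results/03_targets"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
res <- if (file.exists("results/pipeline_run.rds")) {
  readRDS("results/pipeline_run.rds")
} else {
  run_pipeline(pipeline_config())
}
r <- res$report

verd <- res$novel[, c("name", "mature_seq", "mean_conservation",
                      "conserved", "ncrna_derived")]
write.table(verd, file.path(out, "conservation_verdicts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
bg <- res$conservation_background
write.table(
  data.frame(bin = sprintf("[%.1f,%.1f)", 0:9 / 10, 1:10 / 10),
             observed = bg$observed_bins,
             background_mean = colMeans(bg$bin_counts),
             ci_lo = bg$bin_ci[1, ], ci_hi = bg$bin_ci[2, ]),
  file.path(out, "conservation_background.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)
ranked <- rank_score(res$motif_table)
write.table(ranked[order(-ranked$rank_score), ][1:200, ],
            file.path(out, "motif_rank_scores_top200.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
for (side in c("main", "ncrna")) {
  tt <- res$target_tests[[side]]
  if (!is.null(tt)) {
    write.table(tt$results,
                file.path(out, paste0("target_tests_", side, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
}

cat(sprintf(
  "%d of %d putative novel miRNA are conserved (mean score >= 0.8);
%.1f would be expected from the composition-matched background
(empirical p = %.3g).\n",
  r$n_conserved_novel, r$n_novel, r$expected_conserved,
  r$p_conserved_excess))
tt <- res$target_tests$main
if (!is.null(tt)) {
  cat(sprintf(
    "Of %d testable seed families, %.1f%% show a conserved target-site
excess versus %.1f%% in %d seed simulations (p = %.3g); deficit side:
%.1f%% observed vs %.1f%% background.\n",
    tt$n_testable, 100 * tt$observed_excess, 100 * tt$background_excess,
    tt$n_sim, tt$p_excess, 100 * tt$observed_deficit,
    100 * tt$background_deficit))
}
cat(sprintf(
  "Planted-seed recovery: %.0f%% of enriched seeds called excess, %.0f%%
of avoided seeds called deficit.\n",
  100 * r$excess_seed_sensitivity, 100 * r$deficit_seed_sensitivity))
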