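#!/usr/bin/env Rscript

# Step 2: per-voxel activation statistics and volume-of-activation tables.
#
# For every subject: detrending (no spatial smoothing at desk scale; see
# the methods vignette), percent change against the scan 1-50 baseline,
# per-voxel Welch t over the 51-350 stimulation window,
# the rank-based step-up filter at q = 0.2 over the in-brain voxels, and
# per-region positive/negative activated-voxel counts at the 1% threshold.
# Counts are then compared across dose groups region-by-region with
# Kruskal-Wallis tests, producing the four ranked tables (positive and
# negative arms, vehicle vs each dose) with their descriptive FDR critical
# values. Takes a few minutes at the default scale.

suppressMessages(library(phbold))

cfg <- default_config(out_dir = "scratch/pipeline", seed = 1L)
res <- run_pipeline(cfg, "voa")

dir.create("results", showWarnings = FALSE)
truth <- res$effect$effects
for (key in names(res$voa)) {
  vt <- res$voa[[key]]
  out <- file.path("results", paste0(key, ".tsv"))
  utils::write.table(vt$table, out, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  planted <- if (vt$arm == "negative") {
    truth$region_id[truth$sign == "negative"]
  } else truth$region_id[truth$sign == "positive"]
  hits <- intersect(vt$table$region_id, planted)
  cat(sprintf(
    "%s: %d/%d regions significant (FDR P = %.3f); %d/%d planted recovered, %d false -> %s\n",
    key, nrow(vt$table), vt$n_regions_tested, vt$fdr_critical_rounded,
    length(hits), length(planted), nrow(vt$table) - length(hits), out))
}

counts <- res$counts
utils::write.table(
  counts[, c("subject_id", "region_id", "positive_count", "negative_count")],
  "results/voxel_counts.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
tot <- tapply(counts$negative_count, list(counts$subject_id), sum)
gm <- tapply(tot, res$roster$subjects$group[
  match(names(tot), res$roster$subjects$subject_id)], median)
cat("\nMedian total negative-voxel count per group (dose-response):\n")
print(gm[c("Veh", "LSD10", "LSD100")])
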