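#!/usr/bin/env Rscript

# Step 1: generate the synthetic study.
#
# Builds the desk-scale phantom cohort: a 173-region atlas on a 20x20x12
# grid, 31 subjects (10 Veh / 9 LSD10 / 12 LSD100), each with a 350-scan
# TR 6 s phMRI session (32 regions ramp to a -3% plateau after the
# injection at scan 50, 6 regions to +2%, scaled 0 / 0.4 / 1 by dose
# group). Volumes are written under scratch/phantom; the ground-truth
# sidecar records exactly what was planted.

suppressMessages(library(phbold))

cfg <- default_config(out_dir = "scratch/phantom", seed = 1L)
res <- run_pipeline(cfg, "simulate")

cat("\nAtlas:\n")
print(res$atlas)
cat(sprintf("Subjects simulated: %d (%s)\n", nrow(res$roster$subjects),
            paste(sprintf("%s n=%d", names(table(res$roster$subjects$group)),
                          table(res$roster$subjects$group)),
                  collapse = ", ")))
cat(sprintf("Planted effects: %d negative regions at -%g%%, %d positive at +%g%%\n",
            sum(res$effect$effects$sign == "negative"),
            res$effect$effects$magnitude_pct[1],
            sum(res$effect$effects$sign == "positive"),
            res$effect$effects$magnitude_pct[
              match("positive", res$effect$effects$sign)]))
cat("Ground truth written to scratch/phantom/ground_truth.json\n")
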