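#!/usr/bin/env Rscript
# Step 4: per-measure SVM classification over a sensor x context grid.
#
# Pools the three sessions, then sweeps each measure's own-sensor and
# all-sensor combinations over three context sizes (a reduced grid that
# keeps the run to a few minutes; the full 132-cell sweep is the same call
# with the default combos/configs). Reports micro-F1 against the trivial
# majority-class baseline and the per-measure peaks.

suppressPackageStartupMessages(library(bitewatch))

fp <- list.files("scratch", pattern = "_features\\.rds$", full.names = TRUE)
if (!length(fp)) stop("run analysis/02_extract_features.R first")
feats <- lapply(fp, readRDS)

combos <- list(eating_gesture = c("S", "SPR"),
               chewing = c("P", "SPR"),
               swallowing = c("R", "SPR"))
cfgs <- data.frame(past_s = c(0, 3, 7), future_s = c(0, 3, 7))
grid <- run_grid(feats, combos = combos, configs = cfgs,
                 config = model_config(n_iter = 10), seed = 1)

keep <- c("measure", "sensors", "past_s", "future_s", "n_vectors",
          "n_components", "micro_f1", "baseline_f1", "prevalence",
          "tp", "fp", "fn", "tn", "cost", "gamma", "seed")
write.csv(grid[, keep], "results/classification_results.csv",
          row.names = FALSE)
print(grid[, c("measure", "sensors", "past_s", "future_s", "micro_f1",
               "baseline_f1")])

peaks <- summarize_grid(grid)
write.csv(peaks, "results/peak_summary.csv", row.names = FALSE)
cat("\nPer-measure peaks:\n")
print(peaks)
cat("wrote results/classification_results.csv, results/peak_summary.csv\n")
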