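#!/usr/bin/env Rscript
# Step 3: fused feature-vector geometry across the context grid.
#
# For each sensing measure and each of the eleven past/future context
# configurations, assembles all-sensor vectors for one session and tabulates
# the window counts and vector lengths the fusion layout produces.

suppressPackageStartupMessages(library(bitewatch))

fp <- list.files("scratch", pattern = "_features\\.rds$", full.names = TRUE)
if (!length(fp)) stop("run analysis/02_extract_features.R first")
sf <- readRDS(fp[1])

cfgs <- context_configurations()
rows <- list()
for (ms in c("eating_gesture", "chewing", "swallowing")) {
  for (j in seq_len(nrow(cfgs))) {
    vs <- assemble_vectors(sf, ms, "SPR", cfgs$past_s[j], cfgs$future_s[j])
    rows[[length(rows) + 1L]] <- data.frame(
      measure = ms, past_s = cfgs$past_s[j], future_s = cfgs$future_s[j],
      n_windows = vs$n_windows, vector_length = ncol(vs$X),
      n_vectors = nrow(vs$X))
  }
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/vector_lengths.csv", row.names = FALSE)
print(tab)
cat(sprintf("\n3 s-3 s all-sensor layout: %d windows, %d features\n",
            tab$n_windows[tab$measure == "chewing" & tab$past_s == 3 &
                            tab$future_s == 3],
            tab$vector_length[tab$measure == "chewing" & tab$past_s == 3 &
                                tab$future_s == 3]))
cat("wrote results/vector_lengths.csv\n")
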