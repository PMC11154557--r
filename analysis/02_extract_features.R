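#!/usr/bin/env Rscript
# Step 2: preprocess, segment, and compute per-window features.
#
# Reads the sessions written by 01_simulate_sessions.R, runs the filtering /
# scaling / windowing / feature stages, and summarises the per-modality
# feature matrices and label prevalences.

suppressPackageStartupMessages(library(bitewatch))

dirs <- list.dirs("scratch/sessions", recursive = FALSE)
if (!length(dirs)) stop("run analysis/01_simulate_sessions.R first")

rows <- list()
for (d in dirs) {
  sess <- read_session(d)
  sf <- session_features(sess)
  saveRDS(sf, file.path("scratch", paste0(basename(d), "_features.rds")))
  prev <- function(tab, label) {
    mean(label_vectors(tab$windows, sf$annotations, label))
  }
  rows[[d]] <- data.frame(
    subject = sess$subject_id,
    imu_windows = nrow(sf$imu$features),
    piezo_windows = nrow(sf$piezo$features),
    rip_cycles = nrow(sf$rip$features),
    mean_cycle_s = round(mean(sf$rip$windows$t_end -
                                sf$rip$windows$t_start), 3),
    gesture_prevalence = round(prev(sf$imu, "eating_gesture"), 3),
    chewing_prevalence = round(prev(sf$piezo, "chewing"), 3),
    swallow_prevalence = round(prev(sf$rip, "swallowing"), 3))
  cat(sprintf("%s: %d IMU x 27, %d piezo x 29, %d cycles x 36\n",
              sess$subject_id, nrow(sf$imu$features),
              nrow(sf$piezo$features), nrow(sf$rip$features)))
}
summary <- do.call(rbind, c(rows, make.row.names = FALSE))
write.csv(summary, "results/feature_summary.csv", row.names = FALSE)
print(summary)
cat("wrote results/feature_summary.csv\n")
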