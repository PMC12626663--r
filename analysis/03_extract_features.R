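#!/usr/bin/env Rscript
# Step 3: extract the per-cell spectral feature table from the calibrated
# blocks: per-channel means, population SDs, skewness, and all ordered
# channel-mean ratios (3C + C(C-1) = 1224 features for 34 channels).

suppressMessages(library(spectracell))

cal_dir <- "results/calibrated"
out_csv <- "results/features.csv"

sids <- list.dirs(cal_dir, recursive = FALSE, full.names = FALSE)
sids <- setdiff(sids, "calibration_model")
blocks <- list(); labels <- list()
for (sid in sids) {
  blocks[[sid]] <- read_data_block(file.path(cal_dir, sid))
  labels[[sid]] <- attr(read_masks(file.path(cal_dir, sid, "masks.tif")),
                        "label_image")
}

features <- extract_cohort_features(blocks, labels)
write_feature_table(features, out_csv)

counts <- table(features$group_label)
cat(sprintf("extracted %d features for %d cells (%s)\n",
            length(feature_names(features)), nrow(features),
            paste(sprintf("%s: %d", names(counts), counts), collapse = ", ")))
cat("feature table written to", out_csv, "\n")
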