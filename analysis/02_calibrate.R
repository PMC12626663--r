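#!/usr/bin/env Rscript
# Step 2: fit the per-channel calibration model from the reference frames
# (background estimate, unit-mean flat field, spectrofluorometer scale) and
# calibrate every block of the simulated cohort. Writes calibrated blocks and
# the serialized calibration model.

suppressMessages(library(spectracell))

cohort_dir <- "results/cohort"
out <- "results/calibrated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cohort <- read_cohort(cohort_dir)
model <- fit_calibration(cohort$references)
write_calibration_model(model, file.path(out, "calibration_model"))

scale_range <- range(model$scale)
cat(sprintf("calibration model over %d channels; scale factors %.3g-%.3g\n",
            length(model$scale), scale_range[1], scale_range[2]))

for (sid in names(cohort$blocks)) {
  calibrated <- calibrate_block(cohort$blocks[[sid]], model)
  write_data_block(calibrated, file.path(out, sid))
  write_masks(cohort$labels[[sid]], file.path(out, sid, "masks.tif"))
}
cat(sprintf("calibrated %d blocks into %s\n", length(cohort$blocks), out))
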