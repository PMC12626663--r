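#!/usr/bin/env Rscript
# Step 4: entropy-based feature selection for each pairwise group comparison.
# Ranks every feature by threshold information gain and selects a compact
# non-redundant top-8 set per comparison. These global selections are written
# for inspection; the cross-validated classification in step 5 re-selects
# inside each training fold by default (leakage-safe), so these files describe
# the signal, they are not the CV inputs.

suppressMessages(library(spectracell))

features <- read_feature_table("results/features.csv")
groups <- sort(unique(features$group_label))
pairs <- utils::combn(groups, 2, simplify = FALSE)

for (pr in pairs) {
  tab <- restrict_classes(features, pr[1], pr[2])
  sel <- rank_and_select(tab, k = 8)
  cmp <- paste0(pr[1], "_vs_", pr[2])
  write_selection(sel, file.path("results", paste0("selection_", cmp, ".json")))
  cat(sprintf("%s: top features by information gain (bits)\n", cmp))
  top <- sel$ranking[seq_len(8), ]
  cat(sprintf("  %-34s %.3f\n", top$name, top$information_gain_bits), sep = "")
  cat(sprintf("  selected (redundancy-filtered): %s\n",
              paste(sel$selected, collapse = ", ")))
}
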