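#!/usr/bin/env Rscript
# Step 5: cross-validated binary classification for each pairwise group
# comparison: a random forest (method 1) and the logistic reference backend
# (method 2 interface), five stratified folds, per-fold feature selection.
# Writes per-comparison result JSONs, pooled ROC plots, and a summary table.

suppressMessages(library(spectracell))

seed <- as.integer(Sys.getenv("COHORT_SEED", "1"))
features <- read_feature_table("results/features.csv")
groups <- sort(unique(features$group_label))
pairs <- utils::combn(groups, 2, simplify = FALSE)

summary_rows <- list()
for (pr in pairs) {
  cmp <- paste0(pr[1], "_vs_", pr[2])
  res <- run_comparison(features, pr[1], pr[2], k = 8,
                        selection_mode = "fold",
                        classifiers = c("rf", "logistic"), seed = seed)
  for (cl in names(res)) {
    r <- res[[cl]]
    cat(sprintf("%s [%s]: mean AUC %.3f, fold variance %.4f, 95%% CI %.3f-%.3f\n",
                cmp, r$classifier_id, r$mean_auc, r$fold_variance,
                r$ci95[1], r$ci95[2]))
    summary_rows[[paste(cmp, cl)]] <- data.frame(
      comparison = cmp, classifier = r$classifier_id,
      mean_auc = r$mean_auc, fold_variance = r$fold_variance,
      ci_lo = r$ci95[1], ci_hi = r$ci95[2])
    if (cl == "rf") {
      png(file.path("results", paste0("roc_", cmp, ".png")),
          width = 480, height = 480)
      plot_roc(r)
      dev.off()
    }
  }
  jsonlite::write_json(lapply(res, function(r) {
    r <- unclass(r); r$per_fold_roc <- NULL; r
  }), file.path("results", paste0("result_", cmp, ".json")),
  auto_unbox = TRUE, digits = 10, dataframe = "rows")
}

summary <- do.call(rbind, summary_rows)
write.csv(summary, "results/classification_summary.csv", row.names = FALSE)
cat("summary written to results/classification_summary.csv\n")
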