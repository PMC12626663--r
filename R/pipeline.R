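## End-to-end orchestration: simulate/load -> calibrate -> extract -> select
## -> classify -> report, under one serializable configuration.

#' Build a pipeline run configuration
#'
#' A serialized configuration plus a seed fully determines a run's outputs.
#'
#' @param cohort Either a [cohort_config()] (the cohort is simulated) or a
#'   path to a cohort directory written by [write_cohort()].
#' @param out Output directory for run artifacts.
#' @param k,selection_mode,redundancy_rho Selection settings (see
#'   [rank_and_select()], [run_comparison()]).
#' @param classifiers Classifier ids for [run_comparison()].
#' @param n_folds,grouping Fold settings.
#' @param seed Integer seed for fold assignment and classifiers.
#' @param sigma Calibration smoothing SD (pixels).
#' @return A `run_config` list.
#' @export
run_config <- function(cohort, out, k = 8, selection_mode = "fold",
                       redundancy_rho = 0.95, classifiers = c("rf", "logistic"),
                       n_folds = 5, grouping = "CELL", seed = 1L, sigma = 1) {
  structure(list(cohort = cohort, out = out, k = k,
                 selection_mode = selection_mode,
                 redundancy_rho = redundancy_rho, classifiers = classifiers,
                 n_folds = n_folds, grouping = grouping, seed = as.integer(seed),
                 sigma = sigma),
            class = "run_config")
}

#' Validate pipeline inputs
#'
#' Checks channel-table/block consistency, mask bounds and labels, per-class
#' cell counts and fold feasibility. Returns a machine-readable report rather
#' than erroring.
#'
#' @param cohort A cohort list (from [generate_cohort()] or [read_cohort()]).
#' @param n_folds Planned fold count.
#' @return List with `failures` and `warnings` (character vectors); an empty
#'   `failures` vector means the cohort is runnable.
#' @export
validate_inputs <- function(cohort, n_folds = 5) {
  failures <- character(0); warnings <- character(0)
  for (sid in names(cohort$blocks)) {
    b <- cohort$blocks[[sid]]
    missing <- setdiff(cohort$channels$channel_id, names(b$images))
    if (length(missing)) {
      failures <- c(failures, paste0("block ", sid, " missing channel(s): ",
                                     paste(missing, collapse = ", ")))
    }
    lab <- cohort$labels[[sid]]
    if (is.null(lab)) {
      failures <- c(failures, paste0("block ", sid, " has no mask label image"))
    } else {
      if (!identical(dim(lab), dim(b$brightfield))) {
        failures <- c(failures, paste0("block ", sid, " mask geometry mismatch"))
      }
      if (max(lab) == 0) {
        warnings <- c(warnings, paste0("block ", sid, " has zero cells"))
      }
    }
  }
  counts <- table(cohort$cells$group_label)
  for (g in names(counts)) {
    if (counts[[g]] < n_folds) {
      failures <- c(failures, paste0("group ", g, " has ", counts[[g]],
                                     " cells; fewer than ", n_folds, " folds"))
    }
  }
  pat_counts <- table(cohort$cells$patient_id)
  for (p in names(pat_counts)) {
    if (pat_counts[[p]] == 0) {
      warnings <- c(warnings, paste0("patient ", p, " has zero cells"))
    }
  }
  list(failures = failures, warnings = warnings)
}

write_result_json <- function(result, path) {
  ser <- lapply(result, function(r) {
    r <- unclass(r)
    r$per_fold_roc <- NULL  # plotting detail; pooled curve retained
    r
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = 10,
                       dataframe = "rows")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a cohort, fits the calibration model from the
#' reference frames, calibrates every block, extracts the per-cell feature
#' table, then runs every pairwise binary comparison between the groups
#' present (all three for a three-group cohort), writing per-comparison
#' selection and result JSONs, the pooled feature CSV, and a run manifest.
#' Outputs are deterministic given the configuration (including its seeds).
#'
#' @param config A [run_config()].
#' @param channels Channel table used when simulating (default
#'   [default_channel_table()]).
#' @return List with `features` (the pooled `feature_table`), `results`
#'   (nested list: comparison -> classifier -> `cv_result`), `validation`,
#'   and `out` (the run directory).
#' @export
run_pipeline <- function(config, channels = default_channel_table()) {
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  cohort <- if (inherits(config$cohort, "cohort_config")) {
    generate_cohort(config$cohort, channels = channels)
  } else {
    read_cohort(config$cohort)
  }
  validation <- validate_inputs(cohort, n_folds = config$n_folds)
  if (length(validation$failures)) {
    stop("input validation failed:\n  ",
         paste(validation$failures, collapse = "\n  "))
  }

  model <- fit_calibration(cohort$references, sigma = config$sigma)
  calibrated <- lapply(cohort$blocks, calibrate_block, model = model)

  features <- extract_cohort_features(calibrated, cohort$labels)
  write_feature_table(features, file.path(out, "features.csv"))
  message(sprintf("extracted %d features for %d cells (%s)",
                  length(feature_names(features)), nrow(features),
                  paste(sprintf("%s: %d", names(table(features$group_label)),
                                table(features$group_label)), collapse = ", ")))

  groups <- sort(unique(features$group_label))
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  results <- list()
  for (pr in pairs) {
    cmp_id <- paste0(pr[1], "_vs_", pr[2])
    tab2 <- restrict_classes(features, pr[1], pr[2])
    sel <- rank_and_select(tab2, k = config$k,
                           redundancy_rho = config$redundancy_rho)
    write_selection(sel, file.path(out, paste0("selection_", cmp_id, ".json")))
    res <- run_comparison(features, pr[1], pr[2], k = config$k,
                          selection_mode = config$selection_mode,
                          classifiers = config$classifiers,
                          n_folds = config$n_folds, grouping = config$grouping,
                          seed = config$seed,
                          redundancy_rho = config$redundancy_rho)
    write_result_json(res, file.path(out, paste0("result_", cmp_id, ".json")))
    results[[cmp_id]] <- res
    for (r in res) {
      if (!is.null(r$mean_auc)) {
        message(sprintf("%s [%s]: mean AUC %.3f (95%% CI %.3f-%.3f)", cmp_id,
                        r$classifier_id, r$mean_auc, r$ci95[1], r$ci95[2]))
      }
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("spectracell")),
    seed = config$seed, n_folds = config$n_folds, grouping = config$grouping,
    selection_mode = config$selection_mode, k = config$k,
    comparisons = vapply(pairs, paste, "", collapse = "_vs_"),
    n_cells = nrow(features),
    n_features = length(feature_names(features)),
    outputs = c("features.csv",
                paste0("selection_", vapply(pairs, paste, "", collapse = "_vs_"), ".json"),
                paste0("result_", vapply(pairs, paste, "", collapse = "_vs_"), ".json")))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(features = features, results = results,
                 validation = validation, out = out))
}
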