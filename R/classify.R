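## Binary classification with five-fold cross-validation, ROC/AUC summaries,
## and a pluggable score-backend registry (random forest built in, logistic
## baseline as the reference alternative backend).

#' Assign cells to cross-validation folds
#'
#' With `grouping = "CELL"` (the default, mirroring per-cell splitting) the
#' assignment is stratified by class: within each class, cells are shuffled
#' and dealt round-robin, so per-fold class proportions are within one cell of
#' the global proportions. With `grouping = "PATIENT"` whole patients are
#' assigned to folds (every cell of a patient shares a fold), the safer design
#' when cells within a patient are correlated.
#'
#' @param table A `feature_table`.
#' @param n_folds Number of folds (default 5).
#' @param grouping `"CELL"` or `"PATIENT"`.
#' @param seed Integer seed; the assignment is deterministic given it.
#' @return A `fold_plan`: list with `assignment` (named integer vector,
#'   cell_id -> fold), `n_folds`, `grouping`, `stratified`, `seed`.
#' @export
make_folds <- function(table, n_folds = 5, grouping = c("CELL", "PATIENT"),
                       seed = 1L) {
  grouping <- match.arg(grouping)
  n <- nrow(table)
  if (grouping == "CELL" && n < n_folds) stop("fewer cells than folds")
  set.seed(seed)
  assignment <- integer(n)
  names(assignment) <- table$cell_id
  if (grouping == "CELL") {
    for (cl in unique(table$group_label)) {
      idx <- which(table$group_label == cl)
      idx <- idx[sample.int(length(idx))]
      assignment[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  } else {
    patients <- unique(table$patient_id)
    if (length(patients) < n_folds) stop("fewer patients than folds")
    # stratify patients by their (majority) class so every fold sees both
    pclass <- vapply(patients, function(p) {
      names(which.max(table(table$group_label[table$patient_id == p])))
    }, "")
    pfold <- integer(length(patients)); names(pfold) <- patients
    for (cl in unique(pclass)) {
      idx <- which(pclass == cl)
      idx <- idx[sample.int(length(idx))]
      pfold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    assignment[] <- pfold[table$patient_id]
  }
  for (f in seq_len(n_folds)) {
    train_classes <- unique(table$group_label[assignment != f])
    if (length(train_classes) < length(unique(table$group_label))) {
      stop("a class is absent from the training split of fold ", f,
           "; use fewer folds")
    }
  }
  structure(list(assignment = assignment, n_folds = n_folds,
                 grouping = grouping, stratified = grouping == "CELL",
                 seed = seed),
            class = "fold_plan")
}

#' ROC curve and AUC from scores and binary labels
#'
#' AUC uses the rank (Mann-Whitney) formulation with ties counted one half,
#' which equals the trapezoidal area under the step ROC curve. The returned
#' curve is the full step curve over score thresholds (tied scores collapse
#' into single steps), starting at (0, 0) and ending at (1, 1).
#'
#' @param scores Numeric scores, higher = more positive-like.
#' @param labels Binary labels; the positive class is the larger level of
#'   `factor(labels)` unless `positive` is given.
#' @param positive Optional positive-class label.
#' @return List with `auc` and `points` (data.frame `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  stopifnot(length(scores) == length(labels))
  f <- factor(labels)
  if (nlevels(f) != 2) stop("labels must contain exactly two classes")
  if (is.null(positive)) positive <- levels(f)[2]
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes required for ROC")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # step curve: descending unique thresholds, ties in one step
  ord <- order(-scores)
  s <- scores[ord]; p <- pos[ord]
  steps <- cumsum(!duplicated(s))
  tp <- tapply(p, steps, sum); fp <- tapply(!p, steps, sum)
  points <- data.frame(fpr = c(0, cumsum(as.numeric(fp)) / n0),
                       tpr = c(0, cumsum(as.numeric(tp)) / n1))
  list(auc = auc, points = points)
}

#' Train a random forest and score a test set
#'
#' Method 1 of the pipeline: a random forest on the selected features, scored
#' as the forest's class-probability for the positive class. Defaults: 500
#' trees, floor(sqrt(p)) candidate features per split, unlimited depth.
#'
#' @param train,test `feature_table`s (two classes in `train`).
#' @param features Character vector of selected feature names.
#' @param positive Positive-class label (default: larger factor level).
#' @param ntree,mtry Forest size and per-split candidate count.
#' @param seed Integer seed; scores are deterministic given it.
#' @return Numeric vector of scores in [0, 1] for `test` rows.
#' @export
train_rf_and_score <- function(train, test, features, positive = NULL,
                               ntree = 500, mtry = NULL, seed = 1L) {
  stopifnot(all(features %in% names(train)), all(features %in% names(test)))
  y <- factor(train$group_label)
  if (nlevels(y) != 2) stop("degenerate training set: need two classes")
  if (is.null(positive)) positive <- levels(y)[2]
  if (is.null(mtry)) mtry <- max(1, floor(sqrt(length(features))))
  set.seed(seed)
  fit <- randomForest::randomForest(
    x = as.data.frame(train)[, features, drop = FALSE], y = y,
    ntree = ntree, mtry = mtry)
  p <- stats::predict(fit, as.data.frame(test)[, features, drop = FALSE],
                      type = "prob")
  as.numeric(p[, positive])
}

backend_registry <- new.env(parent = emptyenv())

#' Register / list pluggable classifier backends
#'
#' Method 2 of the pipeline explores alternative classifiers through a
#' score-producing backend interface: a function
#' `f(train, test, features, positive, seed)` returning test scores in
#' [0, 1]. A `"logistic"` baseline (regularized only by R's glm fit) ships
#' built in; heavier automated model-selection frameworks can be plugged in by
#' registering a backend under a name. Unregistered backends are skipped
#' gracefully by [run_comparison()].
#'
#' @param name Backend name.
#' @param fn Backend function.
#' @return `register_backend`: `name` invisibly; `list_backends`: character
#'   vector of registered names.
#' @export
register_backend <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  assign(name, fn, envir = backend_registry)
  invisible(name)
}

#' @rdname register_backend
#' @export
list_backends <- function() sort(ls(backend_registry))

logistic_backend <- function(train, test, features, positive, seed = 1L) {
  y <- as.integer(train$group_label == positive)
  df <- as.data.frame(train)[, features, drop = FALSE]
  df$.y <- y
  fit <- suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
  as.numeric(stats::predict(fit, as.data.frame(test)[, features, drop = FALSE],
                            type = "response"))
}

#' Score a test set through a registered backend
#'
#' @param train,test `feature_table`s.
#' @param features Selected feature names.
#' @param backend Backend name (see [register_backend()]).
#' @param positive Positive-class label.
#' @param seed Integer seed.
#' @return List with `status` (`"ok"` or `"backend unavailable"`) and
#'   `scores` (`NULL` when unavailable).
#' @export
run_automl_backend <- function(train, test, features, backend = "logistic",
                               positive = NULL, seed = 1L) {
  if (!exists(backend, envir = backend_registry, inherits = FALSE)) {
    return(list(status = "backend unavailable", scores = NULL,
                backend = backend))
  }
  if (is.null(positive)) positive <- levels(factor(train$group_label))[2]
  fn <- get(backend, envir = backend_registry)
  scores <- tryCatch(fn(train, test, features, positive, seed),
                     error = function(e) e)
  if (inherits(scores, "error")) {
    return(list(status = paste("backend failed:", conditionMessage(scores)),
                scores = NULL, backend = backend))
  }
  list(status = "ok", scores = scores, backend = backend)
}

summarize_fold_aucs <- function(per_fold_auc, ci = c("t", "normal")) {
  ci <- match.arg(ci)
  k <- length(per_fold_auc)
  m <- mean(per_fold_auc)
  v <- stats::var(per_fold_auc)
  half <- if (ci == "t") {
    stats::qt(0.975, df = k - 1) * sqrt(v / k)
  } else {
    stats::qnorm(0.975) * sqrt(v / k)
  }
  list(mean_auc = m, fold_variance = v, ci95 = c(m - half, m + half))
}

#' Run one cross-validated binary comparison
#'
#' For each fold: optionally re-run entropy-based feature selection on the
#' training cells only (`selection_mode = "fold"`, the leakage-safe default),
#' train each classifier on the training cells, score the held-out cells, and
#' compute the fold AUC. `selection_mode = "global"` performs one selection on
#' all cells before cross-validation -- this reproduces fixed published
#' feature sets but lets test cells influence selection, so its AUCs are
#' optimistically biased; results carry a `selection_bias_note`. The 95% CI is
#' `mean +/- t_{0.975, k-1} sqrt(var / k)` over the per-fold AUCs.
#'
#' @param table A `feature_table` containing both classes.
#' @param class_a,class_b Group labels to compare; `class_b` is the positive
#'   class.
#' @param k Number of features to select.
#' @param selection_mode `"fold"` or `"global"`.
#' @param classifiers Character vector: `"rf"` and/or registered backend
#'   names.
#' @param n_folds,grouping,seed Fold-plan parameters (see [make_folds()]).
#' @param redundancy_rho Passed to [rank_and_select()].
#' @param features Optional explicit feature set; overrides selection.
#' @return Named list (one `cv_result` per classifier): `comparison`,
#'   `classifier_id`, `per_fold_auc`, `mean_auc`, `fold_variance`, `ci95`,
#'   `roc_points` (pooled, for plotting), `per_fold_roc`, `feature_sets`,
#'   `status`.
#' @export
run_comparison <- function(table, class_a, class_b, k = 8,
                           selection_mode = c("fold", "global"),
                           classifiers = "rf", n_folds = 5,
                           grouping = "CELL", seed = 1L,
                           redundancy_rho = 0.95, features = NULL) {
  selection_mode <- match.arg(selection_mode)
  tab <- restrict_classes(table, class_a, class_b)
  positive <- class_b
  plan <- make_folds(tab, n_folds = n_folds, grouping = grouping, seed = seed)

  global_features <- features
  if (is.null(global_features) && selection_mode == "global") {
    global_features <- rank_and_select(tab, k = k,
                                       redundancy_rho = redundancy_rho)$selected
  }

  fold_scores <- lapply(classifiers, function(cl) list())
  names(fold_scores) <- classifiers
  fold_labels <- list(); feature_sets <- list()
  status <- stats::setNames(rep("ok", length(classifiers)), classifiers)

  for (f in seq_len(plan$n_folds)) {
    test_idx <- plan$assignment[tab$cell_id] == f
    train <- feature_table(as.data.frame(tab[!test_idx, , drop = FALSE]))
    test <- feature_table(as.data.frame(tab[test_idx, , drop = FALSE]))
    feats <- if (!is.null(global_features)) global_features else {
      rank_and_select(train, k = k, redundancy_rho = redundancy_rho)$selected
    }
    feature_sets[[f]] <- feats
    fold_labels[[f]] <- test$group_label
    for (cl in classifiers) {
      if (cl == "rf") {
        fold_scores[[cl]][[f]] <- train_rf_and_score(
          train, test, feats, positive = positive,
          seed = seed * 1000L + f)
      } else {
        r <- run_automl_backend(train, test, feats, backend = cl,
                                positive = positive, seed = seed * 1000L + f)
        if (r$status != "ok") {
          status[[cl]] <- r$status
          fold_scores[[cl]][[f]] <- NULL
        } else {
          fold_scores[[cl]][[f]] <- r$scores
        }
      }
    }
  }

  results <- list()
  for (cl in classifiers) {
    if (status[[cl]] != "ok") {
      results[[cl]] <- structure(
        list(comparison = c(class_a, class_b), classifier_id = cl,
             status = status[[cl]]),
        class = "cv_result")
      next
    }
    per_fold <- vapply(seq_len(plan$n_folds), function(f) {
      roc_auc(fold_scores[[cl]][[f]], fold_labels[[f]], positive = positive)$auc
    }, numeric(1))
    per_fold_roc <- lapply(seq_len(plan$n_folds), function(f) {
      roc_auc(fold_scores[[cl]][[f]], fold_labels[[f]], positive = positive)$points
    })
    pooled <- roc_auc(unlist(fold_scores[[cl]]), unlist(fold_labels),
                      positive = positive)
    s <- summarize_fold_aucs(per_fold)
    results[[cl]] <- structure(
      list(comparison = c(class_a, class_b),
           classifier_id = if (cl == "rf") "random_forest" else cl,
           per_fold_auc = per_fold, mean_auc = s$mean_auc,
           fold_variance = s$fold_variance, ci95 = s$ci95,
           roc_points = pooled$points, per_fold_roc = per_fold_roc,
           feature_sets = feature_sets, selection_mode = selection_mode,
           grouping = grouping, n_folds = plan$n_folds, seed = seed,
           status = "ok",
           selection_bias_note = if (selection_mode == "global")
             "global selection uses test cells; AUC optimistically biased"
           else NULL),
      class = "cv_result")
  }
  results
}

#' @export
print.cv_result <- function(x, ...) {
  if (!is.null(x$mean_auc)) {
    cat(sprintf("<cv_result> %s vs %s [%s]: mean AUC %.3f (95%% CI %.3f-%.3f)\n",
                x$comparison[1], x$comparison[2], x$classifier_id,
                x$mean_auc, x$ci95[1], x$ci95[2]))
  } else {
    cat(sprintf("<cv_result> %s vs %s [%s]: %s\n",
                x$comparison[1], x$comparison[2], x$classifier_id, x$status))
  }
  invisible(x)
}

#' Plot a pooled ROC curve
#'
#' @param result A `cv_result`.
#' @param ... Passed to [graphics::plot()].
#' @return `result`, invisibly.
#' @export
plot_roc <- function(result, ...) {
  stopifnot(inherits(result, "cv_result"), !is.null(result$roc_points))
  graphics::plot(result$roc_points$fpr, result$roc_points$tpr, type = "s",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("%s vs %s (AUC %.2f)", result$comparison[1],
                                result$comparison[2], result$mean_auc),
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(result)
}
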