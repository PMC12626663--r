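# Independent oracle: AUC by explicit concordant/discordant/tied pair counting.
auc_bruteforce <- function(scores, labels, positive) {
  pos <- which(labels == positive); neg <- which(labels != positive)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  tot / (length(pos) * length(neg))
}

test_that("fold plans are balanced, deterministic, and grouped correctly", {
  tab <- gaussian_table(n_per_class = 5, seed = 2)  # 10 cells
  plan <- make_folds(tab, n_folds = 5, grouping = "CELL", seed = 3)
  expect_equal(as.integer(table(plan$assignment)), rep(2L, 5))
  # stratified: each fold holds one cell of each class
  for (f in 1:5) {
    expect_equal(sort(tab$group_label[plan$assignment == f]), c("neg", "pos"))
  }
  plan2 <- make_folds(tab, n_folds = 5, grouping = "CELL", seed = 3)
  expect_identical(plan$assignment, plan2$assignment)
  # patient grouping: no patient spans folds
  tabp <- gaussian_table(n_per_class = 30, seed = 4, n_patients_per_class = 5)
  planp <- make_folds(tabp, n_folds = 5, grouping = "PATIENT", seed = 1)
  spans <- tapply(planp$assignment, tabp$patient_id,
                  function(v) length(unique(v)))
  expect_true(all(spans == 1))
})

test_that("degenerate folds are refused with advice", {
  tab <- gaussian_table(n_per_class = 3, seed = 5)  # 6 cells
  expect_error(make_folds(tab, n_folds = 7), "fewer cells than folds")
})

test_that("ROC/AUC matches closed cases and the tie convention", {
  r1 <- roc_auc(c(0, 0, 1, 1), c("a", "a", "b", "b"), positive = "b")
  expect_equal(r1$auc, 1.0)
  r0 <- roc_auc(c(1, 1, 0, 0), c("a", "a", "b", "b"), positive = "b")
  expect_equal(r0$auc, 0.0)
  rt <- roc_auc(c(0.2, 0.2), c("a", "b"), positive = "b")
  expect_equal(rt$auc, 0.5)
  expect_error(roc_auc(c(1, 2), c("a", "a")), "two classes")
  # step curve contract: starts at (0,0), ends at (1,1), monotone
  set.seed(12)
  r <- roc_auc(rnorm(30), sample(c("a", "b"), 30, TRUE, prob = c(0.4, 0.6)))
  expect_equal(unlist(r$points[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(r$points[nrow(r$points), ]), c(fpr = 1, tpr = 1))
  expect_true(!is.unsorted(r$points$fpr) && !is.unsorted(r$points$tpr))
})

test_that("rank AUC equals pairwise concordance counting on random data", {
  set.seed(303)
  for (rep in 1:80) {
    n <- sample(4:30, 1)
    scores <- round(runif(n), sample(1:3, 1))  # induce ties
    labels <- sample(c("a", "b"), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c("a", "b")
    r <- roc_auc(scores, labels, positive = "b")
    expect_equal(r$auc, auc_bruteforce(scores, labels, "b"), tolerance = 1e-12)
  }
})

test_that("rank AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(42)
  scores <- rnorm(50)
  labels <- sample(c("a", "b"), 50, TRUE)
  got <- roc_auc(scores, labels, positive = "b")$auc
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores, levels = c("a", "b"),
    direction = "<"))))
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("swapping class labels complements every AUC", {
  set.seed(9)
  scores <- rnorm(40)
  labels <- sample(c("a", "b"), 40, TRUE)
  a1 <- roc_auc(scores, labels, positive = "b")$auc
  a2 <- roc_auc(scores, labels, positive = "a")$auc
  expect_equal(a1, 1 - a2, tolerance = 1e-12)
})

test_that("random forest separates separable data and memorizes duplicates", {
  tab <- gaussian_table(n_per_class = 25, delta = 8, seed = 6)
  plan_test <- seq_len(nrow(tab)) %% 2 == 0
  train <- feature_table(as.data.frame(tab[!plan_test, ]))
  test <- feature_table(as.data.frame(tab[plan_test, ]))
  sc <- train_rf_and_score(train, test, "shifted", positive = "pos", seed = 1)
  expect_true(all(sc >= 0 & sc <= 1))
  expect_equal(roc_auc(sc, test$group_label, positive = "pos")$auc, 1.0)
  # duplicate of a training cell scores towards its own class
  dup <- feature_table(as.data.frame(train[train$group_label == "pos", ][1, ]))
  expect_gt(train_rf_and_score(train, dup, "shifted", positive = "pos",
                               seed = 1), 0.5)
  # determinism under seed
  sc2 <- train_rf_and_score(train, test, "shifted", positive = "pos", seed = 1)
  expect_identical(sc, sc2)
  # one-class training set is degenerate
  oneclass <- feature_table(as.data.frame(train[train$group_label == "pos", ]))
  expect_error(train_rf_and_score(oneclass, test, "shifted"), "degenerate")
})

test_that("backends: logistic works, unknown backends degrade gracefully", {
  tab <- gaussian_table(n_per_class = 20, delta = 8, seed = 7)
  half <- seq_len(nrow(tab)) %% 2 == 0
  train <- feature_table(as.data.frame(tab[!half, ]))
  test <- feature_table(as.data.frame(tab[half, ]))
  expect_true("logistic" %in% list_backends())
  r <- run_automl_backend(train, test, "shifted", backend = "logistic",
                          positive = "pos")
  expect_equal(r$status, "ok")
  expect_equal(roc_auc(r$scores, test$group_label, positive = "pos")$auc, 1.0)
  r2 <- run_automl_backend(train, test, "shifted", backend = "no_such_backend")
  expect_equal(r2$status, "backend unavailable")
  expect_null(r2$scores)
  # a registered custom backend is picked up
  register_backend("constant", function(train, test, features, positive, seed)
    rep(0.5, nrow(test)))
  expect_true("constant" %in% list_backends())
  r3 <- run_automl_backend(train, test, "shifted", backend = "constant")
  expect_equal(r3$status, "ok")
  expect_equal(unique(r3$scores), 0.5)
})

test_that("cross-validated comparison on separable data reaches AUC 1 with zero width", {
  tab <- gaussian_table(n_per_class = 25, delta = 10, seed = 8)
  res <- run_comparison(tab, "neg", "pos", features = "shifted",
                        classifiers = c("rf", "logistic"), seed = 2)
  for (cl in c("rf", "logistic")) {
    expect_equal(res[[cl]]$per_fold_auc, rep(1, 5))
    expect_equal(res[[cl]]$mean_auc, 1.0)
    expect_equal(res[[cl]]$fold_variance, 0)
    expect_equal(diff(res[[cl]]$ci95), 0)
  }
  # mean/variance/CI arithmetic is internally consistent
  expect_equal(res$rf$mean_auc, mean(res$rf$per_fold_auc))
})

test_that("unavailable classifiers are reported but do not stop method 1", {
  tab <- gaussian_table(n_per_class = 15, delta = 6, seed = 12)
  res <- run_comparison(tab, "neg", "pos", features = "shifted",
                        classifiers = c("rf", "missing_backend"), seed = 2)
  expect_equal(res$rf$status, "ok")
  expect_equal(res$missing_backend$status, "backend unavailable")
  expect_null(res$missing_backend$mean_auc)
})

test_that("fold-mode selection never sees held-out cells", {
  # instrument rank_and_select through a wrapper comparison at small n
  tab <- gaussian_table(n_per_class = 15, delta = 2, p_noise = 3, seed = 13)
  res <- run_comparison(tab, "neg", "pos", k = 2, selection_mode = "fold",
                        classifiers = "rf", seed = 5)
  plan <- make_folds(restrict_classes(tab, "neg", "pos"), n_folds = 5,
                     grouping = "CELL", seed = 5)
  # feature sets were chosen per fold; rerunning selection on the training
  # cells only must reproduce them exactly
  for (f in 1:5) {
    train <- feature_table(as.data.frame(tab[plan$assignment[tab$cell_id] != f, ]))
    sel <- rank_and_select(train, k = 2)
    expect_identical(res$rf$feature_sets[[f]], sel$selected)
  }
})

test_that("adding a constant feature barely moves the random-forest AUC", {
  # mtry held fixed so the constant column only enlarges the candidate pool;
  # a constant can never win a split, so the ranking shift is seed jitter only
  tab <- gaussian_table(n_per_class = 30, delta = 2, p_noise = 7, seed = 14)
  df <- as.data.frame(tab); df$const <- 1
  tab2 <- feature_table(df)
  feats <- c("shifted", paste0("noise", 1:7))
  half <- seq_len(nrow(tab)) %% 2 == 0
  tr <- feature_table(as.data.frame(tab[!half, ]))
  te <- feature_table(as.data.frame(tab[half, ]))
  tr2 <- feature_table(as.data.frame(tab2[!half, ]))
  te2 <- feature_table(as.data.frame(tab2[half, ]))
  aucs1 <- aucs2 <- numeric(10)
  for (s in 1:10) {
    aucs1[s] <- roc_auc(
      train_rf_and_score(tr, te, feats, positive = "pos", mtry = 2, seed = s),
      te$group_label, positive = "pos")$auc
    aucs2[s] <- roc_auc(
      train_rf_and_score(tr2, te2, c(feats, "const"), positive = "pos",
                         mtry = 2, seed = s),
      te2$group_label, positive = "pos")$auc
  }
  expect_lt(abs(mean(aucs1) - mean(aucs2)), 0.02)
})
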