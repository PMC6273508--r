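test_that("train/test split is stratified, disjoint and seed-deterministic", {
  ds <- make_classification_dataset(seed = 1, n_active = 40, n_decoy = 960,
                                    k = 10, m = 3)
  sp <- split_train_test(ds$table, ds$labels, seed = 7)
  expect_length(sp$train, 800)
  expect_length(sp$test, 200)
  expect_length(intersect(sp$train, sp$test), 0)
  # 40 actives -> 32 in train within 1
  expect_lte(abs(sum(sp$y_train == "active") - 32), 1)
  sp2 <- split_train_test(ds$table, ds$labels, seed = 7)
  expect_identical(sp$train, sp2$train)
  sp3 <- split_train_test(ds$table, ds$labels, seed = 8)
  expect_false(identical(sp$train, sp3$train))
})

test_that("imbalance strategies transform data and weights as specified", {
  ds <- make_classification_dataset(seed = 2, n_active = 5, n_decoy = 195,
                                    k = 8, m = 2)
  full <- apply_imbalance_strategy(ds$table, ds$labels, "full_1_39")
  expect_identical(full$X, ds$table)
  expect_null(full$class_weights)
  sub <- apply_imbalance_strategy(ds$table, ds$labels, "subsample_1_10",
                                  seed = 3)
  expect_identical(sum(sub$y == "active"), 5L)
  expect_identical(sum(sub$y == "decoy"), 50L)
  # subsampled decoys are a subset of the original decoys
  expect_true(all(rownames(sub$X) %in% rownames(ds$table)))
  sub2 <- apply_imbalance_strategy(ds$table, ds$labels, "subsample_1_10",
                                   seed = 3)
  expect_identical(sub$X, sub2$X)
  wt <- apply_imbalance_strategy(ds$table, ds$labels, "weighted")
  expect_identical(wt$X, ds$table)
  expect_equal(wt$class_weights, c(active = 39, decoy = 1))
})

test_that("classification metrics match brute-force oracles on random fixtures", {
  set.seed(11)
  for (rep in 1:100) {
    n <- sample(10:60, 1)
    t_pos <- runif(n) < runif(1, 0.2, 0.8)
    p_pos <- ifelse(runif(n) < 0.75, t_pos, runif(n) < 0.5)
    m <- classification_metrics(ifelse(t_pos, "active", "decoy"),
                                ifelse(p_pos, "active", "decoy"))
    o <- oracle_class_metrics(t_pos, p_pos)
    for (f in names(o)) expect_equal(m[[f]], o[[f]], tolerance = 1e-12)
    expect_identical(m$TP + m$TN + m$FP + m$FN, n)
  }
})

test_that("the worked confusion matrix gives MCC ~ 0.6156", {
  y <- c(rep("active", 10), rep("decoy", 40))
  p <- c(rep("active", 8), rep("decoy", 2),     # TP = 8, FN = 2
         rep("active", 5), rep("decoy", 35))    # FP = 5, TN = 35
  m <- classification_metrics(y, p)
  expect_identical(c(m$TP, m$TN, m$FP, m$FN), c(8L, 35L, 5L, 2L))
  expect_equal(m$MCC, 270 / sqrt(13 * 10 * 40 * 37), tolerance = 1e-12)
  expect_equal(m$MCC, 0.6156, tolerance = 1e-4)
  # perfect prediction on mixed classes
  mp <- classification_metrics(y, y)
  expect_equal(mp$ACC, 1)
  expect_equal(mp$MCC, 1)
})

test_that("metrics report NA (undefined) on zero denominators", {
  # no predicted positives -> Precision undefined
  m <- classification_metrics(c("active", "decoy"), c("decoy", "decoy"))
  expect_true(is.na(m$Precision))
  expect_false(is.na(m$ACC))
  # MCC symmetric under simultaneous class swap
  set.seed(12)
  yt <- sample(c("active", "decoy"), 30, replace = TRUE)
  yp <- sample(c("active", "decoy"), 30, replace = TRUE)
  swap <- function(v) ifelse(v == "active", "decoy", "active")
  expect_equal(classification_metrics(yt, yp)$MCC,
               classification_metrics(swap(yt), swap(yp))$MCC,
               tolerance = 1e-12)
})

test_that("AUC: oracle agreement, extremes and monotone invariance", {
  set.seed(13)
  for (rep in 1:100) {
    n <- sample(8:30, 1)
    pos <- runif(n) < 0.5
    if (!any(pos) || all(pos)) next
    sc <- round(rnorm(n), 1)  # coarse scores force ties
    expect_equal(auc_score(sc, pos), oracle_auc(sc, pos), tolerance = 1e-12)
    # strictly monotone transform leaves AUC unchanged
    expect_equal(auc_score(exp(2 * sc), pos), auc_score(sc, pos),
                 tolerance = 1e-12)
  }
  pos <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(auc_score(c(4, 3, 2, 1), pos), 1)
  expect_equal(auc_score(c(1, 2, 3, 4), pos), 0)
})

test_that("regression metrics match a hand-computed 5-point fixture", {
  y <- c(6.1, 7.3, 5.8, 8.0, 6.9)
  yhat <- c(6.0, 7.1, 6.2, 7.7, 7.2)
  m <- regression_metrics(y, yhat, cv_pairs = cbind(y, yhat))
  # spreadsheet-style oracle
  o <- oracle_regression(y, yhat)
  expect_equal(m$RMSE, o$RMSE, tolerance = 1e-12)
  expect_equal(m$R2, o$R2, tolerance = 1e-12)
  expect_equal(m$Q2, cor(y, yhat)^2, tolerance = 1e-12)
  # perfect prediction
  mp <- regression_metrics(y, y)
  expect_equal(mp$RMSE, 0)
  expect_equal(mp$R2, 1)
  # constant prediction: R2 = 0, Q2 undefined
  mc <- regression_metrics(y, rep(mean(y), 5),
                           cv_pairs = cbind(y, rep(mean(y), 5)))
  expect_equal(mc$R2, 0, tolerance = 1e-12)
  expect_true(is.na(mc$Q2))
})

test_that("enrichment factor: closed form, cap and random behaviour", {
  # perfect ranking at 1:39, f = 0.10 -> EF = 10
  N <- 1000; n_act <- 25
  labels <- rep(c("active", "decoy"), c(n_act, N - n_act))
  perfect <- seq(N, 1)
  expect_equal(enrichment_factor(perfect, labels, 0.10), 10)
  # the EF cap is 1/active-fraction = 40
  expect_equal(enrichment_factor(perfect, labels, 0.025), 40)
  for (f in c(0.02, 0.1, 0.5)) {
    expect_lte(enrichment_factor(perfect, labels, f), 40)
  }
  # random scores: EF(0.10) ~ 1 in expectation
  set.seed(14)
  efs <- replicate(200, enrichment_factor(runif(N), labels, 0.10))
  expect_equal(mean(efs), 1, tolerance = 0.15)
  # stable tie-breaking by input order
  tied <- rep(1, 10)
  lab <- rep(c("active", "decoy"), 5)
  expect_equal(enrichment_factor(tied, lab, 0.2),
               (1 / 2) / (5 / 10))  # first two inputs: 1 active
})

test_that("grid search separates planted signal and matches a hand CV loop", {
  ds <- make_classification_dataset(seed = 5, n_active = 40, n_decoy = 160,
                                    k = 30, m = 8)
  gs <- grid_search_svm(ds$table, ds$labels, folds = 10, seed = 21)
  expect_gt(gs$cv_score, 0.9)
  # independent CV loop for the winning pair using the public svm API
  aucs <- vapply(1:10, function(f) {
    tr <- which(gs$fold_id != f); te <- which(gs$fold_id == f)
    fit <- svm_train(ds$table[tr, ], ds$labels[tr], C = gs$C,
                     gamma = gs$gamma)
    auc_score(predict(fit, ds$table[te, ]), ds$labels[te])
  }, 0)
  expect_equal(gs$cv_score, mean(aucs), tolerance = 1e-6)
  # tie-break bookkeeping: the winner's score is the grid maximum
  expect_equal(gs$cv_score, max(gs$grid$score), tolerance = 1e-12)
})

test_that("grid search on shuffled labels is near chance", {
  ds <- make_classification_dataset(seed = 6, n_active = 40, n_decoy = 160,
                                    k = 20, m = 6)
  yr <- brs3d:::with_seed(31, sample(ds$labels))
  # coarse sub-grid: chance level does not depend on tuning effort
  gs <- grid_search_svm(ds$table, yr, C_grid = 2^c(-3, 1, 5),
                        gamma_grid = 2^c(-9, -3, 1), folds = 10, seed = 22)
  expect_lt(abs(gs$cv_score - 0.5), 0.1)
})

test_that("grid search validates class counts per fold", {
  ds <- make_classification_dataset(seed = 7, n_active = 5, n_decoy = 50,
                                    k = 5, m = 2)
  expect_error(grid_search_svm(ds$table, ds$labels, folds = 10, seed = 1),
               "per class")
})

test_that("regression grid search minimizes cross-validated RMSE", {
  ds <- make_selectivity_dataset(seed = 8, n = 120, k = 20, n_info = 6)
  y <- ds$records$SR
  gs <- grid_search_svm(ds$table, y, C_grid = 2^seq(-1, 7, 2),
                        gamma_grid = 2^seq(-7, 1, 2), folds = 5,
                        objective = "rmse", seed = 23)
  expect_lt(gs$cv_score, sd(y))  # better than predicting the mean
  # hand CV loop for the winner
  errs <- unlist(lapply(1:5, function(f) {
    tr <- which(gs$fold_id != f); te <- which(gs$fold_id == f)
    fit <- svr_train(ds$table[tr, ], y[tr], C = gs$C, gamma = gs$gamma)
    y[te] - predict(fit, ds$table[te, ])
  }))
  expect_equal(gs$cv_score, sqrt(mean(errs^2)), tolerance = 1e-6)
})

test_that("weighted SVM shifts the decision boundary toward the minority", {
  ds <- make_classification_dataset(seed = 9, n_active = 12, n_decoy = 228,
                                    k = 15, m = 5, delta = 0.12, sigma = 0.1)
  sp <- split_train_test(ds$table, ds$labels, seed = 2)
  plain <- svm_train(sp$X_train, sp$y_train, C = 1, gamma = 0.1)
  wtd <- svm_train(sp$X_train, sp$y_train, C = 1, gamma = 0.1,
                   class_weights = c(active = 39, decoy = 1))
  rec <- function(m) {
    cm <- classification_metrics(sp$y_test,
                                 predict(m, sp$X_test, type = "class"))
    if (is.na(cm$Recall)) 0 else cm$Recall
  }
  expect_gte(rec(wtd), rec(plain))
})

test_that("permutation importance recovers planted dimensions", {
  ds <- make_classification_dataset(seed = 10, n_active = 60, n_decoy = 240,
                                    k = 40, m = 8)
  fr <- rank_features_permutation(ds$table, ds$labels, n_trees = 300,
                                  seed = 5)
  top_m <- fr$ranking[seq_along(ds$informative)]
  expect_gte(length(intersect(top_m, ds$informative)),
             ceiling(0.8 * length(ds$informative)))
  # appended pure-noise feature lands in the bottom half (meaningful when
  # the other dimensions mostly carry signal; among all-junk columns ranks
  # are arbitrary ties)
  dsn <- make_classification_dataset(seed = 12, n_active = 60,
                                     n_decoy = 240, k = 12, m = 8)
  hits <- 0L
  for (s in 1:10) {
    noisy <- cbind(dsn$table,
                   noise = brs3d:::with_seed(s, runif(nrow(dsn$table))))
    fr2 <- rank_features_permutation(noisy, dsn$labels, n_trees = 150,
                                     seed = s)
    if (which(fr2$ranking == ncol(noisy)) > ncol(noisy) / 2) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
  # subset sizes for k = 300
  ds300 <- make_classification_dataset(seed = 11, n_active = 20,
                                       n_decoy = 80, k = 300, m = 15)
  fr3 <- rank_features_permutation(ds300$table, ds300$labels, n_trees = 50,
                                   seed = 1)
  expect_identical(unname(fr3$subset_sizes),
                   c(15L, 30L, 90L, 150L, 210L, 300L))
  # prefix structure of the subsets
  expect_identical(fr3$subsets$top_5, fr3$subsets$top_10[1:15])
  # determinism
  fr4 <- rank_features_permutation(ds300$table, ds300$labels, n_trees = 50,
                                   seed = 1)
  expect_identical(fr3$ranking, fr4$ranking)
})
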