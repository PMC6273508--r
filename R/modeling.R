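# SVM discriminant/regression modelling on descriptor tables: train/test
# splits, class-imbalance strategies, RBF-kernel SVM (weighted C-SVC and
# eps-SVR on a self-contained SMO solver), grid search with stratified
# 10-fold cross-validation, classification and regression statistics,
# enrichment factors and random-forest permutation-importance ranking.

## ---------------------------------------------------------------------------
## Kernel helpers

squared_distances <- function(X, Y = X) {
  xn <- rowSums(X^2); yn <- rowSums(Y^2)
  d2 <- outer(xn, yn, "+") - 2 * X %*% t(Y)
  d2[d2 < 0] <- 0
  d2
}

rbf_kernel <- function(X, Y = X, gamma) exp(-gamma * squared_distances(X, Y))

# SMO iteration budget: 100 iterations per dual variable (at least 10k).
# Degenerate corners of the hyperparameter grid (near-constant kernel with
# a huge C) converge extremely slowly and always lose the model selection;
# the cap bounds their cost without affecting well-posed fits.
smo_budget <- function(n) max(10000L, as.integer(100 * n))

as_pm1 <- function(y) {
  # positive class = "active" (or the factor's first level)
  if (is.factor(y)) ifelse(y == levels(y)[1], 1, -1)
  else if (is.numeric(y)) ifelse(y > 0, 1, -1)
  else ifelse(y == "active", 1, -1)
}

## ---------------------------------------------------------------------------
## SVM fit / predict

#' Fit a weighted RBF-kernel SVM classifier
#'
#' C-support vector classification solved by sequential minimal
#' optimization. Per-class weights multiply the penalty `C`, which is the
#' standard device for class-imbalanced screening data (e.g. weight 39 for
#' actives vs 1 for decoys at a 1:39 ratio).
#'
#' @param X numeric matrix (rows = samples).
#' @param y labels; factor (first level = positive) or `"active"/"decoy"`.
#' @param C penalty parameter.
#' @param gamma RBF kernel width.
#' @param class_weights named weights on `C`, e.g. `c(active = 39, decoy = 1)`;
#'   `NULL` for unweighted.
#' @param tol SMO stopping tolerance.
#' @return object of class `svm_model`.
#' @export
svm_train <- function(X, y, C = 1, gamma = 1 / ncol(X),
                      class_weights = NULL, tol = 1e-3) {
  yy <- as_pm1(y)
  if (length(unique(yy)) < 2) stop("training data contains a single class")
  Cw <- rep(C, nrow(X))
  if (!is.null(class_weights)) {
    pos_w <- class_weights[["active"]] %||% class_weights[[1]]
    neg_w <- class_weights[["decoy"]] %||% class_weights[[2]]
    Cw <- ifelse(yy > 0, C * pos_w, C * neg_w)
  }
  K <- rbf_kernel(X, gamma = gamma)
  sol <- cpp_smo_solve(K, yy, rep(-1, nrow(X)), Cw, tol, smo_budget(nrow(X)))
  coefs <- sol$alpha * yy
  sv <- which(sol$alpha > 1e-12)
  structure(list(type = "classification", X = X[sv, , drop = FALSE],
                 coefs = coefs[sv], rho = sol$rho, gamma = gamma, C = C,
                 class_weights = class_weights),
            class = "svm_model")
}

#' Fit an eps-insensitive RBF-kernel SVM regressor
#'
#' @inheritParams svm_train
#' @param y numeric response.
#' @param eps width of the insensitive tube (default 0.1).
#' @return object of class `svm_model`.
#' @export
svr_train <- function(X, y, C = 1, gamma = 1 / ncol(X), eps = 0.1,
                      tol = 1e-3) {
  n <- nrow(X)
  K <- rbf_kernel(X, gamma = gamma)
  K2 <- rbind(cbind(K, K), cbind(K, K))
  ysign <- c(rep(1, n), rep(-1, n))
  p <- c(eps - y, eps + y)
  sol <- cpp_smo_solve(K2, ysign, p, rep(C, 2 * n), tol, smo_budget(2 * n))
  beta <- sol$alpha[1:n] - sol$alpha[(n + 1):(2 * n)]
  sv <- which(abs(beta) > 1e-12)
  structure(list(type = "regression", X = X[sv, , drop = FALSE],
                 coefs = beta[sv], rho = sol$rho, gamma = gamma, C = C,
                 eps = eps),
            class = "svm_model")
}

#' Predict from an SVM model
#'
#' @param object an `svm_model`.
#' @param newdata numeric matrix.
#' @param type `"decision"` (decision values / regression predictions) or
#'   `"class"` (classification labels `"active"/"decoy"`).
#' @param ... unused.
#' @return numeric vector, or character labels for `type = "class"`.
#' @export
predict.svm_model <- function(object, newdata, type = c("decision", "class"),
                              ...) {
  type <- match.arg(type)
  if (length(object$coefs) == 0) {
    dec <- rep(-object$rho, nrow(newdata))
  } else {
    Kx <- rbf_kernel(newdata, object$X, object$gamma)
    dec <- as.numeric(Kx %*% object$coefs) - object$rho
  }
  if (object$type == "classification" && type == "class")
    ifelse(dec > 0, "active", "decoy")
  else dec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---------------------------------------------------------------------------
## Splits, folds and imbalance strategies

#' Stratified train/test split
#'
#' @param table descriptor matrix (rows = samples).
#' @param labels class labels or numeric response.
#' @param test_fraction fraction held out (default 0.2, the classic 4:1
#'   train:test split).
#' @param seed RNG seed; identical seeds give identical partitions.
#' @param stratified preserve class proportions (classification only).
#' @return list with `train`, `test` (row indices), and the four
#'   sub-objects `X_train`, `X_test`, `y_train`, `y_test`.
#' @export
split_train_test <- function(table, labels, test_fraction = 0.2, seed = 1L,
                             stratified = TRUE) {
  n <- nrow(table)
  stopifnot(length(labels) == n, test_fraction > 0, test_fraction < 1)
  test_idx <- with_seed(seed, {
    if (stratified && !is.numeric(labels)) {
      unlist(lapply(split(seq_len(n), labels), function(ix) {
        sample(ix, round(length(ix) * test_fraction))
      }), use.names = FALSE)
    } else sample(n, round(n * test_fraction))
  })
  train_idx <- setdiff(seq_len(n), test_idx)
  list(train = train_idx, test = sort(test_idx),
       X_train = table[train_idx, , drop = FALSE],
       X_test = table[sort(test_idx), , drop = FALSE],
       y_train = labels[train_idx], y_test = labels[sort(test_idx)])
}

#' Apply a class-imbalance strategy
#'
#' Three strategies for active:decoy imbalance (nominally 1:39):
#' `full_1_39` uses the data unchanged with unit weights; `subsample_1_10`
#' keeps 10 decoys per active, sampled uniformly with `seed`, discarding
#' the rest; `weighted` keeps the data and puts per-class weight factors on
#' the SVM penalty C (default 39 for actives, 1 for decoys).
#'
#' @param X descriptor matrix.
#' @param y labels (`"active"`/`"decoy"` or factor with active first).
#' @param strategy one of `"full_1_39"`, `"subsample_1_10"`, `"weighted"`.
#' @param seed subsampling seed.
#' @param weights class-weight map for the weighted strategy.
#' @return list `X`, `y`, `class_weights`.
#' @export
apply_imbalance_strategy <- function(X, y,
                                     strategy = c("full_1_39",
                                                  "subsample_1_10",
                                                  "weighted"),
                                     seed = 1L,
                                     weights = c(active = 39, decoy = 1)) {
  strategy <- match.arg(strategy)
  is_active <- as_pm1(y) > 0
  if (strategy == "full_1_39")
    return(list(X = X, y = y, class_weights = NULL))
  if (strategy == "weighted")
    return(list(X = X, y = y, class_weights = weights))
  n_keep <- 10L * sum(is_active)
  decoy_idx <- which(!is_active)
  keep <- if (length(decoy_idx) <= n_keep) decoy_idx
          else with_seed(seed, sort(sample(decoy_idx, n_keep)))
  idx <- sort(c(which(is_active), keep))
  list(X = X[idx, , drop = FALSE], y = y[idx], class_weights = NULL)
}

make_stratified_folds <- function(y, folds, seed) {
  n <- length(y)
  fold_id <- integer(n)
  with_seed(seed, {
    if (is.numeric(y)) {
      fold_id <- sample(rep(seq_len(folds), length.out = n))
    } else {
      for (cls in unique(y)) {
        ix <- sample(which(y == cls))
        fold_id[ix] <- rep(seq_len(folds), length.out = length(ix))
      }
    }
  })
  fold_id
}

## ---------------------------------------------------------------------------
## Grid search

#' Grid search for RBF-SVM hyperparameters with k-fold cross-validation
#'
#' Exhaustive search over the standard LIBSVM-recipe grid
#' `C in 2^(-5, -3, ..., 15)`, `gamma in 2^(-15, -13, ..., 3)`.
#' Classification maximizes the mean fold AUC of decision values
#' (rank-based, ties averaged); regression minimizes the pooled
#' cross-validated RMSE. Ties break to smaller C, then smaller gamma. Fold
#' assignment is stratified and deterministic per seed.
#'
#' @param X descriptor matrix.
#' @param y labels (classification) or numeric response (regression).
#' @param C_grid,gamma_grid candidate values.
#' @param folds number of CV folds (default 10).
#' @param objective `"auc"` or `"rmse"`.
#' @param class_weights optional per-class weights on C.
#' @param eps SVR tube width (regression only).
#' @param seed fold-assignment seed.
#' @param verbose print per-gamma progress.
#' @return list of class `svm_grid_search`: winning `C`, `gamma`,
#'   `cv_score`, per-fold scores, the full score `grid`, and `model`
#'   (refit on all of `X`).
#' @export
grid_search_svm <- function(X, y,
                            C_grid = 2^seq(-5, 15, 2),
                            gamma_grid = 2^seq(-15, 3, 2),
                            folds = 10L,
                            objective = c("auc", "rmse"),
                            class_weights = NULL, eps = 0.1,
                            seed = 1L, verbose = FALSE) {
  objective <- match.arg(objective)
  n <- nrow(X)
  classification <- objective == "auc"
  if (classification) {
    cls_n <- table(as_pm1(y))
    if (any(cls_n < folds))
      stop("need at least ", folds, " samples per class for ", folds,
           "-fold CV (have ", paste(cls_n, collapse = "/"), ")")
  }
  fold_id <- make_stratified_folds(if (classification) factor(as_pm1(y))
                                   else y, folds, seed)
  D2 <- squared_distances(X)
  yy <- if (classification) as_pm1(y) else y
  res <- expand.grid(C = C_grid, gamma = gamma_grid)
  res$score <- NA_real_
  fold_scores_best <- NULL
  for (g in gamma_grid) {
    K <- exp(-g * D2)
    for (Cv in C_grid) {
      fold_scores <- numeric(folds)
      sq_err <- 0; n_err <- 0L
      for (f in seq_len(folds)) {
        tr <- which(fold_id != f); te <- which(fold_id == f)
        if (classification) {
          Cw <- rep(Cv, length(tr))
          if (!is.null(class_weights))
            Cw <- ifelse(yy[tr] > 0, Cv * class_weights[["active"]],
                         Cv * class_weights[["decoy"]])
          sol <- cpp_smo_solve(K[tr, tr], yy[tr], rep(-1, length(tr)), Cw,
                               1e-3, smo_budget(length(tr)))
          dec <- as.numeric(K[te, tr] %*% (sol$alpha * yy[tr])) - sol$rho
          fold_scores[f] <- auc_score(dec, yy[te] > 0)
        } else {
          ntr <- length(tr)
          K2 <- rbind(cbind(K[tr, tr], K[tr, tr]),
                      cbind(K[tr, tr], K[tr, tr]))
          sol <- cpp_smo_solve(K2, c(rep(1, ntr), rep(-1, ntr)),
                               c(eps - yy[tr], eps + yy[tr]),
                               rep(Cv, 2 * ntr), 1e-3, smo_budget(2 * ntr))
          beta <- sol$alpha[1:ntr] - sol$alpha[(ntr + 1):(2 * ntr)]
          pred <- as.numeric(K[te, tr] %*% beta) - sol$rho
          fold_scores[f] <- sqrt(mean((yy[te] - pred)^2))
          sq_err <- sq_err + sum((yy[te] - pred)^2); n_err <- n_err + length(te)
        }
      }
      score <- if (classification) mean(fold_scores) else sqrt(sq_err / n_err)
      res$score[res$C == Cv & res$gamma == g] <- score
    }
    if (verbose) message("gamma = ", signif(g, 3), " done")
  }
  ord <- if (classification) order(-res$score, res$C, res$gamma)
         else order(res$score, res$C, res$gamma)
  best <- res[ord[1], ]
  model <- if (classification)
    svm_train(X, y, C = best$C, gamma = best$gamma,
              class_weights = class_weights)
  else svr_train(X, y, C = best$C, gamma = best$gamma, eps = eps)
  structure(list(C = best$C, gamma = best$gamma, cv_score = best$score,
                 objective = objective, folds = folds, fold_id = fold_id,
                 grid = res, model = model, class_weights = class_weights),
            class = "svm_grid_search")
}

#' @export
print.svm_grid_search <- function(x, ...) {
  cat(sprintf("grid search (%s, %d-fold CV): C = %g, gamma = %g, score = %.4f\n",
              x$objective, x$folds, x$C, x$gamma, x$cv_score))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Metrics

#' Rank-based AUC (Mann-Whitney, ties averaged)
#'
#' @param scores numeric scores, larger = more active.
#' @param labels logical or active/decoy labels.
#' @return AUC in `[0, 1]`, `NA` if one class is absent.
#' @export
auc_score <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else as_pm1(labels) > 0
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification performance statistics
#'
#' Computes the confusion counts and ACC = (TP+TN)/(TP+TN+FP+FN),
#' Precision = TP/(TP+FP), Recall = Sensitivity = TP/(TP+FN),
#' Specificity = TN/(TN+FP), and
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), plus
#' rank-based AUC when scores are supplied. Any statistic with a zero
#' denominator is reported as `NA` ("undefined"), never silently 0.
#'
#' @param y_true true labels.
#' @param y_pred predicted labels.
#' @param scores optional decision values for AUC.
#' @return object of class `class_metrics` (a list with `TP`, `TN`, `FP`,
#'   `FN`, `ACC`, `Precision`, `Recall`, `Specificity`, `MCC`, `AUC`).
#' @export
classification_metrics <- function(y_true, y_pred, scores = NULL) {
  t_pos <- as_pm1(y_true) > 0; p_pos <- as_pm1(y_pred) > 0
  TP <- sum(t_pos & p_pos); TN <- sum(!t_pos & !p_pos)
  FP <- sum(!t_pos & p_pos); FN <- sum(t_pos & !p_pos)
  div <- function(num, den) if (den == 0) NA_real_ else num / den
  mcc_den <- as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  structure(list(
    TP = TP, TN = TN, FP = FP, FN = FN,
    ACC = div(TP + TN, TP + TN + FP + FN),
    Precision = div(TP, TP + FP),
    Recall = div(TP, TP + FN),
    Specificity = div(TN, TN + FP),
    MCC = if (mcc_den == 0) NA_real_
          else (as.numeric(TP) * TN - as.numeric(FP) * FN) / sqrt(mcc_den),
    AUC = if (is.null(scores)) NA_real_ else auc_score(scores, t_pos)),
    class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, ...) {
  cat(sprintf("TP %d TN %d FP %d FN %d | ACC %.3f Prec %.3f Rec %.3f Spec %.3f MCC %.3f AUC %.3f\n",
              x$TP, x$TN, x$FP, x$FN, x$ACC, x$Precision, x$Recall,
              x$Specificity, x$MCC, x$AUC))
  invisible(x)
}

#' Regression performance statistics
#'
#' RMSE = sqrt(mean((y - yhat)^2)); R2 = 1 - SS_res/SS_tot (determination
#' coefficient); Q2 = squared Pearson correlation between cross-validated
#' predictions and observations, computed from `cv_pairs` when given.
#' Undefined ratios (zero variance) are reported as `NA`.
#'
#' @param y observed response.
#' @param yhat predictions for `y`.
#' @param cv_pairs optional 2-column matrix / data.frame of
#'   (observed, cross-validated prediction) pairs for Q2.
#' @return object of class `regression_metrics` (`n`, `RMSE`, `R2`, `Q2`).
#' @export
regression_metrics <- function(y, yhat, cv_pairs = NULL) {
  stopifnot(length(y) == length(yhat))
  rmse <- sqrt(mean((y - yhat)^2))
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - sum((y - yhat)^2) / ss_tot
  q2 <- NA_real_
  if (!is.null(cv_pairs)) {
    if (is.data.frame(cv_pairs)) {
      obs <- cv_pairs[[1]]; prd <- cv_pairs[[2]]
    } else {
      obs <- cv_pairs[, 1]; prd <- cv_pairs[, 2]
    }
    if (sd(obs) > 0 && sd(prd) > 0) q2 <- cor(obs, prd)^2
  }
  structure(list(n = length(y), RMSE = rmse, R2 = r2, Q2 = q2),
            class = "regression_metrics")
}

#' @export
print.regression_metrics <- function(x, ...) {
  cat(sprintf("n %d | RMSE %.4f R2 %.4f Q2 %.4f\n", x$n, x$RMSE, x$R2, x$Q2))
  invisible(x)
}

#' Enrichment factor
#'
#' `EF(f) = (actives among the top ceiling(f*N) by score / ceiling(f*N)) /
#' (total actives / N)`. Score ties are broken by stable input order. The
#' maximum attainable EF is `1 / active fraction` (40 at a 1:39 ratio).
#'
#' @param scores numeric ranking scores, larger = better.
#' @param labels active/decoy labels (or logical actives).
#' @param fraction top fraction, e.g. 0.1 or 0.02.
#' @return the enrichment factor.
#' @export
enrichment_factor <- function(scores, labels, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  pos <- if (is.logical(labels)) labels else as_pm1(labels) > 0
  N <- length(scores)
  top <- ceiling(fraction * N)
  ord <- order(-scores)  # radix sort: stable for tied scores
  hits <- sum(pos[ord[seq_len(top)]])
  (hits / top) / (sum(pos) / N)
}

## ---------------------------------------------------------------------------
## Feature ranking

#' Rank features by random-forest permutation importance
#'
#' Fits a random forest (bootstrap CART trees, Gini splits, `mtry =
#' floor(sqrt(p))`) and scores each feature by the mean decrease in
#' out-of-bag accuracy when its column is permuted. Subset sizes are
#' prefixes of the descending ranking at the configured fractions (for
#' k = 300: 15, 30, 90, 150, 210, 300 features).
#'
#' @param table descriptor matrix.
#' @param labels class labels.
#' @param n_trees number of trees (default 500).
#' @param seed forest RNG seed.
#' @param fractions subset fractions (default 5/10/30/50/70/100%).
#' @return object of class `feature_ranking`: `importance`, `ranking`
#'   (feature indices, descending importance), `subsets` (named list of
#'   prefix index vectors) and `oob_accuracy`.
#' @export
rank_features_permutation <- function(table, labels, n_trees = 500L,
                                      seed = 1L,
                                      fractions = c(0.05, 0.10, 0.30,
                                                    0.50, 0.70, 1.00)) {
  X <- as.matrix(table)
  yy <- as.integer(as_pm1(labels) > 0)  # 1 = active, 0 = decoy
  p <- ncol(X)
  fit <- cpp_rf_importance(X, yy, 2L, as.integer(n_trees),
                           max(1L, floor(sqrt(p))), 5L, 25L,
                           as.numeric(seed))
  imp <- fit$importance
  ranking <- order(-imp)  # stable: ties keep column order
  oob_pred <- max.col(fit$oob_votes, ties.method = "first") - 1L
  voted <- rowSums(fit$oob_votes) > 0
  subsets <- lapply(fractions, function(f) ranking[seq_len(round(f * p))])
  names(subsets) <- sprintf("top_%d", round(100 * fractions))
  structure(list(importance = imp, ranking = ranking, subsets = subsets,
                 subset_sizes = vapply(subsets, length, 0L),
                 oob_accuracy = mean(oob_pred[voted] == yy[voted]),
                 n_trees = n_trees),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat(sprintf("feature ranking: %d features, OOB accuracy %.3f, subsets: %s\n",
              length(x$importance), x$oob_accuracy,
              paste(x$subset_sizes, collapse = "/")))
  invisible(x)
}
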