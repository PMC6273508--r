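# Receptor subtype-selectivity analysis: selectivity-ratio labelling,
# Y-randomization, resampling stability and an applicability domain.
#
# The selectivity ratio between two receptor subtypes A and B is
# SR = pKi_A - pKi_B (pKi = -log10 Ki, molar). Compounds with |SR| at or
# beyond a threshold (default 1.3 log units, i.e. a 20-fold affinity
# difference) are called subtype selective.

#' Label compounds by selectivity ratio
#'
#' `SR = pKi_A - pKi_B`; label `A_selective` iff `SR >= threshold`,
#' `B_selective` iff `SR <= -threshold` (boundaries inclusive), else
#' `nonselective`.
#'
#' @param pKi_A,pKi_B numeric vectors of -log10 Ki values.
#' @param threshold selectivity threshold in log units (default 1.3).
#' @param ids optional molecule ids.
#' @return data.frame with `molecule_id`, `pKi_A`, `pKi_B`, `SR`, `label`
#'   (factor A_selective/B_selective/nonselective).
#' @export
label_selectivity <- function(pKi_A, pKi_B, threshold = 1.3, ids = NULL) {
  stopifnot(length(pKi_A) == length(pKi_B), threshold > 0)
  SR <- pKi_A - pKi_B
  # epsilon guard so decimal pKi differences that sit exactly on the
  # boundary at printed precision (e.g. 7.0 - 5.7) stay inclusive
  eps <- 1e-9
  label <- ifelse(SR >= threshold - eps, "A_selective",
                  ifelse(SR <= -threshold + eps, "B_selective",
                         "nonselective"))
  data.frame(
    molecule_id = if (is.null(ids)) sprintf("cpd%d", seq_along(SR)) else ids,
    pKi_A = pKi_A, pKi_B = pKi_B, SR = SR,
    label = factor(label, levels = c("A_selective", "B_selective",
                                     "nonselective")),
    stringsAsFactors = FALSE)
}

#' Y-randomization test
#'
#' Refits the model on `n_iter` response-shuffled copies of the data (with
#' the hyperparameters already selected for the real model) to build a null
#' distribution of the headline statistic (Q2 for regression, MCC for
#' classification) and locate the real model's percentile within it. A real
#' score far above the null excludes chance correlation.
#'
#' @param table descriptor matrix.
#' @param y response (numeric or labels).
#' @param model_fun function `(X, y) -> numeric statistic` embodying the
#'   fixed model recipe (fit + evaluate).
#' @param n_iter number of shuffles (default 500).
#' @param seed RNG seed.
#' @return list of class `y_randomization`: `real_score`, `null_scores`,
#'   `percentile` (percent of null scores below the real score).
#' @export
y_randomization <- function(table, y, model_fun, n_iter = 500L, seed = 1L) {
  X <- as.matrix(table)
  real <- model_fun(X, y)
  null_scores <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i) model_fun(X, sample(y)), 0)
  })
  structure(list(real_score = real, null_scores = null_scores,
                 n_iter = n_iter,
                 percentile = 100 * mean(null_scores < real)),
            class = "y_randomization")
}

#' @export
print.y_randomization <- function(x, ...) {
  cat(sprintf("Y-randomization (%d shuffles): real %.4f vs null %.4f +/- %.4f (percentile %.1f)\n",
              x$n_iter, x$real_score, mean(x$null_scores),
              sd(x$null_scores), x$percentile))
  invisible(x)
}

#' Resampling stability of a modelling recipe
#'
#' Repeats a random stratified 4:1 train/test split `n_iter` times, refits
#' and re-evaluates each time, and summarizes the headline test metric as
#' mean and standard deviation.
#'
#' @param table descriptor matrix.
#' @param y response.
#' @param model_fun function `(X_train, y_train, X_test, y_test) -> numeric`
#'   returning the test metric of one fit.
#' @param n_iter number of resamples (default 100).
#' @param seed RNG seed (split seeds are derived deterministically).
#' @param test_fraction held-out fraction (default 0.2).
#' @return list of class `resample_stability`: per-iteration `scores`,
#'   `mean`, `sd`.
#' @export
resample_stability <- function(table, y, model_fun, n_iter = 100L, seed = 1L,
                               test_fraction = 0.2) {
  X <- as.matrix(table)
  split_seeds <- with_seed(seed, sample.int(2^30, n_iter))
  scores <- vapply(seq_len(n_iter), function(i) {
    sp <- split_train_test(X, y, test_fraction = test_fraction,
                           seed = split_seeds[i],
                           stratified = !is.numeric(y))
    model_fun(sp$X_train, sp$y_train, sp$X_test, sp$y_test)
  }, 0)
  structure(list(scores = scores, mean = mean(scores), sd = sd(scores),
                 n_iter = n_iter),
            class = "resample_stability")
}

#' @export
print.resample_stability <- function(x, ...) {
  cat(sprintf("resampling (%d iterations): %.4f +/- %.4f\n",
              x$n_iter, x$mean, x$sd))
  invisible(x)
}

#' Applicability domain by centroid distance
#'
#' A query is in-domain iff its Euclidean distance to the training centroid
#' in descriptor space is at most `mean + 3 sd` of the training points' own
#' centroid distances. The threshold is computed once and persisted with
#' the object, so decisions are deterministic.
#'
#' @param train_table training descriptor matrix.
#' @return object of class `applicability_domain` with `centroid`,
#'   `threshold` and the training `distances`.
#' @export
applicability_domain <- function(train_table) {
  X <- as.matrix(train_table)
  ctr <- colMeans(X)
  d <- sqrt(rowSums(sweep(X, 2, ctr)^2))
  structure(list(centroid = ctr, distances = d,
                 threshold = mean(d) + 3 * sd(d)),
            class = "applicability_domain")
}

#' @export
print.applicability_domain <- function(x, ...) {
  cat(sprintf("applicability domain: centroid distance threshold %.4f (mean %.4f + 3 sd %.4f)\n",
              x$threshold, mean(x$distances), sd(x$distances)))
  invisible(x)
}

#' Applicability-domain decision for query vectors
#'
#' @param object an `applicability_domain`.
#' @param newdata query matrix or single descriptor vector.
#' @param ... unused.
#' @return data.frame with `distance` and logical `in_domain`.
#' @export
predict.applicability_domain <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  d <- sqrt(rowSums(sweep(newdata, 2, object$centroid)^2))
  data.frame(distance = d, in_domain = d <= object$threshold)
}
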