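# Independent oracles. These deliberately re-derive quantities by brute
# force (numerical integration, naive loops, direct formulas) and never call
# the implementation paths they check.

# Riemann-sum integration of the product of two summed Gaussian densities.
# The first-order analytic overlap is exactly this integral, so a fine grid
# must agree within the discretization error.
grid_overlap_oracle <- function(A, B, step = 0.1, margin = 4.0) {
  allc <- rbind(A$centers, B$centers)
  lo <- apply(allc, 2, min) - margin
  hi <- apply(allc, 2, max) + margin
  xs <- seq(lo[1], hi[1], by = step)
  ys <- seq(lo[2], hi[2], by = step)
  zs <- seq(lo[3], hi[3], by = step)
  grid <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  dens <- function(sh) {
    v <- numeric(nrow(grid))
    for (i in seq_len(nrow(sh$centers))) {
      d2 <- (grid[, 1] - sh$centers[i, 1])^2 +
            (grid[, 2] - sh$centers[i, 2])^2 +
            (grid[, 3] - sh$centers[i, 3])^2
      v <- v + sh$amplitudes[i] * exp(-sh$alphas[i] * d2)
    }
    v
  }
  sum(dens(A) * dens(B)) * step^3
}

# Naive confusion-matrix statistics straight from the defining formulas.
oracle_class_metrics <- function(t_pos, p_pos) {
  TP <- 0; TN <- 0; FP <- 0; FN <- 0
  for (i in seq_along(t_pos)) {
    if (t_pos[i] && p_pos[i]) TP <- TP + 1
    if (!t_pos[i] && !p_pos[i]) TN <- TN + 1
    if (!t_pos[i] && p_pos[i]) FP <- FP + 1
    if (t_pos[i] && !p_pos[i]) FN <- FN + 1
  }
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  mcc_den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  list(ACC = safe(TP + TN, length(t_pos)),
       Precision = safe(TP, TP + FP),
       Recall = safe(TP, TP + FN),
       Specificity = safe(TN, TN + FP),
       MCC = if (mcc_den == 0) NA_real_ else (TP * TN - FP * FN) / mcc_den)
}

# AUC by exhaustive pair comparison (the probabilistic definition).
oracle_auc <- function(scores, pos) {
  ps <- scores[pos]; ns <- scores[!pos]
  if (length(ps) == 0 || length(ns) == 0) return(NA_real_)
  tot <- 0
  for (a in ps) for (b in ns) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(ps) * length(ns))
}

oracle_regression <- function(y, yhat) {
  n <- length(y)
  rmse <- sqrt(sum((y - yhat)^2) / n)
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(RMSE = rmse, R2 = r2)
}

# Best 2-subset by exhaustive enumeration: maximizes the pairwise distance.
oracle_best_pair <- function(D) {
  n <- nrow(D)
  best <- c(1, 2); bd <- -Inf
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (D[i, j] > bd) { bd <- D[i, j]; best <- c(i, j) }
  }
  list(pair = best, dist = bd)
}
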