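# Seedable generators of toy molecules and synthetic descriptor datasets.
# Everything here is bit-reproducible per seed, so the whole geometric and
# modelling stack is testable without downloading any structure database.

#' Generate a toy molecule
#'
#' Four families with controllably distinct 3D shapes:
#' `rigid_ring` (planar carbocycle, optionally decorated with a polar
#' substituent; no rotatable bonds), `chain` (zig-zag heavy-atom chain with
#' random N/O substitutions; flexible), `star` (central carbon with 4
#' two-atom arms), and `random_druglike` (random bonded tree with mixed
#' elements and occasional formal charges). No atom pair is closer than
#' 1.0 A; radii come from the element table and features are assigned by
#' the default rules.
#'
#' @param seed RNG seed; identical seeds give identical molecules.
#' @param family one of `"rigid_ring"`, `"chain"`, `"star"`,
#'   `"random_druglike"`.
#' @param id molecule id (default derived from family and seed).
#' @return a `typed_molecule` with one conformer and features assigned.
#' @export
make_toy_molecule <- function(seed = 1L,
                              family = c("rigid_ring", "chain", "star",
                                         "random_druglike"),
                              id = NULL) {
  family <- match.arg(family)
  if (is.null(id)) id <- sprintf("%s_%d", family, seed)
  mol <- with_seed(seed, switch(family,
    rigid_ring = toy_rigid_ring(id),
    chain = toy_chain(id),
    star = toy_star(id),
    random_druglike = toy_random_druglike(id)))
  assign_feature_types(add_hydrogens(mol))
}

toy_rigid_ring <- function(id) {
  n <- sample(5:7, 1)
  r <- 1.4 / (2 * sin(pi / n))
  th <- 2 * pi * (seq_len(n) - 1) / n
  xyz <- cbind(r * cos(th), r * sin(th), rep(0, n))
  el <- rep("C", n)
  if (runif(1) < 0.5) el[1] <- sample(c("N", "O"), 1)
  bonds <- data.frame(from = seq_len(n), to = c(2:n, 1L), order = 1,
                      aromatic = TRUE)
  # optional exocyclic substituent (terminal, so still rigid)
  if (runif(1) < 0.7) {
    sub <- sample(c("O", "N", "C", "Cl"), 1)
    anchor <- sample(2:n, 1)
    dir <- xyz[anchor, ] / sqrt(sum(xyz[anchor, ]^2))
    xyz <- rbind(xyz, xyz[anchor, ] + 1.4 * dir)
    el <- c(el, sub)
    bonds <- rbind(bonds, data.frame(from = anchor, to = n + 1L, order = 1,
                                     aromatic = FALSE))
  }
  typed_molecule(id, data.frame(element = el, charge = 0L,
                                stringsAsFactors = FALSE),
                 bonds, list(unname(xyz)))
}

toy_chain <- function(id) {
  n <- sample(6:12, 1)
  el <- ifelse(runif(n) < 0.75, "C", sample(c("N", "O"), n, replace = TRUE))
  # tetrahedral zig-zag backbone
  xyz <- matrix(0, n, 3)
  dirs <- cbind(rep(c(1, 1), length.out = n - 1) * 1.25,
                rep(c(0.85, -0.85), length.out = n - 1), 0)
  for (i in 2:n) xyz[i, ] <- xyz[i - 1, ] + dirs[i - 1, ]
  bonds <- data.frame(from = 1:(n - 1), to = 2:n, order = 1,
                      aromatic = FALSE)
  typed_molecule(id, data.frame(element = el, charge = 0L,
                                stringsAsFactors = FALSE),
                 bonds, list(unname(xyz)))
}

toy_star <- function(id) {
  arms <- 4
  el <- "C"; xyz <- matrix(0, 1, 3)
  bonds <- NULL
  axes <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  for (a in seq_len(arms)) {
    e1 <- "C"
    e2 <- sample(c("C", "N", "O"), 1)
    p1 <- axes[a, ] * 1.5
    p2 <- axes[a, ] * 3.0 + runif(3, -0.3, 0.3)
    i1 <- nrow(xyz) + 1L; i2 <- i1 + 1L
    xyz <- rbind(xyz, p1, p2)
    el <- c(el, e1, e2)
    bonds <- rbind(bonds,
                   data.frame(from = c(1L, i1), to = c(i1, i2), order = 1,
                              aromatic = FALSE))
  }
  typed_molecule(id, data.frame(element = el, charge = 0L,
                                stringsAsFactors = FALSE),
                 bonds, list(unname(xyz)))
}

toy_random_druglike <- function(id) {
  n <- sample(8:16, 1)
  el <- sample(c("C", "N", "O"), n, replace = TRUE,
               prob = c(0.7, 0.15, 0.15))
  chg <- integer(n)
  polar <- which(el != "C")
  if (runif(1) < 0.25 && length(polar) > 0) {
    i <- polar[sample.int(length(polar), 1)]
    chg[i] <- sample(c(-1L, 1L), 1)
  }
  xyz <- matrix(0, n, 3)
  parent <- integer(n)
  for (i in 2:n) {
    for (attempt in 1:50) {
      parent[i] <- sample(seq_len(i - 1), 1)
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      cand <- xyz[parent[i], ] + 1.5 * dir
      d <- sqrt(rowSums(sweep(xyz[seq_len(i - 1), , drop = FALSE], 2,
                              cand)^2))
      if (all(d >= 1.1)) break
    }
    xyz[i, ] <- cand
  }
  bonds <- data.frame(from = parent[-1], to = 2:n, order = 1,
                      aromatic = FALSE)
  typed_molecule(id, data.frame(element = el, charge = chg,
                                stringsAsFactors = FALSE),
                 bonds, list(unname(xyz)))
}

#' Random rigidly transformed copy of a molecule
#'
#' Applies one uniform random rotation plus a translation drawn from
#' `[-10, 10]^3` Angstrom to every conformer; internal distances are
#' preserved exactly. Supports pose-invariance tests.
#'
#' @param mol a `typed_molecule`.
#' @param seed RNG seed.
#' @return the transformed molecule (id suffixed `_copy`).
#' @export
random_rigid_copy <- function(mol, seed = 1L) {
  p <- with_seed(seed, pose(random_quaternion(), runif(3, -10, 10)))
  mol$conformers <- lapply(mol$conformers, apply_pose, p = p)
  mol$id <- paste0(mol$id, "_copy")
  mol
}

#' Synthetic classification descriptor dataset with planted signal
#'
#' Emulates the statistics of real shape-similarity profiles, whose scores
#' concentrate in the mid-range (roughly 0.3-0.7): decoy rows are
#' Beta-distributed around 0.45; active rows add a mean shift `delta` on
#' `m` informative dimensions plus Gaussian noise `sigma`, clipped to
#' `[0, 1]`. The informative dimension indices are returned so recovery
#' can be tested.
#'
#' @param seed RNG seed.
#' @param n_active,n_decoy class sizes (defaults 100 / 400).
#' @param k profile length (default 300).
#' @param m number of informative dimensions (default 15).
#' @param delta mean shift on informative dimensions (default 0.25).
#' @param sigma Gaussian noise standard deviation on active rows
#'   (default 0.05).
#' @return list with `table` (matrix with row/col names), `labels` (factor
#'   active/decoy, active first), `informative` (column indices).
#' @export
make_classification_dataset <- function(seed = 42L, n_active = 100L,
                                        n_decoy = 400L, k = 300L, m = 15L,
                                        delta = 0.25, sigma = 0.05) {
  stopifnot(m <= k)
  with_seed(seed, {
    informative <- sort(sample.int(k, m))
    decoys <- matrix(rbeta(n_decoy * k, 4.05, 4.95), n_decoy, k)
    actives <- matrix(rbeta(n_active * k, 4.05, 4.95), n_active, k)
    actives[, informative] <- actives[, informative] + delta
    actives <- actives + rnorm(n_active * k, sd = sigma)
    actives <- pmin(pmax(actives, 0), 1)
    tab <- rbind(actives, decoys)
    rownames(tab) <- c(sprintf("active%d", seq_len(n_active)),
                       sprintf("decoy%d", seq_len(n_decoy)))
    colnames(tab) <- sprintf("T%03d", seq_len(k))
    list(table = tab,
         labels = factor(rep(c("active", "decoy"), c(n_active, n_decoy)),
                         levels = c("active", "decoy")),
         informative = informative)
  })
}

#' Synthetic subtype-selectivity dataset
#'
#' Selectivity ratios are drawn from a three-component mixture (a
#' nonselective core around 0 and two selective tails beyond the +/- 1.3
#' threshold); descriptor rows are Beta baseline profiles whose `n_info`
#' chosen dimensions respond linearly to SR (signs alternating) plus noise,
#' so regression recovery is possible by construction.
#'
#' @param seed RNG seed.
#' @param n number of compounds (default 300).
#' @param k profile length (default 60).
#' @param n_info number of SR-coupled dimensions (default 10).
#' @param threshold selectivity threshold for labels (default 1.3).
#' @param mix_weights mixture weights (core, A tail, B tail).
#' @return list with `activities` (data.frame id, pKi_A, pKi_B),
#'   `table` (descriptor matrix), `records` (labelled selectivity
#'   data.frame) and `informative` (coupled dimensions).
#' @export
make_selectivity_dataset <- function(seed = 7L, n = 300L, k = 60L,
                                     n_info = 10L, threshold = 1.3,
                                     mix_weights = c(0.5, 0.25, 0.25)) {
  with_seed(seed, {
    comp <- sample.int(3, n, replace = TRUE, prob = mix_weights)
    SR <- c(rnorm(n, 0, 0.5), rnorm(n, 2.2, 0.5),
            rnorm(n, -2.2, 0.5))[seq_len(n) + (comp - 1) * n]
    pKi_B <- runif(n, 6, 9)
    pKi_A <- pKi_B + SR
    informative <- sort(sample.int(k, n_info))
    signs <- rep(c(1, -1), length.out = n_info)
    tab <- matrix(rbeta(n * k, 4.05, 4.95), n, k)
    for (j in seq_len(n_info)) {
      tab[, informative[j]] <- tab[, informative[j]] +
        signs[j] * 0.08 * SR + rnorm(n, sd = 0.03)
    }
    tab <- pmin(pmax(tab, 0), 1)
    ids <- sprintf("cpd%03d", seq_len(n))
    rownames(tab) <- ids
    colnames(tab) <- sprintf("T%03d", seq_len(k))
    list(activities = data.frame(molecule_id = ids, pKi_A = pKi_A,
                                 pKi_B = pKi_B, stringsAsFactors = FALSE),
         table = tab,
         records = label_selectivity(pKi_A, pKi_B, threshold, ids = ids),
         informative = informative)
  })
}
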