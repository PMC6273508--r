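test_that("single-atom self volume equals the hard-sphere volume", {
  sh <- make_shape(atom_cloud(matrix(0, 1, 3)))
  expect_equal(sh$self_overlap, 4 / 3 * pi * 1.70^3, tolerance = 0.01)
  # and nitrogen with its own radius
  shN <- make_shape(atom_cloud(matrix(0, 1, 3), "N"))
  expect_equal(shN$self_overlap, 4 / 3 * pi * 1.55^3, tolerance = 0.01)
})

test_that("overlap volume: additivity, decay, translation covariance, symmetry", {
  far <- make_shape(atom_cloud(rbind(c(0, 0, 0), c(50, 0, 0)), id = "far"))
  one <- make_shape(atom_cloud(matrix(0, 1, 3)))
  # two disjoint atoms: self volume is the sum of atomic volumes
  expect_equal(far$self_overlap, 2 * one$self_overlap, tolerance = 1e-6)
  # 10 A apart: cross overlap vanishes
  a <- make_shape(atom_cloud(matrix(0, 1, 3)))
  b <- make_shape(atom_cloud(matrix(c(10, 0, 0), 1, 3)))
  expect_lt(overlap_volume(a, b), 1e-6)
  # translation covariance of make_shape
  m <- atom_cloud(rbind(c(0, 0, 0), c(1.5, 0, 0)))
  mt <- m
  mt$conformers <- list(sweep(m$conformers[[1]], 2, c(1, 2, 3), "+"))
  expect_equal(make_shape(mt)$centers,
               sweep(make_shape(m)$centers, 2, c(1, 2, 3), "+"))
  # symmetry under pose inversion
  set.seed(3)
  A <- small_random_shape(31, 3); B <- small_random_shape(32, 4)
  p <- pose(brs3d:::random_quaternion(), runif(3, -2, 2))
  expect_equal(overlap_volume(A, B, p), overlap_volume(B, A, invert_pose(p)),
               tolerance = 1e-9)
})

test_that("analytic overlap matches grid integration on random pairs", {
  # more pairs are exercised in the acceptance suite; here a quick spotcheck
  for (s in 1:4) {
    A <- small_random_shape(400 + s, 2)
    B <- small_random_shape(500 + s, 3)
    v <- overlap_volume(A, B)
    expect_equal(v, grid_overlap_oracle(A, B, step = 0.1), tolerance = 0.01)
  }
})

test_that("shape tanimoto: identity, disjoint shapes and rigid invariance", {
  A <- small_random_shape(41, 4)
  expect_equal(shape_tanimoto(A, A), 1.0, tolerance = 1e-6)
  B <- A
  B$centers <- sweep(B$centers, 2, c(50, 0, 0), "+")
  expect_lt(shape_tanimoto(A, B), 1e-6)
  # applying one common rigid transform to both (pose composed accordingly)
  set.seed(4)
  C <- small_random_shape(42, 3)
  p <- pose(brs3d:::random_quaternion(), runif(3, -3, 3))   # B -> A frame
  g <- pose(brs3d:::random_quaternion(), runif(3, -3, 3))   # common transform
  A2 <- A; A2$centers <- apply_pose(A$centers, g)
  C2 <- C; C2$centers <- apply_pose(C$centers, g)
  p2 <- brs3d:::compose_poses(g, brs3d:::compose_poses(p, invert_pose(g)))
  expect_equal(shape_tanimoto(A2, C2, p2), shape_tanimoto(A, C, p),
               tolerance = 1e-9)
})

test_that("feature tanimoto handles identity, disjoint types and vacuous case", {
  don <- typed_molecule("don", data.frame(element = c("N", "H", "H"),
                                          charge = 0L),
                        data.frame(from = c(1L, 1L), to = c(2L, 3L),
                                   order = 1, aromatic = FALSE),
                        conformers = list(rbind(c(0, 0, 0), c(1, 0, 0),
                                                c(0, 1, 0))))
  don <- assign_feature_types(don)
  dsh <- make_shape(don)
  expect_equal(feature_tanimoto(dsh, dsh), 1.0, tolerance = 1e-9)
  # a pure-carbon shape has only hydrophobic features: no type in common
  csh <- make_shape(atom_cloud(matrix(0, 1, 3)))
  expect_equal(feature_tanimoto(dsh, csh), 0)
  # both feature-free -> vacuous agreement
  bare <- make_shape(structure(list(id = "x",
    atoms = data.frame(element = "C", charge = 0L, radius = 1.7),
    bonds = data.frame(from = integer(), to = integer(), order = numeric(),
                       aromatic = logical()),
    conformers = list(matrix(0, 1, 3)),
    features = list(character())), class = "typed_molecule"))
  expect_equal(feature_tanimoto(bare, bare), 1.0)
})

test_that("combined score is exactly the configured mixture", {
  A <- small_random_shape(51, 3); B <- small_random_shape(52, 4)
  p <- pose(translation = c(0.5, 0, 0))
  for (w in c(0, 0.25, 0.5, 1)) {
    expect_equal(combined_similarity(A, B, p, w_shape = w),
                 w * shape_tanimoto(A, B, p) +
                   (1 - w) * feature_tanimoto(A, B, p), tolerance = 1e-12)
  }
})

test_that("the C++ pose scorer agrees with the R scorers", {
  # dual-route check: optimized scorer vs the plain R composition
  for (s in 1:5) {
    q <- make_shape(make_toy_molecule(600 + s,
                                      toy_families[1 + s %% 4]))
    t <- make_shape(make_toy_molecule(700 + s,
                                      toy_families[1 + (s + 1) %% 4]))
    par <- brs3d:::with_seed(s, runif(6, -0.5, 0.5))
    R0 <- brs3d:::expmap_to_matrix(brs3d:::with_seed(s + 9, rnorm(3)))
    t0 <- c(1, -2, 0.5)
    types <- union(names(t$feature_points), names(q$feature_points))
    empty <- matrix(0, 0, 3)
    gf <- function(sh, ty) if (is.null(sh$feature_points[[ty]])) empty
                           else sh$feature_points[[ty]]
    fs <- function(sh, ty) {
      v <- sh$feature_self[ty]
      if (is.na(v)) 0 else unname(v)
    }
    cpp <- brs3d:::cpp_pose_score(
      t$centers, t$alphas, t$amplitudes, t$self_overlap,
      q$centers, q$alphas, q$amplitudes, q$self_overlap,
      lapply(types, gf, sh = t), lapply(types, gf, sh = q),
      vapply(types, fs, 0, sh = t), vapply(types, fs, 0, sh = q),
      brs3d:::gp_alpha(1.0), brs3d:::GP_AMPLITUDE,
      0.5, par, R0, t0)
    p <- brs3d:::pose_from_matrix(
      brs3d:::expmap_to_matrix(par[1:3]) %*% R0, t0 + par[4:6])
    expect_equal(cpp, combined_similarity(t, q, p, 0.5), tolerance = 1e-9)
  }
})

test_that("rigid_align recovers a known transform and never degrades", {
  mol <- make_toy_molecule(61, "random_druglike")
  sh <- make_shape(mol)
  # 90 degrees about z plus (5, 0, 0)
  p <- pose(c(cos(pi / 4), 0, 0, sin(pi / 4)), c(5, 0, 0))
  moved <- mol
  moved$conformers <- list(apply_pose(mol$conformers[[1]], p))
  res <- rigid_align(make_shape(moved), sh)
  expect_gte(res$combined_score, 0.99)
  # scores bounded and mixture identity holds
  expect_lte(res$combined_score, 1 + 1e-9)
  expect_equal(res$combined_score,
               0.5 * res$shape_score + 0.5 * res$feature_score,
               tolerance = 1e-12)
  # optimizer contract: refined score >= every starting-pose score
  start <- combined_similarity(sh, make_shape(moved),
                               pose(translation =
                                 colMeans(sh$centers) -
                                 colMeans(make_shape(moved)$centers)))
  expect_gte(res$combined_score, start - 1e-9)
})

test_that("rigid_align handles single-atom shapes via centroid overlay", {
  a <- make_shape(atom_cloud(matrix(c(1, 2, 3), 1, 3)))
  b <- make_shape(atom_cloud(matrix(c(-2, 0, 5), 1, 3)))
  res <- rigid_align(a, b)
  expect_equal(res$combined_score, 1.0, tolerance = 1e-4)
  expect_equal(apply_pose(a$centers, res$pose), b$centers,
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("flexible superimposition pools conformers and orders scores", {
  q <- generate_conformers(make_toy_molecule(62, "chain"), max_confs = 12,
                           rmsd_prune = 0.3, seed = 8)
  tmpl <- make_shape(make_toy_molecule(63, "star"))
  res <- flexible_superimpose(q, tmpl, top_n = 10)
  expect_lte(length(res), 10)
  sc <- vapply(res, `[[`, 0, "combined_score")
  expect_true(all(diff(sc) <= 1e-12))
  # brute force: the reported max equals the max over per-conformer aligns
  brute <- max(vapply(seq_along(q$conformers), function(ci)
    rigid_align(make_shape(q, ci), tmpl)$combined_score, 0))
  expect_equal(sc[1], brute, tolerance = 1e-9)
  # single-conformer query -> list of length 1
  one <- make_toy_molecule(64, "rigid_ring")
  expect_length(flexible_superimpose(one, tmpl, top_n = 10), 1)
  # zero conformers -> explicit error
  none <- one
  none$conformers <- list()
  expect_error(flexible_superimpose(none, tmpl), "unprofiled")
})

test_that("self-superimposition and input-pose invariance hold", {
  mol <- make_toy_molecule(65, "random_druglike")
  tmpl <- make_shape(mol)
  res <- flexible_superimpose(mol, tmpl, top_n = 3)
  expect_gte(res[[1]]$combined_score, 0.99)
  # pre-transforming the query input changes the final max score by <= 0.02
  moved <- random_rigid_copy(mol, 77)
  res2 <- flexible_superimpose(moved, tmpl, top_n = 3)
  expect_lt(abs(res2[[1]]$combined_score - res[[1]]$combined_score), 0.02)
})
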