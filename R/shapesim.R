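# Gaussian shape + pharmacophore-feature similarity scoring and rigid /
# flexible superimposition.
#
# Atoms are modelled as spherical Gaussians in the Grant-Pickup
# parametrization: amplitude p = 2*sqrt(2) and exponent
# alpha = pi * (3 p / (4 pi))^(2/3) / R^2, which makes the isolated-atom
# pairwise self-overlap equal to the hard-sphere volume 4/3 pi R^3. Only
# heavy atoms enter the shape; pharmacophore features are separate Gaussian
# points of fixed 1.0 A radius. Similarity is first-order overlap Tanimoto
# in [0, 1]; the combined score is w * shape + (1 - w) * feature with
# default w = 0.5. A combined score around 0.7 or higher indicates a strong
# shape/property relationship between two molecules.

GP_AMPLITUDE <- 2 * sqrt(2)

gp_alpha <- function(radius) {
  pi * (3 * GP_AMPLITUDE / (4 * pi))^(2 / 3) / radius^2
}

FEATURE_RADIUS <- 1.0

#' Build a Gaussian shape from a molecule conformer
#'
#' @param mol a `typed_molecule` (features are assigned with default rules
#'   if missing).
#' @param conformer_index which conformer to use (default 1).
#' @return object of class `gaussian_shape` with atom-centred Gaussians for
#'   every heavy atom, per-feature-type point sets, and cached self-overlaps.
#' @export
make_shape <- function(mol, conformer_index = 1L) {
  if (length(mol$conformers) < conformer_index)
    stop("molecule ", mol$id, " has no conformer ", conformer_index)
  heavy <- heavy_atoms(mol)
  if (length(heavy) == 0) stop("empty heavy-atom set for ", mol$id)
  if (is.null(mol$features)) mol <- assign_feature_types(mol)
  xyz <- mol$conformers[[conformer_index]][heavy, , drop = FALSE]
  alphas <- gp_alpha(mol$atoms$radius[heavy])
  amps <- rep(GP_AMPLITUDE, length(heavy))
  fp <- list()
  ftypes <- unique(unlist(mol$features[heavy]))
  for (t in ftypes) {
    rows <- which(vapply(mol$features[heavy], function(f) t %in% f, TRUE))
    fp[[t]] <- xyz[rows, , drop = FALSE]
  }
  sh <- structure(list(centers = unname(xyz), alphas = alphas,
                       amplitudes = amps, feature_points = fp,
                       id = mol$id), class = "gaussian_shape")
  sh$self_overlap <- overlap_volume(sh, sh)
  sh$feature_self <- vapply(fp, function(m) feature_point_overlap(m, m), 0)
  sh
}

#' @export
print.gaussian_shape <- function(x, ...) {
  cat(sprintf("gaussian_shape '%s': %d heavy atoms, features: %s\n",
              if (is.null(x$id)) "?" else x$id, nrow(x$centers),
              if (length(x$feature_points))
                paste(names(x$feature_points), collapse = ", ") else "none"))
  invisible(x)
}

feature_point_overlap <- function(ca, cb) {
  n_a <- nrow(ca); n_b <- nrow(cb)
  if (n_a == 0 || n_b == 0) return(0)
  al <- gp_alpha(FEATURE_RADIUS)
  cpp_gaussian_overlap(ca, rep(al, n_a), rep(GP_AMPLITUDE, n_a),
                       cb, rep(al, n_b), rep(GP_AMPLITUDE, n_b))
}

#' First-order Gaussian overlap volume
#'
#' \eqn{V_{AB} = \sum_{ij} p_i p_j (\pi/(\alpha_i+\alpha_j))^{3/2}
#' \exp(-\alpha_i\alpha_j d_{ij}^2/(\alpha_i+\alpha_j))}, the exact integral
#' of the product of the two summed Gaussian densities. The pose is applied
#' to `B`.
#'
#' @param A,B `gaussian_shape` objects.
#' @param p a [pose()] applied to `B` (default identity).
#' @return overlap volume in cubic Angstrom.
#' @export
overlap_volume <- function(A, B, p = identity_pose()) {
  cpp_gaussian_overlap(A$centers, A$alphas, A$amplitudes,
                       apply_pose(B$centers, p), B$alphas, B$amplitudes)
}

#' Shape Tanimoto similarity
#'
#' `V_AB / (V_AA + V_BB - V_AB)` with self-overlaps at identity pose.
#'
#' @inheritParams overlap_volume
#' @return similarity in `[0, 1]`.
#' @export
shape_tanimoto <- function(A, B, p = identity_pose()) {
  vab <- overlap_volume(A, B, p)
  vaa <- if (!is.null(A$self_overlap)) A$self_overlap else overlap_volume(A, A)
  vbb <- if (!is.null(B$self_overlap)) B$self_overlap else overlap_volume(B, B)
  denom <- vaa + vbb - vab
  if (denom <= 0) stop("degenerate shape Tanimoto denominator (",
                       denom, "); shapes are numerically corrupt")
  vab / denom
}

#' Pharmacophore feature Tanimoto similarity
#'
#' Per feature type present in either shape, a Gaussian-overlap Tanimoto of
#' that type's points (fixed 1.0 A radius); the final score is the mean over
#' present types. Two feature-free shapes agree vacuously (score 1).
#'
#' @inheritParams overlap_volume
#' @return similarity in `[0, 1]`.
#' @export
feature_tanimoto <- function(A, B, p = identity_pose()) {
  types <- union(names(A$feature_points), names(B$feature_points))
  types <- types[vapply(types, function(t) {
    (!is.null(A$feature_points[[t]]) && nrow(A$feature_points[[t]]) > 0) ||
    (!is.null(B$feature_points[[t]]) && nrow(B$feature_points[[t]]) > 0)
  }, TRUE)]
  if (length(types) == 0) return(1)
  scores <- vapply(types, function(t) {
    ca <- A$feature_points[[t]]; cb <- B$feature_points[[t]]
    if (is.null(ca) || nrow(ca) == 0 || is.null(cb) || nrow(cb) == 0)
      return(0)
    vab <- feature_point_overlap(ca, apply_pose(cb, p))
    vaa <- if (!is.null(A$feature_self)) A$feature_self[[t]]
           else feature_point_overlap(ca, ca)
    vbb <- if (!is.null(B$feature_self)) B$feature_self[[t]]
           else feature_point_overlap(cb, cb)
    vab / (vaa + vbb - vab)
  }, 0)
  mean(scores)
}

#' Combined shape + feature similarity
#'
#' @inheritParams overlap_volume
#' @param w_shape weight of the shape term in `[0, 1]` (default 0.5).
#' @return `w_shape * shape_tanimoto + (1 - w_shape) * feature_tanimoto`.
#' @export
combined_similarity <- function(A, B, p = identity_pose(), w_shape = 0.5) {
  w_shape * shape_tanimoto(A, B, p) +
    (1 - w_shape) * feature_tanimoto(A, B, p)
}

alignment_result <- function(p, shape_score, feature_score, w_shape,
                             conformer_index = NA_integer_) {
  structure(list(pose = p, shape_score = shape_score,
                 feature_score = feature_score,
                 combined_score = w_shape * shape_score +
                   (1 - w_shape) * feature_score,
                 w_shape = w_shape, conformer_index = conformer_index),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("alignment: combined %.4f (shape %.4f, feature %.4f, w = %.2f)%s\n",
              x$combined_score, x$shape_score, x$feature_score, x$w_shape,
              if (!is.na(x$conformer_index))
                sprintf(", conformer %d", x$conformer_index) else ""))
  invisible(x)
}

# Gaussian-weighted centroid and principal axes (proper rotation).
shape_axes <- function(sh) {
  w <- sh$amplitudes * (pi / sh$alphas)^1.5
  w <- w / sum(w)
  ctr <- as.numeric(t(sh$centers) %*% w)
  xc <- sweep(sh$centers, 2, ctr)
  C <- t(xc) %*% (xc * w)
  ev <- eigen(C, symmetric = TRUE)
  U <- ev$vectors
  if (det(U) < 0) U[, 3] <- -U[, 3]
  list(center = ctr, axes = U, values = ev$values)
}

#' Rigid alignment of one Gaussian shape onto another
#'
#' Search strategy: overlay Gaussian-weighted centroids, align principal
#' axes with the four proper axis-flip sign combinations (four starting
#' poses), then refine each with derivative-free Nelder-Mead maximization
#' of the combined score over 6 rigid degrees of freedom (rotation
#' exponential map + translation; score tolerance 1e-4, at most 500
#' iterations). Deterministic; ties between starts go to the lowest start
#' index. Shapes with a degenerate inertia tensor (e.g. a single atom) skip
#' the axes step and refine from the centroid overlay.
#'
#' @param query,template `gaussian_shape` objects; the returned pose maps
#'   the query onto the template.
#' @param w_shape combined-score shape weight (default 0.5).
#' @return an `alignment_result`.
#' @export
rigid_align <- function(query, template, w_shape = 0.5) {
  stopifnot(nrow(query$centers) >= 1, nrow(template$centers) >= 1)
  aq <- shape_axes(query); at <- shape_axes(template)
  degenerate <- nrow(query$centers) == 1 || nrow(template$centers) == 1 ||
    aq$values[1] < 1e-8 || at$values[1] < 1e-8
  # the query is re-expressed about its Gaussian centroid so that the
  # rotation parameters pivot at the overlay point: refinement is then
  # equivariant to the query's input pose (a translated copy explores the
  # same neighbourhood), which the profile pose-invariance contract needs
  starts <- list()
  if (degenerate) {
    starts[[1]] <- diag(3)
  } else {
    flips <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
    # besides the 4 proper axis flips, seed extra 90-degree rotations about
    # the template axes so near-symmetric shapes are not trapped in a
    # pose-dependent local optimum
    extra <- list(diag(3),
                  expmap_to_matrix(c(pi / 2, 0, 0)),
                  expmap_to_matrix(c(0, pi / 2, 0)),
                  expmap_to_matrix(c(0, 0, pi / 2)))
    for (f in flips) {
      base <- at$axes %*% diag(f) %*% t(aq$axes)
      for (E in extra) {
        starts[[length(starts) + 1L]] <-
          at$axes %*% E %*% t(at$axes) %*% base
      }
    }
  }
  # union of feature types present in either shape, as parallel lists for
  # the C++ scorer (0-row matrix = type absent on that side)
  types <- union(names(template$feature_points), names(query$feature_points))
  empty <- matrix(0, 0, 3)
  tfeat <- lapply(types, function(t) template$feature_points[[t]] %||% empty)
  qfeat <- lapply(types, function(t) query$feature_points[[t]] %||% empty)
  tfs <- vapply(types, function(t) template$feature_self[t] %||% 0, 0)
  qfs <- vapply(types, function(t) query$feature_self[t] %||% 0, 0)
  tfs[is.na(tfs)] <- 0; qfs[is.na(qfs)] <- 0
  fa <- gp_alpha(FEATURE_RADIUS)
  # centred query: coordinates relative to the Gaussian centroid
  qcen <- sweep(query$centers, 2, aq$center)
  qfeat_cen <- lapply(qfeat, function(m)
    if (nrow(m) == 0) m else sweep(m, 2, aq$center))
  t0 <- at$center
  best <- NULL; best_score <- -Inf
  for (R0 in starts) {
    fn <- function(par) {
      cpp_pose_score(template$centers, template$alphas, template$amplitudes,
                     template$self_overlap,
                     qcen, query$alphas, query$amplitudes,
                     query$self_overlap,
                     tfeat, qfeat_cen, tfs, qfs, fa, GP_AMPLITUDE,
                     w_shape, par, R0, t0)
    }
    fit <- optim(rep(0, 6), fn, method = "Nelder-Mead",
                 control = list(fnscale = -1, reltol = 1e-4, maxit = 500))
    # one simplex restart from the converged point guards against
    # premature Nelder-Mead collapse
    fit2 <- optim(fit$par, fn, method = "Nelder-Mead",
                  control = list(fnscale = -1, reltol = 1e-4, maxit = 500))
    if (fit2$value > fit$value) fit <- fit2
    if (fit$value > best_score) {
      best_score <- fit$value
      R <- expmap_to_matrix(fit$par[1:3]) %*% R0
      best <- pose_from_matrix(R,
        as.numeric(t0 + fit$par[4:6] - R %*% aq$center))
    }
  }
  alignment_result(best, shape_tanimoto(template, query, best),
                   feature_tanimoto(template, query, best), w_shape)
}

#' Flexible superimposition of a query molecule onto a rigid template
#'
#' Every query conformer is rigidly aligned onto the template; all results
#' are pooled and the `top_n` best by combined score are returned in
#' descending order (fewer when the query has fewer conformers).
#'
#' @param query a `typed_molecule` with at least one conformer.
#' @param template a `gaussian_shape` held rigid.
#' @param top_n number of poses to return (default 10).
#' @param w_shape combined-score shape weight.
#' @return list of `alignment_result`, scores non-increasing.
#' @export
flexible_superimpose <- function(query, template, top_n = 10L,
                                 w_shape = 0.5) {
  if (length(query$conformers) == 0)
    stop("unprofiled molecule: ", query$id, " has no conformers")
  if (is.null(query$features)) query <- assign_feature_types(query)
  res <- lapply(seq_along(query$conformers), function(ci) {
    r <- rigid_align(make_shape(query, ci), template, w_shape)
    r$conformer_index <- ci
    r
  })
  ord <- order(vapply(res, `[[`, 0, "combined_score"), decreasing = TRUE)
  res[ord][seq_len(min(top_n, length(res)))]
}

#' Export posed conformers of alignment results as SDF
#'
#' @param query the aligned `typed_molecule`.
#' @param results list of `alignment_result` from [flexible_superimpose()].
#' @param path output SDF path.
#' @return `path`, invisibly.
#' @export
export_alignments_sdf <- function(query, results, path) {
  posed <- lapply(results, function(r) {
    ci <- if (is.na(r$conformer_index)) 1L else r$conformer_index
    m <- query
    m$id <- sprintf("%s_conf%d_score%.4f", query$id, ci, r$combined_score)
    m$conformers <- list(apply_pose(query$conformers[[ci]], r$pose))
    m
  })
  write_sdf(posed, path)
}
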