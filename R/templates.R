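# Diverse rigid-template library construction: self-similarity matrix of a
# ligand pool, one-minus-Pearson distance between matrix rows, and greedy
# maximum-dissimilarity (max-min) selection of k cluster centres.

#' Rigid self-similarity matrix of a ligand pool
#'
#' Entry (i, j) is the combined rigid-alignment score of molecule j
#' superimposed onto molecule i, both kept rigid in their single (bioactive)
#' conformation. Raw alignment scores can be asymmetric, so the matrix is
#' symmetrized as `max(S_ij, S_ji)` and the diagonal forced to 1.
#'
#' @param pool list of `typed_molecule`, each with exactly one conformer.
#' @param w_shape combined-score shape weight.
#' @param verbose print progress.
#' @return object of class `similarity_matrix`: the n x n numeric matrix
#'   with molecule ids as dimnames.
#' @export
self_similarity_matrix <- function(pool, w_shape = 0.5, verbose = FALSE) {
  n <- length(pool)
  if (n < 2) stop("pool must contain at least 2 molecules")
  nconf <- vapply(pool, function(m) length(m$conformers), 0L)
  if (any(nconf != 1))
    stop("templates must be frozen single conformations; molecules with ",
         "other than 1 conformer: ",
         paste(vapply(pool[nconf != 1], `[[`, "", "id"), collapse = ", "))
  ids <- vapply(pool, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate molecule ids in pool")
  shapes <- lapply(pool, make_shape)
  S <- matrix(1, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      S[i, j] <- rigid_align(shapes[[j]], shapes[[i]], w_shape)$combined_score
    }
    if (verbose) message("self-similarity row ", i, "/", n)
  }
  S <- pmax(S, t(S))
  diag(S) <- 1
  structure(S, class = c("similarity_matrix", "matrix"))
}

#' One-minus-Pearson distance between two similarity-matrix rows
#'
#' `d = 1 - r(row_i, row_j)` with Pearson `r`; if either row has zero
#' variance the distance is defined as 1.
#'
#' @param row_i,row_j numeric vectors of equal length (at least 3).
#' @return distance in `[0, 2]`.
#' @export
pearson_distance <- function(row_i, row_j) {
  if (length(row_i) != length(row_j))
    stop("row length mismatch: ", length(row_i), " vs ", length(row_j))
  if (length(row_i) < 3) stop("rows must have length >= 3")
  if (sd(row_i) == 0 || sd(row_j) == 0) return(1)
  1 - cor(row_i, row_j)
}

#' Greedy maximum-dissimilarity (max-min) selection
#'
#' The first centre is the point with maximal total distance to all others;
#' each subsequent centre maximizes the minimum distance to the centres
#' already chosen. All ties break to the lowest index; no randomness.
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @param k number of centres, `1 <= k <= nrow(D)`.
#' @return integer vector of centre indices in selection order.
#' @export
maxmin_select <- function(D, k) {
  n <- nrow(D)
  stopifnot(is.matrix(D), ncol(D) == n)
  if (k < 1) stop("k must be >= 1")
  if (k > n) stop("k (", k, ") exceeds pool size (", n, ")")
  centers <- which.max(rowSums(D))  # which.max takes lowest index on ties
  mind <- D[, centers]
  while (length(centers) < k) {
    mind_masked <- mind
    mind_masked[centers] <- -Inf
    nxt <- which.max(mind_masked)
    centers <- c(centers, nxt)
    mind <- pmin(mind, D[, nxt])
  }
  unname(centers)
}

#' Build a diverse template library from a ligand pool
#'
#' Chain: [self_similarity_matrix()] on the pool, pairwise
#' [pearson_distance()] between matrix rows (full rows, diagonal included),
#' [maxmin_select()] of `k` centres, library assembled in selection order.
#' Descriptor element i always refers to template i of this fixed order.
#'
#' @param pool list of single-conformer `typed_molecule`.
#' @param k library size (the classic default is 300 templates; use smaller
#'   values for toy pools).
#' @param w_shape combined-score shape weight, recorded in the metadata.
#' @param verbose print progress.
#' @return object of class `template_library`: `k`, `ids`, `shapes`,
#'   `molecules`, `similarity` (the pool matrix) and `metadata` (distance
#'   function, tie rule, pool hash, `w_shape`).
#' @export
build_template_library <- function(pool, k = 300L, w_shape = 0.5,
                                   verbose = FALSE) {
  if (k > length(pool))
    stop("k (", k, ") exceeds pool size (", length(pool), ")")
  S <- self_similarity_matrix(pool, w_shape = w_shape, verbose = verbose)
  n <- nrow(S)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- pearson_distance(S[i, ], S[j, ])
    }
  }
  sel <- maxmin_select(D, k)
  ids <- rownames(S)[sel]
  structure(list(
    k = as.integer(k),
    ids = ids,
    shapes = lapply(pool[sel], make_shape),
    molecules = pool[sel],
    similarity = S,
    metadata = list(distance = "one_minus_pearson",
                    selection = "greedy_maxmin",
                    tie_rule = "lowest_index",
                    w_shape = w_shape,
                    pool_hash = library_pool_hash(pool),
                    selected = sel)),
    class = "template_library")
}

library_pool_hash <- function(pool) {
  object_hash(lapply(pool, function(m)
    list(m$id, m$atoms$element, round(m$conformers[[1]], 6))))
}

#' Fingerprint of a template library
#'
#' Identifies the (pool, k) combination a descriptor table was computed
#' against; cached profiles are only reused under a matching fingerprint.
#'
#' @param library a `template_library`.
#' @return character scalar.
#' @export
library_fingerprint <- function(library) {
  paste0(substr(library$metadata$pool_hash, 1, 12), "_k", library$k)
}

#' @export
print.template_library <- function(x, ...) {
  cat(sprintf("template_library: k = %d (fingerprint %s)\n", x$k,
              library_fingerprint(x)))
  cat("  ids:", paste(head(x$ids, 8), collapse = ", "),
      if (x$k > 8) "..." else "", "\n")
  invisible(x)
}

#' Persist / load a similarity matrix as delimited text
#'
#' @param S a `similarity_matrix`.
#' @param path file path (tab-separated, header = ids).
#' @return `path` (write) or the matrix (read).
#' @export
write_similarity_matrix <- function(S, path) {
  df <- data.frame(id = rownames(S), S, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_similarity_matrix
#' @export
read_similarity_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  S <- as.matrix(df[, -1, drop = FALSE])
  rownames(S) <- df$id
  structure(S, class = c("similarity_matrix", "matrix"))
}

#' Persist / load a template library
#'
#' The template conformers go to an SDF file and the build metadata to a
#' plain-text key-value sidecar (`<path>.meta`).
#'
#' @param library a `template_library`.
#' @param path SDF file path.
#' @return `path` (write) or a `template_library` (read; the pool
#'   similarity matrix is not persisted).
#' @export
write_template_library <- function(library, path) {
  write_sdf(library$molecules, path)
  meta <- c(k = library$k,
            distance = library$metadata$distance,
            selection = library$metadata$selection,
            tie_rule = library$metadata$tie_rule,
            w_shape = library$metadata$w_shape,
            pool_hash = library$metadata$pool_hash,
            ids = paste(library$ids, collapse = ","))
  writeLines(paste0(names(meta), "\t", meta), paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_template_library
#' @export
read_template_library <- function(path) {
  mols <- read_molecules(path, format = "sdf")
  kv <- strsplit(readLines(paste0(path, ".meta")), "\t")
  meta <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  ids <- strsplit(meta[["ids"]], ",")[[1]]
  stopifnot(length(mols) == as.integer(meta[["k"]]))
  structure(list(
    k = as.integer(meta[["k"]]),
    ids = ids,
    shapes = lapply(mols, make_shape),
    molecules = mols,
    similarity = NULL,
    metadata = list(distance = meta[["distance"]],
                    selection = meta[["selection"]],
                    tie_rule = meta[["tie_rule"]],
                    w_shape = as.numeric(meta[["w_shape"]]),
                    pool_hash = meta[["pool_hash"]])),
    class = "template_library")
}
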