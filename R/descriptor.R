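# The shape-similarity profile: flexibly superimpose a query onto every
# rigid template and keep the per-template maximum combined score. The
# length-k vector (one element per template, in library order) is the
# molecular descriptor used for modelling. The profile only needs computing
# once per (molecule, library) pair; batch profiling caches rows on disk.

#' Compute a shape-similarity profile for one molecule
#'
#' Element i is the maximum combined score over
#' [flexible_superimpose()] of the query onto template i. If the query has
#' no conformers, [generate_conformers()] is invoked with `seed`.
#'
#' @param query a `typed_molecule`.
#' @param library a `template_library`.
#' @param top_n poses retained per template during superimposition
#'   (default 10; only the maximum enters the profile).
#' @param seed conformer-generation seed used when the query arrives
#'   without conformers.
#' @return object of class `brs_vector`: numeric length-k profile named by
#'   template ids, with attributes `molecule_id` and `fingerprint`.
#' @export
compute_profile <- function(query, library, top_n = 10L, seed = 42L) {
  if (length(query$conformers) == 0)
    query <- generate_conformers(query, seed = seed)
  if (isTRUE(query$unprofiled))
    stop("unprofiled molecule: ", query$id, " (conformer generation failed)")
  if (is.null(query$features)) query <- assign_feature_types(query)
  w <- library$metadata$w_shape
  vals <- vapply(library$shapes, function(tmpl) {
    res <- flexible_superimpose(query, tmpl, top_n = top_n, w_shape = w)
    res[[1]]$combined_score
  }, 0)
  structure(stats::setNames(vals, library$ids),
            molecule_id = query$id,
            fingerprint = library_fingerprint(library),
            class = "brs_vector")
}

#' @export
print.brs_vector <- function(x, ...) {
  cat(sprintf("profile of '%s' vs %d templates (range %.3f-%.3f)\n",
              attr(x, "molecule_id"), length(x), min(x), max(x)))
  invisible(x)
}

#' Profile a batch of molecules with on-disk caching
#'
#' Rows already present in the cache (keyed by molecule id under a
#' directory named after the library fingerprint) are reused; only missing
#' rows are computed, making interrupted runs resumable. Molecules whose
#' conformer generation fails are flagged, never zero-filled.
#'
#' @param mols list of `typed_molecule`.
#' @param library a `template_library`.
#' @param cache_path cache directory (`NULL` disables caching).
#' @param top_n poses per template.
#' @param seed conformer-generation seed.
#' @return object of class `descriptor_table`: numeric matrix (rows =
#'   molecules, columns = templates) with attributes `fingerprint`,
#'   `failed` (ids) and `n_computed` (rows computed this run).
#' @export
batch_profile <- function(mols, library, cache_path = NULL, top_n = 10L,
                          seed = 42L) {
  fp <- library_fingerprint(library)
  dir <- NULL
  if (!is.null(cache_path)) {
    marker <- file.path(cache_path, "FINGERPRINT")
    if (dir.exists(cache_path) && file.exists(marker)) {
      seen <- readLines(marker, n = 1)
      if (!identical(seen, fp))
        stop("cache at ", cache_path, " was built for library ", seen,
             ", not ", fp, "; refusing to mix profiles")
    }
    dir <- file.path(cache_path, fp)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeLines(fp, marker)
  }
  rows <- list(); failed <- character(); computed <- 0L
  for (mol in mols) {
    cache_file <- if (!is.null(dir)) file.path(dir, paste0(mol$id, ".tsv"))
    if (!is.null(dir) && file.exists(cache_file)) {
      v <- scan(cache_file, quiet = TRUE)
      stopifnot(length(v) == library$k)
      rows[[mol$id]] <- v
      next
    }
    v <- tryCatch(compute_profile(mol, library, top_n = top_n, seed = seed),
                  error = function(e) e)
    if (inherits(v, "error")) {
      warning("profiling failed for ", mol$id, ": ", conditionMessage(v))
      failed <- c(failed, mol$id)
      next
    }
    computed <- computed + 1L
    rows[[mol$id]] <- as.numeric(v)
    if (!is.null(dir))
      writeLines(format(as.numeric(v), digits = 17), cache_file)
  }
  tab <- do.call(rbind, rows)
  colnames(tab) <- library$ids
  structure(tab, fingerprint = fp, failed = failed, n_computed = computed,
            class = c("descriptor_table", "matrix"))
}

#' Write / read a descriptor table as delimited text
#'
#' Tab-separated; first column `molecule_id`, remaining k columns headed by
#' template ids, full double precision so the round trip is exact.
#'
#' @param table a `descriptor_table` (or plain matrix with dimnames).
#' @param path file path.
#' @return `path` (write) or the table (read).
#' @export
write_descriptor_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("molecule_id", colnames(table)), collapse = "\t"), con)
  for (i in seq_len(nrow(table))) {
    writeLines(paste(c(rownames(table)[i],
                       sprintf("%.17g", table[i, ])), collapse = "\t"), con)
  }
  fp <- attr(table, "fingerprint")
  if (!is.null(fp)) writeLines(fp, paste0(path, ".fingerprint"))
  invisible(path)
}

#' @rdname write_descriptor_table
#' @export
read_descriptor_table <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1) stop("empty descriptor table: ", path)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  k <- length(hdr) - 1L
  rows <- vector("list", length(lines) - 1L)
  ids <- character(length(lines) - 1L)
  for (i in seq_along(rows)) {
    f <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1]]
    if (length(f) != k + 1L)
      stop("malformed descriptor table ", path, " at line ", i + 1L, ": ",
           length(f), " fields, expected ", k + 1L)
    ids[i] <- f[1]
    rows[[i]] <- as.numeric(f[-1])
  }
  tab <- do.call(rbind, rows)
  dimnames(tab) <- list(ids, hdr[-1])
  fp_file <- paste0(path, ".fingerprint")
  fp <- if (file.exists(fp_file)) readLines(fp_file, n = 1) else NULL
  structure(tab, fingerprint = fp,
            class = c("descriptor_table", "matrix"))
}
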