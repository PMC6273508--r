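# Molecule input/output, pharmacophore feature typing and conformer
# generation. Molecules are plain lists of class "typed_molecule":
#   id         character
#   atoms      data.frame(element, charge, radius)
#   bonds      data.frame(from, to, order, aromatic)  (order 1/2/3; aromatic
#              bonds carry order 1 plus the flag)
#   conformers list of n_atoms x 3 coordinate matrices (Angstrom)
#   features   list (one character vector per atom) or NULL before typing

.brs3d_env <- new.env(parent = emptyenv())

vdw_radii_table <- function() {
  if (is.null(.brs3d_env$vdw)) {
    f <- system.file("extdata", "vdw_radii.tsv", package = "brs3d")
    tab <- read.delim(f, stringsAsFactors = FALSE)
    .brs3d_env$vdw <- stats::setNames(tab$radius, tab$element)
  }
  .brs3d_env$vdw
}

#' Van der Waals radius lookup
#'
#' Radii come from a small published table shipped with the package
#' (C 1.70, N 1.55, O 1.52, S 1.80, H 1.20 Angstrom, ...); unknown elements
#' fall back to the table's default (1.70).
#'
#' @param elements character vector of element symbols.
#' @return numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(elements) {
  tab <- vdw_radii_table()
  r <- tab[elements]
  r[is.na(r)] <- tab[["default"]]
  unname(r)
}

# covalent radii for bond-length targets (Angstrom)
.cov_radii <- c(H = 0.37, B = 0.85, C = 0.77, N = 0.75, O = 0.73, F = 0.71,
                P = 1.06, S = 1.02, Cl = 0.99, Br = 1.14, I = 1.33)

cov_radius <- function(el) {
  r <- .cov_radii[el]
  r[is.na(r)] <- 0.77
  unname(r)
}

.default_valence <- c(B = 3, C = 4, N = 3, O = 2, F = 1, P = 3, S = 2,
                      Cl = 1, Br = 1, I = 1)

#' Construct a typed molecule
#'
#' @param id molecule identifier.
#' @param atoms data.frame with columns `element`, `charge`; a `radius`
#'   column is filled from [vdw_radius()] if absent.
#' @param bonds data.frame with columns `from`, `to`, `order` and optionally
#'   `aromatic`; may have zero rows.
#' @param conformers list of n x 3 coordinate matrices.
#' @param features optional list of per-atom feature character vectors.
#' @return object of class `typed_molecule`.
#' @export
typed_molecule <- function(id, atoms, bonds = NULL, conformers = list(),
                           features = NULL) {
  stopifnot(is.character(id), nrow(atoms) >= 1)
  if (is.null(atoms$charge)) atoms$charge <- 0L
  if (is.null(atoms$radius)) atoms$radius <- vdw_radius(atoms$element)
  stopifnot(all(atoms$radius > 0))
  if (is.null(bonds))
    bonds <- data.frame(from = integer(), to = integer(), order = numeric(),
                        aromatic = logical())
  if (is.null(bonds$aromatic)) bonds$aromatic <- FALSE
  for (cf in conformers) {
    stopifnot(is.matrix(cf), nrow(cf) == nrow(atoms), ncol(cf) == 3,
              all(is.finite(cf)))
  }
  structure(list(id = id, atoms = atoms, bonds = bonds,
                 conformers = conformers, features = features),
            class = "typed_molecule")
}

#' @export
print.typed_molecule <- function(x, ...) {
  cat(sprintf("typed_molecule '%s': %d atoms (%d heavy), %d bonds, %d conformer(s)\n",
              x$id, n_atoms(x), length(heavy_atoms(x)), nrow(x$bonds),
              length(x$conformers)))
  invisible(x)
}

#' Number of atoms in a molecule
#' @param mol a `typed_molecule`.
#' @return integer atom count.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

#' Indices of heavy (non-hydrogen) atoms
#' @param mol a `typed_molecule`.
#' @return integer vector.
#' @export
heavy_atoms <- function(mol) which(mol$atoms$element != "H")

mol_graph <- function(mol) {
  igraph::graph_from_data_frame(
    data.frame(from = mol$bonds$from, to = mol$bonds$to),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n_atoms(mol))))
}

# per-atom counts of attached hydrogens
h_neighbor_count <- function(mol) {
  nh <- integer(n_atoms(mol))
  if (nrow(mol$bonds) == 0) return(nh)
  isH <- mol$atoms$element == "H"
  for (b in seq_len(nrow(mol$bonds))) {
    f <- mol$bonds$from[b]; t <- mol$bonds$to[b]
    if (isH[t]) nh[f] <- nh[f] + 1L
    if (isH[f]) nh[t] <- nh[t] + 1L
  }
  nh
}

neighbor_list <- function(mol) {
  nb <- vector("list", n_atoms(mol))
  if (nrow(mol$bonds) > 0) {
    for (b in seq_len(nrow(mol$bonds))) {
      f <- mol$bonds$from[b]; t <- mol$bonds$to[b]
      nb[[f]] <- c(nb[[f]], t); nb[[t]] <- c(nb[[t]], f)
    }
  }
  nb
}

atom_aromatic <- function(mol) {
  ar <- logical(n_atoms(mol))
  if (any(mol$bonds$aromatic)) {
    idx <- mol$bonds[mol$bonds$aromatic, , drop = FALSE]
    ar[unique(c(idx$from, idx$to))] <- TRUE
  }
  ar
}

## ---------------------------------------------------------------------------
## Readers / writers

#' Read molecules from a structure file
#'
#' Supports SDF V2000 (multi-record), MOL2 and SMILES (one record per line,
#' `SMILES<whitespace>id`). Hydrogens are made explicit on read; for SMILES
#' input the conformer list stays empty until [generate_conformers()] is
#' called (set `embed = TRUE` to embed 3D coordinates immediately).
#'
#' Unparsable individual records are skipped with a warning; the number of
#' skipped records is available as `attr(result, "n_skipped")`.
#'
#' @param path file path.
#' @param format one of `"sdf"`, `"mol2"`, `"smiles"`; guessed from the file
#'   extension when missing.
#' @param embed for SMILES input, generate one 3D conformer per molecule at
#'   read time (default `FALSE` so profiling cost stays visible).
#' @param seed seed used when `embed = TRUE`.
#' @return list of `typed_molecule`, in file order.
#' @export
read_molecules <- function(path, format = NULL, embed = FALSE, seed = 42L) {
  if (!file.exists(path)) stop("cannot read molecule file: ", path)
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     sdf = "sdf", mol = "sdf", mol2 = "mol2",
                     smi = "smiles", smiles = "smiles", txt = "smiles",
                     stop("cannot guess format of ", path))
  }
  format <- match.arg(format, c("sdf", "mol2", "smiles"))
  lines <- readLines(path, warn = FALSE)
  out <- switch(format,
                sdf = read_sdf_lines(lines, path),
                mol2 = read_mol2_lines(lines, path),
                smiles = read_smiles_lines(lines, path))
  if (format == "smiles" && embed) {
    out[] <- lapply(out, function(m) {
      tryCatch(embed_molecule(m, seed = seed), error = function(e) {
        warning("embedding failed for ", m$id, ": ", conditionMessage(e))
        m$unprofiled <- TRUE
        m
      })
    })
  }
  out
}

read_sdf_lines <- function(lines, path) {
  # split records on $$$$
  ends <- which(trimws(lines) == "$$$$")
  starts <- c(1L, head(ends, -1) + 1L)
  if (length(ends) == 0) { starts <- 1L; ends <- length(lines) + 1L }
  mols <- list(); skipped <- 0L
  for (r in seq_along(starts)) {
    rec <- lines[starts[r]:(ends[r] - 1L)]
    m <- tryCatch(parse_sdf_record(rec, sprintf("mol%d", r)),
                  error = function(e) e)
    if (inherits(m, "error")) {
      warning("skipping unparsable SDF record ", r, " in ", path, ": ",
              conditionMessage(m))
      skipped <- skipped + 1L
    } else mols[[length(mols) + 1L]] <- m
  }
  structure(mols, n_skipped = skipped)
}

parse_sdf_record <- function(rec, fallback_id) {
  rec <- rec[cumsum(trimws(rec) == "M  END") == 0 | trimws(rec) == "M  END"]
  if (length(rec) < 4) stop("truncated record")
  id <- trimws(rec[1])
  if (!nzchar(id)) id <- fallback_id
  counts <- rec[4]
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb) || na < 1) stop("bad counts line")
  if (length(rec) < 4 + na + nb) stop("truncated atom/bond block")
  atom_lines <- rec[5:(4 + na)]
  x <- as.numeric(substr(atom_lines, 1, 10))
  y <- as.numeric(substr(atom_lines, 11, 20))
  z <- as.numeric(substr(atom_lines, 21, 30))
  el <- trimws(substr(atom_lines, 32, 34))
  if (any(is.na(x) | is.na(y) | is.na(z)) || any(!nzchar(el)))
    stop("bad atom block")
  chg_code <- suppressWarnings(as.integer(substr(atom_lines, 37, 39)))
  chg_code[is.na(chg_code)] <- 0L
  charge <- c(0L, 3L, 2L, 1L, 0L, -1L, -2L, -3L)[chg_code + 1L]
  charge[is.na(charge)] <- 0L
  bonds <- data.frame(from = integer(), to = integer(), order = numeric(),
                      aromatic = logical())
  if (nb > 0) {
    bl <- rec[(5 + na):(4 + na + nb)]
    bf <- as.integer(substr(bl, 1, 3))
    bt <- as.integer(substr(bl, 4, 6))
    bo <- as.integer(substr(bl, 7, 9))
    if (any(is.na(bf) | is.na(bt) | is.na(bo)) ||
        any(bf < 1 | bf > na | bt < 1 | bt > na))
      stop("bad bond block")
    arom <- bo == 4L
    ord <- ifelse(arom, 1, pmin(bo, 3))
    bonds <- data.frame(from = bf, to = bt, order = ord, aromatic = arom)
  }
  # M  CHG properties supersede atom-block charge codes
  chg_lines <- grep("^M  CHG", rec, value = TRUE)
  if (length(chg_lines) > 0) {
    charge <- rep(0L, na)
    for (cl in chg_lines) {
      toks <- as.integer(strsplit(trimws(substr(cl, 7, nchar(cl))),
                                  "\\s+")[[1]])
      nset <- toks[1]
      for (i in seq_len(nset)) {
        charge[toks[2 * i]] <- toks[2 * i + 1]
      }
    }
  }
  mol <- typed_molecule(id,
                        data.frame(element = el, charge = charge,
                                   stringsAsFactors = FALSE),
                        bonds,
                        conformers = list(cbind(x, y, z)))
  add_hydrogens(mol)
}

#' Write molecules to an SDF (V2000) file
#'
#' @param mols a `typed_molecule` or list of them.
#' @param path output file path.
#' @param conformer which conformer's coordinates to write (default 1); use
#'   `"all"` to emit one record per conformer.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path, conformer = 1L) {
  if (inherits(mols, "typed_molecule")) mols <- list(mols)
  con <- file(path, "w")
  on.exit(close(con))
  for (mol in mols) {
    confs <- if (identical(conformer, "all")) seq_along(mol$conformers)
             else conformer
    for (ci in confs) {
      if (length(mol$conformers) < ci) stop("molecule ", mol$id,
                                            " has no conformer ", ci)
      xyz <- mol$conformers[[ci]]
      na <- n_atoms(mol); nb <- nrow(mol$bonds)
      writeLines(c(mol$id, "  brs3d", ""), con)
      writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb),
                 con)
      for (i in seq_len(na)) {
        writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                           xyz[i, 1], xyz[i, 2], xyz[i, 3],
                           mol$atoms$element[i]), con)
      }
      for (b in seq_len(nb)) {
        o <- if (isTRUE(mol$bonds$aromatic[b])) 4L else as.integer(mol$bonds$order[b])
        writeLines(sprintf("%3d%3d%3d  0", mol$bonds$from[b], mol$bonds$to[b],
                           o), con)
      }
      chg <- which(mol$atoms$charge != 0)
      if (length(chg) > 0) {
        writeLines(paste0("M  CHG", sprintf("%3d", length(chg)),
                          paste0(sprintf("%4d%4d", chg,
                                         mol$atoms$charge[chg]),
                                 collapse = "")), con)
      }
      writeLines(c("M  END", "$$$$"), con)
    }
  }
  invisible(path)
}

read_mol2_lines <- function(lines, path) {
  mol_starts <- grep("^@<TRIPOS>MOLECULE", lines)
  if (length(mol_starts) == 0) stop("no MOLECULE record in ", path)
  bounds <- c(mol_starts, length(lines) + 1L)
  mols <- list(); skipped <- 0L
  for (r in seq_along(mol_starts)) {
    rec <- lines[bounds[r]:(bounds[r + 1] - 1L)]
    m <- tryCatch(parse_mol2_record(rec, sprintf("mol%d", r)),
                  error = function(e) e)
    if (inherits(m, "error")) {
      warning("skipping unparsable MOL2 record ", r, " in ", path, ": ",
              conditionMessage(m))
      skipped <- skipped + 1L
    } else mols[[length(mols) + 1L]] <- m
  }
  structure(mols, n_skipped = skipped)
}

parse_mol2_record <- function(rec, fallback_id) {
  id <- trimws(rec[2])
  if (!nzchar(id) || is.na(id)) id <- fallback_id
  sec <- function(name) {
    s <- grep(paste0("^@<TRIPOS>", name), rec)
    if (length(s) == 0) return(character())
    nxt <- grep("^@<TRIPOS>", rec)
    e <- nxt[nxt > s[1]]
    end <- if (length(e)) e[1] - 1L else length(rec)
    body <- rec[(s[1] + 1L):end]
    body[nzchar(trimws(body))]
  }
  at <- sec("ATOM")
  if (length(at) == 0) stop("no atoms")
  toks <- strsplit(trimws(at), "\\s+")
  x <- vapply(toks, function(t) as.numeric(t[3]), 0)
  y <- vapply(toks, function(t) as.numeric(t[4]), 0)
  z <- vapply(toks, function(t) as.numeric(t[5]), 0)
  type <- vapply(toks, function(t) t[6], "")
  if (any(is.na(x) | is.na(y) | is.na(z))) stop("bad atom records")
  el <- vapply(strsplit(type, "\\.", fixed = FALSE), `[`, "", 1)
  el <- paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, 10)))
  pch <- vapply(toks, function(t) {
    if (length(t) >= 9) suppressWarnings(as.numeric(t[9])) else NA_real_
  }, 0)
  charge <- ifelse(!is.na(pch) & abs(pch) >= 0.5, round(pch), 0)
  bl <- sec("BOND")
  bonds <- data.frame(from = integer(), to = integer(), order = numeric(),
                      aromatic = logical())
  if (length(bl) > 0) {
    bt <- strsplit(trimws(bl), "\\s+")
    bf <- vapply(bt, function(t) as.integer(t[2]), 0L)
    bo <- vapply(bt, function(t) as.integer(t[3]), 0L)
    btype <- vapply(bt, function(t) t[4], "")
    if (any(is.na(bf) | is.na(bo))) stop("bad bond records")
    arom <- btype == "ar"
    ord <- suppressWarnings(as.numeric(btype))
    ord[arom | btype == "am" | is.na(ord)] <- 1
    bonds <- data.frame(from = bf, to = bo, order = ord, aromatic = arom)
  }
  mol <- typed_molecule(id,
                        data.frame(element = el, charge = as.integer(charge),
                                   stringsAsFactors = FALSE),
                        bonds, conformers = list(cbind(x, y, z)))
  add_hydrogens(mol)
}

read_smiles_lines <- function(lines, path) {
  lines <- lines[nzchar(trimws(lines))]
  mols <- list(); skipped <- 0L
  for (r in seq_along(lines)) {
    toks <- strsplit(trimws(lines[r]), "\\s+")[[1]]
    id <- if (length(toks) >= 2) toks[2] else sprintf("mol%d", r)
    m <- tryCatch(parse_smiles(toks[1], id), error = function(e) e)
    if (inherits(m, "error")) {
      warning("skipping unparsable SMILES line ", r, " in ", path, ": ",
              conditionMessage(m))
      skipped <- skipped + 1L
    } else mols[[length(mols) + 1L]] <- m
  }
  structure(mols, n_skipped = skipped)
}

## ---------------------------------------------------------------------------
## SMILES subset parser
##
## Supports: organic-subset atoms (B C N O P S F Cl Br I), aromatic
## b c n o p s, bracket atoms with charge and explicit H counts, bonds
## - = # :, branches, ring closures (1-9 and %nn). No stereo descriptors
## (accepted, ignored), no multi-component dots.

parse_smiles <- function(smi, id = smi) {
  if (grepl("\\.", smi)) stop("multi-component SMILES not supported")
  n <- nchar(smi)
  el <- character(); chg <- integer(); arom <- logical(); expH <- integer()
  hasExpH <- logical()
  bf <- integer(); bt <- integer(); bo <- numeric(); bar <- logical()
  stack <- integer(); prev <- 0L
  pend_order <- NA_real_; pend_arom <- FALSE
  rings <- list()
  i <- 1L
  add_atom <- function(sym, aromatic, charge, h, h_explicit) {
    el[length(el) + 1L] <<- sym
    arom[length(arom) + 1L] <<- aromatic
    chg[length(chg) + 1L] <<- charge
    expH[length(expH) + 1L] <<- h
    hasExpH[length(hasExpH) + 1L] <<- h_explicit
    cur <- length(el)
    if (prev > 0L) {
      o <- pend_order; a <- pend_arom
      if (is.na(o)) { a <- aromatic && arom[prev]; o <- 1 }
      bf[length(bf) + 1L] <<- prev; bt[length(bt) + 1L] <<- cur
      bo[length(bo) + 1L] <<- o; bar[length(bar) + 1L] <<- a
    }
    prev <<- cur
    pend_order <<- NA_real_; pend_arom <<- FALSE
    cur
  }
  close_ring <- function(num) {
    key <- as.character(num)
    if (is.null(rings[[key]])) {
      rings[[key]] <<- list(atom = prev, order = pend_order,
                            arom = pend_arom)
      pend_order <<- NA_real_; pend_arom <<- FALSE
    } else {
      open <- rings[[key]]; rings[[key]] <<- NULL
      o <- if (!is.na(pend_order)) pend_order else open$order
      a <- pend_arom || open$arom
      if (is.na(o)) { a <- arom[prev] && arom[open$atom]; o <- 1 }
      bf[length(bf) + 1L] <<- open$atom; bt[length(bt) + 1L] <<- prev
      bo[length(bo) + 1L] <<- o; bar[length(bar) + 1L] <<- a
      pend_order <<- NA_real_; pend_arom <<- FALSE
    }
  }
  while (i <= n) {
    ch <- substr(smi, i, i)
    two <- substr(smi, i, i + 1L)
    if (two %in% c("Cl", "Br")) { add_atom(two, FALSE, 0L, 0L, FALSE); i <- i + 2L }
    else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      add_atom(ch, FALSE, 0L, 0L, FALSE); i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      add_atom(toupper(ch), TRUE, 0L, 0L, FALSE); i <- i + 1L
    } else if (ch == "[") {
      j <- regexpr("]", substr(smi, i, n), fixed = TRUE)
      if (j < 0) stop("unclosed bracket atom")
      body <- substr(smi, i + 1L, i + j - 2L)
      m <- regmatches(body,
        regexec("^([0-9]*)([A-Za-z][a-z]?)(@{0,2})(H([0-9]*))?([+-][0-9+-]*)?", body))[[1]]
      if (!nzchar(m[3])) stop("bad bracket atom: [", body, "]")
      sym <- m[3]
      aromatic <- sym %in% c("b", "c", "n", "o", "p", "s")
      if (aromatic) sym <- toupper(sym)
      sym <- paste0(toupper(substr(sym, 1, 1)), substr(sym, 2, 10))
      h <- if (nzchar(m[5])) { if (nzchar(m[6])) as.integer(m[6]) else 1L } else 0L
      charge <- 0L
      if (nzchar(m[7])) {
        cs <- m[7]
        if (grepl("^[+-][0-9]+$", cs)) {
          charge <- as.integer(cs)
        } else charge <- sum(ifelse(strsplit(cs, "")[[1]] == "+", 1L, -1L))
      }
      add_atom(sym, aromatic, charge, h, TRUE)
      i <- i + j
    } else if (ch == "-") { pend_order <- 1; i <- i + 1L }
    else if (ch == "=") { pend_order <- 2; i <- i + 1L }
    else if (ch == "#") { pend_order <- 3; i <- i + 1L }
    else if (ch == ":") { pend_order <- 1; pend_arom <- TRUE; i <- i + 1L }
    else if (ch %in% c("/", "\\")) { pend_order <- 1; i <- i + 1L }
    else if (ch == "(") { stack <- c(stack, prev); i <- i + 1L }
    else if (ch == ")") {
      if (length(stack) == 0) stop("unbalanced parentheses")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) { close_ring(ch); i <- i + 1L }
    else if (ch == "%") {
      close_ring(substr(smi, i + 1L, i + 2L)); i <- i + 3L
    } else stop("unsupported SMILES token '", ch, "'")
  }
  if (length(stack) > 0) stop("unbalanced parentheses")
  if (length(rings) > 0) stop("unclosed ring bond")
  if (length(el) == 0) stop("empty SMILES")
  bonds <- data.frame(from = bf, to = bt, order = bo, aromatic = bar)
  mol <- typed_molecule(id,
                        data.frame(element = el, charge = chg,
                                   stringsAsFactors = FALSE),
                        bonds, conformers = list())
  mol$atom_aromatic <- arom
  # explicit H counts from brackets are authoritative; organic-subset atoms
  # get implicit counts from the valence model in add_hydrogens()
  add_hydrogens(mol, explicit_h = ifelse(hasExpH, expH, NA_integer_))
}

## ---------------------------------------------------------------------------
## Hydrogen completion

# Add implicit hydrogens as explicit H atoms. For molecules with 3D
# coordinates, H positions are placed crudely (1.09 A away from the heavy
# atom, pointing away from its neighbours) -- adequate because hydrogens are
# used for feature typing only and are excluded from the shape model.
add_hydrogens <- function(mol, explicit_h = NULL) {
  na0 <- n_atoms(mol)
  arom <- if (!is.null(mol$atom_aromatic)) mol$atom_aromatic
          else atom_aromatic(mol)
  deg_order <- numeric(na0)
  if (nrow(mol$bonds) > 0) {
    for (b in seq_len(nrow(mol$bonds))) {
      o <- mol$bonds$order[b]
      deg_order[mol$bonds$from[b]] <- deg_order[mol$bonds$from[b]] + o
      deg_order[mol$bonds$to[b]] <- deg_order[mol$bonds$to[b]] + o
    }
  }
  need <- integer(na0)
  for (i in seq_len(na0)) {
    elem <- mol$atoms$element[i]
    if (elem == "H") next
    if (!is.null(explicit_h) && !is.na(explicit_h[i])) {
      need[i] <- explicit_h[i]
      next
    }
    val <- .default_valence[elem]
    if (is.na(val)) next
    # charge adjustment: N+ binds 4, O- binds 1, etc.
    if (elem %in% c("N", "P")) val <- val + mol$atoms$charge[i]
    if (elem %in% c("O", "S")) val <- val + mol$atoms$charge[i]
    if (elem == "C") val <- val - abs(mol$atoms$charge[i])
    slots <- val - deg_order[i] - if (arom[i]) 1L else 0L
    need[i] <- max(0L, as.integer(round(slots)))
  }
  if (sum(need) == 0) return(mol)
  nb <- neighbor_list(mol)
  has_coords <- length(mol$conformers) > 0
  xyz <- if (has_coords) mol$conformers[[1]] else NULL
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  new_el <- character(); new_from <- integer(); new_xyz <- NULL
  for (i in which(need > 0)) {
    for (hk in seq_len(need[i])) {
      new_el <- c(new_el, "H")
      new_from <- c(new_from, i)
      if (has_coords) {
        if (length(nb[[i]]) > 0) {
          dir <- xyz[i, ] - colMeans(xyz[nb[[i]], , drop = FALSE])
          if (sum(dir^2) < 1e-8) dir <- c(0, 0, 1)
        } else dir <- c(0, 0, 1)
        dir <- dir / sqrt(sum(dir^2))
        d2 <- dir + 0.7 * tet[1 + (hk - 1) %% 4, ]
        d2 <- d2 / sqrt(sum(d2^2))
        new_xyz <- rbind(new_xyz, xyz[i, ] + 1.09 * d2)
      }
    }
  }
  nH <- length(new_el)
  atoms <- rbind(mol$atoms,
                 data.frame(element = new_el, charge = 0L,
                            radius = vdw_radius(new_el),
                            stringsAsFactors = FALSE))
  bonds <- rbind(mol$bonds,
                 data.frame(from = new_from, to = na0 + seq_len(nH),
                            order = 1, aromatic = FALSE))
  confs <- mol$conformers
  if (has_coords) confs <- lapply(confs, function(cf) {
    unname(rbind(cf, new_xyz))
  })
  out <- typed_molecule(mol$id, atoms, bonds, confs)
  out$atom_aromatic <- c(arom, logical(nH))
  out
}

## ---------------------------------------------------------------------------
## Pharmacophore feature typing

#' Default pharmacophore feature rules
#'
#' Rules are data-driven: a named list of predicates taking a per-atom
#' context (`element`, `charge`, `n_h` attached hydrogens, `aromatic`,
#' `neighbor_elements`, `neighbor_charges`) and returning `TRUE` when the
#' feature applies. Replace or extend entries to override behaviour.
#'
#' Defaults: donor = N/O with an attached H; acceptor = N/O with a lone pair
#' (not positively charged, and not an aromatic N-H); positive/negative =
#' formally charged centres; hydrophobic = carbon (or sulfur/halogen) not
#' adjacent to a charged or polar atom.
#'
#' @return named list of predicate functions, one per feature type.
#' @export
default_feature_rules <- function() {
  list(
    donor = function(ctx)
      ctx$element %in% c("N", "O") && ctx$n_h >= 1 && ctx$charge >= 0,
    acceptor = function(ctx)
      ctx$element %in% c("N", "O") && ctx$charge <= 0 &&
        !(ctx$element == "N" && ctx$aromatic && ctx$n_h >= 1),
    positive = function(ctx) ctx$charge > 0,
    negative = function(ctx) ctx$charge < 0,
    hydrophobic = function(ctx)
      ctx$element %in% c("C", "S", "F", "Cl", "Br", "I") && ctx$charge == 0 &&
        !any(ctx$neighbor_elements %in% c("N", "O")) &&
        !any(ctx$neighbor_charges != 0)
  )
}

#' Assign pharmacophore feature types to atoms
#'
#' Populates `mol$features` (a per-atom list of feature names drawn from
#' donor/acceptor/positive/negative/hydrophobic). Assignment depends only on
#' topology and formal charges, never on conformer geometry.
#'
#' @param mol a `typed_molecule` with explicit hydrogens.
#' @param rules feature rule set, see [default_feature_rules()].
#' @return the molecule with `features` populated.
#' @export
assign_feature_types <- function(mol, rules = default_feature_rules()) {
  nb <- neighbor_list(mol)
  arom <- if (!is.null(mol$atom_aromatic)) mol$atom_aromatic
          else atom_aromatic(mol)
  nh <- h_neighbor_count(mol)
  feats <- vector("list", n_atoms(mol))
  for (i in seq_len(n_atoms(mol))) {
    if (mol$atoms$element[i] == "H") { feats[[i]] <- character(); next }
    ctx <- list(element = mol$atoms$element[i],
                charge = mol$atoms$charge[i],
                n_h = nh[i], aromatic = arom[i],
                neighbor_elements = mol$atoms$element[nb[[i]]],
                neighbor_charges = mol$atoms$charge[nb[[i]]])
    hit <- vapply(rules, function(r) isTRUE(r(ctx)), TRUE)
    feats[[i]] <- names(rules)[hit]
  }
  mol$features <- feats
  mol
}

## ---------------------------------------------------------------------------
## Conformer generation

bond_is_bridge <- function(mol) {
  if (nrow(mol$bonds) == 0) return(logical(0))
  g <- mol_graph(mol)
  br <- igraph::bridges(g)
  out <- logical(nrow(mol$bonds))
  out[as.integer(br)] <- TRUE
  out
}

rotatable_bonds <- function(mol) {
  if (nrow(mol$bonds) == 0) return(integer(0))
  heavy_deg <- integer(n_atoms(mol))
  isH <- mol$atoms$element == "H"
  for (b in seq_len(nrow(mol$bonds))) {
    f <- mol$bonds$from[b]; t <- mol$bonds$to[b]
    if (!isH[t]) heavy_deg[f] <- heavy_deg[f] + 1L
    if (!isH[f]) heavy_deg[t] <- heavy_deg[t] + 1L
  }
  br <- bond_is_bridge(mol)
  which(mol$bonds$order == 1 & !mol$bonds$aromatic & br &
          !isH[mol$bonds$from] & !isH[mol$bonds$to] &
          heavy_deg[mol$bonds$from] >= 2 & heavy_deg[mol$bonds$to] >= 2)
}

# atoms on the 'to' side of bond b when the bond is removed
bond_side_atoms <- function(mol, b) {
  g <- mol_graph(mol)
  g2 <- igraph::delete_edges(g, b)
  comp <- igraph::components(g2)$membership
  which(comp == comp[mol$bonds$to[b]])
}

rotate_about_axis <- function(coords, idx, p0, axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  R <- expmap_to_matrix(axis * angle)
  sub <- sweep(coords[idx, , drop = FALSE], 2, p0)
  coords[idx, ] <- sweep(sub %*% t(R), 2, p0, "+")
  coords
}

heavy_clash_score <- function(xyz, heavy, far_pairs, dmin = 2.0) {
  if (nrow(far_pairs) == 0) return(0)
  d <- sqrt(rowSums((xyz[far_pairs[, 1], , drop = FALSE] -
                     xyz[far_pairs[, 2], , drop = FALSE])^2))
  sum(pmax(0, dmin - d)^2)
}

#' Generate a conformer ensemble
#'
#' Conformers are produced by seeded torsion driving around acyclic single
#' bonds starting from the input (or embedded) geometry, rejected on heavy
#' -atom steric clashes, and greedily pruned so that no two retained
#' conformers are within `rmsd_prune` heavy-atom RMSD (optimal
#' superposition). Deterministic for a fixed seed. Molecules without
#' rotatable bonds keep their single input conformer. SMILES-derived
#' molecules without coordinates are embedded first.
#'
#' @param mol a `typed_molecule`.
#' @param max_confs maximum number of retained conformers (default 50).
#' @param rmsd_prune heavy-atom RMSD pruning threshold in Angstrom
#'   (default 0.5).
#' @param seed RNG seed (default 42).
#' @return the molecule with `conformers` replaced by the ensemble; on
#'   embedding failure the molecule is flagged `unprofiled` and returned
#'   with a warning, never silently dropped.
#' @export
generate_conformers <- function(mol, max_confs = 50L, rmsd_prune = 0.5,
                                seed = 42L) {
  stopifnot(max_confs >= 1)
  if (length(mol$conformers) == 0) {
    mol <- tryCatch(embed_molecule(mol, seed = seed), error = function(e) {
      warning("embedding failed for molecule ", mol$id, ": ",
              conditionMessage(e), " (flagged unprofiled)")
      m <- mol; m$unprofiled <- TRUE; m
    })
    if (isTRUE(mol$unprofiled)) return(mol)
  }
  base <- mol$conformers[[1]]
  rot <- rotatable_bonds(mol)
  heavy <- heavy_atoms(mol)
  if (length(rot) == 0) {
    mol$conformers <- list(base)
    return(mol)
  }
  sides <- lapply(rot, function(b) bond_side_atoms(mol, b))
  # heavy-atom pairs >= 4 bonds apart, checked for clashes
  g <- mol_graph(mol)
  gd <- igraph::distances(g)
  fp <- which(upper.tri(gd) & gd >= 4, arr.ind = TRUE)
  fp <- fp[fp[, 1] %in% heavy & fp[, 2] %in% heavy, , drop = FALSE]

  with_seed(seed, {
    n_cand <- min(200L, max(30L, 6L * max_confs))
    cands <- vector("list", n_cand + 1L)
    scores <- numeric(n_cand + 1L)
    cands[[1]] <- base
    scores[1] <- heavy_clash_score(base, heavy, fp)
    torsion_menu <- pi / 180 * c(-120, -60, 60, 120, 180)
    for (ci in seq_len(n_cand)) {
      xyz <- base
      for (ri in seq_along(rot)) {
        b <- rot[ri]
        ang <- sample(torsion_menu, 1) + runif(1, -pi / 12, pi / 12)
        a1 <- mol$bonds$from[b]; a2 <- mol$bonds$to[b]
        xyz <- rotate_about_axis(xyz, sides[[ri]], xyz[a1, ],
                                 xyz[a2, ] - xyz[a1, ], ang)
      }
      cands[[ci + 1L]] <- xyz
      scores[ci + 1L] <- heavy_clash_score(xyz, heavy, fp)
    }
    # prefer clash-free geometries; base conformer first among equals
    ord <- order(scores > 1e-6, scores, seq_along(scores))
    kept <- list()
    for (oi in ord) {
      xyz <- cands[[oi]]
      if (scores[oi] > 0.5) next  # severe clash, reject outright
      ok <- TRUE
      for (kc in kept) {
        if (kabsch_rmsd(kc[heavy, , drop = FALSE],
                        xyz[heavy, , drop = FALSE]) < rmsd_prune) {
          ok <- FALSE; break
        }
      }
      if (ok) kept[[length(kept) + 1L]] <- xyz
      if (length(kept) >= max_confs) break
    }
    if (length(kept) == 0) kept <- list(base)
    mol$conformers <- kept
  })
  mol
}

## ---------------------------------------------------------------------------
## 3D embedding for topology-only molecules (SMILES input)
##
## Seeded stress minimization over distance targets: bond lengths from
## covalent radii (scaled by bond order), 1-3 distances from idealized
## angles (109.47 deg sp3, 120 deg sp2/aromatic, 180 deg at triple bonds),
## and one-sided lower bounds for nonbonded pairs. Not a force field; the
## goal is a chemically plausible starting geometry for torsion search.

ideal_bond_length <- function(mol, b) {
  r <- cov_radius(mol$atoms$element[mol$bonds$from[b]]) +
       cov_radius(mol$atoms$element[mol$bonds$to[b]])
  o <- mol$bonds$order[b]
  scale <- if (isTRUE(mol$bonds$aromatic[b])) 0.93
           else if (o >= 3) 0.78 else if (o >= 2) 0.87 else 1.0
  r * scale
}

embed_molecule <- function(mol, seed = 42L, max_restarts = 3L) {
  na <- n_atoms(mol)
  if (na == 1) { mol$conformers <- list(matrix(0, 1, 3)); return(mol) }
  arom <- if (!is.null(mol$atom_aromatic)) mol$atom_aromatic
          else atom_aromatic(mol)
  nb <- neighbor_list(mol)
  has_double <- logical(na); has_triple <- logical(na)
  for (b in seq_len(nrow(mol$bonds))) {
    if (mol$bonds$order[b] >= 2) {
      has_double[mol$bonds$from[b]] <- TRUE
      has_double[mol$bonds$to[b]] <- TRUE
    }
    if (mol$bonds$order[b] >= 3) {
      has_triple[mol$bonds$from[b]] <- TRUE
      has_triple[mol$bonds$to[b]] <- TRUE
    }
  }
  blen <- vapply(seq_len(nrow(mol$bonds)), function(b)
    ideal_bond_length(mol, b), 0)
  # pair lists: (i, j, target, weight, one_sided)
  pi_ <- mol$bonds$from; pj <- mol$bonds$to; pd <- blen
  pw <- rep(1, length(pd)); pone <- rep(FALSE, length(pd))
  bl_of <- function(i, j) {
    hit <- which((mol$bonds$from == i & mol$bonds$to == j) |
                 (mol$bonds$from == j & mol$bonds$to == i))
    blen[hit[1]]
  }
  for (j in seq_len(na)) {
    ns <- nb[[j]]
    if (length(ns) < 2) next
    th <- if (has_triple[j]) pi else if (arom[j] || has_double[j]) 2 * pi / 3
          else 1.9106  # 109.47 deg
    for (ai in seq_len(length(ns) - 1)) {
      for (bi in (ai + 1):length(ns)) {
        d1 <- bl_of(j, ns[ai]); d2 <- bl_of(j, ns[bi])
        d13 <- sqrt(d1^2 + d2^2 - 2 * d1 * d2 * cos(th))
        pi_ <- c(pi_, ns[ai]); pj <- c(pj, ns[bi]); pd <- c(pd, d13)
        pw <- c(pw, 0.5); pone <- c(pone, FALSE)
      }
    }
  }
  # nonbonded lower bounds for topologically distant pairs
  g <- mol_graph(mol)
  gd <- igraph::distances(g)
  far <- which(upper.tri(gd) & gd >= 3, arr.ind = TRUE)
  if (nrow(far) > 0) {
    isH <- mol$atoms$element == "H"
    dmin <- ifelse(isH[far[, 1]] | isH[far[, 2]], 1.7, 2.4)
    pi_ <- c(pi_, far[, 1]); pj <- c(pj, far[, 2]); pd <- c(pd, dmin)
    pw <- c(pw, rep(0.25, nrow(far))); pone <- c(pone, rep(TRUE, nrow(far)))
  }
  obj <- function(x) {
    xm <- matrix(x, na, 3)
    dv <- xm[pi_, , drop = FALSE] - xm[pj, , drop = FALSE]
    d <- sqrt(rowSums(dv^2)) + 1e-9
    err <- d - pd
    err[pone & err > 0] <- 0
    sum(pw * err^2)
  }
  grad <- function(x) {
    xm <- matrix(x, na, 3)
    dv <- xm[pi_, , drop = FALSE] - xm[pj, , drop = FALSE]
    d <- sqrt(rowSums(dv^2)) + 1e-9
    err <- d - pd
    err[pone & err > 0] <- 0
    coef <- 2 * pw * err / d
    gv <- dv * coef
    gm <- matrix(0, na, 3)
    for (cc in 1:3) {
      gm[, cc] <- gm[, cc] +
        as.numeric(tapply(gv[, cc], pi_, sum)[as.character(seq_len(na))])
      gm[, cc] <- gm[, cc] -
        as.numeric(tapply(gv[, cc], pj, sum)[as.character(seq_len(na))])
    }
    gm[is.na(gm)] <- 0
    as.numeric(gm)
  }
  best <- NULL; best_f <- Inf
  with_seed(seed, {
    for (rs in seq_len(max_restarts)) {
      x0 <- rnorm(3 * na, sd = max(1.5, na^(1 / 3)))
      fit <- tryCatch(optim(x0, obj, grad, method = "L-BFGS-B",
                            control = list(maxit = 500)),
                      error = function(e) NULL)
      if (is.null(fit) || !all(is.finite(fit$par))) next
      if (fit$value < best_f) { best_f <- fit$value; best <- fit$par }
      if (best_f / length(pd) < 5e-3) break
    }
  })
  if (is.null(best) || !is.finite(best_f) ||
      best_f / length(pd) > 0.5) stop("embedding did not converge")
  xm <- matrix(best, na, 3)
  xm <- sweep(xm, 2, colMeans(xm))
  mol$conformers <- list(unname(xm))
  mol
}
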