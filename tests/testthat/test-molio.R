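local_smiles <- function(lines) {
  f <- tempfile(fileext = ".smi")
  writeLines(lines, f)
  f
}

test_that("SDF read/write round-trips counts, elements and coordinates", {
  mols <- lapply(1:3, function(i)
    make_toy_molecule(i, toy_families[i], id = sprintf("m%d", i)))
  f <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(mols, f)
  back <- read_molecules(f, "sdf")
  expect_length(back, 3)
  expect_identical(attr(back, "n_skipped"), 0L)
  for (i in 1:3) {
    expect_identical(back[[i]]$id, mols[[i]]$id)
    expect_identical(n_atoms(back[[i]]), n_atoms(mols[[i]]))
    expect_identical(back[[i]]$atoms$element, mols[[i]]$atoms$element)
    expect_equal(back[[i]]$conformers[[1]], mols[[i]]$conformers[[1]],
                 tolerance = 1e-3, ignore_attr = TRUE)
  }
})

test_that("a corrupt SDF record is skipped with a warning, not fatal", {
  mols <- lapply(1:2, function(i)
    make_toy_molecule(i, "rigid_ring", id = sprintf("ok%d", i)))
  f <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(mols, f)
  txt <- readLines(f)
  corrupt <- c("broken", "", "", "  x  y  0  0  0  0  0  0  0  0999 V2000",
               "M  END", "$$$$")
  cut <- which(txt == "$$$$")[1]
  writeLines(c(txt[1:cut], corrupt, txt[(cut + 1):length(txt)]), f)
  expect_warning(back <- read_molecules(f, "sdf"), "skipping")
  expect_length(back, 2)
  expect_identical(attr(back, "n_skipped"), 1L)
  # unreadable path is fatal and names the path
  expect_error(read_molecules("/nonexistent/file.sdf"), "nonexistent")
})

test_that("formal charges survive the SDF round trip via M CHG", {
  m <- typed_molecule("chg", data.frame(element = c("N", "O"),
                                        charge = c(1L, -1L)),
                      data.frame(from = 1L, to = 2L, order = 1,
                                 aromatic = FALSE),
                      conformers = list(matrix(c(0, 0, 0, 1.4, 0, 0), 2, 3,
                                               byrow = TRUE)))
  f <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(m, f)
  back <- read_molecules(f, "sdf")[[1]]
  heavy <- heavy_atoms(back)
  expect_identical(back$atoms$charge[heavy], c(1L, -1L))
})

test_that("MOL2 records parse atoms, bonds and rounded formal charges", {
  lines <- c("@<TRIPOS>MOLECULE", "probe", " 3 2 1", "SMALL", "USER_CHARGES",
             "@<TRIPOS>ATOM",
             "  1 C1  0.000  0.000  0.000 C.3  1 LIG  0.0200",
             "  2 N1  1.500  0.000  0.000 N.4  1 LIG  0.9100",
             "  3 O1 -1.400  0.300  0.000 O.3  1 LIG -0.1000",
             "@<TRIPOS>BOND", "  1 1 2 1", "  2 1 3 1")
  f <- withr::local_tempfile(fileext = ".mol2")
  writeLines(lines, f)
  mol <- read_molecules(f, "mol2")[[1]]
  expect_identical(mol$id, "probe")
  heavy <- heavy_atoms(mol)
  expect_identical(mol$atoms$element[heavy], c("C", "N", "O"))
  expect_identical(mol$atoms$charge[heavy], c(0L, 1L, 0L))
  expect_equal(mol$conformers[[1]][2, 1], 1.5)
})

test_that("SMILES subset parses topology, charges and hydrogen counts", {
  f <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO ethanol", "c1ccccc1 benzene", "CC(=O)[O-] acetate",
               "C1CC1 cyclopropane", "[NH4+] ammonium"), f)
  mols <- read_molecules(f, "smiles")
  expect_length(mols, 5)
  # conformers stay empty until generation
  expect_length(mols[[1]]$conformers, 0)
  # ethanol: C2H6O -> 9 atoms with explicit H
  expect_identical(n_atoms(mols[[1]]), 9L)
  # benzene: 6 C + 6 H, all aromatic carbons
  expect_identical(n_atoms(mols[[2]]), 12L)
  expect_identical(sum(mols[[2]]$atoms$element == "H"), 6L)
  # acetate: one negative oxygen, 3 H on the methyl
  expect_identical(sum(mols[[3]]$atoms$charge == -1L), 1L)
  expect_identical(sum(mols[[3]]$atoms$element == "H"), 3L)
  # ring closure gives 3 ring bonds
  heavy_bonds <- with(mols[[4]]$bonds,
                      sum(mols[[4]]$atoms$element[from] != "H" &
                          mols[[4]]$atoms$element[to] != "H"))
  expect_identical(heavy_bonds, 3L)
  # ammonium: N+ with 4 explicit H
  expect_identical(mols[[5]]$atoms$charge[1], 1L)
  expect_identical(sum(mols[[5]]$atoms$element == "H"), 4L)
  # bad line is skipped with a warning
  writeLines(c("CCO ok", "C((C bad"), f)
  expect_warning(back <- read_molecules(f, "smiles"), "skipping")
  expect_length(back, 1)
})

test_that("feature rules type water, methane and carboxylate correctly", {
  f <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("O water", "C methane", "CC(=O)[O-] acetate"), f)
  mols <- lapply(read_molecules(f, "smiles"), assign_feature_types)
  expect_setequal(mols[[1]]$features[[1]], c("donor", "acceptor"))
  expect_identical(mols[[2]]$features[[1]], "hydrophobic")
  o_minus <- which(mols[[3]]$atoms$charge < 0)
  expect_true("negative" %in% mols[[3]]$features[[o_minus]])
  # carbons next to O are not hydrophobic under the default rules
  carboxyl_c <- 2L
  expect_false("hydrophobic" %in% mols[[3]]$features[[carboxyl_c]])
  # feature assignment ignores geometry entirely
  m2 <- mols[[3]]
  m2$conformers <- list(matrix(rnorm(3 * n_atoms(m2)), n_atoms(m2), 3))
  expect_identical(assign_feature_types(m2)$features, mols[[3]]$features)
})

test_that("feature rules are data-driven and overridable", {
  rules <- default_feature_rules()
  rules$donor <- function(ctx) FALSE
  m <- assign_feature_types(
    read_molecules(local_smiles("O water"), "smiles")[[1]], rules)
  expect_identical(m$features[[1]], "acceptor")
})

test_that("conformer generation honours rigidity, pruning and the seed", {
  rigid <- make_toy_molecule(11, "rigid_ring")
  rigid <- generate_conformers(rigid, max_confs = 50, seed = 4)
  expect_length(rigid$conformers, 1)

  flex <- make_toy_molecule(12, "chain")
  flex <- generate_conformers(flex, max_confs = 20, rmsd_prune = 0.5,
                              seed = 4)
  expect_gte(length(flex$conformers), 2)
  expect_lte(length(flex$conformers), 20)
  heavy <- heavy_atoms(flex)
  cf <- flex$conformers
  for (i in seq_along(cf)[-1]) {
    for (j in seq_len(i - 1)) {
      expect_gte(kabsch_rmsd(cf[[i]][heavy, ], cf[[j]][heavy, ]), 0.5)
    }
  }
  # determinism
  flex2 <- generate_conformers(make_toy_molecule(12, "chain"),
                               max_confs = 20, rmsd_prune = 0.5, seed = 4)
  expect_identical(flex$conformers, flex2$conformers)
  # different seed explores differently (same first = base conformer)
  flex3 <- generate_conformers(make_toy_molecule(12, "chain"),
                               max_confs = 20, rmsd_prune = 0.5, seed = 5)
  expect_false(identical(flex$conformers, flex3$conformers))
})

test_that("SMILES embedding produces sane geometry deterministically", {
  f <- local_smiles(c("CCCCO butanol", "c1ccccc1 benzene"))
  mols <- read_molecules(f, "smiles")
  but <- generate_conformers(mols[[1]], max_confs = 5, seed = 9)
  expect_gte(length(but$conformers), 1)
  xyz <- but$conformers[[1]]
  bl <- sqrt(rowSums((xyz[but$bonds$from, ] - xyz[but$bonds$to, ])^2))
  expect_true(all(bl > 0.8 & bl < 1.9))
  bz <- generate_conformers(mols[[2]], max_confs = 5, seed = 9)
  ring <- heavy_atoms(bz)
  d <- dist(bz$conformers[[1]][ring, ])
  # aromatic ring: 6 near-equal bonds around 1.43 A
  expect_equal(unname(sort(as.numeric(d))[1:6]),
               rep(1.43, 6), tolerance = 0.15)
  bz2 <- generate_conformers(read_molecules(f, "smiles")[[2]],
                             max_confs = 5, seed = 9)
  expect_identical(bz$conformers, bz2$conformers)
})
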