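# Shared fixture builders (everything generated in code, seeded).

toy_families <- c("rigid_ring", "chain", "star", "random_druglike")

# single-conformer pool for template-library tests
make_pool <- function(n, seed_base = 100L) {
  lapply(seq_len(n), function(i) {
    m <- make_toy_molecule(seed_base + i, toy_families[1 + (i - 1) %% 4],
                           id = sprintf("pool%02d", i))
    m$conformers <- m$conformers[1]
    m
  })
}

# a bare molecule from explicit coordinates (carbons, no bonds)
atom_cloud <- function(xyz, elements = rep("C", nrow(xyz)), id = "cloud") {
  m <- typed_molecule(id, data.frame(element = elements, charge = 0L,
                                     stringsAsFactors = FALSE),
                      conformers = list(xyz))
  assign_feature_types(m)
}

small_random_shape <- function(seed, n_atoms = 3) {
  xyz <- brs3d:::with_seed(seed, matrix(runif(n_atoms * 3, -1.5, 1.5),
                                        n_atoms, 3))
  make_shape(atom_cloud(xyz, id = sprintf("rand%d", seed)))
}
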