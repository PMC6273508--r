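Package: brs3d
Title: Shape-Similarity Profiles Against Diverse 3D Template Ligands for
    Virtual Screening and QSAR
Version: 0.1.0
Authors@R:
    person("BRS-3D", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Encodes small molecules as fixed-length shape-similarity
    profiles against a diverse library of rigid three-dimensional template
    ligands. Each profile element is the maximum Gaussian shape plus
    pharmacophore-feature similarity obtained by flexibly superimposing the
    query onto one rigid template. Provides the template-library builder
    (self-similarity matrix, one-minus-Pearson row distance, greedy
    maximum-dissimilarity selection), molecule input/output for SDF V2000,
    MOL2 and a SMILES subset, conformer generation, support vector machine
    discriminant and regression modelling with class-imbalance strategies,
    grid search with ten-fold cross-validation, enrichment factors,
    random-forest permutation-importance feature ranking, and receptor
    subtype-selectivity analysis with Y-randomization, resampling and an
    applicability domain.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
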