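# brs3d — shape-similarity profiles against diverse 3D template ligands

`brs3d` encodes any small molecule as a fixed-length **shape-similarity
profile**: the molecule is flexibly superimposed onto each of *k* rigid 3D
template ligands (conformations representative of bioactive space), each
superimposition is scored by Gaussian shape overlap plus
pharmacophore-feature overlap, and the per-template maximum score becomes
one element of a length-*k* descriptor vector. Because templates are fixed,
the profile is computed once per molecule and reused across targets. On top
of the descriptor the package provides SVM-based virtual screening and QSAR
regression (with class-imbalance strategies, grid search, 10-fold
cross-validation, enrichment factors and random-forest permutation-importance
feature selection) and receptor subtype-selectivity analysis
(selectivity-ratio labelling, Y-randomization, resampling stability,
applicability domain).

It is written for computational chemists and cheminformaticians who want an
open, self-contained, fully testable implementation of the profile-descriptor
approach — every stage runs on seeded synthetic fixtures with no external
database or proprietary alignment engine.

## The method in brief

Heavy atoms are spherical Gaussians (amplitude `p = 2√2`, exponent
`α = π(3p/4π)^{2/3}/R²`, so an isolated atom's self-overlap equals its
hard-sphere volume `4/3·πR³`). For molecules A, B posed together,

    V_AB = Σ_{i∈A, j∈B} p² (π/(α_i+α_j))^{3/2} exp(−α_iα_j d_ij²/(α_i+α_j))

and shape similarity is the Tanimoto `V_AB / (V_AA + V_BB − V_AB) ∈ [0,1]`.
Pharmacophore types (donor/acceptor/±charge/hydrophobic) are scored the same
way on 1 Å feature Gaussians and averaged over present types; the combined
score is `w·shape + (1−w)·feature`, default `w = 0.5`. Rigid alignment =
principal-axes overlay (16 deterministic starts) + Nelder–Mead refinement
over 6 rigid DOF; flexible superimposition enumerates query conformers
against the rigid template.

The template library is built from any single-conformer ligand pool by
rigid–rigid self-similarity, one-minus-Pearson distance between matrix rows,
and greedy maximum-dissimilarity (max–min) selection of *k* centres
(classically *k* = 300).

Classification models: RBF-SVM (self-contained SMO solver), grid
`C ∈ 2^{−5..15}`, `γ ∈ 2^{−15..3}`, stratified 10-fold CV scored by
rank-based AUC; metrics ACC, Precision, Recall, Specificity,
MCC = (TP·TN − FP·FN)/√((TP+FP)(TP+FN)(TN+FP)(TN+FN)), and the enrichment
factor EF(f) = (active rate in top ⌈fN⌉)/(overall active rate). Regression:
ε-SVR minimizing cross-validated RMSE, with Q² (squared correlation of CV
predictions) and R² = 1 − SS_res/SS_tot. Subtype selectivity:
SR = pKi_A − pKi_B, |SR| ≥ 1.3 (inclusive) = selective.

## Worked example

```r
library(brs3d)

# 1. toy ligand pool -> diverse template library (k = 5)
fams <- c("rigid_ring", "chain", "star", "random_druglike")
pool <- lapply(1:12, function(i) {
  m <- make_toy_molecule(100 + i, fams[1 + (i - 1) %% 4],
                         id = sprintf("lig%02d", i))
  m$conformers <- m$conformers[1]   # templates are frozen conformations
  m
})
lib <- build_template_library(pool, k = 5)
#> template_library: k = 5 (fingerprint ab4dabcf10ee_k5)
#>   ids: lig02, lig08, lig09, lig07, lig04

# 2. profile a flexible query against the library
query <- generate_conformers(make_toy_molecule(7, "chain", id = "query1"),
                             max_confs = 10, seed = 42)
profile <- compute_profile(query, lib)
round(as.numeric(profile), 3)
#> [1] 0.449 0.437 0.558 0.440 0.594
```

Each element is the best combined similarity of any query conformer against
one rigid template — mid-range values (~0.3–0.7) are typical; ≥ 0.99 would
mean the query matches that template's conformation almost exactly.

```r
# 3. screening model on a planted-signal synthetic descriptor table
ds <- make_classification_dataset(seed = 42, n_active = 40, n_decoy = 160,
                                  k = 30, m = 8)
sp <- split_train_test(ds$table, ds$labels, seed = 1)       # 4:1 split
st <- apply_imbalance_strategy(sp$X_train, sp$y_train, "weighted",
                               weights = c(active = 4, decoy = 1))
gs <- grid_search_svm(st$X, st$y, folds = 10, seed = 1,
                      class_weights = st$class_weights)
#> grid search (auc, 10-fold CV): C = 0.03125, gamma = 3.05176e-05, score = 1.0000
classification_metrics(sp$y_test,
                       predict(gs$model, sp$X_test, type = "class"),
                       predict(gs$model, sp$X_test))
#> TP 8 TN 30 FP 2 FN 0 | ACC 0.950 Prec 0.800 Rec 1.000 Spec 0.938 MCC 0.866 AUC 1.000

# 4. which descriptor dimensions drive the model?
fr <- rank_features_permutation(ds$table, ds$labels, n_trees = 300, seed = 2)
sort(fr$ranking[1:8])   # top-8 by permutation importance
#> [1]  1  4  5 10 17 18 25 30
ds$informative          # the 8 planted dimensions — fully recovered
#> [1]  1  4  5 10 17 18 25 30
```

A CV AUC of 1.0 on the planted-signal fixture says the pipeline recovers the
constructed separation; MCC 0.866 and Recall 1.0 on the held-out fifth show
the weighted model catches all actives at a small false-positive cost.

## Layout

- `R/` — molecule I/O and conformers (`molio`), Gaussian shape scoring and
  alignment (`shapesim`), template-library construction (`templates`),
  profile computation (`descriptor`), SVM/RF modelling (`modeling`),
  selectivity analysis (`selectivity`), synthetic fixtures (`fixtures`),
  CLI (`cli`).
- `src/` — Gaussian overlap, SMO solver, random forest (Rcpp).
- `tests/testthat/` — unit + property tests and `test-acceptance.R`.
- `vignettes/shape-profiles.Rmd` — the methods vignette: model, parameter
  choices, what the synthetic world does and does not establish.
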