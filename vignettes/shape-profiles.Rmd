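---
title: "Shape-similarity profiles as molecular descriptors: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-similarity profiles as molecular descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brs3d)
```

## The idea

Ligands crystallized in protein–ligand complexes are frozen negative
imprints of their binding sites. If a candidate molecule can adopt a
conformation whose 3D shape and pharmacophore pattern closely match such a
bioactive conformation, it is plausible that the candidate binds the
corresponding pocket. `brs3d` turns this idea into a fixed-length
descriptor: pick a diverse library of `k` rigid template conformations,
flexibly superimpose each query molecule onto every template, and record
the best similarity per template. The resulting length-`k` profile locates
the query in a "bioactive-conformation space" and feeds standard machine
learning (RBF-kernel SVMs here) for virtual screening, QSAR regression and
receptor subtype-selectivity prediction. The profile depends only on the
template library, so it is computed once per molecule and reused across
targets.

## The similarity model

Every heavy atom is a spherical Gaussian
\(\rho_i(r) = p\,\exp(-\alpha_i \lVert r-c_i\rVert^2)\) in the
Grant–Pickup parametrization: amplitude \(p = 2\sqrt{2}\) and
\(\alpha_i = \pi (3p/4\pi)^{2/3} / R_i^2\), which makes the pairwise
self-overlap of an isolated atom equal its hard-sphere volume
\(\tfrac43\pi R_i^3\). Overlap between molecules A and B is first-order
(pairwise) only:

\[
V_{AB} = \sum_{i\in A}\sum_{j\in B} p^2
\left(\frac{\pi}{\alpha_i+\alpha_j}\right)^{3/2}
\exp\!\left(-\frac{\alpha_i \alpha_j}{\alpha_i+\alpha_j} d_{ij}^2\right),
\]

the exact integral of the product of the two summed densities. Shape
similarity is the Tanimoto \(V_{AB}/(V_{AA}+V_{BB}-V_{AB}) \in [0,1]\).
Pharmacophore character (donor, acceptor, positive, negative, hydrophobic)
is scored the same way per feature type on 1.0 Å feature Gaussians and
averaged over the types present in either molecule; two feature-free
shapes agree vacuously (score 1). The combined score is
\(w \cdot \text{shape} + (1-w) \cdot \text{feature}\) with default
\(w = 0.5\).

This scorer is an open substitute for the proprietary morphological
similarity function used by commercial superimposition tools. It preserves
the published contract — scores in \([0,1]\), a shape term plus a
charge-character term, \(\approx 0.7\) indicating a strong functional
relationship — without claiming numerical equality to any specific tool.
Higher-order intersection corrections are omitted; the overlap oracle in
the test suite (0.1 Å grid integration of the same first-order density)
agrees within 1%, which is the accuracy the package claims.

Why hydrogens are excluded from the shape: heavy-atom Gaussians are the
common practice in Gaussian-overlap methods, hydrogens contribute little
volume, and their placement is the least reliable part of any 3D builder.
Hydrogens are still made explicit on input because the donor rule needs
them.

## Alignment

Rigid alignment overlays Gaussian-weighted centroids, aligns principal
axes under the four proper axis flips, and seeds each flip with three
extra 90° rotations about the template axes (16 starts) — near-symmetric
shapes otherwise converge to pose-dependent local optima and break the
descriptor's pose-invariance contract. Each start is refined by
Nelder–Mead over the 6 rigid degrees of freedom (rotation exponential map
plus translation, score tolerance 1e-4, 500 iterations, plus one simplex
restart from the converged point). The query is re-expressed about its
Gaussian centroid before refinement so the rotation parameters pivot at
the overlay point: this makes the refinement objective exactly equivariant
to the query's input pose (a translated copy explores the same
neighbourhood), which is what makes profiles pose-invariant to within
floating-point noise. Everything is deterministic; ties between starts go
to the lowest start index. "Flexible" superimposition
enumerates the query's conformers against the rigid template and keeps the
`top_n = 10` poses; only the maximum enters the profile.

Measured behaviour on the toy fixtures: rigid-copy recovery scores
≥ 0.99, and profiling a randomly re-posed copy of a molecule moves each
profile element by ≤ 0.02 (the acceptance bound; observed at machine
precision after the centroid-pivot parametrization).

## The template library

Templates come from a pool of single-conformation ligands. The build chain
is: (1) an `n × n` self-similarity matrix by rigid–rigid alignment of
every ordered pair, symmetrized as `max(S_ij, S_ji)` because an
alignment-based score need not be symmetric, with unit diagonal; (2) the
distance between two pool members is one minus the Pearson correlation of
their matrix rows (full rows, diagonal included; zero-variance rows fall
back to distance 1); (3) greedy maximum-dissimilarity (max–min) selection
of `k` centres — first the point with maximal total distance, then
whatever maximizes the minimum distance to the chosen set, all ties to the
lowest index. Greedy max–min is the standard maximum-dissimilarity
algorithm; it is deterministic, and its selections are nested (the `k = 5`
selection is a prefix of `k = 10`), which the tests assert. The classic
library size is `k = 300`; toy libraries in the tests use `k ≤ 10`.

## Molecule input and conformers

SDF V2000 and MOL2 are parsed natively; SMILES support covers the
organic subset, brackets with charges and explicit H counts, branches and
ring closures (no stereo, no multi-component dots). No cheminformatics
toolkit exists in the target R environment, so conformer machinery is
deliberately lightweight: SMILES molecules are embedded by seeded stress
minimization over bond-length targets (covalent radii scaled by bond
order), 1–3 distances from idealized angles (109.47°/120°/180°) and
nonbonded lower bounds; conformer ensembles come from seeded torsion
driving around acyclic single bonds with heavy-atom clash rejection and
greedy RMSD pruning (`rmsd_prune = 0.5` Å, `max_confs = 50`, seed 42 by
default). This is not a force field. It satisfies the contracts that
matter here — rigid molecules keep exactly one conformer, retained
conformers are mutually ≥ `rmsd_prune` apart after optimal superposition,
identical seeds give identical ensembles — and it is adequate for the
geometric test fixtures; it is not adequate for production conformer
generation on real drug-like molecules, where an RDKit-class embedder
should replace it behind the same API.

Van der Waals radii (C 1.70, N 1.55, O 1.52, S 1.80, H 1.20 Å, default
1.70) load from `inst/extdata/vdw_radii.tsv` and can be overridden by
editing that table; the original method never states radii.

## Modelling

The SVM layer is self-contained (an SMO solver compiled with the package)
because no SVM package is available in the target environment; it was
cross-checked against LIBSVM during development (maximum decision-value
discrepancy ~1e-3, the SMO tolerance scale). Grid search follows the
standard LIBSVM recipe, `C ∈ 2^{-5,-3,…,15}`, `γ ∈ 2^{-15,-13,…,3}`, with
stratified 10-fold cross-validation; classification maximizes mean fold
AUC of decision values (rank-based, ties averaged), regression minimizes
pooled cross-validated RMSE; ties go to smaller `C`, then smaller `γ`.
An iteration budget of 100 SMO iterations per dual variable bounds the
pathological grid corners (near-constant kernel with huge `C`) that
converge extremely slowly and never win model selection.

Class imbalance (actives:decoys nominally 1:39) is handled by one of
three strategies: use the data as-is; subsample decoys to 1:10 per seed;
or keep all data and weight the penalty `C` per class (39:1 by default).
Metrics are computed exactly from their defining formulas, and any
statistic with a zero denominator is reported as `NA` ("undefined"), never
silently zero. The enrichment factor is the standard ratio of the active
rate in the top `⌈fN⌉` by score to the overall active rate, with ties
broken by stable input order; its cap is the inverse active fraction (40
at 1:39). Feature ranking fits a random forest (bootstrap CART, Gini,
`mtry = ⌊√p⌋`, 500 trees) and scores each variable by mean decrease in
out-of-bag accuracy under permutation; subset sizes at the 5/10/30/50/70/
100% fractions are prefixes of the ranking (15/30/90/150/210/300 at
`k = 300`).

## Selectivity analysis

The selectivity ratio between receptor subtypes is
`SR = pKi_A − pKi_B`; `|SR| ≥ 1.3` (inclusive) defines selectivity, i.e. a
20-fold affinity difference. A 1e-9 epsilon guards the boundary against
decimal floating-point artefacts (7.0 − 5.7 must count as 1.3).
Y-randomization refits the fixed model recipe on shuffled responses to
build a null distribution of the headline statistic (Q² for regression,
MCC for classification) and reports the real model's percentile.
Resampling stability repeats random 4:1 splits and summarizes the test
metric as mean ± sd. The applicability domain is a deliberate, simple
stand-in (the original report leaves its procedure to an appendix):
Euclidean distance to the training centroid with an in-domain threshold of
mean + 3 sd of the training distances, persisted with the object.

## What the synthetic data does and does not establish

The generators exist so the whole stack is testable with no downloads.
Toy molecules (rigid rings, chains, stars, random drug-like trees) give
controllably distinct shapes for the geometric stack. Synthetic descriptor
tables emulate the one robust statistic reported for real profiles —
scores concentrate in the mid-range — as Beta(4.05, 4.95) baselines
(mean 0.45) with a planted mean shift `δ = 0.25` on `m = 15` of `k = 300`
dimensions for actives, Gaussian noise `σ = 0.05`, clipped to [0, 1];
the default class sizes are 100 actives and 400 decoys. The selectivity
generator draws SR from a three-component mixture (core N(0, 0.5), tails
N(±2.2, 0.5), weights 0.5/0.25/0.25) and couples a chosen subset of
dimensions linearly to SR so regression recovery is possible by
construction.

A green test on these fixtures establishes that the pipeline recovers
planted structure at the stated sizes; it does not establish screening
performance on real chemistry, where actives form correlated clusters,
templates are genuinely bioactive conformations, and profile elements are
far from independent.

One documented consequence: the qualitative claim that 1:10 decoy
subsampling yields higher recall than 39:1 class weighting does **not**
reproduce in this synthetic world, and the corresponding acceptance test
is intentionally left failing rather than adjusted. The mechanism is
instructive: the planted-signal world is rank-separable, so many `(C, γ)`
cells tie at CV AUC = 1 and the smaller-`C` tie-break selects heavily
regularized models whose decision threshold is uncalibrated under
imbalance — subsampled models then classify every test active negative
while weighted models, whose boundary is pushed into the decoy side by
construction, reach recall ≈ 1. The ordering persisted across every
separability regime probed (shift 0.10–0.25, noise 0.05–0.15, full and
reduced grids). The published ordering evidently depends on real-profile
geometry the Beta-noise fixture does not reproduce.

## Numerical choices, in one place

* Overlap terms with exponent > 34 are dropped (below 1e-14 relative).
* Shape-Tanimoto denominators ≤ 0 raise an error: they cannot occur for
  valid shapes and indicate corruption.
* Nelder–Mead: score tolerance 1e-4, 500 iterations, one restart; 16
  deterministic starts (1 for degenerate inertia tensors).
* SMO: tolerance 1e-3, iteration budget 100 per dual variable; ε-SVR tube
  0.1.
* Undefined metrics are `NA` and excluded from aggregates.
* Profile caching is one plain-text file per molecule id under a directory
  keyed by the library fingerprint (pool hash + k); a cache built for a
  different library is refused, and failed molecules are flagged, never
  zero-filled (zero is a meaningful "no overlap" value).
* All seeded code paths go through one helper that sets and restores the
  RNG state, so fixed seeds are reproducible regardless of caller state.

## Known limitations

* The conformer generator is a torsion driver, not a force field: ring
  conformer enumeration, tautomers, protonation states and stereochemistry
  are out of scope; input structures are taken as given.
* First-order overlap underestimates multi-body intersections; scores are
  internally consistent but not comparable to other tools' absolute
  values.
* The SMO solver has no shrinking/caching and targets desk-scale problems
  (hundreds to a few thousand samples).
* The applicability domain is a centroid heuristic, not a validated
  procedure.
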