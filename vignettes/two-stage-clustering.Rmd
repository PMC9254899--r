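---
title: "Two-stage clustering of serial crystallography wedges"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage clustering of serial crystallography wedges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serialmerge)
```

## The model

A serial experiment yields many datasets, each a sparse sample of one
crystal's reciprocal lattice: a unit cell (a, b, c, α, β, γ) plus a
few percent of the symmetry-unique reflection intensities. The sample
may mix several crystal *forms* — ligand-bound states, packing
variants — and the task is to group datasets by form before merging.

`serialmerge` treats the two observables as two metrics used in
sequence:

1. **Cell metric.** Cells are compared either by the classic
   PCA/Euclidean six-vector distance or by a Niggli-cone G6 distance.
   The G6 embedding \[a², b², c², 2bc·cos α, 2ac·cos β, 2ab·cos γ\]
   (units Å²) makes the metric tensor the object of comparison;
   Niggli reduction removes the basis-choice ambiguity, and taking the
   minimum distance over a set of reduced-cone boundary operators
   removes the residual discontinuity when a lattice sits near a
   reduction boundary (nearly cubic cells, type I/type II borders).
2. **Intensity metric.** Merged groups with enough common unique
   indices are compared by Pearson correlation, which is the cosine of
   the angle between the mean-centred, norm-scaled intensity vectors
   and therefore indifferent to each dataset's unknown scale. The
   distance is the chord between those unit vectors,
   d = √(2(1 − CC)), plus a penalty for non-shared reflections.

The staging assumption is explicit: cell distances are meaningful at
any completeness but blind to near-isomorphous differences; intensity
distances resolve those differences but need overlap. Stage 1
clusters on cells *only* until merged clusters reach the completeness
cutover, then stage 2 re-clusters the merged sets on intensities.
Running a single combined metric instead would both require a common
indexing from the start and dilute the well-behaved low-dimensional
cell signal inside the high-dimensional intensity space.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `cutover_completeness` | 0.10 | fraction | stage-1 → stage-2 switch; lower keeps stage-1 clusters small and likely pure, higher gives stage 2 more overlap per set |
| `d_min` | 2.5 | Å | resolution limit for the unique-reflection enumeration |
| `stage1_metric` | `"ncdist"` | — | `"ncdist"` (G6/Niggli) or `"blend_pca"` (classic six-vector PCA) |
| `reduction_tol` | 1e-5 | relative | Niggli boundary tolerance; guards against oscillation for near-degenerate cells |
| `penalty_weight` | 1.0 | distance units | weight of the unmatched-reflection fraction added to SFDist |
| `activation` | 0.90 | fraction | common-fraction threshold below which the penalty applies |
| `scale_mode` | `"none"` | — | optional per-dataset linear scale fit during merging; CC is scale-invariant, so scaling mainly affects merged intensities, not distances |
| `max_lcv` | 2 | % | refuse to merge cells whose face-diagonal spread exceeds this |
| `stage2_cut` | adaptive | — | flat-cut rule for the stage-2 dendrogram (below) |

Angles are degrees in all I/O and radians internally; distances
derived from G6 are in Å².

## The stage-2 cut

The stage-2 dendrogram must be cut into flat clusters, and the choice
matters more than any other: cutting at the largest height gap (the
textbook elbow) reliably returns the *coarsest* split, because Ward
heights grow with cluster size, so the top merges dominate the gap
statistic, and merged sets that are themselves blends of two forms
fill in the height range between "same form" and "different form"
merges. On mixed samples that cut produces large blended clusters and
no pure ones.

The default rule is therefore adaptive and works on the distance
matrix, not the heights: the within-form distance scale `w` is
estimated as the median nearest-neighbour distance (every merged set
with at least one same-form partner has its nearest neighbour within
the form), the between-form scale `b` as the median of all pairwise
distances. If `b < 1.25·w` the data are declared homogeneous — one
cluster. Otherwise the tree is cut at height `(w + b)/2`. This
follows the operating principle that smaller clusters of sufficient
quality are more likely to be pure species than the largest
achievable ones; users who want a specific granularity can cut by
`count` or `height` instead, and the `gap` rule is kept for
comparison.

## What the generator emulates — and what it does not

`generate_experiment` builds: one Wilson (exponential, unit-mean)
reference intensity set per experiment; per form, a mean cell and a
multiplicative intensity signature on a random subset of unique
indices (fraction and scale per `form_spec`); per dataset, a random
subset of unique indices at a target completeness (3–8% by default),
Gaussian relative intensity noise (5%), and a cell drawn around the
form mean (0.05 Å on lengths, 0.02° on angles). The four-form preset
places two forms on one mean cell (N, B) and two on a cell expanded
0.3% in a and b (G, GB), with distinct intensity signatures on all
but N — so cell clustering can separate the two lattices but only
intensity clustering can resolve the pairs within each lattice. The
0.3% shift is ~4.7σ of the per-dataset cell noise per axis: clearly
separable, and consistent with the common reading of LCV values below
1% as good isomorphism.

Choices a real experiment would complicate:

* Wedges are random subsets of the unique-reflection sphere, not
  contiguous rotation slices; the clustering consumes only index sets
  and intensities, for which random subsets reproduce the completeness
  statistics that drive the method, but systematic wedge-geometry
  correlations (shared blind regions, anisotropic coverage) are absent.
* No partiality, radiation damage, indexing ambiguity, twinning, or
  per-dataset scale drift is simulated. CC's scale invariance makes
  the last harmless by construction here, which is exactly why it is
  the default comparison quantity.
* Intensity signatures are index-random multiplicative shifts, not
  structure-factor changes from a real ligand; they reproduce the
  *separability* structure (which pairs of forms are distinguishable
  by which metric), not crystallographic detail.

Passing tests on this generator therefore demonstrate that the staged
method recovers known mixture structure under realistic completeness,
noise and degeneracy conditions — not that any particular real sample
will behave identically.

The intensity scale written to HKL files is 1000 by default
(`mean_intensity`): the HKL4 format carries two decimals in an
8-character field, and a unit-mean signal would quantize badly;
correlation distances are unaffected by the choice.

## Numerical choices

* **Niggli reduction** is the Krivý–Gruber stepwise algorithm with a
  relative tolerance (default 1e-5, scaled by (ABC)^{1/3}) on every
  boundary comparison and a step budget of 1000; exceeding the budget
  raises a typed error carrying the partial result. The 3×3 integer
  transform (det ±1) is accumulated so the reduced metric can be
  verified against the input basis.
* **NCDist** is computed as the minimum over 24 signed-permutation
  boundary operators (6 axis permutations × 4 even sign flips of the
  off-diagonal components) applied once to either reduced vector. The
  operator set is orthogonal and closed under inverse, so one-sided
  minimization equals the two-sided brute force, which the tests
  verify. This is an upper bound on the exact Niggli-cone geodesic;
  the full embedding-space boundary analysis is out of scope.
* **Ward linkage** uses the Lance–Williams recurrence on squared
  distances with heights reported as square roots (the ward.D2
  convention: two singletons merge at their input distance), and
  deterministic tie-breaking by the lowest pair of cluster slot
  indices. Heights match `stats::hclust(method = "ward.D2")` to 1e-9
  in the tests, which keeps that implementation available as an
  independent reference rather than a dependency.
* **ASU mapping** canonicalizes an index to the lexicographically
  greatest image under the Laue group (operators as integer matrices,
  closure computed at construction, Friedel inversion always present).
* **Completeness** denominators are enumerated from the reciprocal
  metric to `d_min`, excluding (0,0,0). For dendrogram annotation the
  numerator and denominator of every node use one reference lattice
  (the mean of the leaf cells) so that values are comparable across
  the tree; per-set `completeness()` uses the set's own cell.
* **LCV** uses the longer parallelogram diagonal of each of the three
  independent cell faces, d = √(x² + y² + 2xy·|cos θ|), the maximum
  pairwise spread over members as a percentage of the smaller
  diagonal, and the same spread in Å for aLCV. The defining
  convention (which diagonal, which denominator) varies between
  implementations; this one is fixed here and used consistently.
* **SFDist base form** is the chord √(2(1−CC)); √(1−CC²) is available
  behind the `sfdist_base` switch. The unmatched-reflection penalty
  is proportional to the unmatched *fraction* of the index union
  (size-invariant), applied only when the common fraction is below
  the activation threshold. Pairs with fewer than 3 common indices or
  zero variance get a configurable sentinel distance and are reported,
  not silently dropped.
* **Degenerate inputs.** Non-positive-definite metrics, cells with
  angles outside (0°, 180°), (0,0,0) indices, non-positive sigmas,
  mixed Laue groups, and merges across cells beyond the LCV guard all
  raise errors naming the offending dataset where applicable. A
  stage-2 run with a single selected cluster degenerates to an
  identity assignment with a warning.

## Problem sizes

The test suite exercises the full pipeline at 999–1000 wedges
(the four-form benchmark with ~4500 unique reflections to 2.5 Å,
~310 selected clusters into stage 2) and the component properties at
50–200 random instances each; the complete suite runs in about a
minute on one CPU. `scripts/acceptance.R` regenerates the benchmark
and reports its headline numbers in ~25 s.

## Known limitations

* The NCDist here is the boundary-operator approximation described
  above, not the exact cone geodesic; Delaunay/Selling (S6/C3)
  reductions are not implemented.
* Laue groups −1, 2/m, mmm, 4/m and 4/mmm are built in; others load
  from operator files. Space-group (as opposed to Laue) logic,
  anomalous pairs, and indexing-ambiguity resolution are out of scope.
* Merging performs inverse-variance weighting with an optional linear
  scale only — no full scaling model, outlier rejection, or error
  model refinement.
* The adaptive cut assumes most merged sets have at least one
  same-form partner; with singleton forms (one merged set for a form)
  the within-scale estimate degrades toward the between-scale and the
  rule becomes conservative (fewer, larger clusters).
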