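---
title: "Interface graphs and the GINet model: methods and design choices"
author: "grappi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interface graphs and the GINet model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grappi)
```

## Overview

`grappi` treats a two-chain protein complex as a residue-level graph and
learns interface properties with a small two-branch graph network. This
vignette explains the model, its assumptions, the tunable parameters and
the numerical choices; it is the place where design decisions that were
genuinely open are recorded.

## From coordinates to a graph

A structure is parsed from a PDB file down to protein heavy atoms: only
`ATOM` records of the first model are read, hydrogens/deuterium, waters
and HETATM-derived residues (including selenomethionine) are removed, and
alternate locations are resolved by keeping the highest-occupancy
conformer (ties: the first listed). Because hydrogens are removed at parse
time, every distance computed downstream is a heavy-atom distance by
construction. Residues are identified by the triple (chain id, residue
number, insertion code); residue names outside the 20 canonical amino
acids are retained but flagged, and the featurization step decides their
encoding.

**Contact residues** are those with at least one heavy atom within the
*interface cutoff* (default 8.5 Å) of any heavy atom of the other chain;
they form the graph's nodes, ordered deterministically by (chain, number,
insertion code). **External edges** join cross-chain node pairs whose
minimal heavy-atom distance is within the interface cutoff; **internal
edges** join same-chain node pairs within the *internal cutoff* (default
3 Å). One open point was whether the cutoff comparisons are strict or
inclusive; `grappi` uses `<=` uniformly for node detection and for both
edge types, and the boundary behaviour is pinned by tests. Graphs are
undirected; each edge is stored once with i < j and expanded to both
directions when the network consumes it. A complex whose chains share no
atom pair within the interface cutoff cannot be converted — this is a
distinct "no interface" error, not an empty graph, and ensemble helpers
(`build_graphs()`, the `graph-gen` CLI) skip such models with a log line,
which is how dissociated docking decoys are handled.

Graph collections are serialized to HDF5 (one group per model: node keys,
feature matrix, 0-based edge index matrices, per-edge distances and
strengths, a `target` subgroup of named scalars, and feature names as
group attributes). The schema is fixed by this package; edge indices are
stored 0-based for language neutrality.

## Features

The edge feature is an interaction strength
\[ e(x) = \tanh(-x/2 + 2) + 1 \]
of the minimal inter-residue heavy-atom distance \(x\): a smooth, strictly
decreasing map from \([0,\infty)\) onto \((0, \tanh 2 + 1]\), i.e. about
\(1.96\) at contact and 0 at long range. The same transform is applied to
internal and external edges (whether these should differ was open; one
transform keeps the two branches comparable).

Node features, in fixed column order:

| block | width | notes |
|---|---|---|
| residue type one-hot | 20 | alphabetical 3-letter order (`AA3`) |
| formal charge | 1 | ARG/LYS +1, ASP/GLU −1, HIS +0.1, others 0 |
| polarity one-hot | 4 | apolar (9) / polar (7) / positive (2) / negative (2) |
| buried surface area | 1 | Å², isolated-chain SASA − complex SASA |
| PSSM profile | 20 | optional, from per-chain profile files |
| information content | 1 | optional |
| conservation | 1 | optional, own-residue PSSM score |

Defaults give 26 columns; with all PSSM features enabled, 48; a PSSM-only
configuration (used for interface classification) gives 20. The charge
and polarity tables are standard pH-7 chemistry fixed in this package;
the +0.1 for histidine approximates its partial protonation. The
conservation score is defined here as the substitution score of the
residue's own amino-acid type (the diagonal read-out of its PSSM row) — a
package convention, since tabular profile formats carry no dedicated
conservation column. Non-canonical residues get all-zero one-hot blocks,
zero charge and zero conservation, with a warning.

Deeper exposure descriptors (residue depth, half-sphere exposure) are not
computed: their information is largely implied by the buried surface area
and the node neighbourhood, and they are costly.

### SASA and buried surface area

SASA uses the Shrake–Rupley method: probe radius 1.4 Å, 100 deterministic
golden-spiral sample points per atom, van der Waals radii C 1.70, N 1.55,
O 1.52, S 1.80 Å. BSA per residue is its SASA on the isolated chain minus
its SASA in the complex, clamped at zero.

Two numerical subtleties are worth recording. First, sampled surface areas
are only rotation invariant if the sample directions co-rotate with the
molecule, so the directions are generated in a canonical PCA frame of the
coordinates with signs fixed on the projected coordinates; this makes
SASA *exactly* invariant under rigid transforms rather than invariant up
to sampling noise. Second, the frame is computed **per chain**: a chain's
atoms are sampled identically whether the chain is evaluated alone or
inside the complex, which makes BSA exactly non-negative (each sample
point accessible in the complex is accessible in the isolated chain) and
exactly zero for residues with no cross-chain neighbours. With a single
global frame, BSA would carry sampling noise of the order of one point
quantum (~1 Å²).

Note that writing coordinates through the fixed-column PDB format rounds
them to 10⁻³ Å; that quantization is not a rigid motion, so
point-sampled BSA may differ at the single-point-quantum level between a
structure and its file round-trip. All invariance guarantees apply to the
computation on given coordinates.

## Docking-quality targets

With a reference (bound) structure, `grappi` computes, per model:

* **f_nat** — the fraction of the reference's cross-chain residue contacts
  (minimal heavy-atom distance ≤ 5 Å) reproduced by the model. Capped in
  [0, 1] by construction, which gives all bad models equal weight — unlike
  RMSDs, which diverge arbitrarily for bad models.
* **iRMSD** — backbone (N, CA, C, O) RMSD over the reference-defined
  interface residues (cross-chain distance ≤ 10 Å) after least-squares
  superposition of those atoms (Kabsch, proper rotation enforced).
* **lRMSD** — the model is superposed on the reference receptor backbone
  (receptor = the chain with more residues; ties: first chain id), then
  the ligand-chain backbone RMSD is reported without further fitting.
* **CAPRI class** — high (f_nat ≥ 0.5 and lRMSD ≤ 1 or iRMSD ≤ 1), medium
  (f_nat ≥ 0.3 and lRMSD ≤ 5 or iRMSD ≤ 2), acceptable (f_nat ≥ 0.1 and
  lRMSD ≤ 10 or iRMSD ≤ 4), else incorrect.

The 5 Å contact cutoff, 10 Å interface cutoff and the class table follow
the CAPRI assessment convention; they are conventions adopted by this
package, not values with a single canonical source. The binary label uses
an inclusive f_nat ≥ 0.3 threshold — deliberately stricter than the CAPRI
0.1 "acceptable" f_nat bound, which is only meaningful in combination with
RMSD criteria; when f_nat is used alone, a 0.3 cut avoids labelling poor
models as positives. Residues present in the reference but absent from a
model are dropped from RMSD atom sets with a warning.

## The GINet network

The graph is processed by two parallel branches: one sees only internal
edges, the other only external edges. The rationale is to learn both the
interaction itself (external branch) and each side's propensity to
interact (internal branch). Each branch applies two graph convolutions

\[ h_i' = \mathrm{ReLU}\!\left(W_{self} h_i + \sum_{j \in N(i)} e_{ij}\, W_{nbr} h_j + b\right) \]

with the edge strengths \(e_{ij}\) as fixed aggregation weights. Nodes
with no edges in a branch (e.g. a graph with zero internal edges) pass
through the self term only. Each branch is flattened by the per-feature
mean over nodes; the two vectors are concatenated and passed through two
fully connected layers (ReLU between) to the output.

Open choices, resolved as follows:

* The exact convolution update is fixed as the edge-strength-weighted sum
  with separate self and neighbour transforms — the simplest rule
  consistent with message passing over edge-featured graphs, and fully
  testable by hand arithmetic and finite-difference gradient checks.
* The branches are parallel and independent; an interleaved variant (the
  two edge sets alternating within one branch) is conceivable but not
  built.
* Pooling inside the convolution blocks is the identity at this graph
  scale; the only pooling is the final per-feature mean, which is what
  makes the output invariant to node ordering.
* Edge strengths are computed once from geometry and held fixed across
  layers.
* Hidden widths default to 16 (convolutions) and 128 (first fully
  connected layer); no published values exist for these, so they are
  configurable.

Because the features are rigid-motion invariant and the network sees only
connectivity and features, predictions are end-to-end invariant to
rotations/translations of the input coordinates, and invariant to node
permutations (mean pooling plus symmetric aggregation); both properties
are asserted to 10⁻⁵ in the test suite.

### Training

Forward, backward (analytic gradients) and the Adam optimizer
(β₁ = 0.9, β₂ = 0.999, ε = 10⁻⁸) are implemented in plain R matrix code;
a finite-difference check in the test suite pins the gradients. Defaults
follow the scoring protocol: 20 epochs, batches of 128 shuffled graphs,
learning rate 0.001, MSE loss for regression on f_nat; classification
uses cross-entropy (50 epochs are typical there). One seed controls
parameter initialization; a second (the train config's) controls
shuffling. The returned model carries the parameters with minimum
**evaluation-set** loss — the defensible variant where a selection
criterion had to be fixed — plus the full per-epoch loss trace.

For imbalanced classification, class weights inversely proportional to
class frequency (normalized to sum 1) can be requested. The weighted
cross-entropy is normalized by the *sum of sample weights in the batch*,
so duplicating every minority example k times under uniform weights is
exactly equivalent to weighting that class by k — a property the test
suite checks at the single-gradient-step level.

Feature scaling is off by default (raw feature values are stored in the
graphs); a train-config flag enables min–max scaling with training-set
statistics, which are stored in the model and re-applied at prediction
time. The worked examples and the learning-pathway check enable it, since
raw BSA values (tens of Å²) otherwise dominate the one-hot blocks at
small learning rates.

## Metrics

Scoring performance is summarized by the ROC AUC (computed as the
Mann–Whitney statistic, i.e. rank-averaging for ties — identical to the
trapezoidal ROC integral), the hit rate (percentage of all positives in
the top N), the per-complex success rate (percentage of complexes with at
least one positive in the top N), Spearman rank correlation, and the
standard confusion-matrix ratios (accuracy, specificity, sensitivity,
precision) for classification. Undefined ratios (zero denominators) are
reported as `NA`, never as 0. Ranking ties are broken by a stable sort on
model id so that top-N metrics are deterministic. Per-complex ROC curves
can be averaged on a fixed FPR grid for cohort-level plots.

## The synthetic fixture generator

The fixtures module stands in for curated docking benchmarks so that the
complete pipeline is testable offline. `make_reference_complex()` builds
two idealized extended chains (N, CA, C, O and CB except glycine;
standard bond lengths; 3.8 Å CA spacing) facing each other across a gap
(default 7 Å between the CA planes) with both chains' CB atoms pointing
into the interface, so that at least five cross-chain residue pairs sit
within the 5 Å contact cutoff. Residue types are sampled from the 20
canonical amino acids, with the first six positions avoiding glycine so
their CB contacts always exist; a ±0.12 Å uniform jitter removes
degenerate exact ties. `make_decoys()` emulates docking models of graded
quality by rigidly rotating the ligand chain about its centroid and
translating it: level L means L Å translation in a random direction and
4L degrees rotation about a random axis (defaults L ∈ {0, 1, 2, 4, 8},
chosen to cover near-native through dissociated). The true transform of
every decoy is recorded in a manifest. `make_pssm()` writes per-chain
profile files with the own-residue column biased positive (≈ +6 vs ≈ −1
background), emulating what an iterative sequence search produces.

What the fixtures deliberately do **not** emulate: side-chain packing,
realistic docking energetics and clash filtering, sequence-correlated
evolutionary profiles, and the size/diversity of real benchmarks. Passing
tests therefore demonstrate that the representation, targets, learning
machinery and metrics are correct and internally consistent at desk
scale — not that the trained toy models transfer to real docking data.

## Problem sizes and determinism

The test suite and acceptance checks use deliberately small problems: the
brute-force oracle comparisons run on 100 random complexes of 5–7
residues per chain, and the learning-pathway check trains on a ~500-decoy
benchmark (10 residues per chain, 5 perturbation levels, 100 decoys per
level; decoys without an interface are skipped), reaching held-out AUC
well above 0.8 in about a minute of CPU. Every source of randomness —
fixture geometry, decoy transforms, profile scores, parameter
initialization, shuffling, splits — is governed by explicit seeds, and
identical seeds give bit-identical outputs (including written files).

## Known limitations

* Two-chain complexes only; no multimer assessment, no nucleic acids,
  no mmCIF input, no atom-level graphs.
* PSSMs are parsed, never computed; profiles must be supplied per chain.
* No clash criterion: models that cannot be converted fail with the
  generic "no interface"/parse errors only.
* The CLI config file is YAML (single file, flags override it).
* Training is CPU-bound plain R; it is meant for desk-scale experiments,
  not for hundreds of thousands of models.
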