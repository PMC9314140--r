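---
title: "Interface-constrained rescoring of docking decoys: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interface-constrained rescoring of docking decoys: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dockface)
```

## The problem

Rigid-body docking pipelines have two stages: a fast scan that
enumerates mutual orientations of two proteins by shape
complementarity, and a scoring stage that must fish the few near-native
arrangements out of hundreds of thousands of decoys. `dockface`
implements a scoring stage driven entirely by *interface predictions* —
per-residue probabilities of belonging to the native binding site,
predicted independently for each chain — together with everything
needed to measure how prediction quality maps to docking success.

## The model

### Pose score

For a pose placing the ligand relative to the fixed receptor,

$$ S \;=\; \sum_{i=1}^{N_1}\sum_{j=1}^{N_2}
   \begin{cases} -\ln\!\left(1 - p_i\, p_j\right) & d_{ij} < d_t \\
   0 & \text{otherwise,} \end{cases} $$

with $p_i, p_j$ the interface probabilities of receptor residue $i$ and
ligand residue $j$, and $d_{ij}$ the distance between their
representative points (Cβ; Cα when Cβ is absent, as for glycine). Each
term is the negative log of the probability that the pair is *not*
jointly interfacial, so $S$ accumulates independent evidence across
contacts: it is zero when no informative pair is in contact,
non-decreasing in every probability, and non-decreasing in $d_t$.

**Parameters.** `d_threshold` defaults to 12 Å (8 and 10 Å are exposed
as the standard alternatives for sensitivity analysis); probabilities
are capped at `cap = 0.99` because $p = 1$ makes a term infinite — a
single certain contact would otherwise override all other evidence.
Residues missing from a probability table contribute $p = 0$: an
unscored residue is treated as predicted non-interface, the
conservative reading of a predictor that skips residues.

**Numerics.** Scores accumulate in double precision over pairs in
receptor-major order, summing only strictly positive terms; this is
bit-identical to the naive double loop over all pairs (adding exact
zeros does not perturb an IEEE sum), which the test suite asserts on
random instances up to 50×50 residues. Ranking is a stable sort:
score ties keep scan order, so rescoring can only reorder, never
scramble, the scan-stage ranking. Distances are compared as
`sqrt(dx² + dy² + dz²) < d_t` with the same expression on both the
vectorized and reference paths so threshold decisions agree bitwise.

### Native interfaces

A residue is *interface* when its solvent accessible surface area in
the isolated chain exceeds its SASA in the complex by more than
`delta_cutoff = 0.01 Å²` — zero in exact arithmetic means "not buried",
and the small positive guard absorbs floating-point noise in the sphere
sampling. SASA is computed by an in-package Shrake–Rupley
implementation: element-based van der Waals radii, a 1.4 Å water probe,
and a *deterministic* 960-point Fibonacci sphere per atom, so interface
sets are bit-stable across runs (a seeded random-sphere implementation
written independently serves as the oracle in tests; the two agree on
which residues lose area). *Surface* residues — the candidate pool for
false-positive injection and the denominator of the I/S baseline — are
those with relative SASA of the isolated chain above 5% of the residue
type's theoretical maximum. The 5% choice is a declared convention:
published benchmarks rarely state their cutoff, and any value in the
1–10% range only moves a handful of borderline residues on our toys.
When a residue has no bound-form correspondence the same criterion is
evaluated on the unbound chain superposed onto its bound counterpart
(`extract_interface_unbound_fallback`).

### Simulated predictions

To study docking success at *controlled* prediction quality, noise is
injected into the native interface in two steps: randomly drop
interface residues until the retained true positives equal
`round(TPR · n_interface)`, then randomly add non-interface surface
residues until `FP = round(TP · (1 − PPV)/PPV)`. Rounding is
nearest-integer (ties to even, R's `round`); the achieved rates
therefore deviate from the targets by at most `0.5/n`, which the tests
assert across the whole grid. Marked residues carry probability 0.99 —
the same value as the native-constraint upper baseline, so "perfect
prediction" and "native constraints" coincide — and everything else 0.
One seeded generator is consumed in chain order A then B, making every
table reproducible from `(targets, seed)`. The default grid degrades
one rate while holding the other at 1: (0.25/1), (0.5/1), (0.75/1),
(1/0.25), (1/0.5), (1/0.75). On small synthetic chains the low-PPV
points can demand more false positives than the surface offers;
`simulate_predictions` then errors with the achievable PPV, and the
benchmark builder records the grid point as infeasible rather than
silently changing the target.

### Model quality

`dockq()` follows the published DockQ combination: Fnat is the fraction
of native interchain residue contacts (any heavy-atom pair < 5 Å)
reproduced by the model; iRMS is the backbone (N, Cα, C, O) RMSD over
the native interface (contacts under a widened 10 Å shell) after
superposing on those atoms; LRMS is the ligand backbone RMSD after
superposing on the receptor; and

$$ \mathrm{DockQ} = \tfrac13\left( F_{nat}
  + \frac{1}{1+(iRMS/1.5)^2} + \frac{1}{1+(LRMS/8.5)^2} \right), $$

with classes acceptable/medium/high at 0.23/0.49/0.80. A model
identical to its native scores exactly 1. SR(N) is the fraction of
complexes with at least one model above 0.23 among the top N.
Difficulty classes use interface Cα RMSD between unbound and bound
forms and the non-native contact fraction: easy below 1.5 Å with
f_non-nat < 0.4, hard at 2.2 Å and above, medium between — the printed
rules leave gaps (e.g. i-RMSD 1.6 Å with f_non-nat 0.3) and exact
boundaries, which we resolve toward the higher difficulty, a
conservative and configurable choice.

### Precision–recall

`pr_auc()` sweeps the unique probability values as thresholds in
decreasing order over the chain's *surface* residues and integrates
precision over recall by the trapezoidal rule, anchored at
(recall 0, precision of the top threshold); a step-wise
average-precision variant sits behind `variant = "step"` because the
literature uses both and they differ on coarse curves. A constant
predictor attains precision equal to the interface/surface count ratio
(I/S) at its single threshold — the random-predictor reference. Binary
predictors get a single (TPR, PPV) point via `confusion_rates()`; an
empty prediction has recall 0 and *undefined* (NA) precision rather
than 0, so averaging over chains does not silently punish abstention.
Because per-chain AUC aggregation is ambiguous (pooled residues vs.
mean of chains), `pr_auc_complex()` emits both, labeled `micro` and
`macro`, plus the `worst_chain` minimum.

## Rigid-body geometry

Poses are a translation plus three Euler angles, rotation about the
ligand's atom centroid. Scan-stage programs rarely document their
angle convention, so the convention is explicit configuration —
`zyz-intrinsic` (default), `zyx-intrinsic`, `xyz-extrinsic` — and is
written into pose-table headers; tests verify each against sequential
single-axis rotations. Superposition is Kabsch via SVD with the
determinant correction, so reflections can never be returned; tests
assert orthonormality and det = +1 to 1e-9.

## The synthetic test bed

`make_toy_complex()` builds two extended poly-alanine chains with
backbone and Cβ atoms: the receptor straight, the ligand running
parallel at a 6.2 Å Cα–Cα gap over a designated contiguous patch and
bending away outside it, so SASA burial happens exactly at the packed
segment (plus at most a one-residue fringe; the recorded ground truth
is the SASA criterion's own output, cross-checked against the
independent oracle). Unbound forms add optional iid Gaussian coordinate
noise, renumbering offsets, and a loop shift, exercising mapping,
trimming and the unbound fallback. `generate_toy_decoys()` mixes
near-native poses (each Euler angle within ±5°, keeping the total
rotation under 15°; translations up to 3 Å) with wrong-site poses:
random orientations slid along random directions until the chains touch
(minimum interatomic distance bisected into the 2.5–5 Å window), so
decoys are surface-to-surface contacts, not interpenetrations. The
default near-native fraction is 5% — enough that a decoy set plausibly
*contains* an acceptable model, which is the premise of any rescoring
experiment, without emulating full scan-stage redundancy.

**What the toys do not emulate:** side-chain packing, realistic
secondary structure, electrostatics or desolvation, conformational
change on binding, and the shape-complementarity bias of real scan
output. Passing tests therefore demonstrate the *mechanics* of the
pipeline — that correct constraints concentrate the score on the
correct patch and that quality metrics respond as designed — not
performance on experimental complexes.

## Problem sizes

The test suite and the acceptance script run entirely on generated
data: toy complexes of 14–28 residues per chain, decoy sets of up to
500 poses across 20 complexes for the end-to-end success-rate check,
200 random scorer fixtures up to 50×50 residues, and 20-seed averages
for the noise-grid calibration. These sizes were chosen so a full run
completes in a few minutes on one core while every check retains its
discriminating power; all of them are arguments, and scale up linearly
if heavier runs are wanted.

## Known limitations

* Interface constraints are residue-level, not contact-level: two
  correct patches can face each other in the wrong relative rotation,
  which the score cannot penalize. `interface_cm_deviation()` exists
  precisely to diagnose this failure mode (small deviation, low DockQ).
* The score rewards contact *count*, so poses that bury more of the
  predicted patch than the native arrangement can outrank near-native
  poses when unbound forms fit imperfectly.
* mmCIF, nucleic-acid chains, and assembly symmetry are out of scope;
  PDB only.
* The SASA engine targets protein heavy atoms with a fixed radius
  table; exotic ligands or modified residues fall back to a 1.7 Å
  default radius.
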