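---
title: "Local fit, local resolution and ensemble flexibility: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local fit, local resolution and ensemble flexibility: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryofit)
```

This vignette explains the models and procedures behind each analysis,
the parameters that matter and their defaults, what the synthetic-data
generator does and does not emulate, and the numerical choices made
where the design was genuinely open.

## Coordinate conventions

All coordinates are orthogonal Ångströms in the model frame. A
`density_grid` stores its field in canonical axis order — `data[ix, iy,
iz]` with x the fastest-varying index — whatever axis permutation the
MRC file used (`MAPC/MAPR/MAPS` are honoured on input and written
canonically on output). The centre of voxel `(1, 1, 1)` sits at
`origin`; every real↔voxel conversion goes through one pair of internal
functions, and nearest-voxel lookups break ties toward the lower index
on each axis, so results are deterministic. Non-orthogonal cells are
rejected: cryo-EM maps are orthogonal in practice. Hydrogens are
ignored in every scoring operation (predictions differ in whether they
include them), and where a (residue, atom) appears with several
alternate locations the alphabetically first is used.

## Simulating density from a model

SMOC compares experimental density with a model-derived density on the
same lattice. Each heavy atom contributes an isotropic Gaussian of
width σ = `sigma_coeff` × resolution with amplitude proportional to its
atomic number. Defaults: `sigma_coeff = 0.356`, the conventional
model-blurring factor of the SMOC lineage, and simulation resolution
equal to the map's reported global resolution (both overridable through
`sim_params()`). Simple Z-weighting is used instead of electron
scattering-factor tables: the overlap coefficient is invariant to
per-atom scale factors that vary slowly over a window footprint, so the
extra fidelity would not change the scores it feeds. The kernel is
truncated at 4σ; linearity in atoms and the closed-form integral
`Σ voxels ≈ Z (2πσ²)^{3/2} / voxel volume` are enforced by tests.

## SMOC and fragment-aligned ΔSMOC

For each chain, windows of `window` residues (default 11, odd) slide
one residue at a time. The window's footprint is the union of voxels
within `radius` (default 2.5 Å) of its atoms; the score assigned to the
central residue is the Manders overlap between experimental and
simulated values over that footprint. At chain termini windows shrink
rather than drop, down to half a window, so every residue is scored;
chains shorter than half a window are skipped with a warning. Missing
scores (empty or zero-power footprints) stay missing — they are never
coerced to 0, because 0 is a meaningful ΔSMOC value.

ΔSMOC removes global pose error before asking whether a prediction
explains the local density: each prediction window is superposed onto
its corresponding target residues by least squares over matched
backbone atoms (N/Cα/C/O for protein, P/O5′/C5′/C4′/C3′/O3′ for
nucleic; representative atoms as a fallback below 3 matches), then both
the transformed fragment and the target residues are simulated *in
isolation* with identical parameters and scored over their own
footprints; the difference goes to the central residue. Simulating
both sides the same way makes the score an exact fixed point: a
prediction identical to its target scores 0 everywhere, bit-exactly,
and a rigidly moved copy scores below 1e-6 (enforced by tests).
Neighbouring non-window atoms are deliberately excluded from both
simulations — including target context around a prediction fragment
would break that symmetry.

Residue correspondence uses author (chain, number, insertion-code) keys
when the numbering agrees, and falls back to a global sequence
alignment (identity scoring +2/−1, affine gaps 5/0.5) for chains with
no key overlap, as happens when predictors renumber.

The 5-residue high-resolution variant keeps the same alignment but
restricts the footprint to the central residue's backbone atoms (N, CA,
C, O, OXT) or its remaining heavy atoms (Cβ counts as sidechain);
glycine has no sidechain entry. It is meant to be combined with
`exclude_by_locres()` at the 2.5 Å cutoff used for sidechain-level
assessment — sidechain density does not exist to score below that.

## Local resolution from half-maps

The Fourier shell correlation between unfiltered half-maps,

`FSC(s) = Re Σ F₁ conj(F₂) / √(Σ|F₁|² Σ|F₂|²)`,

is computed in equal-width shells up to Nyquist; the resolution is the
reciprocal of the first downward crossing of the threshold (0.5 for
half-map local resolution; 0.143 available for global reporting),
linearly interpolated between shells. A curve that never crosses
reports the Nyquist resolution; one already below threshold reports the
first shell.

Local resolution restricts this question to a soft spherical window
(raised-cosine edge over the outer 25% of the radius; default radius
10 voxels). Two computations are provided:

* `method = "bandpass"` (default): both half-maps are decomposed into
  frequency shells on the *full-size* transform, and the per-shell
  products are averaged over the window by convolution, giving a
  per-voxel FSC curve. Because shell decomposition happens before
  windowing, no signal power leaks across shell boundaries.
* `method = "window"`: the textbook procedure — cut the window out,
  FSC the two small volumes — evaluated on a lattice (`step` voxels,
  default 4) and filled in by trilinear interpolation.

The two agree in rank order, and tests require both to order a
two-zone 4 Å/10 Å toy correctly. The bandpass form is the default
because at desk-scale window sizes (a 21-voxel box around an 8 Å
signal) the cut-out procedure is systematically optimistic: the window
transform's sidelobes leak correlated signal beyond the true cutoff,
and on a 64³ toy with a uniform 8 Å pattern it reports a median of
~3.8 Å where the bandpass form reports 6.7 Å (full-map FSC: 8.02 Å).
Values are clamped to [2 × voxel, 2 × window radius] — nothing finer
than Nyquist or coarser than the window diameter is reportable.

Projection onto a model takes, for each atom, the value of the nearest
locres voxel; the per-residue track uses the representative atom (Cα
for amino acids, C4′ for nucleotides) so that RMSF and local resolution
sample the same point. `mean_local_resolution()` averages over all
heavy atoms — over the region the model occupies, not the whole map.
Externally computed local-resolution maps read from MRC behave
identically to internally computed ones.

## Ensemble flexibility and accuracy gating

RMSF of a 5-model prediction set is computed after rigidly superposing
models 2–5 onto model 1 over the representative atoms shared by all
models (the superposition is the proper-rotation Kabsch solution; a
reflection is never returned). For each residue present everywhere,
`RMSF = √(mean over models |r_m − r̄|²)` — the population form over the
m models, about the ensemble mean. Fluctuation about the mean of m
samples removes one degree of freedom, which is why the synthetic
closed form is `3σ²(m−1)/m` for per-coordinate displacement σ; tests
hold the implementation to that expectation within 10%.

Groups enter the flexibility-versus-resolution comparison only when
every model clears, with strict inequality, global lDDT > 0.7 and
TM-score > 0.8, plus interface similarity > 0.8 for multimers. The
gates are implemented from their definitions: lDDT as the fraction of
reference heavy-atom pairs (different residues, within 15 Å) whose
distances are reproduced within 0.5/1/2/4 Å, averaged over thresholds,
with no stereochemistry term; TM-score with d₀ = 1.24(L−15)^⅓ − 1.8
(floored at 0.5 Å) under iterative superposition refined on residues
within d₀ until the inlier set repeats (max 20 iterations, best score
kept, sequence-dependent correspondence — the gate compares
same-sequence predictions, so no structural alignment is needed);
interface similarity as the Jaccard index of inter-chain residue
contact sets at a 5 Å heavy-atom cutoff, a natural reading of an
interface-patch score that is not pinned down elsewhere. Global lDDT
(not the per-residue mean) feeds the gate.

Correlations are sample Pearson coefficients over the residues with
finite values in both tracks, with n reported; fewer than 3 shared
residues or (numerically) zero variance yields a missing value with a
recorded reason rather than an error, so degenerate groups surface in
report tables instead of aborting them. Accuracy-estimate correlations
use |r|, since pLDDT-style scores (higher better, detected on 0–1 or
0–100 scales and normalised) and positional-error estimates (Å, lower
better) point in opposite directions. An all-zero B-factor column
raises a distinguishable "absent" condition — RNA predictions often
carry no estimate, and "absent" must never be read as 0.

## The synthetic-data generator

The generator produces the study conditions the tests run under:
poly-alanine toys (ideal α-helix: 2.3 Å radius, 1.5 Å rise,
100°/residue; or a seeded self-avoiding coil), ensembles built by
displacing each residue rigidly by zero-mean Gaussian offsets with
per-residue scale σᵢ (residue-rigid so fragment superposition stays
meaningful), and half-map pairs built by simulating density, low-pass
filtering nearest-residue zones at their pattern resolution (soft
Gaussian-blended masks, ~3-voxel edges, to avoid ringing), and adding
independent white Gaussian noise to each half at `noise_sigma` times
the signal's standard deviation. Defaults — 60-residue bundles, 1 Å
voxels, `noise_sigma = 1` (map-wide SNR ≈ 1), flexibility gradients of
0.2–1.2 Å mapped to resolution patterns `3.2 + 2.5σ` Å — were chosen
once as desk-scale stand-ins for a mid-resolution single-particle
reconstruction; all grids complete on one CPU in seconds. Everything
is a pure function of its arguments and `seed`.

What it does not emulate: CTF and envelope effects, beam-induced
motion, solvent noise correlations, B-factor variation, real rotamer
chemistry. Passing tests therefore demonstrate the *mechanics* —
recovery of imposed patterns, correct signs and localisation of
constructed errors, closed-form fluctuation statistics — not
performance on experimental reconstructions.

Two limitations are worth stating plainly. First, windowed local
resolution has spatial resolution of order the window radius, so
imposed patterns are recovered smoothed; recovery tolerances (±25% on
a uniform pattern, rank order on a two-zone pattern) reflect that.
Second, a 60-residue chain contains only ~7 independent stretches
after window-scale smoothing, so the shuffled-profile null of the
flexibility correlation is broad: its |PCC| averages ≈ 0.26 over seeds
with individual values up to ~0.55. The coupled condition (PCC > 0.6,
typically 0.8+) separates cleanly from this null on average, but a
single shuffled replicate is not strong evidence either way — real
assessments aggregate over targets for the same reason.

## Numerical choices and degenerate inputs

* Nearest-voxel ties break toward the lower index; footprints are
  sorted unique linear indices — score evaluation order is fixed.
* Kabsch refuses fewer than 3 points or collinear references; exactly
  identical fragment coordinate sets short-circuit to the identity so
  self-ΔSMOC is exactly 0.
* The low-pass filter's raised-cosine edge spans `edge_width` (default
  0.1) of the cutoff frequency below it; `edge_width = 0` gives the
  hard cutoff, which is an exact projection (used where tests need
  exact idempotence). The DC term is always preserved exactly.
* FSC shells with zero power are missing, never 0; the DC shell of
  same-mean maps is 1 by construction.
* `occupancy` outside [0, 1] is clamped with a warning; duplicate
  residue keys with conflicting residue names are an error, never a
  silent overwrite.
* All tolerances asserted in the test suite (1e-12 against brute-force
  oracles, 1e-6 for self-fit and pose-invariance, 10% for stochastic
  closed forms) are stated in the tests themselves.

## Problem sizes used by the reproduction script

`scripts/acceptance.R` uses 30-residue helices for the fit-score
checks, 200 Kabsch trials, 200 ensemble draws for the RMSF closed
form, one 64³ uniform-pattern recovery, 20 two-domain seeds and 20
shuffled-profile seeds — sizes at which every quantity is stable enough
to be meaningful while the whole script finishes in about two minutes
on one CPU.
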