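# cryofit

Residue-level assessment of atomic models against cryo-EM density maps,
for structural biologists comparing predicted (or refined) structures
with experimental reconstructions and their unfiltered half-maps.

Cryo-EM maps rarely have one resolution: flexible regions blur, rigid
cores sharpen. A model that looks globally accurate can still place a
loop or a sidechain outside the density, and — conversely — an ensemble
of predictions can disagree exactly where the map is fuzzy. `cryofit`
quantifies both directions of this comparison on a common per-residue
currency:

* **SMOC** — the Segment-based Manders' Overlap Coefficient. For a
  sliding window of residues (11 by default), the overlap

  `MOC(a, b) = Σᵢ aᵢbᵢ / √(Σᵢ aᵢ² · Σᵢ bᵢ²)`

  between the experimental density `a` and a model-simulated density `b`
  (Gaussian atom kernels, σ = 0.356 × resolution, amplitude ∝ Z) is
  evaluated over the voxels within 2.5 Å of the window's atoms and
  assigned to the central residue.

* **ΔSMOC** — the fragment-aligned difference score. Each prediction
  window is least-squares superposed (Kabsch, matched backbone atoms)
  onto the corresponding target residues before scoring, so global pose
  error cancels; `ΔSMOC = SMOC(fragment) − SMOC(target residues)`.
  Positive values mean the prediction explains the local density better
  than the deposited model. A 5-residue variant scores the central
  residue's backbone and sidechain atoms separately for high-resolution
  maps, restricted via `exclude_by_locres()` to residues resolved better
  than 2.5 Å.

* **Local resolution** — per-voxel FSC-at-0.5 between unfiltered
  half-maps inside a soft spherical window, projected onto the model by
  nearest voxel per atom (`local_resolution()`, `project_locres()`,
  `mean_local_resolution()`).

* **Ensemble flexibility** — per-residue RMSF of a 5-model prediction
  set (models 2–5 aligned onto model 1), gated by accuracy (lDDT > 0.7,
  TM-score > 0.8, interface similarity > 0.8 for multimers, all strict)
  and correlated with local resolution (`rmsf_locres_report()`); plus
  the absolute-Pearson correlation of per-residue accuracy estimates
  (pLDDT-style B-factor column) with local resolution (`extract_lae()`,
  `lae_locres_pcc()`).

A synthetic-data module (`make_polymer()`, `make_ensemble()`,
`make_halfmaps()`, `make_local_error()`, `synth_bundle()`) generates toy
structures, perturbed ensembles and noisy half-map pairs with known
ground truth, so the whole pipeline runs and is tested without any
external data.

Results are tibbles (`residue_track`s, gate tables, correlation tables)
that pipe straight into dplyr/ggplot2; `autoplot()`, `tidy()` and
`glance()` methods are provided.

## Worked example

```r
library(cryofit)

# A 60-residue toy with a flexibility gradient; the half-maps' local
# resolution pattern is generated from that same gradient.
b      <- synth_bundle(60, pattern = "linear_gradient", seed = 42)
locres <- local_resolution(b$half1, b$half2)

mean_local_resolution(b$target, locres)
#> [1] 5.11

rmsf_locres_report(b$ensemble, b$target, locres, gate = FALSE)
#> # A tibble: 1 × 6
#>   group           n_models passed_gate n_residues   pcc note
#> 1 synthetic-group        5 TRUE                60 0.858 ""
```

The mean local resolution (5.11 Å) is the all-atom average of the
projected per-voxel estimates, and the Pearson correlation of 0.86
between per-residue RMSF and local resolution recovers the coupling the
generator imposed: the ensemble spreads exactly where the map blurs.

```r
# Corrupt a loop of the "deposited" model and ask ΔSMOC where the
# pristine prediction fits the map better.
bad  <- make_local_error(b$target, 28:32, "loop_shift", amplitude = 4, seed = 7)
emap <- simulate_density(b$target, sim_params(4, 1))
d    <- delta_smoc(b$target, bad, emap, window = 11, sim = sim_params(4, 1))
dplyr::arrange(tidy(d), dplyr::desc(value))
#> # A tibble: 60 × 4
#>   chain  resi icode  value
#> 1 A        31 ""    0.0374
#> 2 A        30 ""    0.0330
#> 3 A        29 ""    0.0308
#> 4 A        32 ""    0.0266
```

The largest positive ΔSMOC values sit exactly on the corrupted residues
28–32: the prediction's fragments, aligned onto the flawed target,
explain the density better there, and only there.

```r
gate_group(make_ensemble(b$target, 0.2, seed = 1), b$target) |> glance()
#> # A tibble: 1 × 6
#>   group  n_models lddt_min_of_models tm_min_of_models ips_min_of_models passed
#> 1 synth…        5              0.970            0.981                NA TRUE
```

A shell entry point mirrors the R surface
(`exec/cryofit <subcommand> --flag value ...` with subcommands `synth`,
`locres`, `smoc`, `delta-smoc`, `rmsf`, `gate`, `flexcorr`, `laecorr`),
writing TSV reports with a `#`-prefixed metadata header.

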