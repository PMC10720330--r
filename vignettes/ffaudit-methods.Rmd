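---
title: "ffaudit: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ffaudit: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffaudit)
```

`ffaudit` decomposes the prediction error of a force field on a molecular
trajectory dataset along three axes — time (frames), configurational space
(clusters) and system composition (atoms, elements) — so that a single
overall error number becomes a map of where and why a model fails. This
vignette records the models and conventions behind each analysis, the
tunable parameters with their defaults and rationale, what the synthetic
data generator does and does not emulate, and the numerical decisions made
where the design was genuinely open.

## Data model and units

A `configuration_set` is a labelled trajectory with a fixed atom list:
per-frame positions (Å), optional per-frame total energies (kcal/mol) and
per-atom force vectors (kcal/(mol·Å)). These are the package's canonical
units; converters belong at the I/O boundary (`read_npz_bundle()` accepts
multiplicative `energy_factor`/`force_factor` entries in its `key_map`).
Topology is constant by construction: every analysis indexes atoms
consistently across frames, so trajectories with varying atom lists are
rejected at load time. All frame, atom and cluster indices are 1-based, as
is idiomatic in R; ranges are inclusive.

The extended-XYZ dialect follows the dominant community convention: a
`Properties=species:S:1:pos:R:3[:forces:R:3][...]` column descriptor and an
`energy=` key (matched case-insensitively) on the comment line. Additional
scalar (`R:1`) per-atom columns — such as the `atom_error` annotation the
package itself writes — are carried through reads and writes, and
unrecognised comment keys are preserved as opaque metadata. Files are
written at full double precision (`%.17g`), so write→read round-trips are
exact. The NPZ-style bundle uses the MD17/MD22 array names (`R`, `z`, `E`,
`F`) by default and is interoperable with `numpy.savez`/`numpy.load`; the
npy/zip container code is part of the package because no installed R
package provides it.

## Error conventions

Two per-atom force-error scalars are exposed, because they serve different
purposes:

* **`component_mae`** (default): `e_{fi} = (|Δx| + |Δy| + |Δz|)/3` for the
  error vector `Δ = F̂_i − F_i` of atom `i` in frame `f`. The mean of
  `e_{fi}` over any selection equals the component-wise MAE of that
  selection, so per-element (or any disjoint) MAEs recombine *exactly* to
  the overall MAE with atom-count weights. This identity is what makes
  per-element error tables internally consistent, and is the reason this
  convention is the default for summary tables.
* **`vector_norm`**: `e_{fi} = ‖Δ‖`. This is the natural single number to
  paint onto an atom in a structure viewer, and is used for per-atom error
  projection (`export_annotated_structure()`) and for the dummy-model mode,
  where the audited quantity is the reference force magnitude itself.

RMSE is always computed from the mean squared component error, so squared
errors pool the same way (`pool_stats()`), and `rmse ≥ mae` holds for every
selection (Jensen). Energy errors are kept signed per molecule (kcal/mol);
consumers take absolute values where appropriate. Relative per-element
errors divide each element's samples by the element's mean reference
force-vector norm over all frames, which removes trivial force-scale
differences between elements before comparing their error levels.

Density plots use a Gaussian KDE on an even grid spanning
`[min − 3h, max + 3h]`. The default bandwidth is Scott's rule in its
`h = sd(x)·n^{-1/5}` form. With that grid padding the trapezoidal integral
of every returned curve is 1 to within 1% (enforced as an invariant);
degenerate all-equal samples are rejected with a pointer to histograms.
Error timelines are smoothed with a centered moving average whose window
truncates at the edges — length-preserving and free of padding artifacts.
The window is a positive integer; even values use `floor(w/2)` neighbours
per side. Published trajectory-audit figures smooth over windows of order
thousands of frames; the default here is 25, scaled to the shorter
trajectories of the examples, and is a flag everywhere.

Outlier flags on predicted-vs-true pairs use a robust rule,
`|residual| > k · MAD` (MAD scaled by 1.4826; default `k = 4`). Visual
inspection is how outliers are found in interactive use; the fixed rule is
this package's reproducible, headless stand-in, and `k` is exposed.

## Two-stage clustering

Configurational space is partitioned in two stages:

1. **Structural**: agglomerative clustering (Ward linkage, Euclidean
   metric) on the per-frame descriptor of all `N(N−1)/2` pairwise
   interatomic distances — rigid-motion invariant, no atom reordering —
   into `n_structural` groups (default 10).
2. **Energetic**: each structural group is split by k-means on its
   reference energies. Group budgets are proportional to group size with
   largest-remainder rounding and a minimum of one, summing to `n_total`
   (default 40). Budgets are capped by the number of distinct energies in
   a group, and k-means uses deterministic initial centers spread over the
   group's distinct energy values, which avoids empty-cluster failures and
   makes the stage reproducible independent of the seed.

The 40-cluster default is the empirically practical compromise for
medium-size flexible molecules — large enough that clusters are
qualitatively distinct, small enough that each remains well represented;
audits in the literature use totals in the 40–50 range, and both knobs
(`n_total`, `n_structural`) are parameters. How a fixed total should split
between the two stages is not prescribed anywhere; proportional allocation
was chosen so that structurally dominant regions also receive the most
energetic resolution. K-means operates on reference energies (not energy
errors): the partition describes the dataset, not any one model, which is
also why several models audited together share a single clustering and get
directly comparable profiles.

Agglomerative clustering is quadratic in frames; above `max_exact` frames
(default 5000) stage 1 runs on a seeded uniform subsample and the remaining
frames join their nearest structural centroid. Inverse-distance descriptors
are available (`inverse_distances = TRUE`) but off by default. Per-cluster
profiles are sorted ascending by error with ties broken by cluster id;
representatives are the frames nearest the cluster's descriptor centroid,
ties broken by frame index.

## Geometry

The radius of gyration is mass-weighted by default,
`R_g = sqrt(Σ m_i‖r_i − r_cm‖² / Σ m_i)` with standard atomic weights; the
unit-weight variant is exposed because published gyradius traces do not
always state the convention. Internal coordinates (distance, angle,
dihedral) use the IUPAC dihedral sign convention; collinear triples make a
dihedral undefined and raise an error rather than returning a silent 0.

## The synthetic generator

`generate_trajectory()` produces harmonic-basin trajectories: `n_basins`
random reference geometries separated by at least `basin_scale` (mean
per-atom displacement), visited in contiguous blocks, with isotropic
Gaussian jitter of `thermal_scale` per frame. The reference energy is the
exact quadratic `E = E_0(basin) + k/2 Σ‖r_i − c_i‖²` and the forces are its
analytic gradient `F = −k (r − c)`, verified by finite differences in the
test suite via `fixture_energy()`. With `fold_cycle` set, the reference
geometry breathes with a cosine compactness factor (amplitude 0.3), so the
gyradius oscillates and "folded" frames form a distinct error regime.
`generate_predictions()` adds, per force component, a constant bias plus
Gaussian noise of scale `element_scale[element] × basin_factor[basin] ×
atom_factor[atom]`, and Gaussian energy noise. The half-normal expectation
`E|N(0,σ)| = σ√(2/π)` links every planted scale to its expected MAE, which
is how the tests verify recovery in closed form.

The two ready-made suites fix the study conditions used throughout the
examples and tests: `stachyose_like` (C24H42O21, 87 atoms, 500 frames, 3
basins, `basin_scale` 3 Å, `thermal_scale` 0.15 Å, element scales H 0.15 /
C 0.40 / O 0.30 kcal/(mol·Å), ten designated "bond" atoms at 1.5×) and
`dha_like` (C22H32O2, 56 atoms, fold cycle of a third of the trajectory,
folded-frame errors at 2×, element scales H 0.10 / C 0.30 / O 0.35).
Spring constant `k = 50` kcal/(mol·Å²) gives force magnitudes of a few
kcal/(mol·Å), the scale of ab initio benchmark trajectories.

What the generator deliberately does **not** emulate: anharmonicity,
realistic vibrational spectra, temporal correlation of the jitter (frames
are independent draws), bonded topology, or error correlation across
components and neighbouring atoms that real MLFF residuals show. Passing
tests therefore demonstrate that the *bookkeeping* — conventions,
identities, recovery of planted structure — is correct, not that any real
force field behaves like the fixtures.

## Numerical and degenerate-input decisions

* Empty selections in aggregation are errors, never silent zeros.
* Writing an empty frame subset produces a zero-frame file with a warning.
* Requesting more clusters than distinct frames degrades to one cluster per
  distinct frame with a warning; a one-frame dataset short-circuits to a
  single cluster.
* Identity predictions give exactly zero errors (and zero flagged
  outliers, since the robust scale collapses to 0 and the flag is a strict
  inequality).
* The prediction cache (`precompute_cache()`) is fingerprinted by dataset
  name, frame and atom counts and predictor identifier; a mismatch is a
  stale-cache error, never silent reuse. Batching is exactly
  result-invariant because predictions are deterministic per frame.
* JSON reports are written with full numeric precision and a
  `schema_version` field; reports are byte-identical under a fixed seed.

## Problem sizes

The test suite runs trajectories of 30–500 frames on molecules of 4–87
atoms (about 15 s total), and the acceptance script audits the 500-frame
stachyose-like fixture (about 5 s). These sizes keep planted-parameter
recovery inside its statistical tolerances (per-element scale ratios within
5% need a few hundred frames) while staying fast; all analyses scale to
trajectories of 10^4–10^5 frames, with stage-1 clustering switching to its
subsample path beyond `max_exact` frames.

## Known limitations

* No periodic-cell support beyond carrying a lattice line verbatim through
  extended-XYZ metadata; no MD-engine binary formats (DCD/XTC) and no `.db`
  datasets — loaders are pluggable so these can be added.
* No model training, no uncertainty estimation, and no bundled MLFF
  back-ends: external models integrate through the `predictor()` adapter or
  prestored prediction files.
* Statistical significance of error differences between selections is out
  of scope; the package reports effect sizes, not p-values.
* The interactive 3-D visualisation of the workflow this package automates
  is replaced by annotated-structure export for external viewers.
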