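# ffaudit

Error auditing for machine-learning force fields (MLFFs), in R.

Modern MLFFs routinely reach sub-kcal/mol average accuracy on benchmark
trajectories, yet a single overall MAE hides exactly the information a
practitioner needs: *where* in configurational space and *on which atoms* a
model fails. `ffaudit` is a headless auditing toolkit for molecular
trajectory datasets with reference energies and forces (extended XYZ or
MD17/MD22-style NPZ bundles) paired with frame-aligned model predictions.
It is aimed at MLFF developers and users who want to go beyond the headline
error number before trusting a model in molecular dynamics.

## What it computes

For reference forces `F` and predictions `F̂` on `n` frames of an `N`-atom
molecule (canonical units Å, kcal/mol, kcal/(mol·Å)):

- **Error tables** — per-frame per-atom force-error scalars under two
  conventions: the component MAE `⟨|F̂_iα − F_iα|⟩_α` (mean over the three
  Cartesian components; averages of this quantity over any atom selection
  reproduce the selection's MAE exactly) and the error-vector norm
  `‖F̂_i − F_i‖` (used for per-atom error projection onto structures);
  signed per-frame energy errors `Ê − E`.
- **Summaries** — MAE and RMSE over arbitrary frame subsets and atom
  selections (e.g. "only atoms touching a glycosidic bond"), with exact
  count-weighted pooling: per-element MAEs recombine to the overall MAE,
  and pooled MSEs to the overall RMSE.
- **Per-element error densities** — Gaussian kernel-density estimates of the
  per-atom error samples split by chemical element, plus force-scale
  normalised *relative* errors (each element's errors divided by its mean
  reference force-vector norm).
- **Error timelines** — centered moving-average smoothed per-frame force MAE
  and energy error along the trajectory.
- **Configurational-space cluster errors** — two-stage clustering
  (agglomerative/Ward on pairwise interatomic distance descriptors, then
  k-means on reference energies inside each structural group; 40 clusters by
  default) with ascending per-cluster error profiles and representative
  frames.
- **Outlier detection** — predicted-vs-true correlation pairs with robust
  flags (`|residual| > k·MAD`, `k = 4` by default).
- **Geometry** — radius of gyration (mass-weighted or not), distances,
  angles, dihedrals, for correlating errors with folding state.
- **Training-set representativeness** — histogram intersection and
  two-sample Kolmogorov–Smirnov statistics between full-set and subset
  distributions of forces, energies and gyradius.
- **Dummy-model mode** — audit the reference data itself: the "error"
  becomes the reference force norm / energy.
- **Annotated structures** — per-atom mean errors exported as an extra
  extended-XYZ column or a PDB B-factor, for colouring in standard viewers.

A synthetic-trajectory module (`fixture_spec()`, `generate_trajectory()`,
`generate_predictions()`, `fixture_suite()`) generates harmonic-basin
trajectories and pseudo-predictions with planted error structure
(per-element scales, per-basin factors, fold-correlated errors), so the
whole pipeline is testable without external data.

## Worked example

Audit a synthetic 500-frame stachyose-like trajectory (C24H42O21, 87 atoms)
whose prediction stream has planted per-element error scales (H 0.15,
C 0.40, O 0.30 kcal/(mol·Å)) and a 1.5× factor on ten designated
"bond" atoms:

```r
library(ffaudit)

fx  <- fixture_suite("stachyose_like", n_frames = 500, seed = 0)
tab <- compute_error_table(fx$dataset, fx$predictions)

element_summary(tab)
#> # A tibble: 3 × 4
#>   label     n   mae  rmse
#>   <chr> <int> <dbl> <dbl>
#> 1 C     12000 0.362 0.465
#> 2 H     21000 0.120 0.150
#> 3 O     10500 0.263 0.334

pool_stats(element_summary(tab))   # recombines exactly to the overall error
#> # A tibble: 1 × 4
#>   label      n   mae  rmse
#>   <chr>  <int> <dbl> <dbl>
#> 1 pooled 43500 0.221 0.312
```

The per-element MAEs sit at the planted half-normal expectations
(`σ·√(2/π)`: 0.120, 0.36, 0.26 for H/C/O with the basin and bond factors
folded in), and their atom-count-weighted mean *is* the overall force MAE
(0.221) — the same pooling identity that makes published per-element error
tables internally consistent. Filtering to the planted "bond" atoms
recovers their elevated errors:

```r
bond <- atom_selection(fx$truth$bond_atoms, label = "bond atoms")
error_summary(tab, atoms = bond, label = "bond atoms")
#> # A tibble: 1 × 4
#>   label          n   mae  rmse
#>   <chr>      <int> <dbl> <dbl>
#> 1 bond atoms  5000 0.436 0.555
```

Two-stage clustering splits the trajectory's configurational space and
profiles each cluster's error (ascending):

```r
asg <- cluster_configurations(fx$dataset, tab, seed = 1)
glance(asg)
#> # A tibble: 1 × 4
#>   n_frames n_structural n_clusters force_mae_spread
#>      <int>        <int>      <int>            <dbl>
#> 1      500           10         40             1.06

cluster_error_profile(asg)   # tibble (cluster, size, value), ascending
```

`run_audit(audit_config(...))` drives the whole pipeline and writes CSV
tables, PNG figures, annotated structures and a `report.json` with a file
manifest; `tidy()`/`glance()` give broom-style views of the result. The
same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/ffaudit fixture --name dha_like --out fix/
Rscript inst/cli/ffaudit audit --dataset fix/dataset.extxyz \
    --predictions fix/predictions.extxyz --out audit_out/ --seed 1
```

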