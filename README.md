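# islet3d

Whole-organ 3D morphometry of pancreatic islets in cleared-tissue imaging.

Mesoscopic 3D imaging of optically cleared pancreas — optical projection
tomography (OPT, ~21 µm isotropic voxels) for whole tissue discs and light
sheet fluorescence microscopy (LSFM, ~1.9 × 1.9 × 5 µm) for regions of
interest — can measure *every* insulin-positive (INS⁺) object in a volume
instead of extrapolating from 2D sections. `islet3d` is the analysis side
of that workflow, for imaging scientists and islet biologists who have
reconstructed multi-channel volumes (INS, GCG, autofluorescence) and want
reproducible, scriptable quantification:

* **Segmentation** — Gaussian blur, white top-hat background subtraction
  (ball diameter = the "largest object" scale), strict thresholding into
  26-connected 3D components, and the **two-pass surfacing method**: a
  primary threshold captures high-intensity objects, a secondary threshold
  adds low-intensity objects, and second-pass objects overlapping the
  first segmentation by ≥ 10 µm³ are excluded as duplicates, so
  depth-dimmed islets are recovered without double counting. Objects
  outside the autofluorescence-defined tissue mask are dropped.
* **Morphometry** — per-object volume *V*, centre of mass, axis extents,
  equivalent-sphere diameter `(6V/π)^(1/3)`, mean 3D diameter (average of
  X/Y/Z extents), and sphericity `Ψ = π^(1/3)(6V)^(2/3)/A` with the
  surface area *A* from a smoothed marching-tetrahedra iso-surface.
* **Composition** — islet-border objects as the closed union of INS⁺ and
  GCG⁺ masks; glucagon fraction `f = V_GCG/(V_INS + V_GCG)`; classes
  INS⁺GCG⁻ / INS⁺GCG⁺ / INS⁻GCG⁺ under the **< 1% negativity rule**;
  noise (3 × 10³ µm³) and single-cell (< 1.4 × 10⁴ µm³, a ~29 µm sphere)
  filters; composition spectra per glucagon-fraction and size bin.
* **Spatial statistics** — S/M/L size categories each holding one third of
  the total β-cell volume; fixed geometric size-bin histograms normalised
  to tissue volume; mean distance to the 5 nearest neighbours within and
  between categories (k-d tree, centroid-to-centroid, verified against
  brute force); head-to-tail regional assignment along the organ axis.
* **Per-disc statistics** — INS⁺ density with vessel/duct *lumens excluded
  from tissue volume* (walls included); ROUT robust outlier removal at
  Q = 1%; Shapiro–Wilk-gated paired t / Wilcoxon testing with the printed
  star convention; deterministic JSON + CSV report bundles.
* **Synthetic phantoms** — because donor volumes cannot ship with a
  package, `phantom_config()` / `sample_islet_catalog()` /
  `render_volume()` generate OPT- or LSFM-dialect volumes with a complete
  ground-truth catalog: log-normal islet sizes (median 65 µm, GSD 1.6,
  30–300 µm), ~50% glucagon-negative islets concentrated below the
  800 × 10³ µm³ pivot, core-to-rim staining gradients, depth dimming,
  vessel lumens and noise. Every analysis stage is tested against this
  ground truth.

Everything is data-frame-first: measurement tables are tibbles, results
chain with the pipe, fitted objects have `tidy()`/`glance()` methods, and
result tables have `autoplot()` methods.

## Worked example

Simulate one LSFM-dialect region of interest and run the full pipeline
(the phantom background is flat, so background subtraction is switched
off; the two thresholds and all filters are the analysis defaults):

```r
library(islet3d)

cfg <- pipeline_config(
  phantom = phantom_config("LSFM", grid_shape = c(160, 384, 384),
                           n_islets = 40, seed = 42),
  segmentation = segmentation_params("LSFM", background_structure_um = Inf))
res <- run_pipeline(cfg)

nrow(res$islets)                                  # 40  (40 planted)
100 * res$report$pooled$ins_density               # 7.36  (% of tissue is INS+)
100 * mean(res$islets$comp_class == "INS+GCG-")   # 55.0  (planted: 55.0)

dplyr::select(res$islets, id, volume_um3, eq_diameter_um, sphericity,
              f_gcg, comp_class, size_category) |> head(4)
#>      id volume_um3 eq_diameter_um sphericity  f_gcg comp_class size_category
#> 1     1    955585.          122.       0.961 0.377  INS+GCG+   S
#> 2     2   1074950.          127.       0.980 0.0866 INS+GCG+   M
#> 3     3   1390229.          138.       0.953 0.257  INS+GCG+   M
#> 4     4    329033.           85.7      0.985 0      INS+GCG-   S

knn_summary(knn_distances(res$islets, k = 5, by = NULL))
#>   from_category to_category     n mean_um sem_um
#> 1 All           All            40    177.   3.90
```

Reading the output: all 40 planted islets are recovered as single
objects; the pooled insulin density is the INS⁺ volume over the
lumen-excluded tissue volume; per-islet rows carry the full morphometry
(volumes in µm³, diameters in µm, sphericity dimensionless in (0, 1]),
the glucagon volume fraction `f_gcg` and its class under the 1% rule, and
the thirds-of-volume size category; the mean centroid distance to the 5
nearest neighbouring islets is 177 µm in this ROI. The recovered
INS⁺GCG⁻ share (55.0%) matches the planted catalog exactly.

Useful diameter correspondences (what `eq_sphere_diameter()` computes):
400 × 10³ µm³ ↔ 91.4 µm, 12,800 × 10³ µm³ ↔ 290.2 µm, and the
800 × 10³ µm³ composition pivot ↔ 115.2 µm.

A thin CLI wraps the same functions:

```sh
exec/islet3d simulate --out phantom/ --dialect OPT --seed 1
exec/islet3d run      --out report/  --dialect OPT --seed 1
```

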