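---
title: "Whole-organ 3D islet morphometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-organ 3D islet morphometry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis problem

Mesoscopic 3D imaging of optically cleared pancreas — optical projection
tomography (OPT, isotropic voxels around 21 µm) for whole tissue discs, and
light sheet fluorescence microscopy (LSFM, around 1.9 × 1.9 × 5 µm) for
regions of interest — makes it possible to measure every insulin-positive
(INS⁺) object in a tissue volume rather than extrapolating from 2D
sections. `islet3d` implements the downstream analysis as a tested
pipeline: segmentation of hormone-labelled objects in reconstructed
volumes, per-islet morphometry, endocrine composition classification,
spatial statistics, and per-disc reporting. Because donor imaging data
cannot ship with a package, a synthetic phantom generator with a complete
ground-truth catalog stands in for real volumes, so every stage is
verifiable end to end.

## The phantom: what it emulates and what it does not

`phantom_config()` plants ellipsoidal islets in a box-shaped tissue mask:

* **Size law.** Equivalent diameters are log-normal (median 65 µm,
  geometric SD 1.6), truncated to 30–300 µm. Whole-organ measurements of
  the islet size distribution are right-skewed with a mean diameter near
  65 µm once small objects are included; a log-normal on diameter is the
  simplest law with those properties. The truncation keeps every planted
  object resolvable at the coarse OPT voxel size while spanning the range
  (roughly 91–290 µm equivalent diameter) that carries most of the
  beta-cell volume.
* **Shape.** Volume-preserving random semi-axis factors in
  `axis_ratio_range` (default 1–1.6) with a uniform random orientation, so
  sphericity is below 1 as in real islets.
* **Composition.** Each islet is glucagon-negative (GCG fraction < 1%)
  with probability `gcg_neg_fraction_small` below a volume pivot
  (800 × 10³ µm³, about a 115 µm sphere) and `gcg_neg_fraction_large`
  above it. The defaults (0.55 / 0.10) were chosen so that, combined with
  the size law (P(V > pivot) ≈ 0.11), the expected overall negative
  fraction is 50% and negativity concentrates among smaller islets —
  the regime reported for human tissue. Mixed islets draw their glucagon
  volume fraction from a Beta(2, 12) truncated to [0.01, 0.99], putting
  most glucagon into islets with 1–30% GCG. Alpha cells are rendered as
  10–15 µm spheres placed uniformly inside the islet (human islets are
  non-mantled); a `"mantle"` placement mode exists but is off by default.
* **Intensity model.** Insulin intensity follows a linear core-to-rim ramp
  `I(r) = peak · (floor + (1 − floor) · r/R)` — the simplest profile that
  defeats a single global threshold — and, optionally, a per-islet dimming
  with slab depth (`intensity_depth_factor`) emulating limited antibody
  penetration: deep objects become uniformly dim. The anatomy channel is a
  constant autofluorescence level inside the tissue box, zero outside and
  inside vessel lumens (interior capsule tubes), plus Gaussian noise on
  all channels.
* **Not modelled.** No optical physics: no projection or tomographic
  reconstruction artifacts, no point spread function, no light-sheet
  z-elongation, no intensity inhomogeneity along the light path, and no
  organ-shaped tissue mask. Passing tests therefore demonstrate that the
  *analysis* is correct on data with the assumed statistical structure,
  not that segmentation thresholds transfer to any particular scanner.

All randomness flows from one integer seed; the same configuration and
seed reproduce the volume and catalog bit for bit. Placement is rejection
sampling with a conservative bounding-sphere overlap test; an overcrowded
configuration fails loudly with the achieved count rather than degrading.

## Segmentation

`preprocess_channel()` applies a Gaussian blur (sigma in physical units,
converted per axis to voxels) and background subtraction implemented as a
white top-hat with a ball structuring element whose *diameter* is
`background_structure_um` (OPT default 158 µm, LSFM default 10 µm). The
top-hat interpretation — structures larger than this scale are background —
mirrors the semantics of the commercial software's "background
subtraction (largest object)" control; the exact proprietary algorithm is
not published, so this reading is declared rather than certain, and an
element larger than the volume degenerates to the identity.

`threshold_objects()` uses a strict `>` cut-off (default 5), 26-connected
components (diagonal contact merges, matching commercial surfacing;
configurable to 6 or 18), and a physical minimum-volume filter (one voxel
for OPT; 3 × 10³ µm³ for LSFM, where it removes noise specks).

`two_pass_segment()` corrects for the staining gradient across a slab:
pass 1 at the primary threshold captures high-intensity objects; pass 2 at
the secondary threshold (default half the primary) captures low-intensity
objects; any pass-2 object overlapping the pass-1 segmentation by at least
`overlap_exclusion_min_um3` (10 µm³) is discarded as a duplicate, and the
masks are merged. Two consequences are worth stating plainly. First, at
the OPT voxel size one voxel is 9,261 µm³, so *any* non-empty intersection
triggers exclusion; at the LSFM voxel size the 10 µm³ rule needs at least
one shared voxel. Second, the method adds objects that pass 1 missed
entirely — it cannot repair an object that pass 1 captured partially,
because the complete pass-2 version of such an object is excluded as a
duplicate. With the default thresholds this situation does not arise (an
islet whose rim exceeds 5 has its dim core above 5 as well); the
acceptance fixture for the two-pass method therefore uses the depth
gradient, where deep islets fall entirely below the primary threshold and
are recovered whole from pass 2.

Thresholds are explicit configuration with fixed defaults rather than the
interactive per-volume tuning used with commercial software:
reproducibility is preferred over per-disc optimality, and the phantom's
known intensity model makes fixed thresholds exact.

`exclude_outside_tissue()` automates the manual removal of artifacts
outside the tissue: the tissue mask is the largest connected component of
`AF > threshold`, morphologically closed so vessel lumens become internal;
objects whose centroid falls outside are dropped (an object centred in a
lumen is retained).

## Morphometry

Volumes are voxel counts times the physical voxel volume; centroids are
unweighted centres of mass; "diameters in X, Y and Z" are read as
axis-aligned bounding extents (the export convention of the surfacing
software), and the mean 3D diameter is their arithmetic mean. The
equivalent-sphere diameter `(6V/π)^(1/3)` maps volumes onto the diameters
used by 2D stereology: 400 × 10³ µm³ ↔ ~91 µm, 12,800 × 10³ µm³ ↔
~290 µm, and the 800 × 10³ µm³ composition pivot ↔ ~115 µm.

Surface area comes from a marching-tetrahedra iso-surface of the binary
mask at the 0.5 level after one Gaussian smoothing pass (sigma one voxel):
raw voxel face counting overestimates area by ~50% and would bias
sphericity `Ψ = π^(1/3)(6V)^(2/3)/A` far below its true value. Two
numerical details: (i) Ψ is computed from the mesh's own enclosed volume
(divergence theorem over the oriented triangles) rather than the voxel
count, so numerator and denominator describe the same smoothed surface —
otherwise few-voxel objects produce Ψ ≫ 1; (ii) if smoothing dissolves a
tiny object below the iso level, the unsmoothed binary mesh is used for
that object. A 20-voxel digital sphere yields Ψ ≈ 0.99 and a 2:1 prolate
ellipsoid Ψ ≈ 0.93, matching the closed form.

Tissue shrinkage (~5% linear between fixed and cleared tissue) can be
compensated by multiplying lengths by `(1 + s)` — 65 µm becomes 68.25 µm —
but the correction is off by default and all reported values are
uncorrected; `shrinkage_correct()` makes the convention explicit (the
alternative `1/(1 − s)` convention would give 68.4 µm; the multiplicative
form is used because it reproduces the reported corrected diameter).

## Composition

Islet-border objects are connected components of the union of the INS⁺
and GCG⁺ masks after closing at the border-smoothing scale (3.78 µm, the
surfacing grain of the high-resolution dialect); the closing glues hormone
domains separated by less than that scale but reported volumes are counted
on the original masks. The glucagon fraction uses the merged islet as
denominator, `f = V_GCG / (V_INS + V_GCG)`, and the three classes are
INS⁺GCG⁻ (`f` below the 1% negativity threshold), INS⁻GCG⁺ (insulin
fraction below it) and INS⁺GCG⁺ otherwise. Whether the published rule was
applied to voxel or mesh volumes is not stated; voxel volumes are used
here. Two volume filters apply: a 3 × 10³ µm³ noise floor at segmentation
and a strict `< 1.4 × 10⁴ µm³` single-cell exclusion (a ~29 µm sphere) at
classification, with a removal ledger attached to the output. Fraction
bins for the composition spectrum default to edges 0, 0.01, 0.1, 0.2,
0.3, 1 — covering the named ranges of interest — and are configurable
because exact published bin edges are not printed.

## Spatial statistics

The thirds partition sorts islets by ascending volume and cuts the
cumulative volume at total/3 and 2·total/3; an islet straddling a boundary
goes to the lower category (a deterministic tie-break), so each category's
volume is within one islet's volume of an exact third. Fixed-bin
histograms use factor-2 geometric volume bins spanning 25 × 10³ to
25,600 × 10³ µm³ (open-ended top) — published figures do not print their
exact edges, so the edges are configuration.

k-NN statistics use centroid-to-centroid Euclidean distances in physical
micrometres via an exact k-d tree (verified against an O(n²) brute-force
oracle to 10⁻⁹): for each islet, the mean distance to its five nearest
neighbours of the same category, of each other category (directional:
A→B ≠ B→A; both are reported), and of all islets. Groups with at most k
members yield NA with a warning rather than a silently biased mean. On
uniformly placed catalogs the within-category means order L > M > S,
because fewer large islets imply larger spacing.

Regions 1–4 emulate the head-to-tail division: the organ axis is the
first principal component of the tissue-mask voxel coordinates (or an
explicit axis — required for the phantom's near-isotropic box, where PCA
is ambiguous and the code refuses to guess); region 1 covers
`head_boundary_fraction` (default 0.30) of the axis length, standing in
for the anatomical vein landmark that no algorithm can extract from
synthetic data, and the remainder is split into three equal lengths.

## Per-disc statistics and reporting

Disc density divides total INS⁺ volume by the tissue volume, where tissue
is the autofluorescent mask: vessel and duct walls count, lumens (empty
space) do not. Lumens are found as the morphological-closing difference —
cavities filled by closing that do not touch the outside; open boundary
notches count as outside, not lumen.

`rout_outliers()` is the constant-location reduction of the robust
regression and outlier removal procedure, as published for nonlinear
regression: median centre, robust scale from the 68.27th percentile of
absolute residuals with an `n/(n − 1)` small-sample correction, t-like
statistics, and a step-down FDR test at rate Q (default 1%) from the most
extreme point inward, capped at 30% of the sample. A zero robust scale
(all values equal) removes nothing, as does Q = 0.

`paired_compare()` reproduces the published test-selection rule: a
Shapiro–Wilk test per column at 0.05 gates between the paired t-test and
the Wilcoxon matched-pairs signed-rank test, with the printed star
convention. Identical inputs return p = 1 under either branch (the
degenerate all-zero-differences case is handled explicitly). "SDE" in
exported summaries is interpreted as the standard error of the mean.

`build_report()` / `write_report()` emit a schema-versioned JSON plus CSV
bundle containing every table and the fully resolved configuration with
seeds; identical inputs produce byte-identical bundles (no timestamps),
which the acceptance suite verifies by hashing two independent runs.

## Problem sizes and tolerances

The test and acceptance runs use desk-scale volumes chosen as the package's
own verification conditions: a 128³-voxel OPT disc with 80 well-separated
islets (50–250 µm) for exact count recovery (total volume within the 15%
voxelisation bound at 21 µm; 2–3% at 2 µm); four LSFM regions of interest
of 448 × 448 × 160 voxels with 125 islets each — 500 in total, mirroring
the multi-ROI design of donor studies — for composition recovery within
the exact binomial 95% CI of the configured 50%; and a 96³ pipeline run
for byte-level determinism. Recovery runs are noise-free with smoothing
and background subtraction disabled and the noise floor at zero: those
steps exist to suppress noise and background, and on noise-free phantoms
they would only blur the ground-truth comparison (the LSFM noise filter,
for instance, would legitimately delete isolated single alpha cells
planted by the generator). Full preprocessing is exercised by the default
end-to-end pipeline run and its own tests.

## Known limitations

* The two-pass method cannot complete partially captured objects (see
  above); this mirrors the described procedure rather than improving on it.
* Sub-voxel alpha cells at the OPT scale rasterise sparsely, so OPT-dialect
  glucagon fractions are qualitative; composition claims are validated at
  the LSFM scale, as in the source workflow.
* The phantom's tissue mask is a box; regional statistics on real organs
  should supply the anatomical axis explicitly.
* ROUT is specified for nonlinear regression; the constant-location
  reduction used here matches its practical use on column data but is not
  a re-implementation of the proprietary software.
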