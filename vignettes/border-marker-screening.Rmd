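---
title: "Screening for cortical area markers by random-forest border classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for cortical area markers by random-forest border classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortexscreen)
```

## The model

`cortexscreen` asks, gene by gene, whether expression changes abruptly at
the border of a cortical area. The screen never compares two areas
directly; it compares each area against its immediate surround, because a
gene that marks a border need not be expressed uniquely anywhere else in
cortex.

The pipeline rests on one geometric assumption: cortical columns — and
therefore area borders — descend into the tissue perpendicular to the
tangent plane at the pial surface. Under that assumption, collapsing a 3D
expression volume along surface normals (a maximum-intensity surface
projection) preserves borders, and a 2D classifier is as informative as a
3D one at a fraction of the cost. Areas whose borders do not run
perpendicular to the surface violate the assumption and can blur in
projection; this is a known limitation, not corrected here.

The classifier is deliberately a random forest rather than a per-border
statistical test. Real ISH volumes contain whole missing sections (zero
luminance) and strong per-section multiplicative banding, both independent
of true expression. Rather than inpainting or normalizing these artifacts
away, the forest *learns the variance*: zero and rescaled pixels are fed
in as-is, and ensemble voting absorbs them. The same property makes the
Gini variable importance usable as a ranking: all predictors are luminance
values on the identical scale and data type, so importance rank is not
biased by scale differences between predictors.

## Stages and the parameters that matter

**Masking.** A voxel is cortical iff its annotation label is the cortex
root of the structure tree or one of its descendants
(`cortex_mask()`); per-area 3D masks follow the same descendant rule
(`area_mask()`). Expression outside the mask is zeroed exactly
(`mask_volume()`), so subcortical fluorescence cannot leak into the
projection.

**Surface mapping** (`build_surface_mapping()`). The pial surface is the
set of mask voxels adjacent (6-connectivity) to the *exterior* background
component — the component of the mask complement reachable from the grid
corner. This distinguishes the pial surface from the white-matter side,
which borders the enclosed subcortical cavity. The inward normal at each
surface voxel is the central-difference gradient of the Euclidean distance
transform to the mask exterior: parameter-free and robust to voxelization.
Paths take unit steps along the fixed normal with nearest-voxel sampling
until they exit the mask. Two pixel assignments are provided:

* *top*: pixel = the surface voxel's (AP, ML) coordinates; where several
  surface voxels project to one pixel, the shallowest (most dorsal) wins.
  This occlusion rule mimics a view from above and is implementation-defined:
  lateral and ventral cortex is underrepresented or hidden, which is
  precisely why the flat map exists.
* *flatmap*: row = coronal section index; column = signed arc length along
  the section's pial contour, measured from the dorsal midline and rounded
  to pixels. The unfurling is per-section, invertible, and preserves the
  AP coordinate, so dimension reduction stays parallel to columns.

Pixels with no path carry an `NA` sentinel, deliberately distinct from a
measured 0: zero luminance means missing data, `NA` means "not cortex".

**Projection** (`project_volume()`, `project_area_mask()`). Each valid
pixel is the maximum luminance along its path. Area masks are projected
through the *same* mapping by their surface voxel (with a
majority-of-path fallback available where surface voxels are unlabeled),
which guarantees that a noiseless expression step at a radial border and
the projected mask border coincide pixel for pixel.

**Border classification** (`dilate_mask()`, `build_pixel_dataset()`,
`split_train_test()`, `train_forest()`, `evaluate_forest()`,
`importance_table()`). Defaults, all configurable:

| parameter | default | why |
|---|---|---|
| dilation iterations | 30 | ~30 px of surround in each direction defines the "outside" class without letting distant cortex dilute the border signal |
| trees | 100 | stable importance ranking at modest cost |
| forest random state | 0 | reproducibility of the reference configuration |
| held-out test pixels | 100 | small against any screenable area (≥1000 px), so training loses almost nothing |
| mtry | ⌊√G⌋ | standard classification default for the forest's per-node feature subsample |
| bootstrap | on | standard bagging |
| minimum area size | 1000 px | areas smaller than this yield too few pixels for a meaningful split and are excluded, identically for top and flat-map runs |

The dilated ring is intersected with the valid cortical footprint once,
after the iterations. Everything inside the ring that is valid cortex and
not the area — including pixels of *other* areas — is the negative class.
The train/test split is pixelwise random and unstratified; with spatially
smooth expression this inflates accuracy relative to spatially blocked
validation, which is documented here rather than corrected, since the
accuracy is a sanity check and not the screen's output.

Importance of gene g: every split on g contributes
`(n_node / n_tree_samples) * (gini_parent - weighted child ginis)`;
contributions are summed per tree, averaged over trees, and normalized so
all genes sum to exactly 1. Ranks break ties by the stable gene order of
the input list. A forest that never splits (all-constant features) returns
an all-zero table with a warning rather than dividing by zero.

**Screen orchestration** (`run_screen()`). Per area: size filter, ring,
dataset, split, forest, confusion matrix, importance, top-k report. Two
scored flags replace what would otherwise be a manual inspection of the
top candidates, each with an operational definition:

* *hemisphere asymmetry*: contrast = mean(inside) − mean(ring), computed
  separately left and right of the mapping's dorsal midline column; score
  = |Δcontrast| / max(|contrast|). 0 for mirrored expression, 1 for a
  step present in one hemisphere only; flagged above 0.5. Areas that do
  not straddle the midline get `applicable = FALSE` rather than a score.
* *gradient*: R² of a least-squares plane fit to within-area luminance
  over pixel coordinates. 0 for constant or step-at-border expression
  inside the area, 1 for a pure ramp; flagged above 0.5.

Both thresholds (0.5) were chosen a priori as the midpoint of each
score's range, such that planted one-hemisphere markers and planted pure
gradients are flagged while clean symmetric markers are not; they are
configuration, not truth. Flags only annotate: the candidate list is
identical whatever the thresholds, and accept/reject stays with the user.

## The synthetic world

The generator (`synthetic_spec()`, `generate_study()`) emulates exactly
the data properties the screen must tolerate, on a geometry simple enough
to admit closed-form oracles:

* a cylindrical cortical shell — an annulus in every coronal section,
  extruded along AP — embedded in a subcortical disc. A full ring (rather
  than a half shell) is used so that the mask complement separates into
  exterior and enclosed cavity, making the pial surface identifiable from
  the binary mask alone; the ventral half doubles as an occlusion test for
  the top view. Default lattice 80 x 30 x 60 voxels (AP x DV x ML), inner
  radius 8, thickness 6, nominal 200 µm voxels (metadata only);
* areas as contiguous angular x AP sectors, so borders are radial —
  perpendicular to the surface tangent, satisfying the projection
  assumption by construction and guaranteeing zero overlap of projected
  neighbors;
* gene classes: `border_marker` (step `inside_level` → `outside_level` at
  the target area's border, optionally restricted to one hemisphere),
  `gradient` (linear ramp along AP/DV/ML), `uniform`, `noise_only`;
* noise pipeline, in order: additive Gaussian voxel noise → one
  multiplicative banding factor per coronal section, uniform on
  `banding_factor_range` → whole sections zeroed with
  `missing_band_probability` → clipping to [0, 1].

Reference conditions used by the recovery tests: step 0.9 → 0.1, noise sd
0.05, banding factors U[0.5, 1.5], 10% missing sections, 50 genes with
one planted marker per area. The magnitudes of noise are not pinned down
by any measurement — real ISH variability is unquantified — so they are
chosen once as a regime that visibly corrupts projections (3-fold banding,
visible dark bands) while leaving the biology decodable; recovery is then
*swept over seeds* (20) rather than asserted at a single lucky draw.

What a green recovery test establishes: the pipeline finds planted abrupt
borders under section-level artifacts at these magnitudes. What it does
not establish: performance on real cortical anatomy (no curvature
gradients along AP, no layer structure, no inter-gene correlation, no
registration error), nor any claim about specific genes.

## Numerical conventions

* Determinism: every stochastic step takes an explicit seed. The study
  seed fans out into per-gene seeds; the split seed and the forest's
  random state (default 0) are separate, since they control different
  draws. Identical seeds give bitwise-identical volumes and identical
  forests.
* Tree construction: candidate features are examined in ascending index
  order; a split must strictly improve the best decrease, so ties go to
  the lowest gene index and then the lowest threshold (midpoint between
  distinct consecutive values; `x <= threshold` goes left). Trees grow to
  purity. These conventions are mirrored by an independently written
  brute-force oracle in the test suite, and single exhaustive trees match
  it to 1e-9.
* Degenerate inputs: empty masks, single-class training sets, oversized
  test sets, unknown structure ids and lattice mismatches raise immediate
  errors with the offending quantity named; an area missing from a volume
  yields an all-zero mask with a warning (it is valid for an atlas to
  annotate structures absent from a section range).
* The flat-map column quantization can map two contour voxels of one
  section to the same column; the voxel whose arc length is closest to
  the integer grid wins.

## Design choices that were genuinely open

* The unfurling algorithm and the top-view occlusion rule are not forced
  by anything upstream; the per-section arc-length map and the
  shallowest-voxel rule were chosen for invertibility and simplicity and
  are documented as implementation-defined.
* The "surrounding region" includes pixels of other cortical areas inside
  the ring. The alternative (cortex-not-in-any-area only) would starve
  the negative class at interior borders.
* Manual candidate inspection is replaced by scored flags because a
  reusable pipeline needs an operational criterion; the flags annotate
  rather than filter precisely because the original judgment was human.
* File formats: NRRD for volumes and projections (with a JSON sidecar),
  CSV/JSON for trees, ground truth and reports. These are plain,
  line-oriented or well-specified formats readable outside R.

## Limitations

* Accuracy is optimistic under spatial autocorrelation (unblocked split);
  use it comparatively, not absolutely.
* Importance concentrates on whichever of several correlated informative
  genes the trees prefer; in small geometries with few areas, markers of
  *neighboring* areas and well-aligned gradients legitimately share
  importance with the area's own marker.
* The synthetic shell has no laminar structure, so laminar markers
  (which the projection's max would happily pick up) are untested.
* Only two hemispheres-by-convention exist (left/right of the dorsal
  midline); true mirrored anatomy is emulated only through the
  `hemisphere` restriction of planted markers.
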