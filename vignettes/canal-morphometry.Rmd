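---
title: "Trans-cortical canal morphometry: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trans-cortical canal morphometry: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and numerical choices behind
`canalmorph`, the way its good exemplars in the Bioconductor image-analysis
tier document theirs: what is being estimated, under what assumptions, which
tunables matter, and what the synthetic validation does and does not
establish about real data.

## The measurement problem

In a growing long bone, resorption on one cortical surface paired with
formation on the opposite surface ("trans-pairing") shifts the cortex
through tissue space. Cortices undergoing the endosteal-forming variant
carry numerous *trans-cortical canals* — channels 10–30 µm wide running
from the periosteum through the full wall thickness to the marrow cavity —
while the oppositely-polarized cortex carries fewer and narrower ones.
The quantities of interest per specimen are therefore: the number of
canals, their diameters, their *circumferential location* expressed as a
polar angle about the shaft axis, the anterior/posterior split of that
distribution, and canal density per endosteal surface area. Group contrasts
(left control limb vs right denervated limb; one cortex type vs the other)
use the paired t-test and the Mann–Whitney U test respectively.

## Coordinate conventions

Volumes are stored as `values[y, x, z]` with z the proximodistal slice
index and physical coordinates in micrometres from the voxel-(1,1,1)
centre. The **anatomical anterior is fixed as `+x`** and positive angles
turn towards `+y`. The anatomical literature defines these directions
pictorially; fixing them to grid axes makes every angle in the package
reproducible, and a specimen scanned in another pose can be registered to
this convention (or `anterior_direction` adjusted) before quantification.

The shaft axis is *not* assumed to be the grid axis: the reference z-axis
is the line through the centres of gravity of the marrow cavity in the
first and last slices. The polar angle of a canal is measured from the
point on that *line* at the canal's own z-level — not from the per-slice
marrow centroid, which is retained only as a diagnostic. A canal is
**posterior** when |θ| > 90° strictly; the boundary itself counts as
anterior.

## Segmentation model

* **Bone** is `intensity ≥ t`. The automatic `t` minimizes the intra-class
  intensity variance over a 256-bin histogram spanning the observed range,
  which makes it exactly invariant to adding a constant to all voxels.
  Scanner grey levels are arbitrary; the paired bone/background mixture is
  what the criterion models. The threshold used is always logged.
* **Cortex region** = morphological closing of the bone mask with a
  Euclidean ball, computed by two distance transforms, so the radius is
  free. Two geometric constraints govern the radius `closing_radius_um`
  (default 35 µm): it must exceed the radius of the widest void to be
  captured, and it must stay below the smallest radius of curvature of the
  endosteal surface (for an elliptic cavity with semi-axes a > b, that is
  b²/a) — a ball that cannot roll inside the cavity closes part of it.
  Border handling models a diaphysis segment cut perpendicular to its axis:
  the z faces continue the specimen, the lateral faces are air.
* **Marrow** is the largest 6-connected component of the complement of the
  closed region that does not touch a lateral face. The complement of raw
  bone would leak through the canals to the exterior — this is exactly what
  trans-cortical means — hence the closed region is used. Equal-size
  candidate cavities raise an error rather than an arbitrary choice.
* **Voids** are 26-connected components of `cortex \ bone \ marrow`
  (26-connectivity merges diagonal voxel chains, matching the visual
  continuity of canals; bone itself is treated 6-connected). Two
  digitization artefacts of the closing are suppressed explicitly, because
  they otherwise corrupt counts: (i) sub-voxel *slivers* of the cavity
  retained along the endosteal surface can chain distinct canal mouths into
  one component — candidate void voxels simultaneously face-adjacent to
  bone and to a free surface are ascribed to the surface; (ii) detached
  mouth *films* (void components living entirely within two voxels of a
  free surface) are discarded — a real pore at this resolution has deeper
  interior voxels. Surface-contact flags are evaluated within a two-voxel
  neighbourhood so a trimmed canal mouth still registers its contact.
* **Classification**: volume ≤ `lacuna_max_volume_um3` (default 2000 µm³, a
  generous osteocyte-lacuna bound) → lacuna; else trans-cortical with
  diameter ≥ `foramen_min_diameter_um` (default 50 µm, inclusive) →
  nutrient foramen; else trans-cortical → canal; else partial. Only canals
  enter downstream statistics; the foramen is thereby excluded, which in
  the source workflow was a manual step. Both cutoffs are configuration
  values because no community-standard numbers exist.

## Canal diameter

The reported diameter is the **minor axis of the best-fitting ellipse of
the canal-perpendicular cross-section**. The tube axis comes from the
eigenvectors of the second central moments of the component's voxel
coordinates; *all* component voxels are projected onto the plane through
the centroid perpendicular to that axis. For a straight tube this
projection *is* the cross-section, and using every voxel rather than a thin
slab suppresses voxelization noise: a half-voxel slab of a 20 µm canal
holds only ~70 voxels and its moment minor axis scatters by up to a voxel,
while the full projection recovers carved diameters to within half a voxel.
The ellipse is moment-matched (semi-axes are twice the coordinate standard
deviations along the planar principal directions, with the voxel cell
variance v²/12 added) rather than boundary-fitted, for robustness on small
sections. For stubby trans-cortical voids — the nutrient foramen is wider
than the wall is thick — the largest-variance eigenvector is a diameter,
not the tube axis, so the pipeline passes the outward radial direction as
an *axis hint* and the eigenvector most aligned with it is used.
Components under 4 voxels (or degenerate projections) fall back to the
equivalent-circle diameter of their largest single-slice section and are
flagged. Whether diameters should be measured on z-slices or
canal-perpendicular sections is ambiguous in the field; canal-perpendicular
is chosen (and recorded in the output metadata) because it is invariant to
canal inclination.

## Density

`canal_density()` divides the canal count in an angular sector by the
**endosteal** surface area of that sector, computed per slice as the polar
arc length of the marrow boundary (sub-voxel, by interpolated ray casting
from the axis) integrated over the sector and multiplied by the slice
thickness. The endosteal surface is the natural normalizer here because
canals are read off the endocortical panorama. The raw radius profile
carries half-voxel digitization steps; it is smoothed with a short circular
moving average (≈6° window) before differentiation, without which the
finite-difference arc length is inflated by several percent. On noise-free
elliptic phantoms the sector area is within ~0.5% of the analytic value.

## Panoramic unwrapping

Two modes produce the cylindrical panorama of the endocortical surface.
The **stitch** mode reproduces the rotate/crop/stitch workflow: the bone is
rendered from the marrow axis at successive rotation steps (default 20°,
hence 18 views per revolution), each view cropped to its central fraction
(default ¼) and the crops stitched in angle order. The **resample** mode
casts one ray per (θ, z) sample and records the radius and intensity of
first bone contact with sub-voxel refinement; its horizontal axis is
exactly linear in θ, which makes it the quantitative twin (depth maps,
perimeters). Rays are cylindrical — perpendicular to the z-axis — rather
than perspective; the original renderer's projection is unknown, and the
cylindrical choice makes the mapping analytic and hence testable. Rays that
exit the grid without bone contact (canal mouths) become flagged gap
pixels, not errors. An option reproduces the "duplicated anterior regions"
presentation by wrapping 90° of padding onto both ends; it is off by
default.

## Statistics

`mann_whitney_u()` uses midranks; the two-sided p-value is exact by full
enumeration of rank assignments when the combined sample size is ≤ 12 with
no ties (924 arrangements at 6+6 — sub-second), otherwise the normal
approximation with tie-corrected variance and continuity correction; the
method used is recorded. `paired_t_test()` is the closed-form paired t with
the (n−1)-denominator standard deviation. Two-sided p-values throughout; no
multiple-testing correction is applied (none is in the motivating
workflow). The polar histogram default bin is 15° (the original binning is
unstated; 24 bins resolve the anterior/posterior halves cleanly), with
right-closed bins over (−180°, 180°].

## The phantom: what it emulates, what it does not

`generate_phantom()` rasterizes an elliptic-cylindrical shell (optionally
drifting laterally slice to slice), carves straight cylindrical canals
specified by (θ, z, diameter, inclination), ellipsoidal lacunae
rejection-sampled to stay clear of surfaces and of each other, and an
optional wide foramen; it then applies Gaussian partial-volume blur
(default half a voxel — nothing is published about the scanners' intensity
formation, so a minimal smoothing model is used) and additive Gaussian
noise. Carving is masking — a voxel is void if any structure covers it —
so structure order cannot matter, and a seed is mandatory: equal seeds give
bit-identical volumes. Specifications whose structures merge into one
component are rejected outright, because their ground truth would be
ambiguous.

Default geometry is a scaled-down fibula diaphysis: shell semi-axes
130 × 105 µm (outer) and 75 × 60 µm (inner), canal diameters 15–26 µm,
lacunae 8 × 5 × 5 µm, at 1.27 µm/voxel by default (the nano-CT sampling) —
tests and validation use 2 µm voxels on ~170³ grids to keep a twenty-phantom
recovery study around a minute. The phantom does **not** model canal
tortuosity, branching, surface roughness, beam hardening, rings, or
phase-contrast fringes. Passing the validation therefore establishes that
the *geometry pipeline is correct*, not that segmentation is robust to
every real-world artefact; on real scans the threshold, closing radius and
classification cutoffs remain the user's responsibility to sanity-check
against the images.

## Validation design

The test suite validates each stage against independent oracles: exhaustive
search for the automatic threshold; brute-force flood fill for connected
components; analytic cylinders for diameters; the planar arctangent for
orientations; analytic ellipse arcs for areas and depth maps; enumeration,
`wilcox.test`/`t.test` and numeric integration for the statistics; and
dense nearest-point sampling for the thickness operator. End-to-end, twenty
random noise-free phantoms must be recovered with exact canal counts,
diameters within one voxel, orientations within 2°, and posterior fractions
exactly equal to truth; a four-pair control-vs-denervated design with truth
posterior fractions near 8% and 35% must be recovered exactly and rejected
at α = 0.05 by the paired t-test. Rotating a phantom 90° about the z-axis
must shift every recovered θ by 90°, and reinterpreting the same grid at
twice the voxel size must double every diameter exactly.

One geometric caveat is worth recording: the thickness operator measures
along the inner contour's outward normal (paired-edge semantics), while a
nearest-point distance is necessarily ≤ the normal distance. On the strongly
modulated sinusoidal fixture (thickness 5 + 2 sin 2θ µm on a 10 µm circle)
the two differ by ~2.7%; the operator recovers the generating profile's
mean (5 µm) to within 1%, and the nearest-point oracle is checked as a
lower bound within 5%.

## Known limitations

* Canals are counted per connected component; a branched network reaching
  both surfaces counts once. Whether the original counts were per component
  or per surface opening is unknowable from the source material.
* Components touching exactly one surface are reported as `partial` but not
  counted; with heavy noise a true canal whose mouth is occluded by a few
  misclassified voxels would be demoted to partial. Noise-robustness beyond
  the default blur/noise model is untested territory.
* The marrow axis uses only the two end slices (by definition); a strongly
  bowed shaft would make per-slice reference points preferable, and the
  per-slice centroids are exported so users can check the straight-axis
  assumption.
* The closing radius ceiling (endosteal curvature) and floor (foramen
  radius) can conflict for very thin-walled bones with large foramina; in
  that regime the foramen will be missed by the region and simply not
  counted, which is detectable in the `partial`/component diagnostics.
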