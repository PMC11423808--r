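# canalmorph

Quantitative 3D morphometry of **trans-cortical canals** in long-bone
cortices from micro-CT / nano-CT image stacks, with a synthetic phantom
generator for end-to-end validation.

During bone growth, paired resorption and formation on opposite cortical
surfaces ("trans-pairing") moves the cortex through space, and the cortices
undergoing endosteal-forming trans-pairing are riddled with canals that run
from the periosteum clear through to the marrow cavity. Quantifying those
canals — how many, how wide, and **where around the shaft circumference they
sit** — is the readout this package automates for bone biologists working
with high-resolution CT of rodent long bones (the design case is the
developing mouse fibula, scanned at 1.27 µm/voxel).

## What it computes

Given a 3D grayscale volume of a diaphysis:

1. **Segmentation** — bone by thresholding (automatic minimal intra-class
   variance, or fixed); the cortical wall as the morphological closing of the
   bone mask (distance-transform based, so large structuring balls are
   cheap); the marrow cavity; and the intracortical void components
   (26-connected), each classified as *canal* (trans-cortical, i.e. touching
   both surfaces), *osteocyte lacuna* (volume ≤ 2000 µm³), *nutrient foramen*
   (trans-cortical with diameter ≥ 50 µm, excluded from canal statistics), or
   *partial*.
2. **Per-canal geometry** — the marrow z-axis is the line through the
   centers of gravity of the marrow cavity in the first and last slices.
   Each canal gets
   - a **diameter**: the minor axis of the best-fitting (moment-matched)
     ellipse of its tube-perpendicular cross-section, in µm;
   - an **orientation** θ ∈ (−180°, 180°]: the signed angle, at the canal's
     own z-level, between the anterior direction and the view of the canal's
     center of gravity from the marrow axis. Canals with |θ| > 90° lie in
     the **posterior half**;
   - a **density**: canals per mm² of endosteal surface in an angular
     sector.
3. **Panoramic unwrapping** — the endocortical surface rendered as a
   cylindrical panorama, either by the rotate/crop/stitch procedure (20°
   steps → 18 views per revolution, each cropped to its central quarter) or
   by direct (θ, z) ray-cast resampling; canal mouths appear as dark gaps.
4. **Statistics** — polar histograms with anterior/posterior percentages,
   Mann–Whitney U (exact by enumeration for combined n ≤ 12 without ties,
   tie-corrected normal approximation otherwise) and the paired t-test.
5. **Periosteal thickness** (2D) — inter-edge distance between an inner and
   outer contour along the inner contour's outward normals, with angular
   exclusion arcs (e.g. the interosseous membrane).

Because raw CT volumes of this kind are rarely shareable, the package ships
a **phantom generator** (`phantom_spec()` / `generate_phantom()`): a hollow
elliptic-cylindrical cortical shell with straight trans-cortical canals at
prescribed polar angles and diameters, ellipsoidal lacunae, an optional
nutrient foramen, partial-volume blur and Gaussian noise — plus a
ground-truth ledger, so every pipeline stage can be validated against known
geometry.

## Worked example

```r
library(canalmorph)

spec <- random_phantom_spec(seed = 42, n_canals = 10, n_posterior = 3,
                            lacuna_count = 25,
                            foramen = c(theta_deg = -140, z_frac = 0.5,
                                        diameter_um = 60))
ph <- generate_phantom(spec)       # 170 x 170 x 110 voxels at 2 um
q  <- quantify_volume(ph$volume, run_config())
print(q)
#> <canal_quantification> threshold 50.59; components: canal=10, foramen=1, lacuna=25
#>   posterior fraction: 3/10 = 30.0%

print(q$polar)
#> <polar_summary> n = 10; anterior 7 (70.0%), posterior 3 (30.0%)

canals <- q$records[q$records$class == "canal", ]
head(canals[order(canals$theta_deg),
            c("z_um", "diameter_um", "theta_deg", "is_posterior")], 4)
#>      z_um diameter_um theta_deg is_posterior
#> 27 168.10       17.23   -153.63         TRUE
#> 24 162.59       24.32   -104.31         TRUE
#> 12  82.07       20.14    -57.57        FALSE
#> 25 161.29       21.11    -51.17        FALSE

canal_density(q$records, c(-90, 90), marrow = q$marrow, axis = q$axis,
              label = "anterior")
#> <density_result:anterior> 7 canals / 0.04690 mm^2 = 149.25 per mm^2
```

All 10 carved canals (and none of the 25 lacunae, and not the foramen) are
counted; the recovered posterior fraction (3/10) equals the ground truth
exactly, diameters land within half a voxel of the carved values, and
orientations within 0.1°.

A thin command-line wrapper is installed with the package
(`system.file("scripts", "canalmorph", package = "canalmorph")`), with
subcommands `simulate`, `quantify`, `thickness` and `stats`.

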