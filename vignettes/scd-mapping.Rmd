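---
title: "Grid-based subchondral cortical distance mapping: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-based subchondral cortical distance mapping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

Injuries of the posterolateral corner (PLC) of the knee — the lateral
collateral ligament (LCL), popliteus tendon (PT), and popliteofibular
ligament (PFL) — destabilize the lateral femorotibial compartment. Under a
varus load the lateral joint space opens, and the amount of opening is a
functional surrogate for the extent of ligament damage. On stress MRI this
opening can be quantified as the **subchondral cortical distance (SCD)**:
the vertical distance, parallel to the tibial long axis, between the
femoral and tibial subchondral bone plates. The SCD deliberately spans the
cartilage plus the joint space, which keeps it comparable to radiographic
joint-space measurements and independent of cartilage segmentation.

`scdmap` implements this measurement computationally, starting from
multi-label bone segmentations (femur, medial tibia, lateral tibia) of
coronal MRI: it builds a joint-specific coordinate frame, extracts the
opposing subchondral surfaces as height fields, measures SCDs on a regular
measurement grid over the lateral tibial condyle, converts
loaded-versus-unloaded map pairs into regional opening heat maps, and runs
the repeated-measures statistics of a graded-injury study design. Because
cadaveric stress-MRI volumes are not redistributable, the package also
contains a synthetic phantom generator with analytic ground truth, so the
entire chain is testable without any imaging data.

## Coordinate frame

All measurements are made in a joint-specific Cartesian frame:

* **z (craniocaudal)** — the first principal component of the combined
  tibial voxel cloud (the "tibial bone axis"), oriented cranially. The
  principal-component reading is a convention: nothing finer than "the
  tibial bone axis" is standard, and the PCA axis is deterministic and
  landmark-free. Near-isotropic tibiae (possible for symmetric phantoms)
  yield a warning, not an error, when the two leading eigenvalues are
  within 5% of each other; planar or collinear voxel clouds are an error.
* **x (mediolateral)** — the scanner ML axis orthogonalized against z,
  with +x pointing lateral. Laterality cannot be inferred from a label
  volume, so it is an input flag (`"left"` default); +y is posterior in
  the phantom convention.
* **origin** — the centroid of the lateral tibial condyle's top surface,
  so frame z = 0 sits at the tibial plateau.

The frame transform is rigid; pairwise distances are preserved to
numerical precision, and recovering a deliberately rotated phantom's frame
is part of the test suite (rotations up to 15 degrees, recovered within
1 degree).

The **transepicondylar diameter**, which anchors the lateral exclusion
rule, is measured as the femoral extent along the frame's ML axis over the
distal 40% (by z) of the femur label. The distal restriction keeps the
femoral shaft out of the measurement and needs no landmark detection; the
epicondylar region always lies within the distal portion at knee-MRI
fields of view.

## Surfaces, grid, and SCD

For every (x, y) column over the lateral condyle (columns are binned at
the in-plane voxel spacing, anchored on the tibial footprint so columns
map one-to-one onto voxel columns):

* tibial height `t` = top **face** of the highest lateral-tibia voxel,
* femoral height `f` = bottom **face** of the lowest femur voxel *above
  the tibial surface*.

Using voxel faces rather than centers makes abutting surfaces measure
0 mm. Restricting the femoral minimum to voxels above the tibial maximum
stops the posterior femoral cortex, which can dip below the joint line,
from capturing a column. Columns missing either surface are invalid and
excluded downstream; the "hull" is per-column extremal, not convex — this
matches a vertical-ray reading of the measurement and is the package's
documented convention. Unsegmented coronal slices (interslice gaps are
common in coronal acquisitions) are bridged by linear interpolation along
the AP direction and flagged; interpolated columns reproduce a gap-free
phantom's values to within one z voxel in the tests.

The measurement grid uses regular spacings of **3.5 mm (ML) x 3.3 mm
(AP)**, covering the bounding box of the lateral condyle in the baseline
(intact, unloaded) scan with symmetric margins. The grid is *baseline
referenced*: the same point set is reused for every condition and
configuration of a specimen. Since the frame is anchored on the tibia and
only the femur moves under load, no cross-scan registration is needed —
this is one consistent reading of baseline referencing, and the package
makes it explicit. Grid points in the lateralmost 10% of the
transepicondylar diameter are masked (`"lateral-10%"`) to avoid spurious
measurements over the curved epicondyle; points over invalid columns are
masked `"invalid-column"`. Every mask carries exactly one reason code and
the retained count is reported per run, which makes point-count audits
possible.

Per retained point, the SCD is `f - t`, with both height fields bilinearly
interpolated at the grid position (nearest-column lookup is available as a
sensitivity option). A point whose four surrounding columns are not all
valid is masked rather than extrapolated. `scd_compmean()` is the
arithmetic mean over retained points; the six manual-site analogues put
ml1..ml3 at 25/50/75% of the ML extent (lateral to medial) on the
mid-coronal line and ap1..ap3 at 25/50/75% of the AP extent on the
mid-sagittal line. The anatomical definition of the AP sites uses meniscus
landmarks; with no meniscus segmented, the fractional positions are a
documented proxy. "Dividing the condyle into quarters" is read as sites at
the three interior quarter boundaries.

## Phantoms: what they emulate and what they do not

`generate_flat_plate()` and `generate_wedge()` are oracle geometries: the
per-column gap is constant or linear in x, and an exhaustive voxel scan is
the reference in the tests. `generate_knee_like()` adds a sagittally
curved condylar surface (radius 30 mm by default), an optional
intercondylar notch, optional unsegmented coronal slices, and a tibial
shaft block (without which a plateau slab's principal axis would be
mediolateral, not craniocaudal). Default spacing is 0.5 mm isotropic —
coronal-knee-MRI-like in plane, finer than a typical slice thickness,
which is instead emulated explicitly through the slice-gap pattern.

Varus loading is a **rigid rotation of the femur about a medial hinge
line** before re-voxelization (voxel centers are inverse-rotated and
tested against the continuous unloaded solid, so a zero-angle rotation is
voxel-identical to the unloaded volume). The analytic gap increase at a
column is `d * tan(angle)`, with `d` the in-plane perpendicular distance
from the hinge line; tilting the hinge (its posterior end medially) makes
the opening grow both laterally and posteriorly, emulating the
posterolateral rotatory component of PLC insufficiency. Ground-truth gaps
are defined between *voxelized* surfaces with a one-z-voxel tolerance —
that is what any voxel-based measurement can see.

The phantoms contain no MR signal simulation, no bias fields, no
cartilage or meniscus labels, and no soft-tissue deformation: the bones
are rigid and the measurement is bone-to-bone. Passing phantom tests
therefore validates the geometry and statistics of the chain, not
segmentation quality or tissue contrast on real images.

## The synthetic study design

`study_design()` encodes a 10-specimen x 5-condition x 2-configuration
repeated-measures experiment. Its defaults are the magnitudes of the
cadaveric study the package models: baseline apex gap 7.8 mm,
between-specimen SD 1.0 mm, an intact load effect of 2.1 mm, additional
loaded-configuration opening increments of 0 / 1.3 / 1.7 / 2.2 / 2.6 mm
across the graded conditions, and small unloaded drifts of
0 / 0.2 / 0.3 / 0.4 / 0.9 mm. Unloaded cells carry the drift and loaded
cells the load effect plus increment, so condition-versus-intact
contrasts within each configuration equal the injected vectors exactly.

Two modelling choices deserve emphasis:

* **Loading in `generate_study()` is uniform femoral distraction**, not
  hinge rotation: the loaded gap is simply larger by the injected amount.
  This makes the injected increments exact ground truth for
  compartment-mean contrasts; the hinge model is exercised separately by
  the monotonicity and localization tests. A hinged loading study is
  available by generating volumes directly with `generate_knee_like()`.
* **A per-scan repositioning noise** (`cell_noise_sd_mm`, default
  0.15 mm) is added to every cell beyond the between-specimen SD. Real
  repeated scans are never identical; without a residual term the
  within-specimen contrasts of a simulated study would have (near-)zero
  sampling variance and standard-error-based recovery checks would
  degenerate.

Volumes are generated lazily (a full study is ~100 volumes of ~2M voxels;
`run_study()` streams one at a time) and are bit-identical for identical
design and seed.

## Statistics

* **Reader pooling**: two readers' site measurements are averaged per
  key; the six-site mean (`manmean`) is derived from pooled values. Note
  the printed-rounding gap this creates: the six printed intact-unloaded
  site means average to 7.75 mm while the printed row shows 7.8 — group
  tables rounded to 0.1 mm do not commute with averaging. Contrasts are
  therefore computed from per-specimen values in pipeline mode, while the
  packaged printed-means fixture reproduces the published arithmetic
  exactly as printed.
* **ICC**: inter-reader agreement uses the one-way random-effects,
  single-measures ICC(1,1) — the "single scorings, not adjusted" form —
  with the two-way ICC(2,1) available for comparison. Both are computed
  from ANOVA mean squares; zero-variance input is reported as undefined
  rather than 0/0.
* **RM-ANOVA**: within-subject two-factor ANOVA (condition x
  configuration, interaction included) via the classic univariate
  partitioning with effect-by-specimen error strata. Because the
  sphericity treatment of the original analysis is unknowable,
  uncorrected and Greenhouse-Geisser-corrected p-values are reported side
  by side (epsilon from the subject-by-cell covariance; for two-level
  effects epsilon is 1). Degenerate all-equal input returns F = 0, p = 1
  instead of 0/0. Tukey-adjusted pairwise condition comparisons are
  computed within each configuration via `emmeans`.
* **Contrasts**: group-mean differences versus the intact condition per
  configuration, reported at full precision and at the 0.1 mm precision
  of published tables.

## Numerical conventions and degenerate inputs

* Tolerances are stated in z-voxel units: per-column phantom recovery is
  exact to one z voxel; compartment means recover flat-plate gaps to half
  a voxel (0.25 mm at default spacing).
* Nearest-grid-point matching breaks exact ties toward smaller x, then
  smaller y.
* Grid footprints smaller than one spacing degenerate to a single-point
  grid with a warning; empty measurement domains (no column with both
  surfaces) are errors, as are incomplete crossed designs in the ANOVA
  (missing cells are named).
* Stray segmentation labels are warned about and treated as background;
  a missing femur or lateral tibia is a validation error.

## Problem sizes used in the checks

The packaged validation uses phantoms of 120 x 84 x 200 voxels at 0.5 mm
(the default geometry; unit tests use a 72 x 56 x 150 variant), flat-plate
gaps of 2-20 mm, hinge angles 0-5 degrees, 100 randomized
exclusion-rule configurations, an ICC null simulation of 10^4 pairs, 200
ANOVA power replicates, and one full 10 x 5 x 2 synthetic study for
end-to-end recovery. These sizes keep a complete run in the order of a
minute or two on a single core while leaving every quantity's sampling
error well below the tolerances being asserted.

## Known limitations

* The AP manual sites are fractional proxies, not meniscus landmarks;
  absolute site values on real anatomy would differ from a
  landmark-driven reading.
* Binning columns at the in-plane voxel spacing assumes the joint frame
  is close to the scanner axes (true for phantoms and for re-angulated
  acquisitions); strongly oblique volumes are handled but with
  approximate half-voxel face offsets.
* The retained-point count depends on condyle size relative to the grid
  spacing; phantom counts (~60-80) are in the range reported for human
  lateral condyles, but no claim is made beyond positivity.
* Heat maps are descriptive; no per-point hypothesis testing is done.

## A minimal worked example

```{r example}
library(scdmap)

spec <- phantom_spec(gap_mm = 7.8)
unloaded <- generate_knee_like(spec)
spec$varus_angle_deg <- 2
loaded <- generate_knee_like(spec)

frame <- build_frame(unloaded)
te <- transepicondylar_axis(unloaded, frame)
surf_ul <- extract_surfaces(unloaded, frame)
grid <- apply_lateral_exclusion(build_grid(surf_ul), te)

map_ul <- compute_scd_map(surf_ul, grid,
                          provenance = list(specimen = 1, condition = "intact",
                                            configuration = "UL"))
map_lo <- compute_scd_map(extract_surfaces(loaded, frame), grid,
                          provenance = list(specimen = 1, condition = "intact",
                                            configuration = "LO"))
scd_compmean(map_lo) - scd_compmean(map_ul)   # ~ mean lever arm * tan(2 deg)

dm <- difference_map(map_lo, map_ul)
render_heatmap(dm, "intact_abs_diff.png")
```

A whole synthetic study, including heat maps, ANOVA and contrast tables:

```{r study}
cfg <- run_config(design = study_design(seed = 1),
                  out_dir = "scdmap_demo")
res <- run_study(cfg)
res$contrasts
```
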