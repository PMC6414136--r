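---
title: "Designing and validating 3D-printed bolus caps from CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and validating 3D-printed bolus caps from CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boluscap)
```

## The problem

Total scalp irradiation (TSI) needs a bolus cap: a layer of tissue-equivalent
material, conformal to the scalp, that moves the dose build-up region of a
megavoltage photon beam up to the skin so the scalp surface receives full
dose. Hand-fabricated caps (taped bolus sheets under a swim cap, wax shells,
thermoplastic patchworks) are laborious and leave centimetre-scale air gaps
that degrade surface dose. A patient-specific cap can instead be designed
directly from the planning CT and 3D-printed in a flexible, tissue-equivalent
elastomer.

`boluscap` implements that design step as a standalone, scriptable tool: it
reads a CT, segments the external body contour, builds a uniform-thickness
shell over the scalp, and exports a watertight, print-ready binary STL. It
also implements the quantitative QA used to validate such caps: volumetric
air-gap (conformality) and wall-thickness maps, an HU-to-density calibration
utility for verifying that the treatment planning system will model the
printed material correctly, and planned-versus-measured dose agreement
statistics for TLD-based in-vivo verification.

## The pipeline and its geometry conventions

All physical quantities are millimetres in the DICOM LPS patient frame,
bit-compatible with CT headers and with what printing bureaus consume.
Voxel indices address voxel centers; a mask derived from a CT lives on the
identical lattice, so distance-transform geometry is unambiguous.

The stages of `run_pipeline()` are:

1. **Read** (`read_ct_series()` or `read_volume()`): DICOM CT series
   (implicit/explicit VR little endian) or the package's NIfTI container.
   Slices are sorted by position along the slice normal; HU are recovered via
   the rescale slope/intercept; non-uniform or duplicated slice positions are
   hard errors, because silent gap interpolation would corrupt geometry.
2. **Resample** (`resample_isotropic()`): clinical head protocols are
   anisotropic (typically 3 mm slices over sub-mm pixels); all morphology
   runs at a 1 mm isotropic working resolution. One millimetre keeps
   sub-voxel surface errors below print tolerance while a desk machine
   processes a head volume in seconds; it is a package choice, not a fact of
   the original clinical workflow.
3. **Segment** (`segment_body()`): threshold at -400 HU (standard
   external-contour practice, midway between air and any tissue), keep the
   largest 6-connected component, fill enclosed cavities, and close with a
   2 mm spherical structuring element (computed through the Euclidean
   distance transform, so the ball is spherical in mm even on anisotropic
   grids). A segmentation that touches all six grid faces aborts: the
   threshold is then certainly wrong.
4. **Cap extent** (`make_cap_extent()`): the cap covers the scalp at and
   above one axial plane, the operator's "down to here" decision. An
   optional feather tapers the thickness linearly over a rim band. Free-form
   extents can be supplied as masks.
5. **Shell** (`build_bolus_shell()`): see below.
6. **Mesh + STL** (`mask_to_mesh()`, `write_stl()`): marching tetrahedra at
   level 0.5, binary STL output with recomputed facet normals, no
   timestamps (the same configuration yields byte-identical files).

## The shell: distance to a sub-voxel surface

The cap is defined as

> all voxels outside the body whose Euclidean distance to the body surface
> is at most the nominal thickness t (default 5 mm), clipped to the cap
> extent,

with ties at exactly t included, for determinism. The subtlety is what "the
body surface" is. A binary mask quantizes the skin position to half a voxel,
and a shell criterion based on voxel-center-to-voxel-center distances
inherits that quantization twice: at 1 mm spacing the available distances
near 5 mm are sqrt(25), sqrt(26), sqrt(27) -- steps of ~0.1 mm that move
whole voxel layers (several percent of shell volume) in or out at once.
Worse, any *jagged* surface estimate biases minimum distances one-sidedly:
the minimum is always attained on an outward excursion of the staircase.

`boluscap` therefore represents the body surface explicitly at sub-voxel
accuracy: the body indicator is smoothed with a Gaussian of one voxel
(FWHM about 2.4 voxels, the smallest kernel that actually averages
neighbouring staircase columns), its 0.5 level set is triangulated by
marching tetrahedra, and each candidate voxel center is tested against its
exact closest-point distance to that mesh (a uniform spatial hash over
triangles makes this fast). The center-to-center distance transform is kept
as a cheap pre-filter: only voxels within a guard band of the threshold need
the exact test. On spheres with closed-form shell volumes this construction
places the outer shell surface within ~0.1 mm of the analytic one; the
smoothing shifts a surface of curvature radius R by O(sigma^2/R), under
0.02 mm for heads at 1 mm voxels. The trade-off is deliberate: genuinely
sharp sub-voxel features (which a scalp does not have) would be rounded at
the sigma scale.

The same smoothed-isosurface idea underlies `mask_to_mesh()`. Marching
*tetrahedra* on the Kuhn 6-tetrahedra cell decomposition is used instead of
table-based marching cubes: the Kuhn split triangulates shared cell faces
identically in neighbouring cells, so the extracted surface is watertight by
construction and the ambiguous-case tables of classic marching cubes are not
needed. Every exported mesh must pass the validator (each directed edge used
exactly once, opposite edge present, no degenerate faces, positive enclosed
volume).

## QA metrics

**Air gap** (`air_gap_map()`): for every body-surface voxel inside the cap
extent, the distance to the nearest bolus voxel center minus half a voxel
diagonal (the sampling offset between adjacent voxel centers), floored at
zero. This is a genuine 3D distance, independent of slice orientation --
deliberately stricter than reading gaps off individual CT slices. A shell
built directly on its body reports gaps below one voxel; a cap displaced by
d mm reports a maximum gap of d within half a voxel. The rim is excluded via
the extent because the cap necessarily leaves the skin there.

**Wall thickness** (`thickness_map()`): sampled at the shell's inner surface
(bolus voxels adjacent to the body), as the distance to the nearest voxel
that is neither bolus nor body -- a double distance transform through the
wall. On analytic spherical shells the median agrees with the nominal
thickness to within half a voxel, and doubling t doubles the median.

Both metrics operate on masks; a printed cap re-scanned as an STL can be
assessed by voxelizing it back onto the CT grid (`voxelize_mesh()`, parity
ray casting).

## Calibration and dose statistics

`predict_density()` evaluates the scanner's HU-to-density calibration curve
by piecewise-linear interpolation between knots with linear extrapolation
floored at zero, and `density_percent_error()` scores a predicted density
against the physically measured one (mass over caliper volume), with the
measured value as reference. Clinical curves are scanner-specific and must
be supplied as two-column text; the packaged
`generic_calibration_curve()` is a synthetic, representative table for
examples and tests, not a clinical curve.

`summarize_dose_comparison()` reduces per-location planned (TPS) and
measured (TLD) doses to the absolute percent difference
`100 * |measured - planned| / planned` -- planned dose is the denominator,
matching the direction in which planned-vs-measured agreement is reported --
and summarizes mean, sample (n-1) SD, maximum, and the fraction within a
tolerance (default 5%). With a single record the SD is reported as 0 and
flagged undefined. `summarize_fractions()` handles multi-fraction in-vivo
records: per-fraction summaries are averaged, and the interfraction SD is
the per-location SD across fractions averaged over locations. The packaged
`tld_phantom_table()` fixture carries a 20-location phantom validation
table whose summary (mean 2.4%, SD 1.5%, max 6.3%, 95% within 5%) the test
suite recomputes.

## The synthetic phantom and what passing tests mean

`generate_head_phantom()` voxelizes an analytic head: an ellipsoid of
soft-tissue HU (default semi-axes 75 x 95 x 85 mm, an adult cranium) with a
concentric 6 mm bone shell starting 6 mm below the skin, in -1000 HU air,
plus optional seeded Gaussian noise (HU clipped to [-1024, 3071]) and, for
spheres, optional sinusoidal surface bumps that exercise conformality on a
non-convex scalp. Because the surface is a quadric, surface position, cap
volumes, and shell thickness have closed-form ground truth
(`surface_distance()` answers exact signed distance queries), which is what
lets the test suite assert shell volumes against analytic spherical shells
and air gaps against constructed displacements.

What the phantom does *not* emulate: real scalp texture (hair, ears, skin
folds), streak or beam-hardening artifacts, couch and immobilization
hardware in the field of view, and partial-volume blur of the skin. Passing
the synthetic suite therefore demonstrates the geometry engine is correct,
not that segmentation thresholds are optimal for every clinical scan; the
-400 HU default and the 2 mm closing are standard but should be sanity
checked per protocol.

## Numerical choices and degenerate inputs

* Distances are exact Euclidean (lower-envelope-of-parabolas transform),
  never chamfer approximations; anisotropic spacing is honoured in mm.
* Ties at the shell threshold are included; tie-breaks never depend on
  traversal order.
* Empty segmentations, empty cap extents, thickness below one voxel,
  truncated STL files, non-watertight meshes, inconsistent DICOM series,
  and geometry mismatches between masks are hard errors, not warnings.
* Smoothing a mesh (`smooth_mesh()`, Taubin lambda/mu so volume is
  preserved) clamps every vertex's total displacement to a stated bound
  (default 0.5 mm) instead of erroring after the fact; topology is never
  modified.
* Phantom generation restores the caller's RNG state; pipelines are
  deterministic end-to-end.

## Problem sizes

The test suite exercises spheres of 15-40 mm radius at 1-2 mm spacing for
module tests and one 80 mm sphere at 1 mm (a 191-cube grid, ~7M voxels) for
the end-to-end shell checks; the brute-force oracle comparisons run on grids
of at most 40^3, where all voxel-triangle and voxel-voxel pairs can be
enumerated. These sizes were chosen so the full suite runs on a laptop-class
single core in minutes while still covering the clinical scale (a head at
the 1 mm working resolution) once.

## Known limitations

* The cap extent is a single axial plane (plus feather); truly free-form
  rims must be supplied as masks.
* No deformation model: the printed cap is assumed rigid at QA time, while
  flexible materials seat slightly differently on a real head.
* Multi-thickness or graded boluses and avoidance structures are out of
  scope.
* DICOM support is read-only and limited to uncompressed little-endian
  axial CT series; compressed transfer syntaxes are rejected.
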