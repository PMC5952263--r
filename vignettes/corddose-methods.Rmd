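---
title: "Propagating spinal-cord contours to guidance scans and accumulating delivered dose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Propagating spinal-cord contours to guidance scans and accumulating delivered dose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Head-and-neck radiotherapy on a helical tomotherapy unit delivers 30–35
daily fractions, each preceded by a megavoltage CT (MVCT) guidance scan.
The spinal cord — the dose-limiting organ at risk — is delineated by an
oncologist once, on the kilovoltage planning CT (kVCT). Re-contouring the
cord on every noisy guidance scan by hand is impractical, yet knowing where
the cord actually was at each fraction is exactly what is needed to
accumulate the dose it really received. `corddose` implements the full
chain: deformable registration of each MVCT to the planning kVCT,
propagation of the planning contours through the recovered transform,
slice-wise conformity scoring of the auto-contours, and accumulation of
per-fraction dose to cord voxels with a dose-volume summary (the
near-maximum dose D2%).

All geometry lives in DICOM patient coordinates: +x towards the patient's
left, +y posterior, +z superior, in millimetres; voxel indices are 0-based
with the origin at the centre of voxel (0,0,0). Only axial, axis-aligned
volumes are accepted; oblique acquisitions are rejected rather than
silently resampled.

## Registration model

Registration finds a transform $T(\mathbf{x})$ from fixed-frame (kVCT)
points to moving-frame (MVCT) points such that $I_M(T(\mathbf{x}))$ aligns
with $I_F(\mathbf{x})$. The similarity metric is mutual information of the
joint intensity histogram, which is robust to the different contrast of
kilovoltage and megavoltage imaging. Transform stages — translation, rigid
(Euler angles about the fixed-volume centre), affine, and cubic B-spline
free-form deformation — are optimised in sequence, each stage composed
after the previous stages' result, over a three-level Gaussian image
pyramid (shrink 4/2/1, smoothing 2/1/0 voxels).

Key parameter defaults, all exposed in `registration_config()`:

* `bins = 32` histogram bins per image; intensities clamped to
  [-1024, 3071] HU so the histogram support is bounded.
* `samples = 4096` fixed-mask samples per pyramid level for the
  low-dimensional stages; `bspline_samples = 32768` for the B-spline stage
  (see below).
* `cp_spacing = 15` mm isotropic control-point spacing; the spacing sweep
  helper covers 5–25 mm.
* convergence when the relative metric change stays below `tol = 1e-5`
  over `patience = 10` iterations, with at most 250 iterations per level.

Samples are drawn once per stage and pyramid level from the body mask
(seeded), not re-drawn each iteration: a fixed sample set makes the
backtracking line search well defined and runs bit-reproducible for a
fixed seed. The body mask itself is the largest 26-connected component of
voxels above -400 HU on the kVCT, which separates the patient from the
treatment couch without any couch model.

### Two views of the same metric

The *reported* metric value (`mattes_mutual_information()`) uses hard
binning on both images. This estimator satisfies exact identities that
make it testable — MI of a volume with itself equals the marginal
histogram entropy, a constant image gives exactly zero — and those
identities are asserted against an independent `table()`-based oracle in
the test suite. Hard binning is not differentiable, so the *optimiser*
climbs a Parzen-smoothed variant of the same quantity in which each moving
intensity is spread over four bins with a cubic B-spline window; its
analytic gradient with respect to the B-spline coefficients is implemented
in compiled code and verified against finite differences in the tests.
Moving intensities are trilinearly interpolated and samples mapping
outside the moving volume are discarded, never zero-filled, so background
does not manufacture spurious correlation; a stage aborts if fewer than
10% of samples land inside the moving volume.

### Optimising the B-spline stage

The low-dimensional stages use adaptive-step gradient ascent (step halved
when the metric worsens, grown on success) on central finite differences.
The B-spline stage has thousands of coefficients, and two failure modes
appeared during development that shaped the design:

* plain normalised gradient ascent underconverges — the recovered warp's
  metric value stays visibly below the value at the ground-truth transform
  of a synthetic pair;
* an unregularised quasi-Newton optimiser overshoots — it drives the
  *sampled* metric far above the ground-truth value by bending the warp to
  sharpen the finite-sample joint histogram, while the landmark error
  grows.

The default therefore combines three ingredients: L-BFGS on the analytic
gradient (`bspline_optimizer = "lbfgs"`; `"ascent"` retains the plain
scheme), a large sample set (32768) to shrink histogram noise, and a
bending-energy-style penalty — the mean squared second difference of the
coefficient lattice along each axis, weighted by
`bspline_regularization = 0.15` — subtracted from the metric. The
second-difference form is zero for constant and linearly varying fields,
so smooth anatomical warps are not shrunk; a first-difference (membrane)
penalty was tried and rejected because it visibly attenuated the smooth
component of the true field, worst along z where the 6 mm guidance slices
make the metric gradient weakest. With these defaults the synthetic
benchmark (5 mm peak warp) is recovered with a mean landmark error of
0.65–0.97 mm across fraction realisations.

## Contour propagation

Contour vertices are mapped point-by-point through the transform chain.
Mapped polygons leave their original planes, so each is reassigned to the
nearest target slice plane (within half a slice spacing of its mean mapped
z — polygons mapping beyond the target's slice range are dropped with a
warning) and its vertices are projected onto that plane. When two planning
polygons (3 mm slices) land on one guidance slice (6 mm slices) and
overlap, their union is taken by radial compositing about the common
area-weighted centroid: the boundary radius at each of 64 angles is the
outermost ray crossing of any contributing polygon. This is exact for
star-shaped cross-sections, which cord contours are; genuinely
non-star-shaped unions would be approximated by their outer radial
envelope, a known limitation. Non-overlapping polygons are kept as
separate contours on the plane. Polygons degenerating to fewer than three
distinct vertices or below 1 mm^2 are dropped with a warning; empty target
slices are left empty rather than interpolated.

## Conformity metrics

Five slice-wise metrics compare a test region with a reference region:

* **CI** — the Jaccard ratio of intersection to union area;
* **DBC** — distance between area centroids;
* **DTC** — mean, over rasterised pixels of the symmetric difference, of
  the distance to the nearest pixel of the intersection (0 at identity;
  when the intersection is empty the distance is taken to the other
  region's pixels and the value flagged);
* **left–right and anterior–posterior differences** — signed
  test-minus-reference differences of the axis-aligned extents
  (x = left–right, y = anterior–posterior).

Areas, centroids and extents use exact polygon formulas, with
Sutherland–Hodgman clipping for the intersection when both slices hold a
single convex polygon — the typical cord case. Non-convex or
multi-polygon slices fall back to rasterisation at 0.1 mm pitch, the same
pitch used for all DTC distances; the two backends agree within 1% on
convex shapes and that property is asserted in the tests. The DTC
operationalisation follows the symmetric-difference mean-distance
definition and is isolated in one function so an alternative (separate
over- and under-outlining distances) could be swapped in.

Slices are matched between structure sets by nearest z within half the
smallest slice gap; slices with a contour on only one side are excluded
from the paired metrics and reported separately. Aggregation reports the
median, mean and sample standard deviation per metric, the uncertainty on
the mean as $\mathrm{sd}/\sqrt{n}$, and the uncertainty on the median from
a seeded bootstrap (2000 resamples). The inter-observer helper compares
each observer's contours with every other observer's — all N(N-1)/2
unordered pairs, 15 for six observers — computing symmetric metrics once
per pair and signed metrics in both orientations.

## Delivered dose

Cord voxels are the planning-grid voxels whose in-plane centre falls
inside (or exactly on: closed-region rule) a contour polygon on the
matching slice. For each fraction, every cord voxel centre is mapped by
that fraction's transform — with any recorded post-imaging couch shift
composed after it — and the fraction's dose grid is sampled there by
trilinear interpolation. Samples outside a grid are excluded and drive a
coverage flag; only voxels covered by *every* fraction enter the
summaries, and out-of-grid dose is never zero-filled. D2%, the minimum
dose to the hottest 2% of the organ volume, is computed by the voxel-count
rule — the smallest dose among the ⌈0.02 n⌉ highest-dose voxels, which an
exhaustive sort oracle can verify — with a DVH-interpolated variant behind
`interpolate = TRUE`. The cumulative DVH is tabulated on a 0.1 Gy grid.
Per-fraction dose grids are inputs: the treatment-machine dose engines are
out of scope.

## The synthetic phantom

No patient data ship with the package; every claim is validated on a
synthetic neck phantom with known ground truth. The planning volume uses
the archival kVCT voxel size (2.148 × 2.148 × 3.000 mm) and the guidance
volumes the MVCT voxel size (0.754 × 0.754 × 6.000 mm). The anatomy is an
elliptical soft-tissue body (semi-axes 55 × 45 mm, mildly tapered along
z), an air passage whose radius varies smoothly with z, a vertebral ring
(inner radius 8 mm, outer 14 mm) around a CSF-filled canal and a 4 mm
cord cylinder, and a detached couch slab. Two design points deserve
explanation:

* **The ring's bone/disc alternation along z is a raised cosine (24 mm
  period), not a hard switch.** A square-wave pattern interacting with the
  6 mm guidance slice sampling biased the MI optimum itself by half a
  slice in z; a single-frequency profile passes through the symmetric
  resampling kernels without phase distortion, and with it a known 6 mm
  shift is recovered to 0.02 mm.
* **Soft tissue carries a smooth seeded texture field** (trilinear
  interpolation of a coarse random lattice; 30 HU amplitude, 12 mm
  correlation length). Real tissue is not uniform, and without texture a
  nonrigid warp is unobservable in flat regions of the image.

Planning volumes are produced by block-averaging a 2× finer lattice,
emulating archival down-sampling. Each fraction's ground-truth deformation
is a seeded rigid shift (default mean (3, -2, 4) mm, 1 mm jitter per axis)
plus a smooth random B-spline field at 30 mm knot spacing scaled to a
4 mm peak displacement by default; the guard
`deform_max <= 0.4 * deform_spacing` keeps the field invertible, and the
guidance image is produced by resampling the planning volume through the
numerically inverted deformation, then adding Gaussian noise (default
20 HU; kVCT noise 5 HU). Ground-truth contours are the planning contours
mapped by the exact analytic chain — never rasterised masks — so the
evaluation oracle is independent of the registration pipeline. The
recorded "radiographer couch shift" is the true rigid component plus a
0.5 mm-sd seeded error. The per-fraction dose model is a Gaussian
transverse falloff (peak 1.1 Gy, 20 mm sigma) about the deformed cord
axis, chosen so a 30-fraction course gives cord D2% values near 33 Gy,
typical of cord-sparing head-and-neck plans.

What passing on this phantom does and does not show: it demonstrates that
the implementation recovers known deformations of realistic magnitude
through realistic voxel grids, noise and modality-like contrast
differences, and that every bookkeeping rule (coverage, slice matching,
union handling) is exact. It does not demonstrate performance on real
MVCT artefacts (streaks, beam hardening), real anatomy (swallowing,
weight loss, non-smooth sliding at tissue interfaces) or real
inter-observer contouring variability; conformity values on the phantom
(median CI ≈ 0.97 against ground truth) are accordingly higher than what
auto-contouring achieves against human reference contours on clinical
scans, where the reference itself carries observer variability.

## Problem sizes in the shipped checks

The test suite and the acceptance script run the full pipeline at the
study voxel sizes on a 72 × 72 × 32 planning grid with 176 × 176 × 14
guidance fractions — large enough that every algorithmic path (pyramid,
masking, B-spline support, coverage rules) is exercised at realistic
anisotropy, while a complete affine + B-spline registration takes tens of
seconds. The acceptance run uses three fractions for the end-to-end
delivered-dose computation and one fraction for the strategy comparison
and spacing sweep; these sizes are the package's validation design.

## Known limitations

* The DICOM reader/writer is deliberately minimal: explicit/implicit VR
  little endian, the tag subset needed for CT series, RTSTRUCT and RTDOSE,
  single-ROI structure sets. It is not a conformance-tested DICOM stack.
* NIfTI files are written with an RAS affine (sign-flipped from the
  package's LPS convention) so external viewers orient them correctly,
  but only axis-aligned affines are read back.
* Registration assumes the guidance scan is a deformed, noisier view of
  the planning anatomy; it has no model of content appearing or vanishing
  (dental artefacts, bolus, shoulder position changes).
* The radial-union rule for coplanar polygons is exact only for
  star-shaped regions.
* D2% assumes equal voxel volumes, which holds on a regular grid.
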