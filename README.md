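# corddose

Automatic propagation of spinal-cord contours from planning CT to daily
guidance CT, and accumulation of the dose actually delivered to the cord.

## The problem

Head-and-neck radiotherapy patients on a helical tomotherapy unit receive
30–35 daily fractions, each guided by a megavoltage CT (MVCT) scan. The
spinal cord — the organ whose tolerance dose limits the plan — is contoured
by an oncologist only once, on the kilovoltage planning CT (kVCT). To know
the dose the cord *actually* received, its position is needed on every
guidance scan. `corddose` locates it automatically: each MVCT is registered
to the kVCT by intensity-based deformable registration, the planning
contours are mapped through the recovered transform T(x), the resulting
auto-contours are scored slice by slice against reference contours, and
per-fraction dose grids are summed voxel-wise through the transforms to a
delivered-dose map with dose–volume statistics.

The methodological core:

* **Registration** maximises the mutual information of the joint intensity
  histogram of I_F(x) and I_M(T(x)) — robust to the different contrast of
  kV and MV imaging — over translation, rigid, affine and cubic B-spline
  free-form stages, composed in sequence on a three-level image pyramid.
  Registration samples are confined to a body mask (largest 26-connected
  component above −400 HU) so the treatment couch does not take part. The
  B-spline stage (default control-point spacing 15 mm) is optimised by
  L-BFGS on an analytic gradient with a bending-energy penalty.
* **Conformity** of auto-contour A against reference R per slice:
  conformity index CI = |A∩R|/|A∪R| (Jaccard), distance between centres
  (DBC), distance to conformity (DTC, mean distance of the symmetric
  difference to the intersection), and signed left–right /
  anterior–posterior extent differences; aggregated as median/mean/SD with
  statistical uncertainties (bootstrap for the median).
* **Delivered dose** D_A per cord voxel is the sum over fractions of the
  fraction dose interpolated at the transformed voxel position (couch
  shifts composed after the transform); only the region covered by all
  fractions is summarised. The headline statistic is the near-maximum dose
  **D2%** — the minimum dose to the hottest 2% of the cord volume, computed
  by the ⌈0.02 n⌉ voxel-count rule.

A synthetic neck phantom (`generate_phantom()` / `generate_fraction()`)
with analytic ground-truth deformations, contours and dose grids makes the
whole pipeline testable without patient data. DICOM CT series, RTSTRUCT,
RTDOSE and NIfTI-1 readers/writers are included.

## Worked example

```r
library(corddose)

# plan-side phantom: planning CT, cord contours, body mask
phantom <- generate_phantom(phantom_spec(seed = 1))
mask <- build_body_mask(phantom$kvct)

# one guidance fraction with a known (hidden from the pipeline) deformation
fraction <- generate_fraction(phantom, 1)

# register the guidance scan to the planning scan (affine then B-spline)
chain <- register(phantom$kvct, fraction$mvct, mask,
                  registration_config(seed = 1))
#> transform_chain with 2 stage(s): affine -> bspline

# propagate the planning contours and score them against ground truth
auto <- propagate_contours(phantom$cord, chain, fraction$mvct)
records <- compare_structure_sets(auto, fraction$truth_contours)
aggregate_conformity(records)
#>    metric  n      median        mean          sd     se_mean   se_median
#> 1      ci 14  0.96706930  0.96629975 0.011731369 0.003135340 0.002230687
#> 2     dtc 14  0.10194947  0.10542682 0.008012421 0.002141410 0.001546793
#> 3     dbc 14  0.09662444  0.09836534 0.035116439 0.009385263 0.006187820
#> 4 lr_diff 14  0.01582083  0.00879203 0.049312598 0.013179346 0.009017424
#> 5 ap_diff 14 -0.02284340 -0.02490508 0.030449908 0.008138080 0.013428477

# accumulate the fraction dose to cord voxels through the recovered transform
voxels <- cord_voxels(phantom$cord, phantom$kvct)
dmap <- accumulate_dose(voxels, list(chain), list(fraction$dose))
dvh_summary(dmap)
#> dose_summary: n = 312 voxels, mean 1.090 Gy, max 1.098 Gy, D2% 1.098 Gy
```

Reading the output: on the 14 matched guidance slices the auto-contours
overlap the ground-truth cord with a median Jaccard index of 0.967, their
centroids sit within 0.1 mm of the truth, and the bounding-box dimension
differences are hundredths of a millimetre — the registration has
recovered the synthetic inter-fraction deformation to well under a voxel.
The single-fraction cord D2% of 1.098 Gy reflects the phantom's 1.1 Gy
per-fraction dose model sampled at the recovered cord positions.

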