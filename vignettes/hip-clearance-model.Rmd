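---
title: "Modelling anterior femoroacetabular clearance from bone geometry and motion capture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling anterior femoroacetabular clearance from bone geometry and motion capture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipclear)
```

## The problem

Cam morphology (an aspherical femoral head-neck junction) and pincer
morphology (acetabular over-coverage) can bring the femoral head-neck
contour into abnormal contact with the acetabular rim at deep hip flexion,
adduction and internal rotation. The quantity this package predicts is the
**beta angle**: in an image plane aligned with the femoral neck, the angle at
the femoral head centre between (a) the ray to the most lateral bony margin
of the acetabular rim and (b) the ray to the point where the head contour
first deviates from sphericity. Positive beta means clearance remains
between the head-neck junction and the rim; negative beta means the
aspherical region is already under acetabular coverage — impingement.

The subject-specific model combines three inputs:

1. **bone geometry**: point clouds of the femur and acetabulum segmented
   from supine imaging, in mm;
2. **anatomical landmarks**: left/right anterior and posterior superior
   iliac spines for the pelvis, medial/lateral femoral epicondyles for the
   femur;
3. **motion capture**: labelled marker trajectories with a standing
   calibration frame.

From these it predicts beta for any posture reached during motion, and it
reproduces the validation workflow in which predictions are compared against
direct static measurements of the same posture: the imaged posture is
matched to the motion frame minimising the least-squares error (LSQE) in hip
angles, the bone models are posed at that frame, and the minimum beta over a
stack of parallel planes is reported.

## Coordinate systems and angles

Anatomical frames follow the ISB recommendations. The pelvis frame has Z
along the inter-ASIS line toward the subject's right, X in the plane of the
ASIS and the PSIS midpoint pointing anteriorly, and Y = Z × X pointing
superiorly; its origin is the centre of the sphere fitted to the acetabular
lunate surface. The femur frame has y from the epicondyle midpoint to the
femoral head centre, z perpendicular to y in the plane of the head centre
and epicondyles pointing laterally (medial to lateral epicondyle), and
x = y × z pointing anteriorly; its origin is the head centre. Both triads
are exactly right-handed and orthonormal; "anterior/superior/lateral" are
resolved by dot-product sign checks against landmark-derived directions, not
by assuming any scanner orientation. Note that enforcing right-handedness
fixes the anterior femur axis as x = y × z; a construction that instead
forces x "anterior" by sign-flipping would produce a left-handed triad in
some configurations.

Hip angles use the Grood-Suntay joint coordinate system: e1 is the pelvis Z
(flexion/extension), e2 the femur y (internal/external rotation), e3 their
normalised cross product (ab/adduction, the floating axis). Internally this
is an intrinsic Z-X-Y factorisation of the relative rotation, extracted with
`atan2`-based direction cosines so signs are correct near zero. When the
flexion and rotation axes approach alignment (adduction near ±90°,
|e1·e2| > 0.999) a gimbal flag is attached and a warning raised; the angles
are still returned because the postures of interest (deep squat, seated
flexion-adduction-internal-rotation) keep adduction far from ±90°.

**Left hips.** The package computes left-side angles by mirroring the femur
frame across the pelvis mid-sagittal plane (the plane normal to pelvis Z)
and decomposing as a right hip. This is algebraically identical to negating
the flexion axis and mirroring lateral directions, and it makes the
left/right consistency property exact: mirroring all landmarks and flipping
the side label reproduces the same clinical triple to machine precision.

## The clearance model

Given the posed femur and acetabulum:

1. **Alpha plane.** The measurement plane passes through the femoral head
   centre, contains the neck axis, and has normal `unit(neck × shaft)`. The
   neck and shaft axes must be separated by more than 5°.
2. **Plane stack.** Parallel planes are placed every `spacing` mm (default
   2.5 mm, replicating an imaging stack) on both sides; by default the stack
   spans the fitted head radius (`ceiling(radius / spacing)` planes per
   side). Each plane keeps points within `half_thickness` (default 0.5 mm,
   a closed slab) and projects them into one in-plane basis whose `u` axis
   is the projected neck direction — angles around the projected head centre
   are therefore independent of the world frame.
3. **Asphericity onset.** Femur contour points are marched from deep inside
   the acetabulum toward the neck (decreasing angle). The onset is the first
   point whose radius from the head centre exceeds the slice radius of the
   fitted head sphere plus `tolerance` (default 0.5 mm) *and* that starts a
   run of at least 3 consecutive supra-threshold points; isolated spikes are
   treated as noise, and a contour that stays on-sphere yields a no-onset
   flag rather than a value.
4. **Rim.** The acetabular section is an arc around the head centre; the rim
   is the arc endpoint on the marching side, found as the edge of the
   largest circular gap in the sorted acetabular angles. If no gap of at
   least 20° exists the acetabulum covers the whole slice circle and the
   plane carries no rim information.
5. **Beta per plane and minimum.** Beta is the signed angle from the rim ray
   to the onset ray. The two-ray ambiguity is resolved to the range
   (−90°, 270°]: overlap deeper than 90° is anatomically impossible (the
   neck would cross the acetabular wall), so nominal differences beyond that
   are kept as large positive clearances instead of spurious deep negatives.
   The minimum over all usable planes is the reported clearance; planes that
   are unusable (too few points, missing the head sphere, no onset, no rim,
   or near-tangent — see below) are excluded and recorded.

**Near-tangent slices.** Within a slab of half-thickness *w* at offset *h*
from the head centre, points of an exactly spherical head project up to
`sqrt(r² − (|h| − w)²) − sqrt(r² − h²)` outside the slice circle. Once this
spread exceeds the asphericity tolerance a spherical contour is
indistinguishable from an aspherical one, so such planes are flagged
unusable. For the defaults (r ≈ 25 mm, w = tolerance = 0.5 mm) this keeps
planes with |h| ≲ 0.7 r.

**Sphere fits.** Spheres are fitted by the linear (Coope) formulation
followed by Gauss-Newton refinement of the geometric residuals —
deterministic, with no random initialisation. The femoral head fit uses
iterative exclusion of points whose residual exceeds the asphericity
tolerance, so a cam prominence does not bias the head centre (an
unmitigated 3 mm cam shifts the centre by ~0.2 mm, which moves the detected
onset by several degrees).

**Axes.** When a neck-surface cloud is supplied, `hip_model()` takes the
neck axis as the line from the fitted head centre through the neck-cloud
centroid; both points lie on the axis of a cylindrical neck, so this is far
better conditioned than a principal-component fit on a structure whose
length barely exceeds its diameter (for which a PCA axis is several degrees
off at realistic sampling). The shaft axis defaults to the mechanical axis
(epicondyle midpoint to head centre). The generic `fit_axis()` primitive
(principal direction with a sign hint, ambiguity error when the top two
variances are within 5%) remains available; how the original workflow
derived these axes from scan planes is not documented, so both options are
deliberate stand-ins.

## Motion pipeline

The standing calibration records each marker cluster's reference
configuration together with the anatomical frames and the supine
centre-to-centre distance. For every motion frame, each cluster's current
markers are fitted to the calibration configuration by the closed-form
least-squares rigid transform (Kabsch, SVD with reflection guard, using all
visible markers — with 4-marker clusters one noisy marker is averaged down
rather than trusted); the anatomical frames are propagated rigidly and the
Grood-Suntay angles evaluated. Frames with fewer than 3 visible markers per
cluster are reported as gaps, never interpolated, and no filtering is
applied by default. The statically imaged posture is matched to the motion
frame minimising the LSQE (the Euclidean norm of the three angle
differences, in degrees), with ties broken toward the earlier frame. The
bone models are then posed with the supine-to-frame transforms, the femur is
translated along the head-centre-to-acetabulum-centre line so the
centre-to-centre distance equals the supine reference, and the minimum beta
is computed.

Rigid registration between postures of the same bone uses point-to-point
iterative closest point: nearest-neighbour correspondences alternate with
the closed-form rigid update until the RMS change drops below `tol`
(default 1e-4 mm) or `max_iter` (200) is reached; non-convergence is
reported, not raised. An optional worst-fraction trim (default 0) supports
partially overlapping segmentations; initialisation defaults to identity,
with `landmark_transform()` available for pre-alignment of large posture
changes. The neighbour search is a chunked vectorised scan, which registers
clouds of a few thousand points in seconds — adequate for bone
segmentations at the resolutions used here, without a compiled spatial
index.

## Validation statistics

`lsqe()` is the matching metric above. `accuracy_summary()` reports the
mean, sample SD (n−1 denominator; the reporting norm, and both conventions
round to the same published decimals) and RMSE of the absolute differences
between predicted and directly measured beta. `pearson_r()` provides the
product-moment correlation with the two-sided t-test p-value;
`icc_agreement()` implements ICC(A,1) — two-way, absolute agreement, single
measures — computed directly from the two-way ANOVA mean squares, because
absolute agreement (unlike consistency forms) penalises a constant offset
between methods. The published analysis did not state its ICC model; this
choice is recorded in the output. `threshold_inclusion()` formalises the
published inclusion procedure as the largest ascending-LSQE prefix (of at
least 3 records) whose LSQE/error correlation is not significant at `alpha`
(default 0.05); an undefined correlation (zero variance) counts as
non-significant. On the published per-participant records this reproduces
the reported outcomes (all 10 squat and all 7 FADIR participants retained).
All statistics are computed on unrounded values; rounding to one decimal
happens only in human-readable output.

## The synthetic phantom and what the tests show

`generate_phantom()` builds a parametric hip with closed-form clearance
ground truth:

* femoral head: sphere (default radius 25 mm) sampled area-uniformly;
* neck: cylinder (default radius 15 mm) meeting the head at the analytic
  sphere-cylinder junction angle `asin(r_neck / r_head)` ≈ 36.9°, plus a
  shaft stub at a 130° neck-shaft angle;
* cam: a radial Gaussian bump on the head surface (amplitude 0-9 mm,
  angular sigma 12°, centred 12° beyond the junction by default) — smooth,
  with an analytically computable onset: the detection threshold is crossed
  at `cam_centre + sigma * sqrt(2 log(amplitude / tolerance))`;
* acetabulum: a spherical-cap shell concentric with the head (default
  coverage half-angle 100°, radial clearance 0.5 mm), with the rim circle
  additionally sampled as a dense curve — the rim margin is a continuous
  bony edge visible in every image slice that crosses it, and without the
  explicit curve a point-sampled cap under-samples grazing intersections;
* landmarks and marker clusters placed so the neutral pose has exactly zero
  hip angles for a right hip; surface density defaults to 1.5 points/mm²
  (bone-segmentation order of magnitude).

`simulate_motion()` ramps the hip angles from neutral to the scenario peak
with a half-cosine profile (squat default (85, 5, 5)°; FADIR default
(90, 10, 18)°), holds the pelvis static, carries the marker clusters
rigidly, and optionally adds isotropic Gaussian marker noise (independent
per frame — deliberately *not* an autocorrelated soft-tissue artifact
model). Ground-truth poses and analytic beta accompany every frame.

**What the oracle comparisons mean.** At the neutral pose every slice cuts
the phantom transversally and the measured minimum beta matches the
closed-form minimum to within twice the angular sampling step (the mean
angular spacing of slab points on the head circle, ≈1.5° at default
density). At strongly rotated poses a point-sampled slab detects threshold
crossings somewhere between two ideal contours — the one at the plane's own
coordinate and the one at the most favourable slab edge — so the end-to-end
prediction at the matched motion frame is checked against the analytic
bracket formed by those two limits (lower bound: minimum over planes under
most-favourable slab geometry; upper bound: plane-coordinate beta at the
central plane), again with a 2-step margin. Passing these tests shows the
geometry chain (calibration, matching, posing, reslicing, onset/rim
detection, minimisation) is correct on data whose truth is known exactly.
It does not certify accuracy on real anatomy: real femora are not spheres
plus cylinders, segmentation noise is structured, soft tissue moves markers
coherently rather than independently, and the real acetabular rim is a
lunate margin rather than a symmetric cap edge.

## Numerical conventions and degenerate inputs

* Millimetres and degrees at every interface; radians internally.
* Closed slabs (boundary points included), matching "within 0.5 mm".
* Sphere fits reject (numerically) coplanar point sets; axis fits reject
  isotropic clouds (top-two variance ratio < 1.05).
* Coincident ASIS landmarks, coincident epicondyles, or a head centre on
  the epicondyle line raise degenerate-frame errors.
* A zero centre-to-centre distance is a no-op when the reference distance
  is also zero (concentric joint) and an error otherwise.
* Matching ties resolve to the earliest frame; `which.min` semantics.
* Every output artifact embeds the configuration echo, an MD5 hash of it,
  and the package version; reruns with identical inputs are bit-identical.

## Problem sizes in the test suite

The suite generates phantoms at 1.5 points/mm² (≈30k points per joint),
simulates 30-60 motion frames per trial, and runs 20 randomized
phantom/scenario draws for the oracle checks plus a 5×5 severity grid for
monotonicity; the full suite completes in well under a minute on one core.
These sizes were chosen as the smallest at which the discretisation bounds
above are meaningful.

## Known limitations

* The rim and onset definitions are operationalisations; the original
  static measurements were read manually, so the tolerance (0.5 mm) and the
  run guard (3 points) are exposed as parameters rather than asserted as
  facts.
* Point-to-point ICP with identity initialisation assumes rough
  pre-alignment for very large posture changes; use landmark pre-alignment
  when rotations exceed ~45°.
* No C3D reader; marker data enter as TRC or CSV.
* The phantom validates geometry and statistics, not biology: no cartilage,
  labrum, translation of the hip centre during motion, or soft-tissue
  artifact structure.
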