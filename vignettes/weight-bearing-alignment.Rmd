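---
title: "Weight-bearing lower-limb alignment from biplanar radiographs: methods"
author: "limbalign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weight-bearing lower-limb alignment from biplanar radiographs: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(limbalign)
```

## The problem

Corrective osteotomies of the lower limb are planned on 3D bone models
reconstructed from CT, but CT is acquired supine: the knee is unloaded, and
the frontal-plane alignment measures that drive the surgical correction --
the mechanical axis (MA) and the joint line convergence angle (JLCA) --
can differ by clinically relevant amounts between the lying and the
standing, weight-bearing posture.  Calibrated biplanar slot-scanning
radiography (EOS-type systems) images the patient standing, in two
perpendicular planes, but yields only 2D projections.

`limbalign` fuses the two: an intensity-based 2D-3D rigid registration
estimates, per bone, the transform from the CT frame into the world frame
of the standing acquisition.  Applying those transforms to the CT-derived
surface models produces weight-bearing 3D models on which MA and JLCA are
measured in 3D.

## Imaging geometry

The slot scanner sweeps two perpendicular horizontal fan beams vertically
across the standing patient.  Consequences, encoded in `eos_geometry()`:

* The vertical image coordinate is affine in world height with **no
  magnification**: `v = (z0 - Pz) / lambda_z`, where `z0` (mm) is the
  emitter start height and `lambda_z` (mm/px) the vertical pixel pitch.
* The horizontal coordinate is a perspective projection.  The device
  rescales images to a virtual detector through the isocenter, so a
  structure at isocenter depth appears at exactly unit magnification;
  `project_point()` implements `h = principal + f Px / ((f + Py) lambda_h)`
  for the frontal plane (and symmetrically for the lateral one), with `f`
  the source-to-isocenter distance.

The world frame is right-handed with x to the patient's left, y posterior
and z superior.  Emitter placement is not part of the device calibration
we consume, so it is fixed by convention: the frontal source line at
`y = -f_f`, the lateral source line at `x = -f_l`.  Stereo triangulation
(`triangulate_point()`) inverts the forward model: the two horizontal
constraints form a 2x2 linear system in `(Px, Py)`, and
`Pz = z0 - lambda_z (v_f + v_l) / 2` averages the two vertical readings.
The published calibration constants (`f = 918` mm, `z0 = 477.5` mm,
`lambda_z = 0.179363` mm) are the defaults of `geometry_from_parameters()`.
Because typesetting ambiguities make printed forms of such linear systems
unreliable, correctness is anchored instead to the forward model: the test
suite asserts projection followed by triangulation is the identity to
1e-9 mm over 1000 random points, and that the horizontal solution equals a
brute-force least-squares ray intersection.

Two further conventions are defaults rather than device facts: the
horizontal principal pixel sits at the image-center column, and horizontal
pitches equal the vertical pitch (square pixels).  Both are overridable in
the calibration file.

## Digitally reconstructed radiographs

`render_drr()` casts, for every pixel, the horizontal ray from the
emitter position at that row's height through the pixel's position on the
virtual isocenter detector, and integrates linear attenuation along it
(trilinear interpolation; outside-volume samples contribute zero; the ray
is clipped to the volume's bounding box before sampling).  HU are mapped
by `hu_to_attenuation()` as `mu = max(0, (HU + 1000)/1000) * mu_water`.
The model is a monochromatic line integral without exponential film/panel
conversion: the similarity below is invariant to monotone local intensity
rescaling, so the extra nonlinearity would add cost without changing the
optimum.  The default ray step is half the smallest voxel spacing; halving
it changes integrals on a smooth phantom by well under 1% (asserted in the
tests).

## Registration

Per bone, six degrees of freedom are estimated: three intrinsic x-y-z
Euler angles about the volume's intensity centroid (decoupling rotation
from translation) and three translations.

* **Initialization** (`initialize_pose()`): the user draws one arrow
  between the same two anatomical landmarks in the frontal radiograph, the
  lateral radiograph and the CT.  The 2D endpoints are triangulated; the
  initial pose is the minimal rotation taking the CT arrow direction onto
  the triangulated direction plus the midpoint-to-midpoint translation.
  Roll about the arrow axis is unobservable from one arrow and left zero.
* **Similarity** (`lncc_similarity()`): localized normalized cross
  correlation with a 9-pixel patch, aggregated as a weighted mean with
  weights proportional to the local variance of the fixed radiograph.
  Variance weighting concentrates the score on structured regions; the
  weight normalization keeps the score in [-1, 1], and zero-variance
  patches are excluded, which makes degenerate inputs well defined.  The
  cost is the negated sum of the frontal and lateral scores inside
  per-plane rectangular masks drawn around the bone.
* **Optimization** (`register_bone()`): BOBYQA (bound-constrained
  derivative-free quadratic approximation, via `minqa`).  Bounds default
  to +/-30 mm and +/-30 degrees around the initialization -- generous for a
  manual initialization whose residual is a few millimetres and degrees.
  The initial trust radius is 3 (in the mixed mm/degree units), the final
  radius 1e-3, and the evaluation budget 400.  A manual restart simply
  re-invokes `register_bone()` with an adjusted `init`.  An optional
  two-level mode runs a coarse pass at doubled ray step first.

The output transform maps CT coordinates into the world frame; the
registration error against a ground truth `GT` is decomposed from
`E = T^-1 GT` into per-axis translations and intrinsic x-y-z Euler angles
(`registration_error()`).  At the sub-degree magnitudes of interest all
Euler conventions agree to first order; the convention is fixed and
documented rather than configurable.

## 3D measurements

`measure_alignment()` runs the measurement chain in five steps.

1. **Joint centers.**  Hip: algebraic least-squares sphere fit to points
   picked on the femoral head.  Knee: midpoint of the two intercondylar
   eminences.  Ankle: centroid of all tibia and fibula vertices whose
   exact point-to-triangle distance to the talus surface falls below a
   threshold (default 3 mm, configurable); the selected-vertex count is
   reported so the threshold can be adjusted until the articular surface
   is covered, mirroring the visual workflow.
2. **Anatomical alignment** (`align_anatomical()`): the ankle-to-hip axis
   is rotated onto +y (superior), then the frame is spun about y until the
   best-fit plane of the anterior patellar points faces +z (anterior).
   In this frame +x is the patient's left and the frontal plane is x-y.
3. **MA** (`compute_ma()`): the frontal-plane deviation-from-collinearity
   angle between the hip-knee and knee-ankle lines; a straight leg
   measures 0.  The sign is taken from the side of the hip-ankle chord the
   knee falls on: varus (knee lateral) positive.  The
   deviation convention (rather than the 180-degree-based hip-knee-ankle
   angle) matches the signed varus-positive reporting and the few-degree
   magnitudes of clinical interest.
4. **FCT** (`compute_fct()`): femoral longitudinal axis from the first
   principal component of the mesh vertices; the distal epiphysis is
   isolated by a perpendicular cut just above the epicondyles -- 5 mm
   proximal of the more proximal epicondyle landmark when landmarks are
   given, otherwise at the most distal 15% of femoral length (a robust
   default for femur models that include the full shaft).  A 2-means
   split, seeded deterministically with the two mediolaterally extremal
   epiphysis vertices, separates the condyles; per condyle the three most
   distal vertices are averaged, and the tangent joins the two means.
5. **JLCA** (`compute_jlca()`): the tibial plateau plane is a total
   least-squares fit to eight user-picked plateau points; its frontal
   trace is the tibial condyle tangent.  JLCA is the frontal-plane angle
   between the femoral tangent and that trace, positive when the joint
   space opens laterally.

All measurements are invariant under a common rigid motion of every input
(asserted to 1e-6 degrees), and mirrored constructions with the side flag
flipped preserve values while constructed varus/lateral-opening cases
yield positive signs.

## Fiducial validation machinery

The validation module reproduces a marker-based accuracy protocol: six
3 mm radiopaque spheres per bone, visible in CT and both radiographs.
`marker_centers_from_volume()` thresholds the CT, labels 6-connected
components and localizes each as a sphere -- by a least-squares fit to the
component's boundary voxels (radius corrected by half a voxel for the
inward bias of inside-surface voxel centers) when at least 12 boundary
voxels exist, else by the component centroid with an equivalent-volume
diameter.  A +/-50% diameter gate rejects clutter.  The 2D marker picks are
triangulated per label; `rigid_fit_points()` computes the ground-truth
transform from the 12 labeled correspondences in closed form
(Kabsch/Umeyama) -- with known correspondences the iterative
closest-point loop terminates after a single assignment, so the closed
form is exact.  Both a joint 12-marker fit (default) and per-bone fits are
possible by passing the marker subsets.

## The synthetic phantom

`build_phantom()` constructs a desk-scale digital analog of a rigid
full-leg validation phantom from implicit solids: femoral head sphere,
shaft cylinders, two condyle spheres, a tibial plateau disk, fibula,
patella and talus, plus a soft-tissue envelope in the full CT volume and
six fiducials per bone.  Everything is voxelized at 1.5 mm (default) and
the same solids are triangulated analytically into surface meshes, so the
surfaces coincide with the HU iso-level by construction.  Key constructive
choices:

* **Deformity is built in analytically.**  The tibial mechanical axis is
  tilted in the frontal plane by the requested MA about the knee center
  (varus positive), and the plateau disk normal is tilted by the requested
  JLCA (lateral opening positive) independently, so the ground-truth
  angles are exact properties of the geometry, not measured quantities.
  The default deformity (MA +5, JLCA +3 degrees, left leg) is in the
  mid-range of osteotomy candidates.
* The fibula's distal tip is kept well clear (more than twice the default
  threshold) of the talus so the selected ankle articular surface is the
  symmetric distal tibial face and the constructed MA stays analytic.
* Tissue HU defaults (cortical 1200, marker 3000, soft tissue 40, air
  -1000) are plausible CT contrast values; they are fixture parameters,
  not claims about tissue physics.
* `simulate_eos_pair()` renders the two rigid assemblies (thigh: femur +
  patella; shank: tibia + fibula + talus) each at its own pose and
  composites additively -- a rigid approximation of a postural change that
  ignores soft-tissue deformation.  It also emits exact 2D marker
  projections, arrow annotations derived from the true landmarks, and
  per-bone masks.  The masks are tight silhouette boxes whose knee-side
  edge is retracted by the similarity patch radius, so that no 9x9 patch
  window straddles the joint space into the other, differently posed
  bone; without the retraction, high-variance patches containing the
  other bone's plateau or condyle edge measurably bias the optimum.
* The simulation geometry (`phantom_geometry()`) keeps the published
  918 mm source distance and 477.5 mm emitter height but uses a 1.5 mm
  pixel pitch and a 320 x 96 image, matching the phantom's voxel scale.

What the phantom does **not** emulate: anatomical bone shape and
population variation, soft-tissue deformation between postures, scatter,
beam hardening, detector noise (optional additive Gaussian noise is
available for both the volume and the images, default off), and scanner
artifacts.  Because the simulated radiographs are produced by the same
renderer used inside the registration, the registration experiment is a
best-case, internally consistent exercise: it validates the geometry,
similarity, optimizer and error decomposition as a chain, not the
renderer's physics against a real device.  Passing it shows the pipeline
recovers known poses under its own forward model; accuracy on clinical
images will be poorer and depends on image quality.

## Problem sizes and numerical choices

The registration accuracy experiment
(`phantom_registration_experiment()`) simulates the biplanar pair at
known per-bone poses (a few millimetres / degrees, emulating postural
change), perturbs the arrow-based initialization by 5 mm and 5 degrees in
a seeded random direction, registers femur and tibia, and decomposes
`E = T^-1 GT` per axis, over 5 seeds by default.  At the default 1.5 mm
phantom a single registration takes a few seconds and the full ten-run
experiment about a minute on one CPU; these sizes were chosen so the whole
loop remains an interactive desk exercise, with `spacing` and the
geometry available for higher-resolution studies.

Other numerical choices: sphere and plane fits reject coplanar/collinear
input by rank and singular-value checks; the triangulation refuses
2x2 systems within 1e-6 of singular; zero-variance LNCC patches carry
weight zero; optimizer output is re-orthonormalized by polar decomposition
before being returned as a rigid transform; antiparallel arrow directions
fall back to a fixed perpendicular rotation axis; and k-means condyle
seeding is deterministic, so identical inputs yield identical results.

## Limitations

Beyond the phantom simplifications above: masks and arrows are manual
inputs (automatic landmark detection is out of scope); registration is
rigid and per-bone (no deformable motion, no joint-level coupling); only
frontal-plane measures (MA, JLCA) are computed -- torsional and sagittal
deformity measures are not; and the DICOM ingestion path expects the
calibration fields to be supplied or mapped externally rather than parsing
vendor-private tags itself.
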