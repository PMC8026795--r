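# limbalign

Weight-bearing lower-limb alignment from biplanar standing radiographs via
intensity-based 2D–3D registration.

## The problem

Corrective osteotomies around the knee are planned on 3D bone models
segmented from CT — but CT is acquired lying down. The two measures that
drive the correction, the **mechanical axis (MA)** and the **joint line
convergence angle (JLCA)**, change between the supine and the standing,
weight-bearing posture. Calibrated biplanar slot-scanning radiography
(EOS-type systems) captures the standing posture, but only in 2D.

`limbalign` registers each bone's CT volume to the biplanar standing
radiographs and transfers the 3D models into the weight-bearing pose:

1. **Geometry** — slot-scan fan-beam model: vertical pixels map to world
   height without magnification, `v = (z0 − P_z)/λ_z`; horizontal pixels
   are a perspective projection rescaled to a virtual detector through the
   isocenter. Stereo triangulation inverts the model, with
   `P_z = z0 − λ_z (v_f + v_l)/2`.
2. **Registration** — per bone, a 6-DOF rigid pose (3 Euler angles + 3
   translations) is initialized from user arrow annotations (triangulated
   2D arrows matched to a 3D CT arrow) and optimized with BOBYQA,
   maximizing the sum over both planes of a variance-weighted localized
   normalized cross correlation (patch size 9) between digitally
   reconstructed radiographs (DRRs) of the CT and the measured images,
   inside per-bone masks. Output: a 4×4 transform `T` (CT → world).
3. **Measurement** — hip center by least-squares sphere fit, knee center
   as the intercondylar-eminence midpoint, ankle center as the centroid of
   the distal tibio-fibular articular surface (talus-distance threshold);
   anatomical reorientation (leg axis → +y, patella → +z); then MA as the
   frontal-plane deviation between hip–knee and knee–ankle lines (varus
   positive) and JLCA as the frontal-plane angle between the femoral
   condyle tangent and the tibial plateau trace (lateral opening
   positive).
4. **Validation machinery** — spherical fiducial extraction from CT,
   stereo triangulation of labeled 2D marker picks, closed-form rigid
   ground-truth fit (Kabsch), and error decomposition
   `E = T⁻¹·GT` into per-axis translations (mm) and intrinsic x-y-z Euler
   angles (degrees).
5. **Synthetic phantom** — a parametric digital leg phantom (CT volume,
   surface meshes, 6 × 3 mm fiducials per bone, all landmarks, known
   MA/JLCA built in analytically) plus a biplanar image simulator, so the
   whole pipeline is testable end to end without clinical data.

## Worked example

Generate a synthetic case with a known deformity (MA +5°, JLCA +3°, left
leg) and small per-bone "weight-bearing" pose offsets, then run the whole
pipeline on the written files:

```r
library(limbalign)

d <- file.path(tempdir(), "case")
case <- write_phantom_case(d)          # volumes, images, meshes, annotations

cfg <- pipeline_config(
  geometry = case$geometry, frontal = case$frontal, lateral = case$lateral,
  ct_femur = case$ct_femur, ct_tibia = case$ct_tibia,
  annotations = case$annotations, landmarks = case$landmarks,
  mesh_dir = case$meshes, side = "left", out_dir = file.path(d, "out"))

report <- run_pipeline(cfg)
cat(sprintf("MA   %+.1f -> %+.1f deg\nJLCA %+.1f -> %+.1f deg\n",
            report$non_weight_bearing$ma, report$weight_bearing$ma,
            report$non_weight_bearing$jlca, report$weight_bearing$jlca))
#> MA   +5.0 -> +4.4 deg
#> JLCA +3.0 -> +4.0 deg
```

The non-weight-bearing values reproduce the phantom's constructed
deformity; the weight-bearing values shift because the simulated standing
pose rotates the tibia relative to the femur, and both registrations
converge to a summed LNCC similarity of ≈ 2.0 (the attainable maximum).
The same flow is scriptable from a shell via `inst/cli/limbalign.R`
(subcommands `simulate`, `register`, `measure`, `validate`, `run`).

Measuring the phantom directly (no registration) recovers the constructed
angles:

```r
ph <- build_phantom(phantom_spec())    # MA +5 deg, JLCA +3 deg by construction
measure_alignment(ph$meshes, ph$landmarks, ph$side)
#> Lower-limb alignment (left leg)
#>   MA:   +5.0 deg (varus positive)
#>   JLCA: +3.0 deg (lateral opening positive)
#>   ankle articular surface: 29 vertices selected
```

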