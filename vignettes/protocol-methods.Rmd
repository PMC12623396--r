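---
title: "Methods: coordinate systems, calibration and kinematics for running-specific prostheses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coordinate systems, calibration and kinematics for running-specific prostheses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rspkin)
```

This vignette documents the model behind `rspkin`, the choices that were
genuinely open when it was designed, and what its verification on
synthetic data does and does not establish about real laboratory data.

## The processing model

The pipeline assumes pre-labelled C3D trials (a standing static trial,
one short wand-pointing trial per calibrated landmark, and dynamic runs
with manually detected foot-strike/foot-off events) and proceeds in four
steps:

1. **Landmark localization.** Wand-calibrated landmarks (e.g. adapter
   screws that cannot carry a marker during running) are located by
   fitting the known wand geometry to the observed wand markers frame by
   frame and mapping the tip offset; the per-frame tips are combined with
   a coordinate-wise median. Each landmark is then expressed in the frame
   of its host technical cluster (CAST). The hip joint centre is a
   regression point: fixed fractions of the inter-ASIS distance in the
   pelvis frame.
2. **Processed static trial.** All physical markers plus all localized
   landmarks, re-expressed globally, in one trial. Static-only markers
   (removed after the standing trial) are stored relative to their
   cluster here too.
3. **Dynamic reconstruction.** Per frame, each cluster's pose is fitted
   by least squares (SVD, proper rotation enforced) from whatever cluster
   markers are valid (minimum three), and hosted landmarks are mapped
   through the fitted pose. Nothing is interpolated or extrapolated:
   frames with insufficient cluster visibility stay invalid. The knee
   hinge markers KL/KM are always passed through as measured — mapping
   them through a cluster fit would re-introduce exactly the cluster
   deformation crosstalk the functional-knee construction avoids. The
   technical FP triad additionally backs up occluded foot-clamp markers.
4. **Frames and angles.** Every protocol coordinate system is constructed
   per frame from the reconstructed marker set; joint angles are
   intrinsic Cardan decompositions of the proximal-to-distal relative
   rotation, segment orientations are roll-pitch-yaw against the lab, and
   curves are resampled to 101 points per stride or stance phase.

Assumptions: segments (and the two RPF sub-segments separately) are rigid
between markers; the lab frame has x along the running direction and y
opposing gravity; marker data have already been labelled, gap-filled and
low-pass smoothed by the acquisition software (`smooth_trial()`
reproduces that upstream step for raw or synthetic input; the pipeline
itself never smooths).

## Side conventions

Published frame constructions are written for the right side. For the
left side the operand built from a lateral-minus-medial line is negated
(equivalently the cross-product operand order is swapped) so the z axis
points to the subject's right on both sides. Sign harmonization then
happens once, after decomposition: the 2nd and 3rd angle channels are
flipped on the left side, so flexion (dorsiflexion at ankles), adduction
and internal rotation are positive bilaterally; knees additionally negate
the first channel so flexion is positive. This is pinned by a property
test: mirroring an entire scene through the lab sagittal plane and
swapping side labels reproduces every trace to 1e-8 degrees.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| Wand rms warning threshold | 2 | mm | above typical photogrammetric residuals: indicates a bent or mislabelled wand |
| Wand minimum usable frames | 10 | frames | rejects accidental captures |
| HJC regression coefficients | (-0.19, -0.30, 0.36)·PW | – | classic inter-ASIS-width family; configurable because labs standardize on different regressions |
| Gimbal tolerance | 0.5 | deg | below it, the 1st/3rd Cardan angles are numerically meaningless; NaN is reported, never interpolated |
| Normalization grid | 101 | points | the 0–100% convention of the gait literature |
| Smoothing cutoff | 10 | Hz | above the harmonic content of sprint kinematics at 200 Hz capture; the mildest filter that leaves the signal intact |
| Minimum cluster visibility | 3 | markers | an exact-fit pose; flagged, residual 0 by construction |

## The synthetic rig

`build_rig()` + `simulate_trial()` implement an articulated
pelvis–prosthesis–sound-limb chain whose local marker placements follow
the protocol layouts (socket lateral/medial/frontal axes; 4-screw
socket-clamp; hinge-axis KL/KM; C- or J-shape clamp; FP T-cluster; blade
tip with FDM/FDL 50 mm proximal at a 60 mm blade width). The blade has a
revolute plus prismatic degree of freedom between its proximal and distal
portions, so virtual-ankle deflection and compression have exact ground
truth; a blade pre-angle (default 10°) makes the static virtual ankle
deliberately non-zero, and an optional pylon misalignment produces the
expected constant offset on prosthetic-knee flexion. Contact events come
from a height threshold on the blade tip / sound heel — plausible event
placement only, not a model of gait-event science.

Study conditions used throughout verification: dynamic trials of 2 s at
200 Hz; static and wand trials of 2 s (calibration trials last seconds in
practice, and their duration sets the calibration bias floor); hip
amplitude ±40°, prosthetic-knee flexion 0–90°, blade deflection 12° and
compression 25 mm in stance; forward speeds 6.7 m/s (TF) and 8.7 m/s
(TT); marker noise i.i.d. Gaussian per coordinate.

What the rig does **not** emulate: soft-tissue artefact (its noise is
white, not correlated with motion), genuine blade bending modes (one
lumped hinge + shortening), labelling errors, and camera-volume
visibility effects beyond explicit occlusion windows. Passing the
synthetic end-to-end tests therefore demonstrates correctness of the
geometry, calibration, reconstruction and decomposition chain — not that
real skin-mounted clusters are rigid.

## Numerical choices

* Rotations are validated to 1e-10 (orthonormality and determinant);
  degenerate constructions (collinear markers, zero-length axes) raise
  errors naming the construction rather than returning garbage.
* The SVD pose fit corrects reflection solutions by sign-flipping the
  last singular axis; it equals a closed-form quaternion solution to
  1e-9 on noisy sets (tested on 1000 seeded problems).
* Cluster frames for CAST localization use origin = first marker, x
  toward the second, plane through the third; any consistent choice
  cancels in the localize/reconstruct round trip.
* Static averaging uses the coordinate-wise median (robust to brief
  occlusions).
* Unwrapping is relative to the previous valid frame; NaN (gimbal) frames
  break continuity chains.
* The 2D equivalent-leg frame (GT-KL) is lab-referenced by construction
  (sagittal-plane projection, z pinned to the lab lateral axis); it is
  equivariant only under transforms that preserve that plane family
  (z-rotations and translations), and is tested as such. All other frame
  constructions are equivariant under arbitrary rigid motion to 1e-9.

## Design decisions that were open

* **Angle storage in enriched C3D**: point-type channels with suffix
  `.ang`, degrees in all three components — keeps one self-contained
  output file per trial.
* **Model schema**: a small XML dialect (see
  `inst/extdata/models/*.xml`) with `{s}`/`{c}` side placeholders for
  marker names, frame recipes, clusters, the joint chain and the
  orientation list. Sound-side recipes are ISB-default and marked as
  such in the files.
* **Configuration identity**: (subject id, session date). A new static
  after a detached marker is an *update* — revision incremented, wand
  landmarks hosted on the affected cluster flagged for recalibration —
  never a new configuration; changing level, side or RPF shape is.
* **Events**: read from the C3D EVENT section only; no automatic
  detection.
* **Roll-pitch-yaw**: reported as (anterior leaning, roll, yaw) via the
  intrinsic y–z'–x'' factorization; the choice is isolated behind the
  `rpy` sequence tag.
* **CLI**: three subcommands (`configure`, `process-static`, `analyze`)
  mirroring the three pipeline stages, with structured per-trial logging
  (cluster fit residuals, stride counts) instead of dialogs.

## Known limitations

* With 1 mm i.i.d. marker noise the maximum angle error over a stride is
  bounded below by geometry: the distal-RPF frame rests on a 50 mm
  long-axis baseline, so even after 10 Hz zero-lag smoothing
  (effective noise ≈ 0.3 mm) its per-frame angular noise is ≈ 0.4°, and
  the stride-window maximum lands at 1.2–1.6° for the virtual ankle and
  0.7–0.9° for large segments (these are the `recovery_noisy_max_deg_*`
  values the acceptance script measures). Sub-half-degree worst-case
  accuracy there requires either longer tip baselines or sub-0.5 mm
  effective noise, not a different algorithm. Noise-free recovery is at
  machine precision (~2e-12°).
* Kinetics, joint moments and inertial parameters are out of scope, as is
  any soft-tissue-artifact compensation or global-optimization inverse
  kinematics.
* The C3D writer stores float (negative scale) Intel-format files with
  int16 frame counts, which covers trials up to ~32000 frames.
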