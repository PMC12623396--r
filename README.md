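# rspkin

Marker-based motion-capture kinematics for sprinters with transfemoral
(TF) or transtibial (TT) amputation.

Sprinters using a running-specific prosthesis (RSP) — socket, optional
monocentric prosthetic knee, carbon running blade (running prosthetic
foot, RPF) — cannot be analysed with conventional gait models: the
prosthetic side has no anatomy to palpate, the blade deforms heavily in
stance, and components are joined by adapters whose alignment is itself a
quantity of interest. `rspkin` implements a standardized protocol for this
population: dedicated mechanical coordinate systems on every prosthetic
component, CAST-style calibration of landmarks that cannot carry a marker
during running, SVD rigid-pose reconstruction in dynamic trials, and
Cardan joint kinematics along the full chain, from C3D files in to
enriched C3D plus tidy CSV out. It is aimed at biomechanists,
prosthetists and test engineers who need comparable in-vivo kinematics
across athletes, sessions and prosthetic set-ups.

## The model

All frames are right-handed triads (x forward, y up, z to the subject's
right; published constructions are for the right side and are
side-adapted so z points rightward on both sides):

* **SK** (socket): from socket lateral/medial/frontal axis markers.
* **SC** (socket-clamp, TF): from the four wand-calibrated screws of the
  socket's distal adapter.
* **PK / DK** (functional prosthetic knee, TF): both centred at the
  KL–KM midpoint with z exactly on the hinge axis; PK takes its forward
  axis from SC, DK from the foot-clamp. Because the z axis is shared,
  knee ab/adduction and axial rotation are *structurally* zero — a
  built-in validity check.
* **FC** (foot-clamp): C-shape (TF, from four wand-calibrated plaque
  screws averaged into clamp midpoints) or J-shape (TT, from four markers
  on the proximal blade).
* **FD** (distal RPF): blade-tip frame from FDA and the FDM/FDL pair
  50 mm proximal. The **virtual ankle** is the FC→FD rotation (zy'x''
  sequence); its *static* dorsiflexion is non-zero by design and is
  reported, never subtracted.
* **FP** (technical proximal RPF): T-cluster used for reconstruction
  backup, alignment tracking and **RPF compression** (FDA excursion in
  the FP frame).
* **HJC-K / GT-KL**: 3D and 2D (sagittal-video-comparable) equivalent-leg
  frames.
* Pelvis and sound-side thigh/shank/foot follow ISB-style recipes.

Joint angles are intrinsic Cardan decompositions (zx'y'' everywhere,
zy'x'' at ankles) of `T_prox^-1 T_dist`, signed so that flexion
(dorsiflexion), adduction and internal rotation are positive bilaterally;
segment orientations use a roll-pitch-yaw convention against the lab.
Curves are time-normalized to 101 points per stride (or stance).

A forward-kinematics synthetic rig (`build_rig()`, `simulate_session()`)
generates protocol-compliant static, wand and running trials with exact
ground truth, so the entire pipeline is verifiable to machine precision
without laboratory data.

## Worked example

```r
library(rspkin)

rig <- build_rig("TF", side = "L")                       # synthetic athlete
ses <- simulate_session(rig, duration = 2, rate = 200,
                        speed = 6.7, seed = 42)

cfg <- configure_session("TF", "ATH01", "2026-01-15", side = "L")
ps  <- process_static_trial(cfg, ses$static$trial, ses$wand,
                            ses$wand_geometry)
res <- analyze_trial(cfg, ps, ses$dynamic$trial)
```

This prints / returns:

```
<rsp_configuration> subject ATH01 @ 2026-01-15 rev 1
  TF, prosthetic side L, RPF shape C; 36 markers, 6 joints
<rsp_trial> 36 markers x 400 frames @ 200 Hz, 0 events
mean running speed: 6.70 m/s
strides detected: 2 (frames 43-49-176, 176-183-309)
static reference, virtual ankle (latf): 10.0 deg dorsiflexion
prosthetic knee off-axis |max|: 7.4e-16 deg
prosthetic knee flexion range: 0.0 to 90.0 deg
peak RPF compression: 25.0 mm
```

Reading: the athlete ran at 6.70 m/s; two full left strides were framed
by the foot-strike/foot-off events. The virtual ankle's static reference
is 10°, reflecting the blade tip's resting orientation — a property of
the RPF model, not an error. The prosthetic knee's off-axis channels are
zero to machine precision (the shared-hinge-axis construction), its
flexion spans 0–90° across stance and swing, and the blade shortened by
up to 25 mm under load. `res$cycles` holds the tidy 0–100% curves
(`joint, side, stride, domain, percent, a1..a3, foot_off_pct`), and
`write_enriched()` (or `analyze_trial(out_c3d =, out_csv =)`) writes the
enriched C3D with reconstructed points and `.ang` channels.

The same workflow is scriptable from a shell:

```sh
exec/rspkin configure --level TF --subject ATH01 --date 2026-01-15 \
    --side L --out config.xml
exec/rspkin process-static --config config.xml --static static.c3d \
    --wand LWAM=wam.c3d ... --out processed.c3d
exec/rspkin analyze --config config.xml --static processed.c3d \
    --trial run1.c3d --out-dir results/
```

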