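---
title: "Measuring implant migration from paired CT volumes: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring implant migration from paired CT volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctmotion)
```

## The measurement problem

Early migration of a hip implant relative to its host bone — fractions of a
millimetre over the first months — predicts later aseptic loosening.
Radiostereometry (RSA) measures it from stereo radiographs of implanted
tantalum beads; CT-based micromotion analysis reaches the same quantity from
two ordinary CT volumes by registering the images twice: once on the pelvic
bone (beads or surface anatomy) and once on the implant (the metal thread of
the cup and the beads in its liner). If $T_{bone}$ and $T_{implant}$ are the
rigid maps from the exam-1 world frame to the exam-2 world frame for the two
bodies, the migration is

$$M \;=\; T_{bone}^{-1} \circ T_{implant},$$

the motion of the implant expressed in a bone-anchored frame. It is the
identity when the two bodies moved together, i.e. when the patient was
merely repositioned. `ctmotion` implements this pipeline end to end, plus
the double-examination precision statistics and the dose-length-product
(DLP) effective-dose estimate that accompany such studies, and a digital
phantom generator that makes every stage testable against known ground
truth.

## Reporting convention

A `migration_result` reports six degrees of freedom: the displacement of
the implant center of mass (mm) and fixed-frame Cardan angles $x \to y \to
z$ (degrees) of the rotation part, i.e. $R = R_z R_y R_x$. Choices a reader
should know:

* **Rotation origin.** "Motion of the center of mass" fixes the translation
  report but not the rotation origin; we fix the rotation origin at the
  implant center of mass and document it, since different origins change
  reported translations of a rotating body.
* **Cardan sequence.** The sequence is not standardised across migration
  software; ours is configurable (`euler_order`), defaults to fixed-frame
  x–y–z, and results within 0.1° of gimbal lock ($|r_y| \approx 90°$) are
  flagged with the alternate sequence attached. Cross-software comparison
  of individual rotation components is convention-dependent; the total
  rotation angle is not.
* **Frames.** The native frame is the scanner (DICOM/LPS) patient frame.
  `reorient()` conjugates the motion into a user-supplied orthonormal
  anatomical basis and applies per-axis rotation sign conventions,
  mirroring the clinical step of re-slicing the CT so axes match the
  RSA-style anatomical frame. NIfTI input (RAS) is converted to LPS on
  read.

## Segmentation and registration primitives

Thresholds follow clinical practice: 2200 HU isolates metal and tantalum,
600 HU isolates bone (per-exam overrides, e.g. 400/550 HU for deviant
reconstructions, are supported in the configuration). Beads are
26-connected components whose volume falls in a window (default 0.1–2.0
mm³, matching 1-mm tantalum beads and excluding the much larger cup), with
intensity-weighted centroids using weights $\max(HU - \text{threshold},
0)$ — an approximation to partial-volume sub-voxel localisation that
recovers centres to a few hundredths of a millimetre at 0.6-mm voxels.

Matched point sets are registered by the closed-form least-squares rigid
fit (SVD with reflection correction). Two marker-quality metrics gate the
result, in the radiostereometric tradition: the **condition number**
(ratio of largest to smallest singular value of the centred marker matrix;
spread of the configuration) with limit 100, and the **mean error of
rigid-body fitting** (RMS marker residual; marker stability) with limit
0.30 mm. The exact condition-number normalisation used by commercial RSA
software is proprietary, so both the definition and the limit are
configurable and documented rather than claimed equivalent. A gate failure
flags the result but does not suppress it — the report-and-judge workflow.

### Surface registration

The markerless mode registers the pelvic bone surface. Three numerical
choices matter, and each was forced by a measurable failure of the naive
alternative:

1. **Sub-voxel iso-surface points.** Boundary-voxel centres are quantised
   to the grid; two exams of the same anatomy on differently-posed grids
   produce staircase patterns, and point-to-point ICP between such clouds
   can prefer an alignment that keeps the *grids* in phase over the one
   that aligns the *anatomy* (we measured a lower point-to-point RMS at a
   pose cancelling the repositioning rotation). Each boundary point is
   therefore moved onto the HU iso-surface by one Newton step along the
   local intensity gradient, which also yields surface normals.
2. **Point-to-plane ICP.** On smooth, nearly symmetric surfaces
   point-to-point ICP creeps and stalls in shallow local minima.
   Production surface registrations minimise point-to-plane distances with
   a linearised 6-DOF solve per iteration. The plain point-to-point
   engine (`icp_register`) remains available and tested; on matched
   noise-free clouds both agree with the closed-form fit.
3. **Initialisation.** Principal-axes alignment is unstable when the
   eigenvalues of the cloud are close — a pelvis-like shell is nearly
   rotationally symmetric. `coarse_align` therefore scores all four proper
   principal-axes sign combinations *and* a centroid-only candidate by a
   short decimated ICP and returns the refined winner. (A note on the
   sign disambiguation: fourth moments are invariant under axis flips, so
   they cannot disambiguate sign; the short-ICP score can.)

Bone surface points within 3 mm of segmented metal are discarded: the
partial-volume halo around the implant moves with the implant and would
bias a bone registration. Points within 2 voxels of the grid boundary are
discarded as well, since structures cut by the field of view leave flat
patches with no counterpart in the other exam.

### Implant registration

The implant is registered from "thread and beads": matched liner beads
give the initial fit and the marker-style quality metrics, then
point-to-plane ICP on the threaded cup surface refines the pose using the
cup's much larger lever arm. The bead pairs stay in the refinement as
weighted exact-correspondence anchors, because a threaded hemisphere is
nearly invariant under a screw motion (rotate and advance by the pitch)
and an unanchored surface match can slide along that direction. With fewer
than 3 surviving implant beads the surface ICP alone carries the
registration, initialised from the bone transform; its rotation about the
cup axis then rests on the shell's screw holes and thread, and is
correspondingly weaker.

## Precision and dose

A double examination — two scans in immediate succession with
repositioning — has zero true migration, so the spread of measured
migrations estimates precision. Per degree of freedom the report gives the
mean of the signed values (bias check; signed, so systematic bias shows in
the mean rather than inflating the SD), the standard deviation with the
$n-1$ denominator (consistent with the small-sample coverage-factor
rationale), and the precision bound $t_{n-1,0.975} \times SD$, which
approaches the familiar $1.96 \times SD$ as $n$ grows. Effective dose is
the DLP times a body-region coefficient, 0.0129 mSv/(mGy·cm) for the
pelvis by default and configurable for other regions; Monte-Carlo organ
dose simulation is out of scope.

## The digital phantom: what it emulates, and what it does not

`generate_phantom_pair()` renders a hip-like scene twice: exam 1 in
canonical pose; exam 2 with the whole scene moved by a repositioning
transform and the implant additionally moved by the migration under test.
The stated world follows the clinical protocol where it is stated:
isotropic 0.6-mm voxels; bone ≈ 900 HU against soft tissue ≈ 40 HU;
implant metal ≈ 3000 HU; 1-mm beads; beads and metal separable at 2200 HU
and bone at 600 HU by construction; additive Gaussian noise (default
20 HU) and streak artefacts near the metal. Values the protocol does not
state were fixed once at field-realistic levels:

* **Geometry.** A 24-mm outer-radius threaded cup (thickness 2.5 mm,
  thread pitch 2 mm, amplitude 0.5 mm, three screw holes) seated in a
  hemispherical bone shell (2-mm cement gap, 7-mm wall) carrying 4 large
  and 30 small seeded surface bumps. The bumps matter: a smooth
  hemisphere leaves surface registration rotationally under-constrained,
  and real pelvic anatomy is highly irregular. The screw holes and the
  helical thread break the cup's surface-of-revolution symmetry.
* **Beads.** 9 bone beads and 5 liner beads, typical clinical marker
  counts; placement is seeded with minimum angular separation, bone beads
  inside the shell wall, liner beads clear of the screw holes (a bead
  directly under a hole has no metal above it and would defeat the
  clearance-based bone/implant attribution). Beads render as anti-aliased
  spheres so sub-voxel centroid recovery is genuinely exercised. Tantalum
  gets its own peak intensity (default 8000 on an extended HU scale,
  distinct from the 3000 HU alloy): with a single 3000 HU metal value a
  1-mm bead centred between 0.6-mm voxels peaks *below* 2200 HU and
  silently vanishes from the segmentation, which contradicts both the
  stated world and clinical experience.
* **Artefacts.** Streaks are a scanner-fixed azimuthal sinusoid around
  the cup, decaying within about a quarter cup radius of the metal. An
  earlier variant let the pattern extend across the whole bone; because
  the pattern does not move with the patient, surface registration
  systematically drifted toward cancelling the repositioning rotation —
  a useful reminder that coherent artefacts are a real failure mode of
  markerless CT registration, but an unphysical default.
* **Rendering.** Exam 2 is rendered analytically at the transformed
  poses rather than resampling exam 1. The two exams thus have
  independent partial-volume samplings — exactly the property that makes
  double examinations informative — and the ground truth (bead
  coordinates, voxel class counts) is exact. Identical spec, transforms
  and seed give bit-identical volumes.
* **Repositioning.** The clinical protocol does not quantify how much a
  patient moves between the two scans; `sample_repositioning()` defaults
  to generous bounds (20 mm, 10°) and stays configurable. Tests use
  4 mm / 3° so the full scene (checked explicitly, beads, cup and bone)
  stays inside the rendered field of view.

A green phantom test therefore establishes that the pipeline recovers
known rigid motion under partial-volume sampling, repositioning, noise and
local streaks. It does not establish performance under real scanner
physics (beam hardening, reconstruction kernels, motion blur), real
pelvic anatomy, soft-tissue contrast, or anatomical change between
time points — the markerless mode's robustness to bone remodelling, for
example, is an asserted clinical property that a rigid phantom cannot
probe.

## Degenerate inputs and numerical edges

Collinear marker sets are rejected (rank check) or flagged with an
infinite condition number; mutual-nearest-neighbour bead matching
tolerates dropout as long as 3 pairs survive, rejects pairs farther than
5 mm after initialisation, and breaks ties towards the smaller label;
nearest-neighbour ties inside the kd-tree resolve to the smaller index, so
matching is deterministic; ICP returns its best iterate with
`converged = FALSE` when the RMS never improves; all subsampling is
seeded. Rotations are validated to $R^TR = I$ and $\det R = +1$ within
1e-6 at construction, and compositions stay well within 1e-9 across the
test suite.

## Scale-down for desk-scale testing

The default phantom (184³ voxels) accommodates large repositioning; the
test suite runs the clinical geometry in a 144³ grid (unit tests: 104³
with a 14-mm cup) to keep the whole suite within a CI budget. The
acceptance suite asserts end-to-end recovery of applied migrations
(0.2–2 mm, 0.5–5°) within 0.1 mm and 0.3° in both registration modes
over 20 seeded cases, and that a 10-pair zero-motion double-examination
study stays inside the clinically reported precision envelopes (0.16 mm
translation; 0.37° rotation with bone beads, 0.31° without); in practice
both pass with a margin of roughly a factor two at this operating point.
At the reduced unit-test scale the implant bead lever arm is about half
the clinical one, so the corresponding smoke test uses proportionally
looser rotation tolerances.

## Known limitations

* Rigid bodies only: no deformable registration, no femoral-stem
  analysis (the stem is typically cut by the field of view and needs its
  own protocol).
* Intensity-based (mutual-information) registration is not implemented;
  the surface pipeline depends on a segmentable bone surface.
* The DICOM reader handles explicit-VR little-endian single-frame CT
  series (the package's own exports and standard uncompressed scanner
  output); compressed transfer syntaxes are rejected.
* The condition-number gate value (100) transfers the *intent* of the
  marker-spread check; numeric equivalence with proprietary RSA software
  is not claimed.
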