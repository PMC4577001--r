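---
title: "Intensity-based 2D/3D registration: model, algorithm and phantom design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intensity-based 2D/3D registration: model, algorithm and phantom design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drrreg)
```

## The problem

In image-guided radiotherapy the patient must be placed on the treatment
couch in the same position as in the planning CT.  Two orthogonal X-ray
radiographs (flat-panel detector, FPD) are acquired in the room, and the
residual rigid misalignment of the patient — three translations and three
rotations, the 6DOF pose — is estimated by registering the planning CT to
those radiographs.  `drrreg` implements the intensity-based formulation of
this problem: digitally reconstructed radiographs (DRRs) are computed from
the CT at a trial pose, compared with the acquired images inside
calculation regions of interest (ROIs), and the pose is refined until the
similarity is maximal.  The fitted pose is the couch correction.

## Coordinate conventions

The fixed room frame has its origin at the isocenter.  X is lateral, Y is
the couch long axis (shared by the two imaging planes), Z is vertical.  A
pose $p = (t_x, t_y, t_z, \psi, \varphi, \theta)$ acts on the volume as
$T(p) = \mathrm{Trans}(t)\,R_z(\theta)R_y(\varphi)R_x(\psi)$ about the
isocenter; angles are stored in degrees.  The rotation order is a fixed
convention — for the $\le 2^\circ$ misalignments this protocol evaluates,
any fixed order parameterizes the same neighborhood of the identity.

The default two-view geometry reproduces a clinical orthogonal FPD pair:
the vertical view fires upward (+Z, tube under the floor), the horizontal
view sideways (+X); source-to-isocenter distance 1550 mm, source-to-detector
distance 2130 mm (magnification 1.374 at the isocenter plane), 0.16 mm pixel
pitch on a 350 x 430 mm panel.  The stated 155 cm is interpreted as the
source-to-isocenter distance: reading it as isocenter-to-detector would put
the source 58 cm from the patient, which is physically implausible for a
room-mounted tube.  Both detectors share the room Y axis, which is what
makes per-view parameter partitioning (below) possible.

## DRR projection

CT numbers are converted to linear attenuation with the linear map
$\mu = \max(0, \mu_w (1 + \mathrm{HU}/1000))$, $\mu_w = 0.02\,
\mathrm{mm}^{-1}$ by default, with an optional piecewise-linear bone
emphasis above a configurable HU threshold (off by default; the clinical
CT-number weighting for the imaging beam energy is site equipment
specific).  The patient body is segmented at $-300$ HU — between air and
any tissue — keeping the largest 6-connected component and filling internal
cavities so the lungs stay inside; the projector then only walks rays
through the body's bounding box.

A DRR pixel is the line integral of $\mu$ along the ray from the source to
that pixel center.  The integrand is trilinear interpolation of the
attenuation grid with **zero padding** (the field decays continuously to
zero one voxel beyond the grid — air beyond the field of view), which keeps
it continuous everywhere.  The integral uses composite midpoint quadrature
with a step of half the smallest voxel spacing, on a step grid anchored at
the source rather than at the bounding box: interior sample positions are
then independent of the bounding box, so restricting integration to the
body region is exactly lossless on air-clamped volumes, and the quadrature
is second-order accurate (a seeded random-volume test pins it within 1% of
a 0.05-voxel-step brute-force integral; measured agreement is ~2e-5).

During optimization, a trial pose that differs from the last fully cast
DRR only by a small in-plane motion (up to 5 mm on the detector, 1 degree;
configurable) is served by rigidly resampling that DRR — translation by the
magnified shift, rotation about the projection of the isocenter — instead
of re-casting.  The rotation sign flips between the views: the vertical
detector basis (X, Y, ray +Z) is right-handed, the horizontal one
(Z, Y, ray +X) is left-handed.  The shortcut is an approximation (the
divergent beam makes a shifted object not exactly a shifted image); it is
tested against a re-cast oracle at 2% RMS of the dynamic range.

## Radiograph preprocessing

Acquired images are (1) bilinearly resampled onto the DRR grid with the
detector centers aligned, (2) converted from transmitted counts to
attenuation line integrals by $\log(I_0 / I)$ clipped at zero, with $I_0$
either supplied or estimated as the median of the brightest 5% of pixels
(the unattenuated air region), and (3) optionally edge-enhanced by unsharp
masking ($\sigma = 2$ px, strength 1).  The log conversion is needed
because detectors record transmitted intensity while DRRs are attenuation
sums; with it, a noiseless synthetic radiograph inverts exactly to its
generating DRR.  When gradient-difference scoring is active the same
unsharp operator is applied to every DRR before scoring, so both images see
the same filter; with purely statistical metrics (ZNCC, NMI) no enhancement
is applied to either side.

## Similarity metrics and the combined cost

Three ROI-restricted metrics are available, in their canonical literature
forms:

* **NMI** $(H(A) + H(B))/H(A,B)$ from a joint histogram of 64 x 64
  equal-width bins spanning each image's ROI min–max (64 bins at every
  resolution stage); 2 for identical images, ~1 for independent ones.
* **Gradient difference**: with derivative images along the two pixel axes
  and a scale $s$ on the moving image's gradients,
  $\sum A_u/(A_u + (\partial_u A - s\,\partial_u B)^2) + \sum A_v/(A_v +
  (\partial_v A - s\,\partial_v B)^2)$, where $A_u, A_v$ are the variances
  of the reference gradients; $s$ is optimized by Brent search on
  $[0.1, 10]$.  Offsets vanish under differentiation; the normalizer makes
  it asymmetric in its arguments by construction.
* **ZNCC**: the Pearson correlation of ROI pixels; invariant to positive
  affine intensity rescaling.

Each metric maps to a normalized dissimilarity in $[0, 1]$ (NMI:
$2 - \mathrm{NMI}$; ZNCC: $(1 - \mathrm{ZNCC})/2$; GD: $1 - \mathrm{GD} /
(2\,N_{\mathrm{ROI}})$, its maximum being $2 N_{\mathrm{ROI}}$ at
identity), is averaged over the two views, and the configured weights
combine them into a single cost (equal weights by default; per-site
clinical weightings are not published).  Identical image pairs cost 0
under any weights.

## Optimization

The driver is a Powell direction-set method with Brent line searches
(derivative-free — the histogram- and ROI-based costs are not smooth
enough for reliable gradients; an L-BFGS mode with numerical gradients is
provided for smooth ZNCC costs).  Line searches bracket by golden-section
expansion and are capped per parameter (32 mm translations, 8 degrees
rotations): the method is local by construction and a single line move
outside its capture range is never meaningful.  A sweep that fails to
decrease the cost by a relative `tol` terminates the stage.

**Per-view partition.**  In-plane motion is far better conditioned than
out-of-plane motion, so the vertical view estimates $\{t_x, t_y, \theta,
\varphi\}$ and the horizontal view $\{t_y, t_z, \psi, \varphi\}$, each
against its own image only; the shared couch-axis translation $t_y$ and
the rotation $\varphi$ are averaged between the views, the rest taken from
the view that observes them in-plane.  The estimate–fuse cycle repeats (up
to 10 times per stage) until the fused update falls below 0.1 mm / 0.1
degrees.  A joint 6-parameter mode over the summed two-view cost is also
provided and is the route for non-orthogonal custom view pairs; the two
modes agree within 0.5 mm / 0.3 degrees on noiseless phantoms.

**Multi-resolution.**  Three stages downsample the CT by (3,3,3), (2,2,2),
(1,1,1) (box means) while the DRR grid coarsens by the same 3/2/1 factor.
Stage radiographs are box-mean downsampled onto corner-anchored coarse
grids whose pixels cover exact blocks of fine pixels — the standard
antialiasing choice, which also averages detector noise at the coarse
stages.  Stage cost tolerances are 1e-3/1e-4/1e-5 with line-search
tolerances 0.1/0.02/0.002 (mm or degrees); coarse stages only initialize
the next level, so convergence is judged on the finest stage.  Because the
coarse stages score a smoothed surrogate of the fine cost, a stage that
drifts off an already-good incoming pose is restarted from the original
start when that scores better under the stage's own cost — a cheap
monotonicity safeguard that in particular makes an exactly self-consistent
start a true fixed point.  Iteration
and termination settings of clinical systems are not published; these
defaults are declared assumptions, chosen so the finest stage resolves
well below the 0.5 mm scale of couch positioning accuracy.

## Error protocol

Registration accuracy is reported as the target registration error
$\mathrm{TRE} = \sqrt{\Delta x^2 + \Delta y^2 + \Delta z^2}$ (mm) and
angular error $\mathrm{AE} = \sqrt{\Delta\psi^2 + \Delta\varphi^2 +
\Delta\theta^2}$ (degrees); equal per-axis errors of 0.58 mm correspond to
TRE = 1.0 mm.  The protocol: register the unperturbed setup (the residual
is the *registration offset*), displace the starting pose by (20, 20, 20)
mm and (2, 2, 2) degrees — all six components simultaneously — re-register,
subtract the offset componentwise, and summarize mean ± SD (sample SD,
n−1) per metric configuration.  Rotation differences are per-axis in the
degree parameterization, matching the small-angle regime.  Runs that fail
to converge are flagged, excluded from the summary and counted.

## What the phantoms emulate — and what they do not

Clinical accuracy tables require patient CT/FPD data, so the package ships
a parametric phantom generator whose three sites reproduce the *structure*
of the clinical problem: a bone-rich, rigid, well-textured pelvis (easiest),
a head with a skull shell, air cavities and a jaw block, and a low-contrast
thorax (hardest).  Radiographs are synthesized as intensity-perturbed DRRs:
transmitted counts $I_0 e^{-\mathrm{DRR}}$, gain/offset/gamma distortion,
seeded Poisson and/or Gaussian noise.  All randomness (2 mm structure
jitter, noise) is fixed by the seed.

Two design points came out of calibrating the phantoms against the
method's known failure modes:

* Early drafts with spherical-shell "rings" and identical, equally spaced
  ribs were pathologically self-similar: registrations locked onto the
  30 mm rib period (a 20 mm couch-axis offset sits inside the alias basin).
  Real anatomy is not periodic; the shipped phantoms use a pelvic ring
  torus about the couch axis with iliac wings and femoral heads, and a
  barrel-tapered rib cage with spine, sternum, a diaphragm/liver dome and
  pulmonary vessel trees radiating from each hilum.
* The out-of-plane rotation $\varphi$ is the weakest parameter: its image
  effect is a depth-proportional in-plane shift.  With a small tumor-only
  ROI and 2%-of-$I_0$ Gaussian noise its cost landscape is flat over
  several degrees and the noise biases the minimum by up to ~2.5 degrees.
  The thoracic protocol therefore uses a 40 mm ROI margin (vs the 20 mm
  default) so the calculation ROI spans the diaphragm edge and ribs — the
  clinical practice for this site, where ROI choice is acknowledged to be
  decisive.  The lower-lobe tumor position makes that anatomy available to
  an automatically derived ROI.

The phantoms do **not** emulate deformable anatomy (breathing, jaw or
femur repositioning), scatter, beam hardening, detector blur, or realistic
CT texture.  Passing the synthetic recovery tests therefore demonstrates
that the estimator is correct and robust under the stated noise model, not
that clinical accuracy figures transfer: with intra-fractional deformation
the clinical errors are necessarily larger, and the qualitative metric
ordering (gradient difference alone stalls in local minima; ZNCC-family
metrics are the most reliable; the thorax is the hardest site) is the
property the synthetic experiments are designed to reproduce.

## Numerical choices and degenerate inputs

* Pixels and voxels are 0-based; ROIs are half-open rectangles; world
  coordinates are mm; voxel centers sit at `origin + (i + 0.5) * spacing`.
* Histogram edges: per-image ROI min–max; a constant image inside an ROI
  is a degeneracy error, as are flat gradients (GD) and zero variance
  (ZNCC); degenerate view estimation aborts the run with the best pose so
  far flagged not-converged.
* The optimizer never accepts a cost increase; a non-finite cost aborts
  with the best point so far.
* The in-plane shortcut is refused (and the caller re-casts) beyond its
  limits; its cache is per view and per stage.
* Determinism: identical inputs and configuration give bitwise-identical
  traces and result files (modulo the recorded wall-clock runtime).

## Problem sizes used in the shipped experiments

The test-suite and acceptance experiments run 128-cubed phantoms at 2 mm
voxels with the 256 x 256 / 1.6 mm phantom detector (a 10x coarser panel
than the clinical 0.16 mm device, with the clinical source geometry) —
sizes chosen so a full three-stage registration completes in well under a
minute on one core while the finest stage still resolves sub-voxel pose
differences.  Module tests use 64-cubed instances of the same phantoms.
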