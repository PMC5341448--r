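---
title: "Aortic centreline tracking and pulse wave velocity: methods"
author: "aortapath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aortic centreline tracking and pulse wave velocity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

Aortic pulse wave velocity (PWV) is the speed at which the systolic
pressure/flow pulse travels down the aorta, a widely used marker of wall
stiffness. From cardiovascular MR it is estimated as

$$\mathrm{PWV} = \frac{\Delta x}{\Delta t},$$

where $\Delta t$ is the transit time between volumetric flow waveforms
measured by 2D phase-contrast (PC) CMR at two aortic planes — ascending
(ASC), descending (DESC) and diaphragmatic (DIAPH) — and $\Delta x$ is the
length of the aortic centreline between those planes. Because mm/ms equals
m/s, lengths in mm divided by transit times in ms give PWV in m/s directly.

The transit time is comparatively well studied; this package addresses the
path-length term. Measuring $\Delta x$ on a single 2D oblique-sagittal view
ignores out-of-plane curvature and is sensitive to plane planning and to
patient motion between scans, so the package implements (i) automated 3D
centreline tracking in volumetric images, (ii) the flow-waveform chain that
produces $\Delta t$, and (iii) the geometric and statistical machinery to
compare 2D-projected against 3D lengths.

## Centreline tracking

Tracking proceeds in three stages between two user seeds (the lumen
centres on the first PC phase at the ASC and DIAPH planes).

**Seed re-centering.** Because the patient may move between the PC scan
and the anatomical volume, each seed is re-centred: 36 rays are cast in
the cross-sectional plane (normal given by a local axis hint), the lumen
edge on each ray is the maximum intensity-gradient sample (with parabolic
sub-sample refinement), and the centre of a direct least-squares ellipse
fit through the edge points replaces the seed. Rays whose intensity range
is below 5% of the volume's range are discarded; fewer than six valid
edges raises an error and the caller keeps the original seed with a
warning.

**Multi-scale vesselness.** The tubularity filter computes, at each
Gaussian scale $\sigma$ (in mm), the image Hessian from scale-space
derivatives and combines its magnitude-sorted eigenvalues
$|\lambda_1|\le|\lambda_2|\le|\lambda_3|$ through the classic three-ratio
response

$$V = \left(1-e^{-R_A^2/2\alpha^2}\right)\,
      e^{-R_B^2/2\beta^2}\,
      \left(1-e^{-S^2/2c^2}\right),$$

with $R_A = |\lambda_2|/|\lambda_3|$,
$R_B = |\lambda_1|/\sqrt{|\lambda_2\lambda_3|}$ and
$S = \sqrt{\lambda_1^2+\lambda_2^2+\lambda_3^2}$; $V$ is zeroed wherever
the eigenvalue signs contradict the polarity (a bright lumen needs
$\lambda_2,\lambda_3 < 0$; dark-blood images use the opposite gate rather
than intensity inversion, which avoids assumptions about the intensity
range). Defaults $\alpha = \beta = 0.5$ and $c$ = half the maximum
Frobenius norm per scale are the filter's canonical choices. Derivatives
are $\gamma$-normalised ($\times\sigma^2$, $\gamma = 1$) so responses are
comparable across scales, and the per-voxel maximum over the scale set is
taken. Scales are interpreted literally as $\sigma$ in mm; the default set
is $\{4, 6\}$ mm, matching expected aortic calibres, and is configurable
because the diameter-to-$\sigma$ mapping is a convention, not a fact.
Anisotropic grids are handled by per-axis $\sigma/\mathrm{spacing}$
kernels, so everything is computed in physical mm.

**Minimal path.** A speed map $F = V + \varepsilon$ (floor
$\varepsilon = 10^{-3}$, making off-vessel travel about a thousand-fold
slower) feeds bidirectional fast marching: the eikonal equation
$|\nabla T|\,F = 1$ is solved from both seeds with an upwind scheme on the
6-neighbourhood. Numerical choices that matter:

* *Second-order differences.* One-sided second-order upwind differences
  are used wherever two accepted in-line neighbours exist (with the usual
  causality condition and first-order fallback). The first-order scheme's
  diagonal error is large enough to bow backtraced geodesics by more than
  a voxel at aortic path lengths; the second-order scheme reduces the
  uniform-speed distance error by roughly an order of magnitude.
* *Source factorisation.* Any upwind scheme has O(1) relative error next
  to a point source, so a small ball around each seed (radius 6 of the
  smallest spacing, safely inside an aortic lumen) is initialised with
  the analytic distance times the local slowness and frozen.
* *Meeting rule.* Propagation stops shortly after the fronts first share
  an accepted voxel (a slack of 4 voxels of local travel grows a small
  doubly-accepted lens), and the meeting voxel is the argmin of
  $T_\mathrm{start}+T_\mathrm{end}$ over that lens.
* *Valley-corrected backtrace.* The path is traced by gradient descent on
  the trilinearly interpolated arrival time (step 0.25 of the smallest
  spacing), and — inside the lens — each step is followed by a transverse
  parabolic correction toward the valley line of
  $T_\mathrm{start}+T_\mathrm{end}$. The minimal path is exactly the
  transverse minimum of that sum, so this removes the kink that a single
  discrete meeting voxel would imprint; without it the two half-paths form
  a visible "tent" through the meeting voxel.

**Open active contour.** The raw path is decimated to ~1 mm control
spacing and evolved under two equally weighted terms with pinned
endpoints: a second-difference (curvature-minimising) regulariser and a
centring term that pulls each interior point toward the lumen centre in
the plane normal to the local tangent. The centre is estimated per point
by the same ray-cast edge detector as the seed re-centering, followed by a
least-squares circle fit; the normal section of a constant-radius bent
tube is an exact circle, so the target is unbiased even on the arch,
where the multi-scale vesselness ridge is measurably displaced toward the
inside of the bend and too flat to centre a contour by gradient ascent
(which is why the centring force acts on the intensity image, not on the
response map). Each iteration solves the regularised least-squares system
semi-implicitly; evolution stops when the largest displacement falls below
0.01 mm or plateaus at the centring estimator's noise floor (~0.05 mm), in
which case the last two chains are averaged. The refined chain is
resampled at 0.1 mm by arc-length-parameterised linear interpolation.

A tracing is declared *failed* when any point of the result lies outside
the lumen — operationalised on phantoms as a distance to the analytic
centreline exceeding the lumen radius, or by a supplied lumen mask.

## Flow waveforms and transit time

Lumen segmentation of PC frames uses the same ray-cast edge detection
with a least-squares circle (36 rays), propagated across phases by seeding
each fit at the previous phase's centre. Volumetric flow is the sum of
through-plane velocity over pixels inside the circle times the pixel area
(mm³/s, reported as ml/s).

The foot-to-foot transit time locates, per waveform, the intersection of
the systolic upstroke tangent with the pre-systolic baseline. The
"average maximum gradient" tangent is operationalised as the least-squares
line through samples whose gradient is at least 80% of the peak upstroke
gradient (threshold configurable); the baseline is the minimum before the
upstroke onset (gradient < 10% of peak). Because the foot is a
continuous-time quantity, the waveform is first spline-resampled to at
most 1 ms so neither the window selection nor the intersection is
quantised at the acquisition's temporal resolution (8.4 ms by default);
the small tangent-construction bias this leaves is common to both
waveforms of a pair and cancels in the difference. Transit times are
signed; the PWV layer rejects non-positive values as non-physical.

## 2D-vs-3D comparison

The "2D method" is modelled as orthogonal projection of a centreline onto
a total-least-squares oblique-sagittal plane (SVD of the centred points),
clipped where the PC flow planes intersect the measurement plane.
Projection can only shorten a curve, with equality exactly for curves
parallel to the plane — so any 2D measurement is a lower bound on the 3D
length. Rigid motion of the anatomy with fixed flow planes preserves the
3D arc length but moves the clip marks, changing the clipped 2D length:
this is the mechanism by which 2D measurements can paradoxically *exceed*
3D ones in practice, and `simulate_motion()` reproduces it directly.

Agreement statistics follow the conventions of the field: Bland–Altman
bias with 1.96 SD limits of agreement, paired Wilcoxon signed-rank tests
(exact by dynamic-programming enumeration of the sign-flip distribution
for up to 25 non-zero differences, midranks for ties; normal approximation
with tie and continuity correction beyond), a one-sample
Kolmogorov–Smirnov normality screen against a normal with estimated
parameters (conservative for that reason — its power on skewed samples is
below the nominal level a Lilliefors correction would restore, which is
documented rather than corrected since the screen only gates the switch to
median/IQR summaries), and type-7 (linear-interpolation) quantiles so
summaries are bit-reproducible.

## What the phantoms emulate — and what they do not

The synthetic fixtures make every stage testable without patient data:

* **Tube phantoms** — straight (100 mm), half-circle arch (R = 30 mm) and
  a tangent-continuous "candy-cane" (R = 25 mm arch with 30/50 mm limbs,
  chosen so the tube fits a 128 mm field of view with a two-lumen-radius
  margin) with a 6 mm lumen radius, both bright- and dark-lumen, 1 mm
  Gaussian blur and additive noise (SD 2 at 90 intensity-unit contrast).
  Ground-truth lengths are closed-form, never numerically integrated. A
  dropout variant attenuates 50 mm of the arch to background intensity,
  emulating the signal-loss failure mode of bright-blood sequences; the
  window is wide enough that the straight shortcut across it necessarily
  leaves the lumen (11.5 mm chord sagitta against the 6 mm radius), so
  the failure is geometrically detectable.
* **Waveforms** — flat baseline, sigmoidal upstroke whose maximum-gradient
  tangent intersects the baseline exactly at the specified foot time
  (time constant = upstroke duration / 4), then exponential decay. Foot
  delays between paired waveforms are therefore analytic.
* **PC stacks** — disks of parabolic through-plane velocity whose
  volumetric flow has the closed form $v_\mathrm{peak}\pi r^2/2$.

All generation is deterministic given the seed. What the phantoms do *not*
emulate: MR physics (coil shading, phase wraps, k-space artefacts),
intensity inhomogeneity along the vessel, non-circular or tapering lumina,
branching vessels and adjacent bright structures (the pulmonary artery and
heart that real failed tracings wander into), and breathing-state
differences between scans. Passing the phantom battery therefore
demonstrates the geometric and numerical correctness of the chain, not
clinical robustness.

## Problem sizes and runtime choices

The validation battery runs three geometries at two polarities on
128-voxel 1 mm isotropic grids with the default scale set, plus a
64-voxel uniform-speed grid for the eikonal oracle; unit tests use
64-voxel tubes. These sizes keep at least eight voxels across the lumen
(the smallest feature the scale set targets) while remaining comfortable
on a single CPU.

## Known limitations

* The tracker needs both seeds inside the vessel and a connected
  vesselness ridge; it cannot recover from a fully attenuated arch other
  than by flagging the failure (waypoint-assisted tracking is out of
  scope).
* The snake assumes a locally circular cross-section; strongly elliptical
  or dissected lumina would bias its centring target (the seed
  re-centering, which fits a full ellipse, is less affected).
* The foot-to-foot estimator assumes a single clean systolic upstroke per
  waveform; arrhythmic or heavily aliased waveforms are rejected rather
  than guessed at.
* The KS normality screen is conservative (estimated parameters), as
  noted above.
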