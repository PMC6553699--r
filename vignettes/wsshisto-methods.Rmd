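---
title: "Mapping wall shear stress onto serial plaque histology: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping wall shear stress onto serial plaque histology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wsshisto)
```

## The problem

Wall shear stress (WSS) — the frictional force per unit area that flowing
blood exerts on the endothelium, in Pa — is a candidate driver of
atherosclerotic plaque composition. Testing that hypothesis on human carotid
plaques requires linking two data worlds that never share a coordinate frame:
patient-specific WSS maps, computed on the in vivo lumen geometry, and serial
histology of the excised endarterectomy specimen, which is the gold standard
for plaque composition but lives in its own deformed, sectioned 2D space.

`wsshisto` implements a registration pipeline that carries both worlds into
one shared frame — the stack of en-face photographs taken of each 1 mm
transverse tissue section — and then quantifies WSS and plaque morphology on
matched radial sectors of each cross-section:

1. **Stack assembly.** Adjacent en-face photos are registered rigidly
   (rotation + translation; all photos share one calibrated pixel size) from
   labelled landmarks, and the transforms are accumulated into the first
   photo's frame.
2. **Cross-modality registration.** In vivo MRI is registered to ex vivo MRI,
   and ex vivo MRI to the photo stack, each time by a landmark-anchored
   similarity transform (rotation, isotropic scale, translation) followed by
   a contour-driven 2D B-spline free-form deformation. Histology sections are
   registered to their en-face photos by per-slice similarity transforms.
3. **Projection.** The composed chain maps the WSS surface into the en-face
   frame. For each section, mesh vertices within an axial window of
   ±0.3 mm are pooled, assigned to 8 radial sectors about the lumen
   centerline point, and reduced to per-bin mean/min/max WSS. Plaque
   thickness per bin is the mean shortest distance from the lumen border to
   the media border of the registered histology contours.
4. **QC and exclusion.** Per-section Dice coefficients and Hausdorff
   distances quantify residual mismatch; bins carrying observer-assigned
   error flags (histology artefact, histology–photo mismatch, MRI–photo
   mismatch) are excluded by set-union semantics.
5. **Sensitivity.** The WSS field is deliberately relocated axially
   (±0.3, ±0.6 mm) and the per-bin WSS change, paired Wilcoxon tests and the
   WSS–thickness Pearson correlations are re-evaluated.

Because no patient data ship with the package, a first-class phantom module
generates synthetic specimens with known ground truth, and every claim the
test suite makes is anchored to analytic values on those phantoms.

## The phantom: a stated world

`phantom_spec()` defines a single-lumen tube (no bifurcation — the
bifurcation's only pipeline role, anchoring the rigid registration, is played
by a designated reference slice). Its WSS magnitude on the lumen surface is

$$\tau(z, \theta) = \tau_0 + g\,z + A\cos\theta,$$

with baseline $\tau_0$ (default 2 Pa), axial gradient $g$ (default
0.1 Pa/mm), and circumferential amplitude $A$ (default 0.5 Pa, constrained to
$A \le \tau_0$ so WSS stays non-negative). Defaults reflect the pipeline's
stated world: 12 sections at 1 mm spacing (the sectioning protocol), a
stenotic Gaussian radius profile dropping from 3 mm to 1.2 mm (a >70 %
area stenosis, typical of endarterectomy candidates), a 1.5 mm wall, and a
time-averaged scalar field — all reported per-bin statistics are spatial, so
the cardiac-cycle dimension is collapsed to one scalar per vertex.

Truth transforms are drawn per modality: a similarity (rotation ±25°, scale
0.9–1.15, translation ±2 mm — or user-fixed values) plus a B-spline
free-form deformation on a coarse 4×4 control grid with displacements uniform
in $[-d, +d]$, where $d$ is `deformation_magnitude_mm`. Modality contours are
the en-face geometry mapped through the *inverses* of these chains (B-spline
inverses by fixed-point iteration), so applying the truth chain reproduces
the en-face contours to numerical tolerance by construction. With $d = 0$
every truth transform is the identity and the pipeline must reproduce the
closed-form bin values exactly.

Two deliberate modelling choices deserve emphasis:

* **Landmarks carry only the similarity.** Fiducial correspondences are
  generated from the similarity component of each truth chain; the B-spline
  deformation applies to contours (tissue) but not to the landmark pairs.
  This mirrors the pipeline's own division of labour — points anchor the
  rigid step, drawn contours drive the non-rigid step — and makes the
  similarity-recovery tolerances (1° / 1 % / 0.1 mm) meaningful. With 1 mm of
  non-rigid contamination on the landmarks themselves, no estimator could
  meet them.
* **Thickness–WSS coupling.** Setting `thickness_wss_coupling = k > 0` makes
  the wall thickness $t(z,\theta) = t_0(z) - k(\tau - \tau_0)$, i.e. plaque
  thickness anti-proportional to local WSS. This constructs the ground truth
  for the correlation-robustness tests; $k = 0$ (the default) leaves
  thickness circumferentially uniform, in which case per-location
  correlations are undefined (zero variance) and are reported as skipped.

What the phantom does **not** emulate: bifurcating geometry, MRI contrast
and noise, segmentation error, histology processing artefacts (error flags
are inputs, as in practice they come from observer consensus), and
out-of-plane (z) tissue distortion. A green test therefore establishes the
correctness of the geometry/statistics machinery under the stated world, not
robustness to real-world segmentation noise.

## Numerical choices

**Similarity fits** use the closed-form 2D least-squares estimator
(Umeyama/Procrustes with isotropic scale). It is exact on noise-free
correspondences; the test suite also checks it against a brute-force
optimizer on random instances. Degenerate configurations (coincident points)
are rejected, not regularized.

**B-spline registration.** The named metric is mean squares between
rasterized contour distance maps. We rasterize the *fixed* stack's unsigned
distance-to-contour field at 0.1 mm/pixel and minimize its mean square at the
transformed moving contour points — the same metric restricted to the moving
contour, where the moving distance map vanishes identically. This keeps the
objective smooth, differentiable and directly interpretable: its square root
bounds the mean post-registration contour distance. The optimizer is
stochastic gradient descent over random subsets of ~120 contour points with
step decay $a_k = a_0 (1 + k/50)^{-0.602}$ (the 0.602 exponent is the
classic Spall/ASGD choice), $a_0$ calibrated so the first step moves no
control point more than 0.15 mm, 500 iterations by default, control-grid
spacing 5 mm, and a deterministic seed. The best iterate (by full-set metric)
is kept, so the reported metric trace is non-increasing over accepted
iterations and the post-registration contour distance can never exceed the
pre-registration one. The sampler is a package-local linear congruential
generator, so registration does not perturb the caller's RNG stream.

**B-spline support.** Control grids are built with a 1.5-spacing margin
around the working bounding box; points outside the valid support raise an
error rather than extrapolating. Inverses are computed by fixed-point
iteration ($x \leftarrow y - u(x)$), which converges for the sub-unit-Jacobian
warps in scope and is validated to 1e-9 in the tests.

**Centerline.** The reference method computes a 3D centerline from maximally
inscribed spheres of the Voronoi diagram. Its only downstream role here is
the per-section centerpoint seeding the radial sectors, so this package
computes the slice restriction of the same criterion: the 2D maximal
inscribed circle per contour, seeded from interior Voronoi vertices of the
densified boundary (`deldir`), polished by Nelder–Mead on the exact
distance-to-boundary function, then smoothed along z with a centered
3-section moving average. End sections, where the full window does not fit,
keep their raw centers — a truncated average would bias a drifting
centerline. If smoothing pushes a point outside the lumen, the raw point is
kept. An exhaustive 0.01 mm grid search is the independent test oracle.

**Radial bins.** Bin 0's lower edge lies along the +x axis of the en-face
frame (configurable via `bin_zero_deg`); wedges are half-open
counter-clockwise intervals, so every point (except the undefined
centerpoint itself) falls in exactly one bin. Within-bin statistics are
vertex-based, matching nearest-neighbour pick-up of mesh vertex values; empty
bins are `NA` and flagged, never imputed as zero. Whether axial averaging
precedes binning or vertices are pooled across the window is immaterial for
the mean (the implemented pooling and any two-stage average agree there);
min/max are spatial extremes of the time-averaged field over the pooled
vertices.

**Projection window.** The ±0.3 mm half-width matches half the in vivo axial
resolution. Window membership uses a 1e-9 mm tolerance on the boundary so
that mesh vertices lying exactly on the window edge are included
symmetrically — this is what makes the symmetric-window mean of a linear
field exact.

**Dice and Hausdorff.** Dice is computed on masks rasterized from contours at
0.05 mm/pixel on a shared grid; two empty masks have Dice 1 by convention,
one empty mask is an error. Hausdorff is the symmetric continuous-curve
distance: both contours are resampled at ≤0.02 mm arc spacing and exact
point-to-segment distances are used, so the value refers to the curves, not
to pixel sets.

**Wilcoxon signed-rank.** Zero differences are dropped; ties receive average
ranks. For n ≤ 25 the null distribution of the positive-rank sum is computed
exactly by convolution over sign assignments on doubled (hence integral)
ranks — mathematically identical to enumerating all $2^n$ sign vectors, which
the tests verify literally for n ≤ 10. Above 25, a normal approximation with
continuity and tie correction is used. Two-sided p-values are
$\min(1, 2\min(P_{\le}, P_{\ge}))$.

**Relocation convention.** `relocate_surface(field, dz)` adds `dz` to the
field's vertex z-coordinates (positive dz moves the field cranially);
sections, centerpoints and bins stay fixed, so only the sampling window
shifts relative to the field. For a field linear in z this gives the exact
identity $|\Delta\overline{\tau}| = |g\,dz|$, the analytic analogue of the
mismatch-simulation scaling. Per-axial-location correlation tests across the
sweep are reported raw at $\alpha = 0.05$ with no multiple-testing
correction, matching the source analysis; locations with fewer than three
usable bins, or zero variance, are skipped and logged.

## Tolerances the tests assert

* Zero-deformation round trip: bin means equal the closed-form values to
  1e-6 Pa for constant and linear fields. For the $\cos\theta$ component the
  mesh's midpoint sampling of the sector integral carries an
  $O(\Delta\theta^2) \approx 3\times10^{-4}$ relative error, so
  circumferential cases are asserted at the 1 % projection tolerance instead.
* Registration recovery on phantoms (similarity 30°/1.2 plus ≤1 mm B-spline):
  rotation within 1°, scale within 1 %, translation within 0.1 mm, and
  post-chain lumen Hausdorff below 0.2 mm (measured values are ~0.03–0.05 mm).
* Kernel oracles: Wilcoxon equals literal sign enumeration (n ≤ 10) exactly;
  Pearson matches the covariance formula to 1e-12; Dice/Hausdorff match
  brute-force pixel counting and dense point-pair scans.

## Known limitations

* Registration is 2D-per-slice after rigid z-anchoring by matched slice
  index; longitudinal tissue deformation is assumed minimal, and no z-warping
  B-spline is fitted. The axial-mismatch simulation exists precisely to bound
  the consequences of that assumption.
* The number of anchor points for the cross-modality similarity fit is a
  user/phantom input (≥ 2; the phantom supplies 4); the method is exact on
  noise-free points but no landmark-noise model is provided.
* Volume I/O covers uncompressed/gzipped NIfTI-1 and MetaImage with scalar
  payloads and diagonal orientation; rotated sforms are not applied.
* DSC/HD summaries average per section (not per bin), and Table-style
  cross-specimen values are reported to two decimals; both conventions are
  fixed and documented rather than configurable.
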