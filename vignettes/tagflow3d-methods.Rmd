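---
title: "Measuring 3D myocardial deformation from tagged MR: models and methods"
author: "tagflow3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring 3D myocardial deformation from tagged MR: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

SPAMM tissue tagging imprints dark saturation stripes on the myocardium at
the cardiac trigger; the stripes are material — they move with the tissue —
so a cine acquisition of a tagged heart carries dense landmarks from which
the deformation of the left-ventricular (LV) wall can be recovered. With
only the conventional in-plane tag grid, motion through the imaging plane is
unobservable (the aperture problem). Adding a third, oblique tag-plane
family makes the full 3D velocity observable from a single acquisition, and
a volumetric optical-flow method (OFM) can then track every voxel of the
wall through systole with sub-voxel resolution. `tagflow3d` implements that
pipeline: a synthetic tagged LV phantom with exactly known motion, the
hierarchical 3D optical-flow tracker, Green-Lagrange strain analysis, and
LV sectorization with regional tables and bull's-eye maps.

## The tracker

Motion between two adjacent phases is estimated by minimizing the sum of
squared differences (SSD)

$$\mathrm{SSD}(\mathbf u) \;=\; \sum_{\mathbf r \in \Omega}
\bigl[ L_b(\mathbf r) - L_a(\mathbf r - \mathbf u(\mathbf r)) \bigr]^2$$

on band-pass filtered image pairs $(L_a, L_b)$, in two stages:

* **Global stage.** A 6-parameter model (translation plus small-angle
  rotation about the volume center) is estimated over the entire image on a
  Gaussian pyramid, coarse to fine (3 levels, 8 Gauss-Newton iterations per
  level by default). The pyramid makes the quadratic approximation valid
  for large bulk motion.
* **Local stage.** Initialized from the global motion, a per-voxel 3-vector
  flow is refined on Laplacian-filtered (difference-of-Gaussians) data by
  Gauss-Newton iterations over an inspection window centered on each voxel
  (default $3\times3\times3$; 1 pyramid level, 8 iterations). Band-pass
  filtering removes the local intensity offset so that matching is driven
  by structure rather than brightness — important because T1 relaxation
  brightens the tags from frame to frame.

Each Gauss-Newton increment solves the normal equations built from the
residual and the spatial gradients, computed as forward and backward
differences at $\pm 1$ voxel and averaged **between the two images**
(a symmetric linearization; it makes a single step exact when the intensity
surface is quadratic). Steps are safeguarded: a step that increases the SSD
is halved up to 4 times and then rejected, so the accepted SSD sequence is
non-increasing, which is also the convergence test. Near-singular
$3\times3$ systems receive diagonal loading ($10^{-6}$ of the trace);
voxels whose normal matrix has condition number above $10^6$ (no local
structure) keep the global-stage motion and are flagged in the validity
mask.

Pair-wise (Eulerian) flows are integrated into Lagrangian displacement: the
trajectory of the reference-grid point $\mathbf r_0$ is updated with the
flow sampled trilinearly *at its current tracked position*,
$U_{p+1}(\mathbf r_0) = U_p(\mathbf r_0) + u_{p\to p+1}(\mathbf r_0 + U_p(\mathbf r_0))$,
maintaining sub-voxel positions throughout. The Lagrangian reading of
"vector integration" is required for material-point strain to be
meaningful.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `global_levels` / `global_iters` | 3 / 8 | Gaussian-pyramid depth and Gauss-Newton iterations of the global stage |
| `local_levels` / `local_iters` | 1 / 8 | pyramid depth and per-voxel iterations of the local stage |
| `window` | 3 | in-plane extent (voxels) of the local inspection window |
| `window_z` | 3 | through-plane extent of the window; 1 restricts it to the voxel's slice |
| `filter_sigma` | 1 voxel | scale of the Gaussian / difference-of-Gaussians pre-filters |
| `regularization` | 1e-6 | diagonal loading fraction for near-singular systems |
| `cond_max` | 1e6 | condition-number threshold for the validity mask |

The stage structure (Gaussian filtering for the global stage, Laplacian for
the local stage, 3/8 and 1/8 level/iteration counts, the 3-wide window) is
the published optimum of the method; we found the through-plane window
extent to be load-bearing and expose it separately (`window_z`): an
in-slice window (`window_z = 1`) roughly doubles the through-plane error on
the default phantom, so the volumetric window is the default.

## The phantom

The generator builds an annular LV wall (defaults: endo/epi radii 10/17 mm,
30 mm long-axis extent on a $64\times64\times24$ grid at
$0.70\times0.70\times1.5$ mm) with a dark cavity and background, multiplied
by three tag-plane families: two in-plane (normals along x and y) and an
oblique third family whose normal makes angle $\beta$ with the z-axis at a
fixed 45 degree azimuth, $\mathbf n = (\cos\beta\cos45^\circ,
\cos\beta\sin45^\circ, \sin\beta)$. Stripes are hard-edged level sets
$|\,\mathbf r\cdot\mathbf n - k\,s\,| < w/2$ (defaults $w = 2$, $s = 6$
voxels; optional Gaussian edge smoothing), saturated to zero at tag
application and recovering as $SI = M_0(1 - e^{-t/T_1})$ with $T_1 =
900$ ms; phase times default to a uniform 50–350 ms grid (systole at
roughly 100 bpm).

**Texture.** The wall carries a seeded band-limited speckle (correlation
length 0.6 voxel, modulation depth 0.5, tanh-squashed so intensities stay
in $(0, M_0]$). The depth and fineness matter scientifically: tag planes
are sparse along any one axis, so much of the through-plane tracking
information in a real scan comes from tissue texture; a smooth, low-contrast
wall makes the phantom strictly less informative than real data. (Notably,
the published tag-angle sweep finds its *best* through-plane error when the
third family carries no z-information at all, which is only possible if
texture dominates z-tracking.)

**Motion.** Systole is modelled as three additive components, each linear
in the phase fraction $\lambda$ (a 0 to 1 ramp over phases):
torsion linear in z with opposite sign at apex and base (the "wringing"
effect; default $\pm4^\circ$), uniform in-plane radial contraction toward
the LV axis (default fraction 0.10), and longitudinal shortening linear in
z with the apex fixed (default 2.5 mm at the base). Peak motion is about
3 px in-plane and 1.7 slices through-plane. The linear longitudinal profile
is a deliberate simplification: the phantom's job is to provide *exactly
known* motion, not a physiological one.

Because the forward displacement $\mathbf u_\lambda = \lambda \mathbf
u_1(\mathbf r)$ is affine in the in-plane coordinates given z, and the
z-map is linear, the deformation map has a closed-form inverse; the images
are backward-warped with that exact inverse while the exported ground truth
is the exact forward displacement on the reference grid. The truth is
therefore consistent with the images to machine precision — tracker scores
are not contaminated by any Eulerian/Lagrangian approximation.

**Noise.** Two models are provided. `noise_mode = "baseline"` (default for
the noise experiment) adds a single zero-mean Gaussian realization
($\sigma$ = percent of the maximum intensity) to the tagged baseline
volume *before* warping, so the noise pattern deforms with the tissue like
acquired texture — this matches the published experiment's construction and
its observation that performance is maintained at 20% noise.
`noise_mode = "per_phase"` (and `add_noise()`) adds independent
observation noise to every frame; it degrades tracking much faster, since
independent noise cannot be matched across frames.

### What the phantom does not emulate

No Bloch-equation simulation, k-space sampling, slice-profile or PSF blur,
motion artifacts, or respiratory/cardiac gating effects; fading is the
closed-form recovery only, and frames are produced by trilinear warping of
a discrete volume. That last point has a measurable consequence: two frames
at different sub-voxel motion phases are attenuated differently by the
interpolation, which is the dominant per-pair error source on the clean
phantom (a pair "reference vs warped" tracks to $10^{-8}$ voxels, a pair
of two differently-phased warps to about 0.2 voxels). Passing tests on
this phantom therefore demonstrates correct recovery of smooth systolic
motion from tagged, fading, textured images — not robustness to scanner
physics that the generator does not model.

## Strain analysis

From the integrated displacement (voxels, converted to mm via the voxel
spacing), the deformation gradient $F = I + \partial\mathbf u/\partial
\mathbf X$ is computed by central differences in the mask interior and
one-sided differences at mask boundaries, in material (reference, mm)
coordinates. The Green-Lagrange tensor $E = \tfrac12(F^\top F - I)$ is
exactly zero for rigid motion and valid for large deformation. The
symmetric eigen-problem of $E$ gives the principal strains $\varepsilon_1
\ge \varepsilon_2 \ge \varepsilon_3$ — positive values are lengthening or
thickening, negative shortening; $\varepsilon_1$ is interpreted as radial
wall thickening and $\varepsilon_3$ as combined
circumferential-longitudinal shortening — and the angle $\alpha \in
[0^\circ, 90^\circ]$ between the $\varepsilon_1$ eigenvector and the
in-plane radial direction from the endocardial center ($\pm$ sign of the
eigenvector is irrelevant by construction).

Differentiating a per-voxel tracked field amplifies tracking noise by the
reciprocal grid spacing; `deformation_gradient()` therefore offers optional
Gaussian pre-smoothing of the displacement (off by default; exact for
affine deformations). The package's stretch-recovery validation uses
$\sigma = 1.5$ voxels, consistent with deriving strain from an "analytic"
(smooth) displacement representation.

## Regional analysis

Endo/epicardial contours (closed polygons per slice, mm) may be supplied
sparsely: they are resampled to a fixed vertex count by arc length,
linearly interpolated between drawn slices, and propagated to other phases
by advecting vertices with the measured displacement. Voxels inside the
epicardial and outside the endocardial polygon form the myocardial mask.
From the anterior RV insertion point, each slice is divided into 12
circumferentially equal sectors (counterclockwise viewed from the apex;
boundary ties go to the lower sector), mapped pairwise to the six
anatomical regions AS, PS, PST, PL, AL, ANT; slices between the apical- and
basal-most masked slice split into three equal longitudinal levels. Outputs
are a 6-region x 3-level mean +/- SD table of $\varepsilon_1$ and
$\varepsilon_3$ (voxel SD for one subject, across-subject SD for several)
and a 22-ring x 12-sector bull's-eye matrix (rings = equal longitudinal
bins, apex innermost; empty cells are reported missing, never zero).

## Validation experiments and numerical choices

* `rms_error()` — per-axis RMS over myocardial voxels, in voxels and mm.
* `beta_sweep()` — regenerate tags for $\beta = 0^\circ$ to $90^\circ$ in
  $15^\circ$ steps, track, score. On this phantom the through-plane error
  *decreases* monotonically with $\beta$: for a volumetric-window tracker
  the slice-parallel tag bands at $\beta = 90^\circ$ are sharp material
  z-edges and a net through-plane landmark gain. The published sweep (on a
  real ex-vivo heart, whose saturated slices lose their texture landmarks)
  reports the opposite ordering at high $\beta$; the discrepancy is a
  genuine limitation of the surrogate, discussed honestly rather than
  tuned away.
* `noise_sensitivity()` — 0/5/10/15/20% noise, 3 realizations per level,
  RMS reported against both the ground truth and the noiseless baseline
  estimate, in voxels and mm (both unit systems are reported everywhere
  because the published results mix them).
* `compare_2d_3d()` — the same data tracked slice-wise in 2D vs in 3D;
  in-plane RMS pools x and y. With through-plane motion present, 2D
  tracking projects it into apparent in-plane motion and 3D tracking wins
  decisively (about 70% in-plane RMS reduction on the default phantom).

Problem sizes used by the validation suite: the headline experiment runs
the full $64\times64\times24$, 8-phase phantom; the tag-angle sweep uses a
$48\times48\times16$, 5-phase phantom (7 trackings), chosen so the entire
suite completes in a few minutes on one core.

## Known limitations

* The tag-angle-sweep ordering at high $\beta$ does not reproduce the
  published inversion (see above); all other phantom results do.
* The 2D tracker inherits ~$\sqrt{3}$ more interpolation-artifact noise
  than the 3D tracker simply from its smaller window, so 2D-vs-3D
  comparisons on this phantom contain a window-size component on top of the
  through-plane confound.
* Contour temporal propagation assumes the contours are referenced to the
  tracking reference phase.
* Sectorization uses the per-slice myocardial-mask centroid as the
  endocardial center; identical for an annular wall, an approximation for
  strongly asymmetric walls.
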