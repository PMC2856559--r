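# tagflow3d

Quantifying 3D left-ventricular (LV) deformation from 3D SPAMM-tagged
cardiovascular MR image sequences. The package is for cardiac-imaging
researchers who want dense, sub-voxel myocardial motion and strain from a
single tagged cine acquisition — and for methodologists who need a tagged
phantom with exactly known ground-truth motion to score any tracker
against.

SPAMM tagging imprints dark saturation stripes that move with the tissue.
Two in-plane tag-plane families plus an oblique third family (at angle β to
the slice axis) make full 3D motion observable from one acquisition,
resolving the aperture problem that limits conventional 2D tag analysis.

## What it computes

**Tracking.** Voxel motion between adjacent phases is estimated by
minimizing the sum of squared differences on band-pass filtered images,

SSD(u) = Σ_r [ L_b(r) − L_a(r − u(r)) ]²,

in two stages: a global translation+rotation fit on a 3-level Gaussian
pyramid, then a per-voxel Gauss-Newton refinement on Laplacian-filtered
data over a 3×3×3 inspection window (8 iterations each, SSD-tested
convergence, descent-safeguarded steps). Pair-wise flows are
vector-integrated along material trajectories into the Lagrangian
displacement U_p(r₀) of every reference-grid point.

**Strain.** From U the deformation gradient F = I + ∂u/∂X (central
differences, material mm coordinates) gives the Green-Lagrange tensor
E = ½(FᵀF − I), its principal strains ε₁ ≥ ε₂ ≥ ε₃ (ε₁ ≈ radial wall
thickening, ε₃ ≈ circumferential-longitudinal shortening) and the angle α
between the ε₁ direction and the local radial direction.

**Phantom.** A synthetic tagged LV (annular textured wall, three tag
families, T1 = 900 ms tag fading, systolic torsion + radial contraction +
longitudinal shortening, optional Gaussian noise) generated together with
its exact forward displacement, via a closed-form inverse warp — so any
tracker can be scored without approximation.

**Regional analysis.** Contour interpolation and rasterization, 12
circumferential sectors from the anterior RV insertion point mapped to the
six anatomical regions (AS, PS, PST, PL, AL, ANT) × 3 longitudinal levels,
regional mean ± SD strain tables, and 22-ring × 12-sector bull's-eye maps.

## Worked example

```r
library(tagflow3d)

config  <- phantom_config(grid_shape = c(48, 48, 16), n_phases = 5,
                          endo_radius = 8, epi_radius = 13, wall_extent = 18)
phantom <- lv_phantom_sequence(config, beta_deg = 30)
phantom
#> lv_phantom: 48 x 48 x 16 voxels, 5 phases, 3 tag families
#>   myocardial voxels: 8208
#>   motion: torsion 4 deg, radial contraction 0.1, shortening 2.5 mm

fit <- track_sequence(phantom$seq)     # the fitting function
fit
#> ofm_track (3d): 5 phases on a 48 x 48 x 16 grid
#>   invalid voxels: 31.19%

err <- rms_error(fit$displacements[[5]], phantom$truth[[5]],
                 phantom$mask, config$spacing)
lapply(err, round, 3)
#> $vox
#>     x     y     z
#> 0.363 0.356 0.496
#>
#> $mm
#>     x     y     z
#> 0.254 0.249 0.744
```

The per-axis RMS error of the tracked end-systolic displacement over the
8208 myocardial voxels is about a third of a voxel in-plane and half a
voxel through-plane — sub-pixel in every direction. (The flagged "invalid"
voxels are structureless background; none lie in the myocardium.) Strain
and regional summaries follow the same flow:

```r
strains <- strain_analysis(fit, phantom$mask, smooth_sigma = 1.5)
strains
#> principal_strain_field: 8208 voxels
#>   eps1: median 0.0155   eps3: median -0.1598   alpha: median 46.0 deg

sectors <- sectorize(phantom$mask, rv_insertion = c(40, 23))
tab <- regional_strain_table(strains, sectors)   # 6 regions x 3 levels
be  <- bullseye(strains$eps1, sectors)
be
#> bullseye: 22 rings (apex -> base) x 12 sectors, 120 empty cells
```

The ε₃ median of −0.16 reflects the prescribed systolic contraction and
torsional shear; ε₁ is near zero because the simple phantom motion contracts
the wall without radial thickening.

A shell entry point wrapping the same functions is installed at
`inst/cli/tagflow3d` (subcommands `phantom`, `track`, `strain`, `regions`,
`validate`), e.g.

```sh
tagflow3d phantom --beta 30 --tag-width 2 --tag-spacing 6 --seed 42 --out out/
tagflow3d track --input out/phantom.nii.gz --out out/disp.nii.gz
```

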