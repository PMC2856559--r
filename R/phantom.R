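#' Phantom configuration
#'
#' Describes the synthetic tagged left-ventricle phantom: grid geometry,
#' voxel spacing, cardiac phase timing, the annular LV geometry, intensity
#' levels and the T1 relaxation constant governing tag fading.
#'
#' Defaults emulate a short-axis acquisition of an ex-vivo heart:
#' 0.70 mm in-plane resolution, 1.5 mm slice thickness, T1 = 900 ms,
#' and phase times spanning 50--350 ms after tag application (systole at
#' roughly 100 bpm).
#'
#' @param grid_shape integer length-3, voxels per axis (x, y, z); each >= 8.
#' @param spacing numeric length-3, mm per voxel.
#' @param n_phases number of cardiac phases.
#' @param phase_times ms from tag application, strictly increasing; default
#'   uniform over 50--350 ms.
#' @param endo_radius,epi_radius endocardial/epicardial radii in mm.
#' @param wall_extent long-axis extent of the myocardial wall in mm.
#' @param myo_intensity,cavity_intensity,background_intensity mean intensities
#'   (fractions of `M0`).
#' @param texture_seed integer seed for the myocardial texture.
#' @param texture_sigma correlation length (voxels) of the myocardial speckle
#'   texture; about half a voxel emulates the near-voxel-scale tissue speckle
#'   of a high-resolution ex-vivo scan.
#' @param texture_amp modulation depth of the speckle in (0, 1); the texture
#'   multiplies the mean myocardial intensity by `(1 - amp) + amp * tanh(g)`
#'   for a smoothed unit-variance Gaussian field `g`, so intensities stay in
#'   `(0, M0]`. Tissue texture carries much of the through-plane tracking
#'   information (tag planes are sparse along any single axis), so this depth
#'   matters for realistic tracker performance.
#' @param T1 longitudinal relaxation time in ms (> 0).
#' @param M0 maximum signal intensity.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(64, 64, 24),
                           spacing = c(0.70, 0.70, 1.5),
                           n_phases = 10,
                           phase_times = NULL,
                           endo_radius = 10,
                           epi_radius = 17,
                           wall_extent = 30,
                           myo_intensity = 1,
                           cavity_intensity = 0.05,
                           background_intensity = 0,
                           texture_seed = 1L,
                           texture_sigma = 0.6,
                           texture_amp = 0.5,
                           T1 = 900,
                           M0 = 1) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8L))
    stop("grid_shape must be 3 integers, each >= 8")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("spacing must be positive")
  if (is.null(phase_times))
    phase_times <- seq(50, 350, length.out = n_phases)
  phase_times <- as.numeric(phase_times)
  if (length(phase_times) != n_phases) stop("phase_times must have n_phases entries")
  if (phase_times[1] < 0 || (n_phases > 1 && any(diff(phase_times) <= 0)))
    stop("phase_times must be non-negative and strictly increasing")
  if (T1 <= 0) stop("T1 must be > 0")
  if (epi_radius <= endo_radius || endo_radius <= 0)
    stop("need 0 < endo_radius < epi_radius")
  # geometry must fit the grid (1-voxel margin)
  half_fov <- (min(grid_shape[1:2]) / 2 - 1) * min(spacing[1:2])
  if (epi_radius > half_fov)
    stop(sprintf("epi_radius %.3g mm exceeds the grid extent (max %.3g mm)",
                 epi_radius, half_fov))
  if (wall_extent > grid_shape[3] * spacing[3])
    stop("wall_extent exceeds the grid's long-axis extent")
  structure(list(grid_shape = grid_shape, spacing = spacing,
                 n_phases = as.integer(n_phases), phase_times = phase_times,
                 endo_radius = endo_radius, epi_radius = epi_radius,
                 wall_extent = wall_extent,
                 myo_intensity = myo_intensity,
                 cavity_intensity = cavity_intensity,
                 background_intensity = background_intensity,
                 texture_seed = as.integer(texture_seed),
                 texture_sigma = texture_sigma, texture_amp = texture_amp,
                 T1 = T1, M0 = M0),
            class = "phantom_config")
}

# voxel-space geometry helpers shared by the generator and the motion model
phantom_geometry <- function(config) {
  d <- config$grid_shape
  center <- (d - 1) / 2
  half_wall_vox <- config$wall_extent / 2 / config$spacing[3]
  z_apex <- center[3] - half_wall_vox   # apex -> base along +z
  z_base <- center[3] + half_wall_vox
  list(center = center, z_apex = z_apex, z_base = z_base)
}

#' Generate the untagged LV phantom volume
#'
#' Builds an annular ("donut" short-axis) myocardial wall with a smooth,
#' seeded random texture, a dark cavity and dark background, replicated over
#' all phases, together with the boolean myocardial mask. Tags, motion and
#' noise are applied by [apply_tags()], [warp_volume()] and [add_noise()],
#' or all at once by [lv_phantom_sequence()].
#'
#' @param config a [phantom_config()].
#' @return list with `seq` (a [vol_sequence()] with identical frames) and
#'   `mask` (logical 3D array of myocardial voxels).
#' @export
make_lv_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  d <- config$grid_shape
  geo <- phantom_geometry(config)
  pts <- grid_points(d)
  # in-plane radius in mm from the LV axis
  r_mm <- sqrt(((pts[, 1] - geo$center[1]) * config$spacing[1])^2 +
               ((pts[, 2] - geo$center[2]) * config$spacing[2])^2)
  in_wall_z <- pts[, 3] >= geo$z_apex & pts[, 3] <= geo$z_base
  myo <- r_mm >= config$endo_radius & r_mm <= config$epi_radius & in_wall_z
  cavity <- r_mm < config$endo_radius & in_wall_z

  # seeded band-limited speckle on the wall: multiplicative modulation of the
  # mean myocardial intensity, bounded in (1 - 2*amp, 1) by the tanh squash
  tex <- with_seed(config$texture_seed, array(rnorm(prod(d)), dim = d))
  tex <- gaussian3d(tex, sigma = config$texture_sigma)
  tex <- tex / max(sd(tex), .Machine$double.eps)
  tex <- (1 - config$texture_amp) + config$texture_amp * tanh(tex)

  vol <- array(config$background_intensity * config$M0, dim = d)
  vol[cavity] <- config$cavity_intensity * config$M0
  vol[myo] <- (config$myo_intensity * config$M0 * tex)[myo]
  mask <- array(myo, dim = d)

  frames <- array(vol, dim = c(d, config$n_phases))
  list(seq = vol_sequence(frames, config$spacing, config$phase_times),
       mask = mask)
}

#' Unit normal of the oblique third tag-plane family
#'
#' The two in-plane tag families have normals along x and y. The third family
#' lies at a fixed 45 degree azimuth to them; `beta_deg` is the angle between
#' the z-axis and the tag plane, so `beta = 90` puts the plane perpendicular
#' to z (stripes parallel to the imaging plane, saturating whole slices) and
#' `beta = 0` makes the plane parallel to the z-axis.
#'
#' @param beta_deg angle between the z-axis and the tag plane, in [0, 90].
#' @param azimuth_deg in-plane azimuth of the family, default 45.
#' @return unit 3-vector `(cos(beta) cos(az), cos(beta) sin(az), sin(beta))`.
#' @export
third_tag_normal <- function(beta_deg, azimuth_deg = 45) {
  if (beta_deg < 0 || beta_deg > 90)
    stop("beta_deg must be in [0, 90]")
  b <- beta_deg * pi / 180
  a <- azimuth_deg * pi / 180
  c(cos(b) * cos(a), cos(b) * sin(a), sin(b))
}

#' Tag-plane family specification
#'
#' Tag planes are the level sets `r . normal = k * spacing` in voxel
#' coordinates; voxels within `width/2` of the nearest plane are saturated at
#' tag application and recover by T1 relaxation.
#'
#' @param normal 3-vector (normalized internally); ignored if `beta_deg` given.
#' @param spacing plane spacing in voxels along the normal.
#' @param width stripe width in voxels (0 < width < spacing).
#' @param beta_deg if non-NULL, the normal is [third_tag_normal()] of this angle.
#' @param azimuth_deg azimuth for `beta_deg`-derived normals.
#' @param edge_sigma optional Gaussian smoothing (voxels) of the stripe edges
#'   to mimic a finite tag profile; 0 = hard-edged.
#' @return object of class `tag_spec`.
#' @export
tag_spec <- function(normal = c(1, 0, 0), spacing = 6, width = 2,
                     beta_deg = NULL, azimuth_deg = 45, edge_sigma = 0) {
  if (!is.null(beta_deg)) normal <- third_tag_normal(beta_deg, azimuth_deg)
  nrm <- sqrt(sum(normal^2))
  if (nrm == 0) stop("normal must be non-zero")
  normal <- normal / nrm
  if (width <= 0 || width >= spacing) stop("need 0 < width < spacing")
  structure(list(normal = normal, spacing = spacing, width = width,
                 beta_deg = beta_deg, azimuth_deg = azimuth_deg,
                 edge_sigma = edge_sigma),
            class = "tag_spec")
}

#' Multiplicative tag field with T1 fading
#'
#' Returns the scalar field in `[0, 1]` that multiplies a base image to
#' imprint one tag-plane family at time `t` after tag application: stripes
#' carry the recovery value `1 - exp(-t/T1)` (zero at `t = 0`, i.e. full
#' saturation) and off-stripe voxels are exactly 1.
#'
#' @param spec a [tag_spec()].
#' @param dim integer length-3 grid shape.
#' @param t time in ms since tag application (>= 0).
#' @param T1 relaxation time in ms.
#' @return 3D array in `[0, 1]`.
#' @export
tag_field <- function(spec, dim, t, T1 = 900) {
  stopifnot(inherits(spec, "tag_spec"))
  if (t < 0) stop("t must be >= 0")
  pts <- grid_points(dim)
  s <- pts %*% spec$normal
  m <- s %% spec$spacing
  stripe <- m < spec$width / 2 | m >= spec$spacing - spec$width / 2
  ind <- array(as.numeric(stripe), dim = dim)
  if (spec$edge_sigma > 0) ind <- gaussian3d(ind, spec$edge_sigma)
  f <- 1 - exp(-t / T1)
  1 - (1 - f) * ind
}

#' Superimpose tag-plane families on a base sequence
#'
#' Element-wise product of the base intensity with all tag fields evaluated
#' at each phase's time, so tag contrast fades over the cardiac cycle as the
#' saturated magnetization recovers.
#'
#' @param base a [vol_sequence()].
#' @param specs list of [tag_spec()] (may be empty: returns `base` unchanged).
#' @param T1 relaxation time in ms.
#' @return tagged [vol_sequence()].
#' @export
apply_tags <- function(base, specs, T1 = 900) {
  stopifnot(inherits(base, "vol_sequence"))
  if (length(specs) == 0) return(base)
  d <- dim(base$data)[1:3]
  out <- base$data
  for (p in seq_len(n_phases(base))) {
    fld <- array(1, dim = d)
    for (sp in specs) fld <- fld * tag_field(sp, d, base$phase_times[p], T1)
    out[, , , p] <- out[, , , p] * fld
  }
  vol_sequence(out, base$spacing, base$phase_times)
}

#' Analytic systolic deformation model
#'
#' Smooth parametric stand-in for systolic LV motion: linear-in-z torsion
#' (opposite rotation of apex and base, the "wringing" effect), uniform
#' in-plane radial contraction toward the LV axis, and linear-in-z
#' longitudinal shortening with the apex end fixed. Displacement scales
#' linearly with the phase fraction, so it is identically zero at fraction 0.
#'
#' @param torsion_deg peak rotation magnitude (degrees) at each wall end;
#'   the apex rotates by `-torsion_deg`, the base by `+torsion_deg`.
#' @param radial_contraction peak fractional inward displacement (so a point
#'   at radius r moves inward by `radial_contraction * r` at peak).
#' @param longitudinal_shortening peak base-toward-apex displacement in mm.
#' @return object of class `deformation_model`.
#' @export
deformation_model <- function(torsion_deg = 4,
                              radial_contraction = 0.10,
                              longitudinal_shortening = 2.5) {
  structure(list(torsion_deg = torsion_deg,
                 radial_contraction = radial_contraction,
                 longitudinal_shortening = longitudinal_shortening),
            class = "deformation_model")
}

#' Ground-truth displacement field of the phantom motion model
#'
#' `type = "forward"` returns the Lagrangian displacement of the material
#' point at each reference-grid voxel (what a tracker should recover);
#' `type = "backward"` returns the field used for backward image warping,
#' derived from the exact closed-form inverse of the forward map so that the
#' warped images and the exported ground truth are mutually consistent.
#'
#' All components are in voxel units per axis. The forward field is additive
#' in the three motion components and exactly linear in `phase_fraction`.
#'
#' @param model a [deformation_model()].
#' @param config a [phantom_config()] (fixes grid, spacing and wall geometry).
#' @param phase_fraction in [0, 1]; 0 = reference (no motion).
#' @param type "forward" (ground truth) or "backward" (warp field).
#' @return 4D array (nx, ny, nz, 3) of displacements in voxels.
#' @export
synth_displacement <- function(model, config, phase_fraction,
                               type = c("forward", "backward")) {
  stopifnot(inherits(model, "deformation_model"),
            inherits(config, "phantom_config"))
  type <- match.arg(type)
  if (phase_fraction < 0 || phase_fraction > 1)
    stop("phase_fraction must be in [0, 1]")
  if (abs(config$spacing[1] - config$spacing[2]) > 1e-9)
    warning("torsion assumes isotropic in-plane spacing")
  d <- config$grid_shape
  geo <- phantom_geometry(config)
  pts <- grid_points(d)
  px <- pts[, 1] - geo$center[1]
  py <- pts[, 2] - geo$center[2]
  zeta <- (pts[, 3] - geo$z_apex) / (geo$z_base - geo$z_apex)
  theta <- model$torsion_deg * (2 * zeta - 1) * pi / 180  # -tor at apex, +tor at base
  shorten_vox <- model$longitudinal_shortening / config$spacing[3]
  lam <- phase_fraction

  if (type == "forward") {
    ct <- cos(theta); st <- sin(theta)
    ux <- (ct - 1) * px - st * py - model$radial_contraction * px
    uy <- st * px + (ct - 1) * py - model$radial_contraction * py
    uz <- -shorten_vox * zeta
    return(field_array(cbind(lam * ux, lam * uy, lam * uz), d))
  }

  # backward: invert z' = z - lam * shorten_vox * zeta(z), then the in-plane
  # affine map p' - C = M(z) (p - C), M = (1 - lam*c) I + lam (R(theta) - I)
  S <- lam * shorten_vox / (geo$z_base - geo$z_apex)
  z0 <- geo$z_apex
  z_src <- z0 + (pts[, 3] - z0) / (1 - S)
  zeta_src <- (z_src - z0) / (geo$z_base - geo$z_apex)
  theta_src <- model$torsion_deg * (2 * zeta_src - 1) * pi / 180
  ct <- cos(theta_src); st <- sin(theta_src)
  k <- 1 - lam * model$radial_contraction - lam
  m11 <- k + lam * ct; m12 <- -lam * st
  m21 <- lam * st;     m22 <- k + lam * ct
  det <- m11 * m22 - m12 * m21
  x_src <- (m22 * px - m12 * py) / det
  y_src <- (-m21 * px + m11 * py) / det
  ub <- cbind(px - x_src, py - y_src, pts[, 3] - z_src)
  field_array(ub, d)
}

#' Backward-warp a volume by a displacement field
#'
#' `output(r) = input(r - u(r))` with trilinear interpolation; samples that
#' fall outside the grid take the `background` intensity.
#'
#' @param volume 3D array.
#' @param displacement 4D array (nx, ny, nz, 3), voxel units, same grid.
#' @param background intensity for out-of-grid samples.
#' @return warped 3D array.
#' @export
warp_volume <- function(volume, displacement, background = 0) {
  stopifnot_dim3(volume)
  d <- dim(volume)
  if (!identical(dim(displacement), c(d, 3L)) &&
      !identical(dim(displacement), as.integer(c(d, 3))))
    stop("displacement grid does not match the volume")
  u <- field_matrix(displacement)
  if (all(u == 0)) return(volume)  # exact identity
  pts <- grid_points(d) - u
  out <- sample_volume(volume, pts, background)
  attr(out, "inside") <- NULL
  array(out, dim = d)
}

#' Add zero-mean Gaussian noise scaled to the image maximum
#'
#' The noise standard deviation is `percent/100` of the maximum intensity of
#' the noiseless input (global maximum over the whole sequence).
#'
#' @param x a [vol_sequence()] or numeric array.
#' @param percent noise level as a percentage of the maximum intensity.
#' @param seed integer seed; the realization is reproducible given the seed.
#' @return same type as `x`.
#' @export
add_noise <- function(x, percent, seed = 1L) {
  if (percent < 0) stop("percent must be >= 0")
  if (percent == 0) return(x)
  data <- if (inherits(x, "vol_sequence")) x$data else x
  sigma <- percent / 100 * max(data)
  noise <- with_seed(seed, array(rnorm(length(data), sd = sigma), dim = dim(data)))
  out <- data + noise
  if (inherits(x, "vol_sequence"))
    vol_sequence(out, x$spacing, x$phase_times)
  else out
}

#' Generate a complete deforming tagged phantom with ground truth
#'
#' Orchestrates the phantom pipeline: untagged annular LV, three tag-plane
#' families (in-plane x and y plus the oblique third family at angle `beta`),
#' T1 tag fading per phase, systolic deformation via the exact inverse warp,
#' and optional additive Gaussian noise. The ground-truth Lagrangian
#' displacement from the first phase is exported for every phase so any
#' tracker can be scored without re-deriving the motion.
#'
#' @param config a [phantom_config()].
#' @param model a [deformation_model()]; the temporal profile is a linear
#'   ramp of the phase fraction from 0 to 1 across phases.
#' @param beta_deg third tag-plane angle to the z-axis (degrees).
#' @param tag_width,tag_spacing stripe width and plane spacing in voxels.
#' @param noise_percent additive Gaussian noise level (percent of max).
#' @param noise_seed seed for the noise realization.
#' @param noise_mode `"baseline"` adds one noise realization to the tagged
#'   baseline (pre-warp) frames, so the noise pattern deforms with the tissue
#'   like acquired texture; `"per_phase"` adds independent observation noise
#'   to every output frame.
#' @param tags if FALSE, no tags are applied (untagged moving phantom).
#' @return object of class `lv_phantom`: `seq` (tagged noisy sequence),
#'   `truth` (list of forward displacement fields per phase, voxels),
#'   `mask` (reference-phase myocardial mask), `base`, `config`, `model`,
#'   `tag_specs`.
#' @export
lv_phantom_sequence <- function(config = phantom_config(),
                                model = deformation_model(),
                                beta_deg = 30, tag_width = 2, tag_spacing = 6,
                                noise_percent = 0, noise_seed = 1L,
                                noise_mode = c("baseline", "per_phase"),
                                tags = TRUE) {
  noise_mode <- match.arg(noise_mode)
  base <- make_lv_phantom(config)
  specs <- if (tags) list(
    tag_spec(normal = c(1, 0, 0), spacing = tag_spacing, width = tag_width),
    tag_spec(normal = c(0, 1, 0), spacing = tag_spacing, width = tag_width),
    tag_spec(beta_deg = beta_deg, spacing = tag_spacing, width = tag_width)
  ) else list()
  tagged <- apply_tags(base$seq, specs, T1 = config$T1)
  if (noise_percent > 0 && noise_mode == "baseline") {
    # one material noise realization, common to all pre-warp frames
    sigma <- noise_percent / 100 * max(tagged$data)
    nz <- with_seed(noise_seed,
                    array(rnorm(prod(config$grid_shape), sd = sigma),
                          dim = config$grid_shape))
    for (p in seq_len(config$n_phases))
      tagged$data[, , , p] <- tagged$data[, , , p] + nz
  }

  np <- config$n_phases
  fractions <- if (np == 1) 0 else (seq_len(np) - 1) / (np - 1)
  d <- config$grid_shape
  out <- array(0, dim = c(d, np))
  truth <- vector("list", np)
  bg <- config$background_intensity * config$M0
  for (p in seq_len(np)) {
    frame <- tagged$data[, , , p]
    dim(frame) <- d
    if (fractions[p] == 0) {
      out[, , , p] <- frame
    } else {
      ub <- synth_displacement(model, config, fractions[p], type = "backward")
      out[, , , p] <- warp_volume(frame, ub, background = bg)
    }
    truth[[p]] <- synth_displacement(model, config, fractions[p], type = "forward")
  }
  seq <- vol_sequence(out, config$spacing, config$phase_times)
  if (noise_percent > 0 && noise_mode == "per_phase")
    seq <- add_noise(seq, noise_percent, noise_seed)
  structure(list(seq = seq, truth = truth, mask = base$mask,
                 base = base$seq, config = config, model = model,
                 tag_specs = specs,
                 phase_fractions = fractions,
                 noise_percent = noise_percent, noise_seed = noise_seed,
                 noise_mode = noise_mode,
                 beta_deg = beta_deg, tag_width = tag_width,
                 tag_spacing = tag_spacing, tags = tags),
            class = "lv_phantom")
}

#' @export
print.lv_phantom <- function(x, ...) {
  d <- x$config$grid_shape
  cat(sprintf("lv_phantom: %d x %d x %d voxels, %d phases, %d tag famil%s\n",
              d[1], d[2], d[3], x$config$n_phases, length(x$tag_specs),
              if (length(x$tag_specs) == 1) "y" else "ies"))
  cat(sprintf("  myocardial voxels: %d\n", sum(x$mask)))
  cat(sprintf("  motion: torsion %.3g deg, radial contraction %.3g, shortening %.3g mm\n",
              x$model$torsion_deg, x$model$radial_contraction,
              x$model$longitudinal_shortening))
  if (x$noise_percent > 0)
    cat(sprintf("  noise: %.3g%% of max intensity (seed %d)\n",
                x$noise_percent, x$noise_seed))
  invisible(x)
}

#' Analytic endo/epicardial contours of the phantom geometry
#'
#' Circles at the configured endocardial and epicardial radii for each wall
#' slice, in mm, in the contour format consumed by the regions module.
#'
#' @param config a [phantom_config()].
#' @param n_vertices vertices per polygon.
#' @param phase phase index the contours refer to.
#' @return a `contour_set` data.frame.
#' @export
phantom_contours <- function(config, n_vertices = 64, phase = 1L) {
  geo <- phantom_geometry(config)
  slices <- which(seq_len(config$grid_shape[3]) - 1 >= geo$z_apex &
                  seq_len(config$grid_shape[3]) - 1 <= geo$z_base)
  ang <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  cx <- geo$center[1] * config$spacing[1]
  cy <- geo$center[2] * config$spacing[2]
  rows <- list()
  for (s in slices) {
    for (role in c("endo", "epi")) {
      r <- if (role == "endo") config$endo_radius else config$epi_radius
      rows[[length(rows) + 1]] <- data.frame(
        slice = s, phase = phase, role = role,
        vertex = seq_along(ang),
        x = cx + r * cos(ang), y = cy + r * sin(ang),
        provenance = "given", stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("contour_set", class(out))
  out
}
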