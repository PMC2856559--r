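#' Optical-flow tracker configuration
#'
#' Defaults are the optimized settings of the method: a global
#' translation/rotation stage on a 3-level Gaussian pyramid with 8
#' Gauss-Newton iterations per level, followed by a single-level local stage
#' on Laplacian-filtered (difference-of-Gaussians) data with 8 iterations and
#' a 3x3x3 inspection window around each voxel.
#'
#' @param global_levels Gaussian pyramid levels for the global stage.
#' @param global_iters Gauss-Newton iterations per global level.
#' @param local_levels pyramid levels for the local stage.
#' @param local_iters Gauss-Newton iterations per voxel.
#' @param window odd in-plane inspection-window extent (>= 3).
#' @param window_z window extent along the slice axis: 1 confines the
#'   inspection window to the pixel's own slice (the through-plane velocity
#'   component is still estimated, from the through-plane image gradient);
#'   3 extends the window across the neighboring slices.
#' @param filter_sigma Gaussian scale (voxels) of the pre-filters.
#' @param regularization diagonal loading of near-singular normal equations,
#'   as a fraction of the matrix trace.
#' @param cond_max condition-number threshold above which a voxel's normal
#'   matrix is treated as degenerate (the voxel keeps the global-stage motion
#'   and is flagged in the validity mask).
#' @param max_halvings step halvings allowed before a Gauss-Newton step is
#'   rejected (the SSD sequence is kept non-increasing by construction).
#' @param mode "3d", or "2d" for independent slice-by-slice in-plane tracking.
#' @return object of class `ofm_config`.
#' @export
ofm_config <- function(global_levels = 3, global_iters = 8,
                       local_levels = 1, local_iters = 8,
                       window = 3, window_z = 3, filter_sigma = 1,
                       regularization = 1e-6, cond_max = 1e6,
                       max_halvings = 4, mode = c("3d", "2d")) {
  mode <- match.arg(mode)
  window <- as.integer(window)
  window_z <- as.integer(window_z)
  if (window < 3L || window %% 2L == 0L) stop("window must be odd and >= 3")
  if (window_z < 1L || window_z %% 2L == 0L) stop("window_z must be odd and >= 1")
  if (global_iters < 1 || local_iters < 1) stop("iteration counts must be >= 1")
  if (global_levels < 1 || local_levels < 1) stop("level counts must be >= 1")
  structure(list(global_levels = global_levels, global_iters = global_iters,
                 global_filter = "gaussian",
                 local_levels = local_levels, local_iters = local_iters,
                 local_filter = "laplacian",
                 window = window, window_z = window_z,
                 filter_sigma = filter_sigma,
                 regularization = regularization, cond_max = cond_max,
                 max_halvings = max_halvings, mode = mode),
            class = "ofm_config")
}

# spatial gradients by averaged forward/backward differences at +/- h voxels
gradient_volumes <- function(vol, h = 1L) {
  k <- numeric(2L * h + 1L)
  k[1] <- -0.5 / h
  k[2L * h + 1L] <- 0.5 / h
  list(gx = cpp_convolve_axis(vol, k, 0L),
       gy = cpp_convolve_axis(vol, k, 1L),
       gz = if (dim(vol)[3] > 1) cpp_convolve_axis(vol, k, 2L)
            else array(0, dim = dim(vol)))
}

#' Sum of squared differences under a candidate motion
#'
#' `sum over region of (Lb(r) - La(r - u(r)))^2` with trilinear sampling of
#' `La`; voxels whose sample position falls outside the grid are excluded.
#' `u` may be a uniform 3-vector, a dense (nx, ny, nz, 3) field, or a
#' [global_transform()].
#'
#' @param La,Lb 3D arrays of equal shape.
#' @param u candidate motion.
#' @param region logical array (default: the whole grid).
#' @return scalar SSD with attribute `n` (number of voxels summed).
#' @export
ssd <- function(La, Lb, u = c(0, 0, 0), region = NULL) {
  stopifnot_dim3(La)
  if (!identical(dim(La), dim(Lb))) stop("La and Lb must have the same shape")
  d <- dim(La)
  if (is.null(region)) region <- array(TRUE, dim = d)
  idx <- which(region)
  if (length(idx) == 0) stop("empty region")
  pts <- grid_points(d)[idx, , drop = FALSE]
  u_at <- motion_at(u, pts, d)
  vals <- sample_volume(La, pts - u_at, background = NA_real_)
  inside <- attr(vals, "inside")
  e <- Lb[idx][inside] - vals[inside]
  structure(sum(e^2), n = sum(inside))
}

# evaluate a uniform vector / dense field / global transform at positions
motion_at <- function(u, pts, d) {
  if (inherits(u, "global_transform")) {
    center <- (d - 1) / 2
    p <- sweep(pts, 2, center)
    t(u$t + (u$R - diag(3)) %*% t(p))
  } else if (is.array(u) && length(dim(u)) == 4L) {
    m <- field_matrix(u)
    lin <- 1 + pts[, 1] + d[1] * (pts[, 2] + d[2] * pts[, 3])
    m[lin, , drop = FALSE]
  } else {
    matrix(as.numeric(u), nrow = nrow(pts), ncol = 3, byrow = TRUE)
  }
}

#' One Gauss-Newton increment for a uniform motion over a region
#'
#' Linearizes the SSD residual around `u_current` using spatial gradients
#' computed from forward and backward differences at +/- half the window
#' width and averaged between the two images, solves the 3x3 normal
#' equations (with diagonal loading when near-singular), and safeguards the
#' step by halving it up to `max_halvings` times until the SSD does not
#' increase. Degenerate systems return a zero increment and are flagged.
#'
#' @param La,Lb 3D arrays.
#' @param u_current current uniform motion estimate (3-vector, voxels).
#' @param region logical array (default whole grid).
#' @param config an [ofm_config()].
#' @return list with `du` (accepted increment), `u` (updated motion),
#'   `ssd_before`, `ssd_after`, `accepted`, `degenerate`.
#' @export
gauss_newton_step <- function(La, Lb, u_current = c(0, 0, 0), region = NULL,
                              config = ofm_config()) {
  d <- dim(La)
  if (is.null(region)) region <- array(TRUE, dim = d)
  idx <- which(region)
  if (length(idx) == 0) stop("empty region")
  h <- (config$window - 1L) %/% 2L
  ga <- gradient_volumes(La, h)
  gb <- gradient_volumes(Lb, h)
  pts <- grid_points(d)[idx, , drop = FALSE]
  pos <- sweep(pts, 2, as.numeric(u_current))
  vals <- sample_volume(La, pos, background = NA_real_)
  inside <- attr(vals, "inside")
  e <- Lb[idx][inside] - vals[inside]
  J <- cbind(
    0.5 * (sample_volume(ga$gx, pos, NA)[inside] + gb$gx[idx][inside]),
    0.5 * (sample_volume(ga$gy, pos, NA)[inside] + gb$gy[idx][inside]),
    0.5 * (sample_volume(ga$gz, pos, NA)[inside] + gb$gz[idx][inside])
  )
  A <- crossprod(J)
  g <- crossprod(J, e)
  tr <- sum(diag(A))
  degenerate <- FALSE
  if (!(tr > 0) || kappa(A, exact = TRUE) > config$cond_max) {
    A <- A + diag(3) * max(tr, 1) * config$regularization
    degenerate <- !(tr > 0)
  }
  du <- tryCatch(-solve(A + diag(3) * tr * config$regularization, g),
                 error = function(e) NULL)
  if (is.null(du) || any(!is.finite(du))) {
    return(list(du = c(0, 0, 0), u = u_current, ssd_before = sum(e^2),
                ssd_after = sum(e^2), accepted = FALSE, degenerate = TRUE))
  }
  du <- as.numeric(du)
  ssd0 <- as.numeric(ssd(La, Lb, u_current, region))
  scale <- 1
  for (i in 0:config$max_halvings) {
    cand <- u_current + scale * du
    s <- as.numeric(ssd(La, Lb, cand, region))
    if (s <= ssd0) {
      return(list(du = scale * du, u = cand, ssd_before = ssd0, ssd_after = s,
                  accepted = TRUE, degenerate = degenerate))
    }
    scale <- scale / 2
  }
  list(du = c(0, 0, 0), u = u_current, ssd_before = ssd0, ssd_after = ssd0,
       accepted = FALSE, degenerate = degenerate)
}

#' Global rigid transform (translation + rotation)
#'
#' Small-angle rotation about the volume center plus translation, in voxel
#' units. The identity is all-zero parameters.
#'
#' @param translation 3-vector, voxels.
#' @param rotation 3-vector of rotation parameters (radians, axis-angle).
#' @return object of class `global_transform` with the rotation matrix `R`.
#' @export
global_transform <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0)) {
  structure(list(t = as.numeric(translation), omega = as.numeric(rotation),
                 R = rodrigues(rotation)),
            class = "global_transform")
}

rodrigues <- function(omega) {
  th <- sqrt(sum(omega^2))
  if (th < 1e-12) return(diag(3))
  k <- omega / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' @export
print.global_transform <- function(x, ...) {
  cat(sprintf("global_transform: t = (%.4g, %.4g, %.4g) voxels, rotation = (%.4g, %.4g, %.4g) deg\n",
              x$t[1], x$t[2], x$t[3],
              x$omega[1] * 180 / pi, x$omega[2] * 180 / pi, x$omega[3] * 180 / pi))
  invisible(x)
}

#' Global parametric motion estimate between two volumes
#'
#' Coarse-to-fine Gauss-Newton estimation of a 6-parameter translation +
#' rotation model over the entire image, on a Gaussian pyramid. Iterations at
#' each level stop early when the SSD no longer decreases.
#'
#' @param volA,volB 3D arrays of equal shape (reference, target).
#' @param config an [ofm_config()].
#' @return a [global_transform()] with attribute `ssd` (final SSD).
#' @export
estimate_global <- function(volA, volB, config = ofm_config()) {
  if (!identical(dim(volA), dim(volB))) stop("volumes must have the same shape")
  d <- dim(volA)
  mode2d <- config$mode == "2d"
  n_levels <- min(config$global_levels, 1 + floor(log2(min(d[1:2]) / 4)))
  n_levels <- max(n_levels, 1)
  pyrA <- build_pyramid(volA, n_levels, "gaussian", config$filter_sigma)
  pyrB <- build_pyramid(volB, n_levels, "gaussian", config$filter_sigma)
  center <- (d - 1) / 2
  p <- rep(0, 6) # (t, omega) in finest voxel units
  active <- if (mode2d) c(1L, 2L, 6L) else 1:6
  last_ssd <- NA_real_
  for (lev in rev(seq_len(n_levels))) {
    La <- pyrA[[lev]]$data
    Lb <- pyrB[[lev]]$data
    ga <- gradient_volumes(La, 1L)
    gb <- gradient_volumes(Lb, 1L)
    fsc <- as.numeric(pyrA[[lev]]$factor)
    for (it in seq_len(config$global_iters)) {
      R <- rodrigues(p[4:6])
      acc <- cpp_global_accum(La, Lb, ga$gx, ga$gy, ga$gz, gb$gx, gb$gy, gb$gz,
                              p[1:3], as.numeric(R), center, fsc, mode2d)
      A <- acc$A[active, active, drop = FALSE]
      g <- acc$g[active]
      tr <- sum(diag(A))
      if (!(tr > 0)) break
      dp <- tryCatch(-solve(A + diag(length(active)) * tr * config$regularization, g),
                     error = function(e) NULL)
      if (is.null(dp) || any(!is.finite(dp))) break
      ssd0 <- acc$ssd
      scale <- 1
      accepted <- FALSE
      for (hh in 0:config$max_halvings) {
        cand <- p
        cand[active] <- p[active] + scale * dp
        s <- cpp_global_ssd(La, Lb, cand[1:3], as.numeric(rodrigues(cand[4:6])),
                            center, fsc)$ssd
        if (s < ssd0) {
          p <- cand
          last_ssd <- s
          accepted <- TRUE
          break
        }
        scale <- scale / 2
      }
      if (!accepted) break # SSD converged at this level
    }
  }
  out <- global_transform(p[1:3], p[4:6])
  attr(out, "ssd") <- last_ssd
  out
}

# dense motion field of a global transform, in voxel units
transform_field <- function(gt, d) {
  pts <- grid_points(d)
  field_array(motion_at(gt, pts, d), d)
}

#' Per-voxel local flow refinement
#'
#' Windowed Gauss-Newton SSD minimization around every voxel of the
#' band-pass-filtered pair, initialized from the global transform's motion.
#' Gradients per axis use forward and backward differences at +/- half the
#' window width, averaged between the two images. Voxels with insufficient
#' local structure (ill-conditioned 3x3 normal matrix) keep the global
#' motion and are flagged invalid.
#'
#' @param volA,volB 3D arrays (reference, target).
#' @param init a [global_transform()] (may be the identity).
#' @param config an [ofm_config()].
#' @return list of class `flow_field`: `u` (nx, ny, nz, 3 array of voxel
#'   motions; Eulerian, A -> B), `valid` (logical array).
#' @export
estimate_local <- function(volA, volB, init = global_transform(),
                           config = ofm_config()) {
  if (!identical(dim(volA), dim(volB))) stop("volumes must have the same shape")
  d <- dim(volA)
  mode2d <- config$mode == "2d"
  whalf <- (config$window - 1L) %/% 2L
  n_levels <- min(config$local_levels, 1 + floor(log2(min(d[1:2]) / 4)))
  n_levels <- max(n_levels, 1)
  pyrA <- build_pyramid(volA, n_levels, "laplacian", config$filter_sigma)
  pyrB <- build_pyramid(volB, n_levels, "laplacian", config$filter_sigma)
  u_level <- NULL
  for (lev in rev(seq_len(n_levels))) {
    La <- pyrA[[lev]]$data
    Lb <- pyrB[[lev]]$data
    dl <- dim(La)
    fsc <- as.numeric(pyrA[[lev]]$factor)
    if (is.null(u_level)) {
      # initialize from the global transform, expressed in level voxels
      pts <- grid_points(dl)
      fine_pts <- sweep(pts, 2, fsc, `*`)
      uf <- motion_at(init, fine_pts, d)
      u_level <- sweep(uf, 2, fsc, `/`)
    }
    ga <- gradient_volumes(La, 1L)
    gb <- gradient_volumes(Lb, 1L)
    res <- cpp_local_flow(La, Lb, ga$gx, ga$gy, ga$gz, gb$gx, gb$gy, gb$gz,
                          u_level, whalf, (config$window_z - 1L) %/% 2L,
                          config$local_iters, mode2d,
                          config$regularization, config$cond_max,
                          config$max_halvings)
    if (lev > 1) {
      # upsample to the next finer level
      fine_d <- dim(pyrA[[lev - 1]]$data)
      ratio <- fsc / as.numeric(pyrA[[lev - 1]]$factor)
      pts_f <- grid_points(fine_d)
      pos_in_coarse <- sweep(pts_f, 2, ratio, `/`)
      u_level <- matrix(0, nrow(pts_f), 3)
      for (a in 1:3) {
        comp <- array(res$u[, a], dim = dl)
        u_level[, a] <- sample_volume(comp, pos_in_coarse, 0) * ratio[a]
      }
    } else {
      u <- field_array(res$u, dl)
      valid <- array(res$valid, dim = dl)
      return(structure(list(u = u, valid = valid), class = "flow_field"))
    }
  }
}

#' Dense flow between two volumes (global stage then local stage)
#'
#' The full pair-wise estimator: global translation/rotation on the Gaussian
#' pyramid, then per-voxel refinement on Laplacian-filtered data. Fully
#' deterministic: identical inputs and config give bit-identical output.
#'
#' @param volA,volB 3D arrays (reference, target).
#' @param config an [ofm_config()].
#' @return a `flow_field` (see [estimate_local()]) with attribute
#'   `transform`, the global stage's [global_transform()].
#' @export
estimate_flow <- function(volA, volB, config = ofm_config()) {
  gt <- estimate_global(volA, volB, config)
  flow <- estimate_local(volA, volB, gt, config)
  attr(flow, "transform") <- gt
  flow
}

#' Track a tagged sequence and integrate flow into Lagrangian displacement
#'
#' The fitting function of the package. Adjacent phases are pair-wise
#' compared with [estimate_flow()]; the incremental (Eulerian) flows are then
#' vector-integrated along each material trajectory: the displacement of the
#' reference-grid point r0 is updated by the flow sampled (trilinearly) at
#' its current tracked position, maintaining sub-voxel positions throughout.
#' With `config$mode = "2d"` the identical algorithm runs slice-by-slice
#' with 2-vector flow and the through-plane component is reported as `NA`.
#'
#' @param seq a [vol_sequence()] with at least 2 phases.
#' @param config an [ofm_config()].
#' @param reference reference phase index (displacements are zero there).
#' @return object of class `ofm_track`: `displacements` (one (nx,ny,nz,3)
#'   array per phase, voxel units, at reference-grid positions), `flows`
#'   (per-pair `flow_field`s), `valid`, `transforms`, `config`, `spacing`,
#'   `phase_times`, `reference`.
#' @export
track_sequence <- function(seq, config = ofm_config(), reference = 1L) {
  stopifnot(inherits(seq, "vol_sequence"))
  np <- n_phases(seq)
  if (np < 2) stop("need at least 2 phases to track")
  if (reference != 1L) stop("only reference = 1 (first phase) is supported")
  d <- dim(seq$data)[1:3]
  mode2d <- config$mode == "2d"
  pts <- grid_points(d)
  U <- matrix(0, nrow(pts), 3)
  displacements <- vector("list", np)
  flows <- vector("list", np - 1)
  transforms <- vector("list", np - 1)
  displacements[[1]] <- field_array(U, d)
  valid <- array(TRUE, dim = d)
  for (p in seq_len(np - 1)) {
    va <- phase_volume(seq, p)
    vb <- phase_volume(seq, p + 1)
    if (mode2d) {
      fl <- flow_2d_pair(va, vb, config)
    } else {
      fl <- estimate_flow(va, vb, config)
    }
    flows[[p]] <- fl
    transforms[[p]] <- attr(fl, "transform")
    valid <- valid & fl$valid
    pos <- pts + U
    for (a in if (mode2d) 1:2 else 1:3) {
      comp <- array(fl$u[, , , a], dim = d)
      U[, a] <- U[, a] + sample_volume(comp, pos, 0)
    }
    displacements[[p + 1]] <- field_array(U, d)
  }
  if (mode2d) {
    for (p in seq_len(np)) displacements[[p]][, , , 3] <- NA_real_
  }
  structure(list(displacements = displacements, flows = flows,
                 valid = valid, transforms = transforms, config = config,
                 spacing = seq$spacing, phase_times = seq$phase_times,
                 reference = 1L),
            class = "ofm_track")
}

# slice-by-slice 2D flow for one pair, assembled into a 3D flow_field
flow_2d_pair <- function(va, vb, config) {
  d <- dim(va)
  u <- array(0, dim = c(d, 3))
  valid <- array(TRUE, dim = d)
  for (z in seq_len(d[3])) {
    sa <- array(va[, , z], dim = c(d[1], d[2], 1L))
    sb <- array(vb[, , z], dim = c(d[1], d[2], 1L))
    fl <- estimate_flow(sa, sb, config)
    u[, , z, 1] <- fl$u[, , 1, 1]
    u[, , z, 2] <- fl$u[, , 1, 2]
    valid[, , z] <- fl$valid[, , 1]
  }
  structure(list(u = u, valid = valid), class = "flow_field")
}

#' Slice-wise 2D tracking of a sequence
#'
#' Applies the identical hierarchical estimator independently to every slice
#' with 2-vector flow (the in-plane projection of the motion); the z
#' component of the returned displacement fields is `NA`.
#'
#' @param seq a [vol_sequence()].
#' @param config an [ofm_config()]; its mode is forced to "2d".
#' @return an `ofm_track` object (see [track_sequence()]).
#' @export
estimate_flow_2d <- function(seq, config = ofm_config()) {
  config$mode <- "2d"
  track_sequence(seq, config)
}

#' @export
print.ofm_track <- function(x, ...) {
  d <- dim(x$displacements[[1]])[1:3]
  cat(sprintf("ofm_track (%s): %d phases on a %d x %d x %d grid\n",
              x$config$mode, length(x$displacements), d[1], d[2], d[3]))
  cat(sprintf("  invalid voxels: %.2f%%\n", 100 * mean(!x$valid)))
  invisible(x)
}

#' @export
summary.ofm_track <- function(object, ...) {
  np <- length(object$displacements)
  comp <- if (object$config$mode == "2d") 1:2 else 1:3
  mag <- vapply(object$displacements, function(U) {
    m <- field_matrix(U)[, comp, drop = FALSE]
    stats::median(sqrt(rowSums(m^2)))
  }, numeric(1))
  out <- data.frame(phase = seq_len(np),
                    time_ms = object$phase_times,
                    median_disp_vox = mag)
  class(out) <- c("summary.ofm_track", class(out))
  out
}

#' @export
coef.ofm_track <- function(object, ...) {
  do.call(rbind, lapply(seq_along(object$transforms), function(p) {
    tr <- object$transforms[[p]]
    c(pair = p, tx = tr$t[1], ty = tr$t[2], tz = tr$t[3],
      wx = tr$omega[1], wy = tr$omega[2], wz = tr$omega[3])
  }))
}

#' @export
residuals.ofm_track <- function(object, ...) {
  vapply(object$transforms, function(tr) {
    s <- attr(tr, "ssd")
    if (is.null(s) || is.na(s)) NA_real_ else s
  }, numeric(1))
}

#' Sample tracked displacement at arbitrary reference positions
#'
#' @param object an `ofm_track`.
#' @param positions n x 3 matrix of 0-based reference-grid voxel coordinates.
#' @param phase phase index (default: last phase, end-systole).
#' @param ... unused.
#' @return n x 3 matrix of displacements in voxels.
#' @export
predict.ofm_track <- function(object, positions = NULL, phase = NULL, ...) {
  if (is.null(phase)) phase <- length(object$displacements)
  U <- object$displacements[[phase]]
  d <- dim(U)[1:3]
  if (is.null(positions)) return(U)
  positions <- as.matrix(positions)
  out <- matrix(NA_real_, nrow(positions), 3)
  comp <- if (object$config$mode == "2d") 1:2 else 1:3
  for (a in comp) {
    cmp <- array(U[, , , a], dim = d)
    out[, a] <- sample_volume(cmp, positions, NA_real_)
  }
  colnames(out) <- c("x", "y", "z")
  out
}

#' Plot a mid-slice displacement map of a tracked sequence
#'
#' In-plane displacement magnitude as an image with a sparse quiver overlay.
#'
#' @param x an `ofm_track`.
#' @param phase phase to plot (default last).
#' @param slice slice to plot (default middle).
#' @param every arrow decimation factor.
#' @param ... passed to [graphics::image()].
#' @export
plot.ofm_track <- function(x, phase = NULL, slice = NULL, every = 4, ...) {
  if (is.null(phase)) phase <- length(x$displacements)
  U <- x$displacements[[phase]]
  d <- dim(U)[1:3]
  if (is.null(slice)) slice <- ceiling(d[3] / 2)
  ux <- U[, , slice, 1]
  uy <- U[, , slice, 2]
  mag <- sqrt(ux^2 + uy^2)
  image(x = seq_len(d[1]), y = seq_len(d[2]), z = mag,
        col = hcl.colors(64, "viridis"), xlab = "x (voxel)", ylab = "y (voxel)",
        useRaster = TRUE, ...)
  xi <- seq(1, d[1], by = every)
  yi <- seq(1, d[2], by = every)
  gx <- rep(xi, times = length(yi))
  gy <- rep(yi, each = length(xi))
  keep <- is.finite(ux[cbind(gx, gy)]) & mag[cbind(gx, gy)] > 1e-3
  if (any(keep))
    arrows(gx[keep], gy[keep],
           gx[keep] + ux[cbind(gx, gy)][keep], gy[keep] + uy[cbind(gx, gy)][keep],
           length = 0.03, col = "white")
  title(sub = sprintf("phase %d, slice %d", phase, slice))
  invisible(x)
}
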