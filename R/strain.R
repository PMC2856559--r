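# shift a 3D array by one voxel along an axis, NA-filling the vacated face
shift3 <- function(a, axis, by) {
  d <- dim(a)
  out <- array(NA_real_, dim = d)
  src <- lapply(d, seq_len)
  dst <- src
  if (by == 1L) {
    dst[[axis]] <- seq_len(d[axis] - 1L)
    src[[axis]] <- 2:d[axis]
  } else {
    dst[[axis]] <- 2:d[axis]
    src[[axis]] <- seq_len(d[axis] - 1L)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# masked finite difference: central where both neighbors are in the mask,
# one-sided otherwise, NA where no valid neighbor exists
masked_derivative <- function(a, mask, axis, h) {
  ap <- shift3(a, axis, 1L)
  am <- shift3(a, axis, -1L)
  mp <- shift3(array(as.numeric(mask), dim(mask)), axis, 1L) == 1
  mm <- shift3(array(as.numeric(mask), dim(mask)), axis, -1L) == 1
  mp[is.na(mp)] <- FALSE
  mm[is.na(mm)] <- FALSE
  out <- array(NA_real_, dim = dim(a))
  both <- mask & mp & mm
  fwd <- mask & mp & !mm
  bwd <- mask & mm & !mp
  out[both] <- (ap[both] - am[both]) / (2 * h)
  out[fwd] <- (ap[fwd] - a[fwd]) / h
  out[bwd] <- (a[bwd] - am[bwd]) / h
  out
}

#' Deformation gradient from a Lagrangian displacement field
#'
#' `F = I + du/dX` where `u` is the displacement in mm (voxel displacement
#' times spacing) and `X` the material (reference, end-diastolic) coordinates
#' in mm. Derivatives use central differences in the mask interior and
#' one-sided differences at mask boundaries; voxels with no valid neighbor
#' along some axis are flagged undefined.
#'
#' @param U displacement field (nx, ny, nz, 3) in voxel units, defined on the
#'   reference grid.
#' @param spacing voxel size in mm per axis.
#' @param mask logical array of voxels where strain is wanted.
#' @param smooth_sigma optional Gaussian pre-smoothing of the displacement
#'   (voxels); 0 = off.
#' @return object of class `strain_field` with `F` (nx, ny, nz, 3, 3 array),
#'   `defined` (logical array) and `mask`. Use [green_lagrange()] next.
#' @export
deformation_gradient <- function(U, spacing, mask = NULL, smooth_sigma = 0) {
  d <- dim(U)[1:3]
  if (is.null(mask)) mask <- array(TRUE, dim = d)
  if (!any(mask)) stop("empty mask")
  Farr <- array(NA_real_, dim = c(d, 3, 3))
  defined <- array(TRUE, dim = d)
  for (i in 1:3) {
    u_mm <- array(U[, , , i], dim = d) * spacing[i]
    if (smooth_sigma > 0) {
      u_mm[!mask] <- NA
      u_mm <- gaussian_masked(u_mm, mask, smooth_sigma)
    }
    for (j in 1:3) {
      der <- masked_derivative(u_mm, mask, j, spacing[j])
      Farr[, , , i, j] <- der + (i == j)
      defined <- defined & (!mask | is.finite(der))
    }
  }
  defined <- defined & mask
  structure(list(F = Farr, defined = defined, mask = mask, spacing = spacing),
            class = "strain_field")
}

# Gaussian smoothing that ignores NA outside the mask (normalized convolution)
gaussian_masked <- function(a, mask, sigma) {
  w <- array(as.numeric(mask), dim(mask))
  a0 <- a
  a0[!mask] <- 0
  num <- gaussian3d(a0, sigma)
  den <- gaussian3d(w, sigma)
  out <- num / pmax(den, .Machine$double.eps)
  out[!mask] <- NA
  out
}

#' Green-Lagrange strain tensor field
#'
#' `E = (F'F - I) / 2`; exactly zero for rigid motion and suitable for large
#' deformations. Symmetric by construction.
#'
#' @param x a `strain_field` from [deformation_gradient()], or a single 3x3
#'   matrix `F`.
#' @return the input `strain_field` with an `E` component (nx, ny, nz, 3, 3),
#'   or a 3x3 matrix for matrix input.
#' @export
green_lagrange <- function(x) {
  if (is.matrix(x)) return(0.5 * (crossprod(x) - diag(3)))
  stopifnot(inherits(x, "strain_field"))
  d <- dim(x$F)[1:3]
  E <- array(NA_real_, dim = c(d, 3, 3))
  for (i in 1:3)
    for (j in i:3) {
      acc <- 0
      for (k in 1:3) acc <- acc + x$F[, , , k, i] * x$F[, , , k, j]
      E[, , , i, j] <- 0.5 * (acc - (i == j))
      if (j > i) E[, , , j, i] <- E[, , , i, j]
    }
  x$E <- E
  x
}

#' Principal strains and directions
#'
#' Solves the symmetric eigenvalue problem of the Green-Lagrange tensor at
#' every defined voxel: `eps1 >= eps2 >= eps3` with unit eigenvectors `v1`
#' (direction of greatest stretch, interpreted as radial wall thickening) and
#' `v3` (greatest shortening). Positive values indicate lengthening or
#' thickening, negative values shortening. The sign of `v1` is fixed so that
#' its in-plane projection points outward from the slice's endocardial
#' center (ties resolve to positive x). `alpha` is the absolute angle in
#' degrees, folded into [0, 90], between `v1` and the in-plane radial
#' direction from the endocardial center to the voxel.
#'
#' @param x a `strain_field` with `E` (from [green_lagrange()]), or a single
#'   symmetric 3x3 matrix.
#' @param centers optional per-slice endocardial centers: matrix (nz x 2) of
#'   0-based in-plane voxel coordinates; default: per-slice mask centroid.
#' @param tol symmetry tolerance for matrix input.
#' @return for field input, object of class `principal_strain_field` with
#'   `eps1`, `eps2`, `eps3`, `alpha` (3D arrays), `v1`, `v3` (nx,ny,nz,3),
#'   `defined`; for matrix input, a list with `values` and `vectors`.
#' @export
principal_strains <- function(x, centers = NULL, tol = 1e-8) {
  if (is.matrix(x)) {
    if (max(abs(x - t(x))) > tol) stop("E must be symmetric")
    e <- eigen((x + t(x)) / 2, symmetric = TRUE)
    return(list(values = e$values, vectors = e$vectors))
  }
  stopifnot(inherits(x, "strain_field"))
  if (is.null(x$E)) stop("call green_lagrange() first")
  d <- dim(x$E)[1:3]
  idx <- which(x$defined)
  eps1 <- eps2 <- eps3 <- alpha <- array(NA_real_, dim = d)
  v1 <- v3 <- array(NA_real_, dim = c(d, 3))
  if (is.null(centers)) centers <- mask_slice_centers(x$mask)
  pts <- grid_points(d)
  n <- prod(d)
  Emat <- matrix(x$E, nrow = n)
  v1m <- matrix(NA_real_, n, 3)
  v3m <- matrix(NA_real_, n, 3)
  for (v in idx) {
    Ev <- matrix(Emat[v, ], 3, 3)
    Ev <- (Ev + t(Ev)) / 2
    e <- eigen(Ev, symmetric = TRUE)
    eps1[v] <- e$values[1]
    eps2[v] <- e$values[2]
    eps3[v] <- e$values[3]
    z <- pts[v, 3] + 1L
    ctr <- centers[z, ]
    radial <- c(pts[v, 1] - ctr[1], pts[v, 2] - ctr[2], 0)
    rn <- sqrt(sum(radial^2))
    vec1 <- e$vectors[, 1]
    if (rn > 0) {
      s <- sum(vec1 * radial / rn)
      if (s < 0 || (s == 0 && vec1[1] < 0)) vec1 <- -vec1
      alpha[v] <- alpha_angle(vec1, pts[v, 1:2], ctr)
    } else if (vec1[1] < 0) vec1 <- -vec1
    v1m[v, ] <- vec1
    v3m[v, ] <- e$vectors[, 3]
  }
  v1[] <- v1m
  v3[] <- v3m
  structure(list(eps1 = eps1, eps2 = eps2, eps3 = eps3,
                 v1 = v1, v3 = v3, alpha = alpha,
                 defined = x$defined, mask = x$mask),
            class = "principal_strain_field")
}

# per-slice centroid of the myocardial mask (stand-in for the endocardial
# contour center; identical for an annular wall)
mask_slice_centers <- function(mask) {
  d <- dim(mask)
  out <- matrix(NA_real_, d[3], 2)
  for (z in seq_len(d[3])) {
    sl <- mask[, , z]
    if (!any(sl)) {
      out[z, ] <- (d[1:2] - 1) / 2
    } else {
      w <- which(sl, arr.ind = TRUE)
      out[z, ] <- c(mean(w[, 1]) - 1, mean(w[, 2]) - 1)
    }
  }
  out
}

#' Angle between the principal-stretch direction and the radial line
#'
#' The absolute angle, folded into [0, 90] degrees, between the eigenvector
#' of the maximum principal strain and the in-plane line connecting the
#' endocardial center with the voxel; `v1` and `-v1` give the same angle.
#'
#' @param v1 3-vector (need not be normalized).
#' @param voxel_xy in-plane voxel coordinates (x, y).
#' @param center_xy in-plane endocardial center (x, y).
#' @return angle in degrees in [0, 90].
#' @export
alpha_angle <- function(v1, voxel_xy, center_xy) {
  radial <- c(voxel_xy[1] - center_xy[1], voxel_xy[2] - center_xy[2], 0)
  rn <- sqrt(sum(radial^2))
  if (rn == 0) stop("voxel coincides with the endocardial center")
  vn <- sqrt(sum(v1^2))
  if (vn == 0) stop("zero eigenvector")
  ca <- abs(sum(v1 * radial)) / (vn * rn)
  acos(min(1, ca)) * 180 / pi
}

#' @export
print.strain_field <- function(x, ...) {
  cat(sprintf("strain_field: %s on %d voxels (%d defined)\n",
              if (is.null(x$E)) "F" else "F, E",
              sum(x$mask), sum(x$defined)))
  invisible(x)
}

#' @export
print.principal_strain_field <- function(x, ...) {
  i <- x$defined
  cat(sprintf("principal_strain_field: %d voxels\n", sum(i)))
  cat(sprintf("  eps1: median %.4f   eps3: median %.4f   alpha: median %.1f deg\n",
              median(x$eps1[i]), median(x$eps3[i]), median(x$alpha[i], na.rm = TRUE)))
  invisible(x)
}

#' End-systolic strain of a tracked sequence
#'
#' Convenience wrapper running displacement -> deformation gradient ->
#' Green-Lagrange -> principal strains for a chosen phase pair (default:
#' reference end-diastole to the last phase, end-systole).
#'
#' @param fit an `ofm_track` from [track_sequence()].
#' @param mask logical myocardial mask on the reference grid.
#' @param phase deformed phase index (default last).
#' @param smooth_sigma optional displacement pre-smoothing in voxels.
#' @return a `principal_strain_field`.
#' @export
strain_analysis <- function(fit, mask, phase = NULL, smooth_sigma = 0) {
  stopifnot(inherits(fit, "ofm_track"))
  if (is.null(phase)) phase <- length(fit$displacements)
  U <- fit$displacements[[phase]]
  sf <- deformation_gradient(U, fit$spacing, mask, smooth_sigma)
  sf <- green_lagrange(sf)
  principal_strains(sf)
}
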