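#' Separable 3D Gaussian smoothing
#'
#' Reflect padding at the borders; `sigma = 0` returns the input unchanged.
#' The kernel is truncated at 3 sigma and normalized to unit DC gain.
#'
#' @param volume 3D numeric array.
#' @param sigma standard deviation in voxels (>= 0).
#' @return smoothed 3D array.
#' @export
gaussian3d <- function(volume, sigma = 1) {
  stopifnot_dim3(volume)
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(volume)
  storage.mode(volume) <- "double"
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k <- k / sum(k)
  out <- volume
  for (axis in 0:2) out <- cpp_convolve_axis(out, k, axis)
  out
}

#' Band-pass ("Laplacian") pre-filter
#'
#' Removes the local intensity offset and enhances edges by subtracting the
#' Gaussian-smoothed image from the original (difference-of-Gaussians
#' band-pass). This makes the optical-flow matching sensitive to structure
#' rather than absolute brightness, which matters for tagged images whose
#' brightness drifts with T1 relaxation. A 6-neighbor second-difference
#' stencil is available as an alternative.
#'
#' @param volume 3D numeric array.
#' @param sigma Gaussian scale of the subtracted low-pass, in voxels.
#' @param kind "dog" (default) or "stencil" (6-neighbor discrete Laplacian).
#' @return filtered 3D array with (near-)zero response to constant input.
#' @export
laplacian3d <- function(volume, sigma = 1, kind = c("dog", "stencil")) {
  stopifnot_dim3(volume)
  kind <- match.arg(kind)
  storage.mode(volume) <- "double"
  if (kind == "dog") return(volume - gaussian3d(volume, sigma))
  k <- c(1, -2, 1)
  out <- cpp_convolve_axis(volume, k, 0L)
  out <- out + cpp_convolve_axis(volume, k, 1L)
  out + cpp_convolve_axis(volume, k, 2L)
}

binomial_decimate <- function(volume, halve_z = TRUE) {
  k <- c(1, 4, 6, 4, 1) / 16
  out <- cpp_convolve_axis(volume, k, 0L)
  out <- cpp_convolve_axis(out, k, 1L)
  if (halve_z && dim(volume)[3] > 1) out <- cpp_convolve_axis(out, k, 2L)
  d <- dim(volume)
  xi <- seq(1, d[1], by = 2)
  yi <- seq(1, d[2], by = 2)
  zi <- if (halve_z) seq(1, d[3], by = 2) else seq_len(d[3])
  out <- out[xi, yi, zi]
  dim(out) <- c(length(xi), length(yi), length(zi))
  out
}

#' Coarse-to-fine image pyramid
#'
#' Level 0 is the filtered input; each next level is the previous one
#' smoothed with a binomial (1,4,6,4,1)/16 anti-alias kernel, decimated by 2
#' per axis (ceil(dim/2)), then filtered again. With `filter_kind =
#' "laplacian"` the levels are the band-pass components of a Laplacian
#' pyramid; with `"gaussian"` they are low-pass. Volumes with fewer than 8
#' slices stop decimating the z-axis so thin stacks keep through-plane
#' support.
#'
#' @param volume 3D numeric array.
#' @param n_levels number of levels (>= 1).
#' @param filter_kind "laplacian" or "gaussian".
#' @param sigma filter scale passed to [laplacian3d()] / [gaussian3d()].
#' @return list of levels, each a list with `data`, `level` (0 = finest),
#'   `filter_kind` and `factor` (per-axis decimation factor to level 0).
#' @export
build_pyramid <- function(volume, n_levels, filter_kind = c("laplacian", "gaussian"),
                          sigma = 1) {
  stopifnot_dim3(volume)
  filter_kind <- match.arg(filter_kind)
  if (n_levels < 1) stop("n_levels must be >= 1")
  max_feasible <- 1 + floor(log2(min(dim(volume)[1:2])))
  if (min(dim(volume)[1:2]) / 2^(n_levels - 1) < 1)
    stop(sprintf("too many pyramid levels for this grid (max %d)", max_feasible))
  filt <- function(v) switch(filter_kind,
                             laplacian = laplacian3d(v, sigma),
                             gaussian  = gaussian3d(v, sigma))
  levels <- vector("list", n_levels)
  raw <- volume
  factor <- c(1, 1, 1)
  for (i in seq_len(n_levels)) {
    levels[[i]] <- list(data = filt(raw), level = i - 1L,
                        filter_kind = filter_kind, factor = factor)
    if (i < n_levels) {
      halve_z <- dim(raw)[3] >= 8
      raw <- binomial_decimate(raw, halve_z = halve_z)
      factor <- factor * c(2, 2, if (halve_z) 2 else 1)
    }
  }
  levels
}
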