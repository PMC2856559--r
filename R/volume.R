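#' Tagged image volume sequences
#'
#' A `vol_sequence` holds a 4D grayscale image (x, y, z, cardiac phase)
#' together with the anisotropic voxel spacing in mm and the time of each
#' phase in ms after tag application. It is the common currency between the
#' phantom generator, the optical-flow tracker and the I/O layer.
#'
#' @param data 4D numeric array (nx, ny, nz, n_phases); a 3D array is treated
#'   as a single-phase sequence.
#' @param spacing numeric length-3, voxel size in mm per axis (x, y, z).
#' @param phase_times numeric, ms from tag application for each phase;
#'   strictly increasing.
#' @return An object of class `vol_sequence`.
#' @export
vol_sequence <- function(data, spacing, phase_times = NULL) {
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 4L) stop("data must be a 3D or 4D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 positive numbers (mm/voxel)")
  np <- dim(data)[4]
  if (is.null(phase_times)) phase_times <- seq_len(np) - 1
  phase_times <- as.numeric(phase_times)
  if (length(phase_times) != np) stop("phase_times must match the phase count")
  if (np > 1 && any(diff(phase_times) <= 0))
    stop("phase_times must be strictly increasing")
  storage.mode(data) <- "double"
  structure(list(data = data, spacing = spacing, phase_times = phase_times),
            class = "vol_sequence")
}

#' @export
print.vol_sequence <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("vol_sequence: %d x %d x %d voxels, %d phase(s)\n", d[1], d[2], d[3], d[4]))
  cat(sprintf("  spacing: %.3g x %.3g x %.3g mm\n", x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  phase times: %s ms\n", paste(signif(x$phase_times, 4), collapse = ", ")))
  cat(sprintf("  intensity range: [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

n_phases <- function(seq) dim(seq$data)[4]

phase_volume <- function(seq, p) {
  v <- seq$data[, , , p]
  dim(v) <- dim(seq$data)[1:3]
  v
}
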