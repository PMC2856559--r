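# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# 0-based voxel index grids as an n x 3 matrix (x fastest-varying, matching
# R's column-major array layout).
grid_points <- function(dim) {
  nx <- dim[1]; ny <- dim[2]; nz <- dim[3]
  cbind(
    x = rep.int(seq_len(nx) - 1, times = ny * nz),
    y = rep.int(rep(seq_len(ny) - 1, each = nx), times = nz),
    z = rep(seq_len(nz) - 1, each = nx * ny)
  )
}

stopifnot_dim3 <- function(vol) {
  if (is.null(dim(vol)) || length(dim(vol)) != 3L)
    stop("expected a 3D array", call. = FALSE)
}

# Sample a 3D volume at positions `pts` (n x 3, 0-based voxel coords) with
# trilinear interpolation. Outside-grid samples get `background`; the
# "inside" attribute flags them.
sample_volume <- function(vol, pts, background = 0) {
  stopifnot_dim3(vol)
  storage.mode(vol) <- "double"
  cpp_sample_trilinear(vol, as.matrix(pts), background)
}

# displacement / flow fields: 4D arrays (nx, ny, nz, 3), voxel units.
field_array <- function(mat, dim3) {
  array(mat, dim = c(dim3, 3L))
}

field_matrix <- function(field) {
  d <- dim(field)
  matrix(field, ncol = 3L,
         dimnames = list(NULL, c("x", "y", "z")))
}

vapply_num <- function(x, f) vapply(x, f, numeric(1))
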