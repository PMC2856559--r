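sidecar_path <- function(path) paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")

write_sidecar <- function(path, extra = list()) {
  meta <- c(list(software = "tagflow3d",
                 version = as.character(utils::packageVersion("tagflow3d")),
                 axis_order = "x fastest, z = slice axis (apex to base), 0-based"),
            extra)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (file.exists(sp)) jsonlite::read_json(sp, simplifyVector = TRUE) else NULL
}

#' Read an image volume sequence
#'
#' NIfTI (3D or 4D; spacing from the header, phase times from the JSON
#' sidecar if present) or a directory of multi-page TIFF stacks (one file
#' per phase, pages = slices; spacing must come from a `spacing.json`
#' sidecar in the directory). A 3D file yields a single-phase sequence.
#'
#' @param path NIfTI file or TIFF directory.
#' @return a [vol_sequence()].
#' @export
read_volume <- function(path) {
  if (dir.exists(path)) return(read_tiff_dir(path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("not a readable NIfTI file: ", path,
                                           " (", conditionMessage(e), ")", call. = FALSE))
  spacing <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("missing voxel spacing in NIfTI header; supply a corrected header")
  arr <- array(as.vector(as.array(img)), dim = dim(img))
  side <- read_sidecar(path)
  vol_sequence(arr, spacing, phase_times = side$phase_times)
}

read_tiff_dir <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("reading TIFF stacks requires the 'tiff' package")
  sp <- file.path(path, "spacing.json")
  if (!file.exists(sp))
    stop("TIFF input needs a spacing.json sidecar with 'spacing' (mm) ",
         "and optionally 'phase_times' (ms)")
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE))
  if (length(files) == 0) stop("no TIFF files in ", path)
  phases <- lapply(files, function(f) {
    pages <- tiff::readTIFF(f, all = TRUE)
    simplify2array(lapply(pages, function(p) t(p)[, rev(seq_len(nrow(p)))]))
  })
  arr <- simplify2array(phases)
  vol_sequence(arr, meta$spacing, phase_times = meta$phase_times)
}

#' Write a volume sequence as 4D NIfTI with a JSON sidecar
#'
#' @param vol a [vol_sequence()].
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "vol_sequence"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- c(vol$spacing, 1)
  RNifti::writeNifti(img, path)
  write_sidecar(path, list(kind = "volume_sequence",
                           spacing_mm = vol$spacing,
                           phase_times = vol$phase_times))
  invisible(path)
}

#' Write / read a displacement (or flow) field as 4D NIfTI
#'
#' The last axis is the vector component (x, y, z) in voxel units; the JSON
#' sidecar records the units, reference phase and software version.
#'
#' @param field 4D array (nx, ny, nz, 3).
#' @param path output path.
#' @param spacing voxel size in mm per axis.
#' @param reference reference phase index recorded in the sidecar.
#' @return `path` (write) / 4D array with attributes `spacing`, `reference`
#'   (read).
#' @export
write_field <- function(field, path, spacing = c(1, 1, 1), reference = 1L) {
  stopifnot(length(dim(field)) == 4L, dim(field)[4] == 3L)
  img <- RNifti::asNifti(field)
  RNifti::pixdim(img) <- c(spacing, 1)
  RNifti::writeNifti(img, path)
  write_sidecar(path, list(kind = "displacement_field", units = "voxel",
                           components = c("x", "y", "z"),
                           spacing_mm = spacing, reference_phase = reference))
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("not a readable NIfTI file: ", path,
                                           call. = FALSE))
  arr <- array(as.vector(as.array(img)), dim = dim(img))
  if (length(dim(arr)) != 4L || dim(arr)[4] != 3L)
    stop("field file must be 4D with 3 components")
  side <- read_sidecar(path)
  attr(arr, "spacing") <- side$spacing_mm
  attr(arr, "reference") <- side$reference_phase
  arr
}
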