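#' Per-axis RMS tracking error over myocardial voxels
#'
#' Root-mean-square of the per-voxel difference between estimated and true
#' displacement, per axis, over the masked voxels, reported both in voxels
#' and in mm (via the voxel spacing).
#'
#' @param estimated displacement field (nx, ny, nz, 3), voxel units.
#' @param truth ground-truth displacement field, same grid.
#' @param mask logical array of myocardial voxels (non-empty).
#' @param spacing voxel size in mm per axis.
#' @return list with `vox` and `mm`, each a named length-3 vector (x, y, z);
#'   axes with no finite estimate (e.g. z in 2D mode) are `NA`.
#' @export
rms_error <- function(estimated, truth, mask, spacing = c(1, 1, 1)) {
  if (!any(mask)) stop("empty mask")
  idx <- which(mask)
  d <- dim(truth)[1:3]
  n <- prod(d)
  vox <- numeric(3)
  for (a in 1:3) {
    e <- estimated[idx + (a - 1) * n] - truth[idx + (a - 1) * n]
    vox[a] <- if (all(is.na(e))) NA_real_ else sqrt(mean(e^2, na.rm = TRUE))
  }
  names(vox) <- c("x", "y", "z")
  list(vox = vox, mm = vox * spacing)
}

# pooled in-plane RMS (x and y errors pooled into one RMS)
inplane_rms <- function(estimated, truth, mask, spacing = c(1, 1, 1)) {
  idx <- which(mask)
  d <- dim(truth)[1:3]
  n <- prod(d)
  ex <- estimated[idx] - truth[idx]
  ey <- estimated[idx + n] - truth[idx + n]
  c(vox = sqrt(mean(c(ex^2, ey^2))),
    mm = sqrt(mean(c((ex * spacing[1])^2, (ey * spacing[2])^2))))
}

track_and_score <- function(phantom, config = ofm_config(), phase = NULL) {
  fit <- track_sequence(phantom$seq, config)
  if (is.null(phase)) phase <- length(fit$displacements)
  err <- rms_error(fit$displacements[[phase]], phantom$truth[[phase]],
                   phantom$mask, phantom$config$spacing)
  list(fit = fit, rms = err, phase = phase)
}

#' Third-tag-angle sweep
#'
#' Regenerates the tagged phantom for each angle of the oblique third
#' tag-plane family, tracks it, and scores the end-systolic displacement
#' against the exported ground truth. Through-plane accuracy degrades as the
#' third plane approaches the imaging plane (beta = 90 saturates whole
#' slices, destroying z landmarks).
#'
#' @param config a [phantom_config()].
#' @param model a [deformation_model()].
#' @param betas angles in degrees (default 0 to 90 in 15-degree steps).
#' @param ofm an [ofm_config()].
#' @param tag_width,tag_spacing stripe geometry in voxels.
#' @return data.frame: `beta`, `rms_x`, `rms_y`, `rms_z` (voxels) and
#'   `rms_x_mm`, `rms_y_mm`, `rms_z_mm`.
#' @export
beta_sweep <- function(config = phantom_config(), model = deformation_model(),
                       betas = seq(0, 90, by = 15), ofm = ofm_config(),
                       tag_width = 2, tag_spacing = 6) {
  rows <- lapply(betas, function(b) {
    ph <- lv_phantom_sequence(config, model, beta_deg = b,
                              tag_width = tag_width, tag_spacing = tag_spacing)
    sc <- track_and_score(ph, ofm)
    data.frame(beta = b,
               rms_x = sc$rms$vox[1], rms_y = sc$rms$vox[2], rms_z = sc$rms$vox[3],
               rms_x_mm = sc$rms$mm[1], rms_y_mm = sc$rms$mm[2],
               rms_z_mm = sc$rms$mm[3])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$beta), ]
}

#' Noise sensitivity of the tracker
#'
#' Adds zero-mean Gaussian noise (sigma = percent of the maximum image
#' intensity) to the baseline tagged phantom, re-tracks, and reports per-axis
#' RMS both against the ground truth and against the noise-free baseline
#' estimate, averaged over noise seeds. The 0% row is the baseline run
#' itself. With `noise_mode = "baseline"` (default) the noise is applied to
#' the tagged baseline volume before warping, i.e. it deforms with the
#' tissue like acquired image texture; `"per_phase"` adds independent
#' observation noise to every frame instead.
#'
#' @param phantom an `lv_phantom` built without noise.
#' @param percents noise levels (percent of max intensity).
#' @param n_seeds noise realizations averaged per level.
#' @param ofm an [ofm_config()].
#' @param seed base seed; realization seeds derive from it.
#' @param noise_mode see [lv_phantom_sequence()].
#' @return data.frame with one row per level: per-axis RMS vs truth
#'   (`rms_*`) and vs the noiseless baseline estimate (`rms_*_vs_baseline`),
#'   in voxels, mm variants (`*_mm`), and pooled in-plane mm columns.
#' @export
noise_sensitivity <- function(phantom, percents = c(0, 5, 10, 15, 20),
                              n_seeds = 3, ofm = ofm_config(), seed = 1L,
                              noise_mode = c("baseline", "per_phase")) {
  stopifnot(inherits(phantom, "lv_phantom"))
  noise_mode <- match.arg(noise_mode)
  if (phantom$noise_percent > 0) stop("phantom must be noise-free")
  spacing <- phantom$config$spacing
  base <- track_and_score(phantom, ofm)
  phase <- base$phase
  U0 <- base$fit$displacements[[phase]]
  truth <- phantom$truth[[phase]]
  mask <- phantom$mask
  zero <- array(0, dim = dim(U0))
  rows <- lapply(percents, function(pc) {
    if (pc == 0) {
      vt <- base$rms
      vb <- rms_error(U0, U0, mask, spacing)
      ip_t <- inplane_rms(U0, truth, mask, spacing)
      ip_b <- inplane_rms(U0, U0, mask, spacing)
      reps <- 1
    } else {
      acc_t <- acc_b <- matrix(0, n_seeds, 3)
      acc_ip <- matrix(0, n_seeds, 2)
      for (k in seq_len(n_seeds)) {
        s <- seed + 1000L * k + round(10 * pc)
        noisy <- if (noise_mode == "baseline")
          lv_phantom_sequence(phantom$config, phantom$model,
                              beta_deg = phantom$beta_deg,
                              tag_width = phantom$tag_width,
                              tag_spacing = phantom$tag_spacing,
                              noise_percent = pc, noise_seed = s,
                              noise_mode = "baseline", tags = phantom$tags)
        else {
          tmp <- phantom
          tmp$seq <- add_noise(phantom$seq, pc, s)
          tmp
        }
        fit <- track_sequence(noisy$seq, ofm)
        Up <- fit$displacements[[phase]]
        acc_t[k, ] <- rms_error(Up, truth, mask, spacing)$vox
        acc_b[k, ] <- rms_error(Up, U0, mask, spacing)$vox
        acc_ip[k, ] <- c(inplane_rms(Up, truth, mask, spacing)["mm"],
                         inplane_rms(Up, U0, mask, spacing)["mm"])
      }
      vt <- list(vox = colMeans(acc_t), mm = colMeans(acc_t) * spacing)
      vb <- list(vox = colMeans(acc_b), mm = colMeans(acc_b) * spacing)
      ip_t <- c(mm = mean(acc_ip[, 1]))
      ip_b <- c(mm = mean(acc_ip[, 2]))
      reps <- n_seeds
    }
    data.frame(percent = pc, n_seeds = reps,
               rms_x = vt$vox[1], rms_y = vt$vox[2], rms_z = vt$vox[3],
               rms_x_mm = vt$mm[1], rms_y_mm = vt$mm[2], rms_z_mm = vt$mm[3],
               rms_x_vs_baseline = vb$vox[1], rms_y_vs_baseline = vb$vox[2],
               rms_z_vs_baseline = vb$vox[3],
               rms_x_mm_vs_baseline = vb$mm[1], rms_y_mm_vs_baseline = vb$mm[2],
               rms_z_mm_vs_baseline = vb$mm[3],
               inplane_mm = unname(ip_t["mm"]),
               inplane_mm_vs_baseline = unname(ip_b["mm"]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' 2D-vs-3D in-plane tracking comparison
#'
#' Tracks the same phantom with the slice-wise 2D estimator and the full 3D
#' estimator and compares pooled in-plane RMS errors against the ground
#' truth. When the motion has a through-plane component, slice-wise tracking
#' projects it into apparent in-plane motion; the 3D tracker does not.
#'
#' @param phantom an `lv_phantom`.
#' @param ofm an [ofm_config()].
#' @return list with `rms2d_mm`, `rms3d_mm`, `rms2d_vox`, `rms3d_vox` and
#'   `percent_decrease` = 100 * (RMS2D - RMS3D) / RMS2D (in-plane, mm).
#' @export
compare_2d_3d <- function(phantom, ofm = ofm_config()) {
  stopifnot(inherits(phantom, "lv_phantom"))
  phase <- phantom$config$n_phases
  spacing <- phantom$config$spacing
  truth <- phantom$truth[[phase]]
  fit3 <- track_sequence(phantom$seq, ofm)
  cfg2 <- ofm
  cfg2$mode <- "2d"
  fit2 <- track_sequence(phantom$seq, cfg2)
  r3 <- inplane_rms(fit3$displacements[[phase]], truth, phantom$mask, spacing)
  r2 <- inplane_rms(fit2$displacements[[phase]], truth, phantom$mask, spacing)
  list(rms2d_vox = unname(r2["vox"]), rms3d_vox = unname(r3["vox"]),
       rms2d_mm = unname(r2["mm"]), rms3d_mm = unname(r3["mm"]),
       percent_decrease = percent_decrease(r2["mm"], r3["mm"]))
}

#' @rdname compare_2d_3d
#' @param rms_2d,rms_3d pooled in-plane RMS errors.
#' @export
percent_decrease <- function(rms_2d, rms_3d) {
  unname(100 * (rms_2d - rms_3d) / rms_2d)
}
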