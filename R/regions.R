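#' Contour sets
#'
#' Endo- and epicardial contours are closed polygons per (slice, phase),
#' stored long-format: columns `slice`, `phase`, `role` ("endo"/"epi"),
#' `vertex`, `x`, `y` (mm) and `provenance` ("given" or "interpolated").
#'
#' @param df data.frame with the columns above (`provenance` optional).
#' @return a `contour_set`.
#' @export
contour_set <- function(df) {
  need <- c("slice", "phase", "role", "vertex", "x", "y")
  if (!all(need %in% names(df))) stop("missing contour columns: ",
                                      paste(setdiff(need, names(df)), collapse = ", "))
  if (is.null(df$provenance)) df$provenance <- "given"
  if (!all(df$role %in% c("endo", "epi"))) stop("role must be 'endo' or 'epi'")
  class(df) <- unique(c("contour_set", class(df)))
  df
}

# resample a closed polygon to n vertices, uniformly in arc length
resample_polygon <- function(xy, n) {
  xy <- as.matrix(xy)
  closed <- rbind(xy, xy[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  target <- seq(0, total, length.out = n + 1)[seq_len(n)]
  cbind(approx(s, closed[, 1], xout = target)$y,
        approx(s, closed[, 2], xout = target)$y)
}

one_contour <- function(cs, slice, phase, role) {
  sub <- cs[cs$slice == slice & cs$phase == phase & cs$role == role, , drop = FALSE]
  if (nrow(sub) == 0) return(NULL)
  as.matrix(sub[order(sub$vertex), c("x", "y")])
}

#' Interpolate sparse contours across slices and propagate across phases
#'
#' Spatial interpolation: contours drawn on a subset of slices are resampled
#' to a fixed vertex count (arc-length parameterized, aligned by starting
#' angle) and linearly interpolated vertex-wise between the drawn slices.
#' Temporal propagation: if a displacement series is given, vertices of the
#' reference-phase contours are advected by the measured Lagrangian
#' displacement to every other phase.
#'
#' @param sparse a [contour_set()] with contours on >= 2 slices at one phase.
#' @param all_slices slice indices to fill in.
#' @param all_phases phase indices to propagate to (ignored without `fit`).
#' @param fit optional `ofm_track` providing the displacement series.
#' @param n_vertices vertex count of the output polygons.
#' @param spacing voxel spacing in mm (needed to convert mm vertices to voxel
#'   coordinates for displacement sampling; required with `fit`).
#' @return a denser `contour_set`; slices given in the input pass through
#'   untouched at their drawn phase.
#' @export
interpolate_contours <- function(sparse, all_slices, all_phases = NULL,
                                 fit = NULL, n_vertices = 64, spacing = NULL) {
  sparse <- contour_set(sparse)
  phase0 <- unique(sparse$phase)
  if (length(phase0) != 1)
    stop("contours must be drawn at a single phase")
  drawn <- sort(unique(sparse$slice))
  if (length(drawn) < 2) stop("need contours on at least 2 slices to interpolate")
  out <- list()
  for (role in c("endo", "epi")) {
    # resample drawn contours; align start vertex by angle from centroid
    polys <- lapply(drawn, function(s) {
      xy <- one_contour(sparse, s, phase0, role)
      if (is.null(xy)) stop(sprintf("missing %s contour on slice %d", role, s))
      p <- resample_polygon(xy, n_vertices)
      ctr <- colMeans(p)
      ang <- atan2(p[, 2] - ctr[2], p[, 1] - ctr[1])
      rot <- which.min(abs(ang)) # start near angle 0
      p[c(rot:nrow(p), seq_len(rot - 1)), , drop = FALSE]
    })
    names(polys) <- as.character(drawn)
    for (s in all_slices) {
      if (s %in% drawn) {
        # drawn slices pass through untouched
        xy <- one_contour(sparse, s, phase0, role)
        out[[length(out) + 1]] <- data.frame(
          slice = s, phase = phase0, role = role, vertex = seq_len(nrow(xy)),
          x = xy[, 1], y = xy[, 2], provenance = "given",
          stringsAsFactors = FALSE)
        next
      } else {
        lo <- max(drawn[drawn < s], -Inf)
        hi <- min(drawn[drawn > s], Inf)
        if (!is.finite(lo) || !is.finite(hi)) next # no extrapolation
        w <- (s - lo) / (hi - lo)
        p <- (1 - w) * polys[[as.character(lo)]] + w * polys[[as.character(hi)]]
        prov <- "interpolated"
      }
      out[[length(out) + 1]] <- data.frame(
        slice = s, phase = phase0, role = role, vertex = seq_len(nrow(p)),
        x = p[, 1], y = p[, 2], provenance = prov, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (!is.null(fit) && !is.null(all_phases)) {
    if (is.null(spacing)) spacing <- fit$spacing
    base <- res[res$phase == phase0, , drop = FALSE]
    prop <- list()
    for (ph in setdiff(all_phases, phase0)) {
      pv <- base
      vox <- cbind(base$x / spacing[1], base$y / spacing[2], base$slice - 1)
      Up <- predict(fit, vox, phase = ph)
      U0 <- predict(fit, vox, phase = phase0)
      U0[is.na(U0)] <- 0
      Up[is.na(Up)] <- 0
      pv$x <- base$x + (Up[, 1] - U0[, 1]) * spacing[1]
      pv$y <- base$y + (Up[, 2] - U0[, 2]) * spacing[2]
      pv$phase <- ph
      pv$provenance <- "interpolated"
      prop[[length(prop) + 1]] <- pv
    }
    res <- rbind(res, do.call(rbind, prop))
  }
  contour_set(res)
}

#' Rasterize contours into a myocardial mask
#'
#' A voxel belongs to the myocardium when its center lies inside the
#' epicardial polygon and outside the endocardial polygon of its slice
#' (even-odd rule).
#'
#' @param contours a [contour_set()] (single phase).
#' @param dim grid shape (nx, ny, nz).
#' @param spacing voxel size in mm per axis.
#' @return logical 3D array.
#' @export
myocardial_mask <- function(contours, dim, spacing) {
  contours <- contour_set(contours)
  phase <- unique(contours$phase)
  if (length(phase) > 1) stop("give contours for a single phase")
  mask <- array(FALSE, dim = dim)
  gx <- (seq_len(dim[1]) - 1) * spacing[1]
  gy <- (seq_len(dim[2]) - 1) * spacing[2]
  pts <- cbind(rep(gx, times = dim[2]), rep(gy, each = dim[1]))
  for (s in sort(unique(contours$slice))) {
    endo <- one_contour(contours, s, phase, "endo")
    epi <- one_contour(contours, s, phase, "epi")
    if (is.null(endo) || is.null(epi)) next
    r_endo <- max(sqrt(rowSums(sweep(endo, 2, colMeans(epi))^2)))
    r_epi <- min(sqrt(rowSums(sweep(epi, 2, colMeans(epi))^2)))
    if (r_endo > r_epi + 1e-9)
      stop(sprintf("endocardial contour not inside epicardial contour on slice %d", s))
    inside_epi <- mgcv::in.out(rbind(epi, epi[1, ]), pts)
    inside_endo <- mgcv::in.out(rbind(endo, endo[1, ]), pts)
    sl <- inside_epi & !inside_endo
    if (!any(sl)) warning(sprintf("empty myocardium on slice %d", s))
    mask[, , s] <- matrix(sl, dim[1], dim[2])
  }
  mask
}

#' Sectorize the LV into circumferential sectors, regions and levels
#'
#' Divides each slice's myocardium into `n_sectors` circumferentially equal
#' sectors (30 degrees each for 12), counting counterclockwise (viewed from
#' the apex) from the ray that joins the slice's endocardial center to the
#' anterior right-ventricular insertion point. Sectors map pairwise onto the
#' six anatomical regions in order AS, PS, PST, PL, AL, ANT. Slices between
#' the apical-most and basal-most masked slice are split into three equal
#' longitudinal levels (apical, mid, basal; the z axis is ordered apex to
#' base). A voxel exactly on a sector boundary takes the lower sector index.
#'
#' @param mask logical 3D myocardial mask.
#' @param rv_insertion in-plane voxel coordinates (x, y), 0-based, of the
#'   anterior RV insertion point.
#' @param n_sectors circumferential sector count (default 12).
#' @param drop_apical drop this many of the most apical masked slices.
#' @return object of class `sector_map`: integer arrays `sector` (1..12),
#'   `level` (1 apical, 2 mid, 3 basal) and character array `region`, all NA
#'   off-mask.
#' @export
sectorize <- function(mask, rv_insertion, n_sectors = 12, drop_apical = 0) {
  if (is.null(rv_insertion) || length(rv_insertion) != 2)
    stop("rv_insertion (x, y) is required")
  d <- dim(mask)
  zs <- which(apply(mask, 3, any))
  if (length(zs) == 0) stop("empty mask")
  if (drop_apical > 0) {
    drop <- zs[seq_len(min(drop_apical, length(zs)))]
    mask[, , drop] <- FALSE
    zs <- setdiff(zs, drop)
  }
  centers <- mask_slice_centers(mask)
  sector <- array(NA_integer_, dim = d)
  level <- array(NA_integer_, dim = d)
  zmin <- min(zs); zmax <- max(zs)
  width <- 2 * pi / n_sectors
  for (z in zs) {
    sl <- which(mask[, , z], arr.ind = TRUE)
    ctr <- centers[z, ]
    ref <- atan2(rv_insertion[2] - ctr[2], rv_insertion[1] - ctr[1])
    ang <- atan2(sl[, 2] - 1 - ctr[2], sl[, 1] - 1 - ctr[1])
    rel <- (ang - ref) %% (2 * pi)
    sec <- pmin(floor(rel / width) + 1L, n_sectors)
    lev <- if (zmax == zmin) 1L else
      pmin(floor(3 * (z - zmin) / (zmax - zmin + 1)) + 1L, 3L)
    for (i in seq_len(nrow(sl))) {
      sector[sl[i, 1], sl[i, 2], z] <- sec[i]
      level[sl[i, 1], sl[i, 2], z] <- lev
    }
  }
  region_names <- c("AS", "PS", "PST", "PL", "AL", "ANT")
  region <- array(NA_character_, dim = d)
  ok <- !is.na(sector)
  region[ok] <- region_names[(sector[ok] - 1L) %/% 2L + 1L]
  structure(list(sector = sector, level = level, region = region,
                 n_sectors = n_sectors, mask = mask,
                 region_names = region_names,
                 level_names = c("apical", "mid", "basal"),
                 z_range = c(zmin, zmax)),
            class = "sector_map")
}

#' @export
print.sector_map <- function(x, ...) {
  cat(sprintf("sector_map: %d sectors x 3 levels over %d voxels (slices %d..%d)\n",
              x$n_sectors, sum(!is.na(x$sector)), x$z_range[1], x$z_range[2]))
  invisible(x)
}

#' Regional principal-strain table
#'
#' Mean and SD of the maximum (eps1) and minimum (eps3) principal strains per
#' anatomical region and longitudinal level. With a single subject the SD is
#' across member voxels; with a list of subjects, per-subject regional means
#' are aggregated and the SD is the across-subject sample SD. The layout is
#' 6 regions x 3 levels for each of eps1 and eps3 (36 cells); empty cells are
#' reported as missing, not zero.
#'
#' @param principal a `principal_strain_field` or a list of them (subjects).
#' @param sectors a `sector_map` or a list matching `principal`.
#' @return data.frame with columns `strain`, `level`, `region`, `mean`, `sd`,
#'   `n`, of class `regional_strain_table`.
#' @export
regional_strain_table <- function(principal, sectors) {
  if (inherits(principal, "principal_strain_field")) principal <- list(principal)
  if (inherits(sectors, "sector_map")) sectors <- rep(list(sectors), length(principal))
  region_names <- sectors[[1]]$region_names
  level_names <- sectors[[1]]$level_names
  cells <- expand.grid(region = region_names, level = level_names,
                       strain = c("eps1", "eps3"), stringsAsFactors = FALSE)
  subj_means <- array(NA_real_, dim = c(nrow(cells), length(principal)))
  nvox <- numeric(nrow(cells))
  for (s in seq_along(principal)) {
    ps <- principal[[s]]
    sm <- sectors[[s]]
    for (ci in seq_len(nrow(cells))) {
      sel <- ps$defined & !is.na(sm$region) &
        sm$region == cells$region[ci] &
        sm$level == match(cells$level[ci], level_names)
      vals <- if (cells$strain[ci] == "eps1") ps$eps1[sel] else ps$eps3[sel]
      vals <- vals[is.finite(vals)]
      nvox[ci] <- nvox[ci] + length(vals)
      if (length(vals)) subj_means[ci, s] <- mean(vals)
    }
  }
  if (length(principal) == 1) {
    # voxel-level statistics for a single subject
    res <- cells
    res$mean <- NA_real_
    res$sd <- NA_real_
    res$n <- 0L
    ps <- principal[[1]]; sm <- sectors[[1]]
    for (ci in seq_len(nrow(cells))) {
      sel <- ps$defined & !is.na(sm$region) &
        sm$region == cells$region[ci] &
        sm$level == match(cells$level[ci], level_names)
      vals <- if (cells$strain[ci] == "eps1") ps$eps1[sel] else ps$eps3[sel]
      vals <- vals[is.finite(vals)]
      res$n[ci] <- length(vals)
      if (length(vals)) {
        res$mean[ci] <- mean(vals)
        res$sd[ci] <- if (length(vals) > 1) sd(vals) else 0
      }
    }
  } else {
    res <- cells
    res$mean <- rowMeans(subj_means, na.rm = TRUE)
    res$mean[!is.finite(res$mean)] <- NA_real_
    res$sd <- apply(subj_means, 1, function(v) {
      v <- v[is.finite(v)]
      if (length(v) > 1) sd(v) else if (length(v) == 1) 0 else NA_real_
    })
    res$n <- rowSums(is.finite(subj_means))
  }
  class(res) <- c("regional_strain_table", class(res))
  res
}

#' @export
print.regional_strain_table <- function(x, digits = 3, ...) {
  for (s in unique(x$strain)) {
    cat(s, "(mean +/- SD)\n")
    sub <- x[x$strain == s, ]
    txt <- ifelse(is.na(sub$mean), "--",
                  sprintf("%.*f +/- %.*f", digits, sub$mean, digits, sub$sd))
    m <- matrix(txt, nrow = length(unique(sub$level)), byrow = TRUE,
                dimnames = list(unique(sub$level), unique(sub$region)))
    print(m, quote = FALSE)
  }
  invisible(x)
}

#' Bull's-eye polar map
#'
#' Summarizes a per-voxel field over the LV as an `n_rings x n_sectors`
#' matrix: rings are equal longitudinal bins from the apex (ring 1, inner
#' circle) to the base (outer circle); each cell is the mean over its member
#' voxels; empty cells are `NA`.
#'
#' @param values 3D numeric array defined on the mask.
#' @param sectors a `sector_map`.
#' @param n_rings number of concentric rings (default 22).
#' @return `n_rings x n_sectors` matrix of class `bullseye`.
#' @export
bullseye <- function(values, sectors, n_rings = 22) {
  stopifnot(inherits(sectors, "sector_map"))
  d <- dim(sectors$sector)
  zmin <- sectors$z_range[1]; zmax <- sectors$z_range[2]
  out <- matrix(NA_real_, n_rings, sectors$n_sectors)
  idx <- which(!is.na(sectors$sector) & is.finite(values))
  if (length(idx)) {
    z <- ((idx - 1) %/% (d[1] * d[2])) + 1
    ring <- if (zmax == zmin) rep(1L, length(z)) else
      pmin(floor(n_rings * (z - zmin) / (zmax - zmin + 1)) + 1L, n_rings)
    sec <- sectors$sector[idx]
    agg <- tapply(values[idx], list(ring, sec), mean)
    out[cbind(as.integer(rownames(agg)[row(agg)]),
              as.integer(colnames(agg)[col(agg)]))] <- agg
  }
  structure(out, class = c("bullseye", "matrix"))
}

#' @export
print.bullseye <- function(x, ...) {
  cat(sprintf("bullseye: %d rings (apex -> base) x %d sectors, %d empty cells\n",
              nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}

#' Plot a bull's-eye map
#'
#' @param x a `bullseye` matrix.
#' @param main plot title.
#' @param ... unused.
#' @export
plot.bullseye <- function(x, main = "bull's-eye", ...) {
  n_r <- nrow(x); n_s <- ncol(x)
  cols <- hcl.colors(64, "viridis")
  rng <- range(x, na.rm = TRUE)
  graphics::plot.new()
  graphics::plot.window(c(-1, 1), c(-1, 1), asp = 1)
  for (r in seq_len(n_r)) {
    for (s in seq_len(n_s)) {
      if (is.na(x[r, s])) next
      th <- seq((s - 1) / n_s, s / n_s, length.out = 16) * 2 * pi
      r0 <- (r - 1) / n_r; r1 <- r / n_r
      ci <- cols[pmax(1, pmin(64, round(1 + 63 * (x[r, s] - rng[1]) /
                                          max(rng[2] - rng[1], 1e-12))))]
      graphics::polygon(c(r0 * cos(th), r1 * cos(rev(th))),
                        c(r0 * sin(th), r1 * sin(rev(th))),
                        col = ci, border = NA)
    }
  }
  title(main = main)
  invisible(x)
}
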