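circle_contours <- function(slices, r_endo, r_epi, center = c(20, 20), n = 48,
                            phase = 1) {
  ang <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  rows <- list()
  for (s in slices) for (role in c("endo", "epi")) {
    r <- if (role == "endo") r_endo else r_epi
    rows[[length(rows) + 1]] <- data.frame(
      slice = s, phase = phase, role = role, vertex = seq_len(n),
      x = center[1] + r * cos(ang), y = center[2] + r * sin(ang))
  }
  contour_set(do.call(rbind, rows))
}

test_that("contours interpolate linearly across slices and pass through drawn slices", {
  cs <- rbind(circle_contours(1, 20, 24), circle_contours(3, 20, 24))
  out <- interpolate_contours(contour_set(cs), all_slices = 1:3)
  mid <- out[out$slice == 2 & out$role == "endo", ]
  radii <- sqrt((mid$x - 20)^2 + (mid$y - 20)^2)
  expect_true(all(abs(radii - 20) < 0.5))
  mide <- out[out$slice == 2 & out$role == "epi", ]
  expect_true(all(abs(sqrt((mide$x - 20)^2 + (mide$y - 20)^2) - 24) < 0.5))
  expect_true(all(out$provenance[out$slice == 2] == "interpolated"))
  expect_true(all(out$provenance[out$slice %in% c(1, 3)] == "given"))
  g1 <- out[out$slice == 1 & out$role == "endo", ]
  expect_true(all(abs(sqrt((g1$x - 20)^2 + (g1$y - 20)^2) - 20) < 1e-6))
  expect_error(interpolate_contours(circle_contours(1, 20, 24), 1:3), "2 slices")
})

test_that("varying radii interpolate to the midpoint value", {
  cs <- rbind(circle_contours(1, 20, 26), circle_contours(3, 16, 22))
  out <- interpolate_contours(cs, 1:3)
  mid <- out[out$slice == 2 & out$role == "endo", ]
  expect_true(all(abs(sqrt((mid$x - 20)^2 + (mid$y - 20)^2) - 18) < 0.5))
})

test_that("temporal propagation leaves contours unchanged under zero displacement", {
  cs <- rbind(circle_contours(1, 10, 14, center = c(11, 11)),
              circle_contours(5, 10, 14, center = c(11, 11)))
  d <- c(32, 32, 6)
  fit <- structure(list(
    displacements = list(array(0, c(d, 3)), array(0, c(d, 3))),
    spacing = c(1, 1, 1),
    config = ofm_config()), class = "ofm_track")
  out <- interpolate_contours(cs, 1:5, all_phases = 1:2, fit = fit,
                              spacing = c(1, 1, 1))
  p2 <- out[out$phase == 2 & out$slice == 1 & out$role == "endo", ]
  p1 <- out[out$phase == 1 & out$slice == 1 & out$role == "endo", ]
  expect_equal(p2$x, p1$x, tolerance = 1e-10)
  expect_equal(p2$y, p1$y, tolerance = 1e-10)
})

test_that("rasterized annulus matches its analytic area and rejects bad nesting", {
  d <- c(40, 40, 3)
  cs <- circle_contours(2, 10, 16, center = c(19.5, 19.5), n = 96)
  mask <- myocardial_mask(cs, d, spacing = c(1, 1, 1))
  expect_equal(sum(mask[, , 1]), 0)
  area <- sum(mask[, , 2])
  expect_lt(abs(area - pi * (16^2 - 10^2)) / (pi * (16^2 - 10^2)), 0.05)
  # a point outside the epicardium is excluded
  expect_false(mask[38, 38, 2])
  # degenerate endo = epi gives an empty slice with a warning
  eq <- circle_contours(1, 12, 12, center = c(19.5, 19.5))
  expect_warning(m0 <- myocardial_mask(eq, d, c(1, 1, 1)), "empty")
  expect_equal(sum(m0), 0)
  bad <- circle_contours(1, 18, 12, center = c(19.5, 19.5))
  expect_error(myocardial_mask(bad, d, c(1, 1, 1)), "inside")
})

annulus_mask <- function(d = c(40, 40, 9), r0 = 8, r1 = 15) {
  pts <- tagflow3d:::grid_points(d)
  ctr <- (d - 1) / 2
  r <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
  array(r >= r0 & r <= r1, d)
}

test_that("sectorization divides the wall into 12 equal sectors and 3 levels", {
  mask <- annulus_mask()
  d <- dim(mask)
  ctr <- (d[1:2] - 1) / 2
  rv <- c(ctr[1] + 14, ctr[2])  # insertion point along +x
  sm <- sectorize(mask, rv)
  expect_s3_class(sm, "sector_map")
  # every masked voxel gets exactly one sector and level
  expect_true(all(!is.na(sm$sector[mask])))
  expect_true(all(is.na(sm$sector[!mask])))
  expect_true(all(sm$sector[mask] %in% 1:12))
  expect_true(all(sm$level[mask] %in% 1:3))
  # sector angular widths are 30 degrees (up to one-voxel quantization)
  pts <- tagflow3d:::grid_points(d)
  ang <- (atan2(pts[, 2] - ctr[2], pts[, 1] - ctr[1])) %% (2 * pi)
  for (s in 1:12) {
    a <- ang[which(sm$sector == s)]
    expect_gt(length(a), 0)
  }
  counts <- table(sm$sector[mask])
  expect_lt(max(counts) / min(counts), 1.3)
  # a voxel on the reference ray is sector 1 / region AS
  vx <- round(ctr[1]) + 12
  expect_equal(sm$sector[vx + 1, round(ctr[2]) + 1, 5], 1L)
  expect_equal(sm$region[vx + 1, round(ctr[2]) + 1, 5], "AS")
  # 9 masked slices -> 3 levels of 3 slices each
  lv <- apply(sm$level, 3, function(x) unique(x[!is.na(x)]))
  expect_equal(unlist(lv), rep(1:3, each = 3))
  expect_error(sectorize(mask, NULL), "rv_insertion")
})

test_that("rotating the insertion point by 30 degrees shifts every sector by one", {
  mask <- annulus_mask()
  d <- dim(mask)
  ctr <- (d[1:2] - 1) / 2
  a0 <- 0.3
  rv1 <- ctr + 14 * c(cos(a0), sin(a0))
  rv2 <- ctr + 14 * c(cos(a0 + pi / 6), sin(a0 + pi / 6))
  s1 <- sectorize(mask, rv1)$sector
  s2 <- sectorize(mask, rv2)$sector
  ok <- !is.na(s1)
  expect_true(all(((s1[ok] - 1 - 1) %% 12) + 1 == s2[ok]))
})

test_that("regional strain table reproduces uniform and two-subject statistics", {
  mask <- annulus_mask()
  d <- dim(mask)
  ctr <- (d[1:2] - 1) / 2
  sm <- sectorize(mask, c(ctr[1] + 14, ctr[2]))
  mkps <- function(e1, e3) {
    structure(list(eps1 = array(e1, d), eps2 = array(0, d),
                   eps3 = array(e3, d), alpha = array(10, d),
                   defined = mask, mask = mask),
              class = "principal_strain_field")
  }
  tab <- regional_strain_table(mkps(0.15, -0.1), sm)
  expect_equal(nrow(tab), 36)
  expect_equal(sum(tab$strain == "eps1"), 18)
  expect_equal(sum(tab$strain == "eps3"), 18)
  expect_true(all(abs(tab$mean[tab$strain == "eps1"] - 0.15) < 1e-12))
  expect_true(all(tab$sd[tab$strain == "eps1"] == 0))
  # two subjects with uniform 0.1 and 0.2: mean 0.15, sample SD 0.0707
  tab2 <- regional_strain_table(list(mkps(0.1, -0.1), mkps(0.2, -0.2)),
                                list(sm, sm))
  e1 <- tab2[tab2$strain == "eps1", ]
  expect_true(all(abs(e1$mean - 0.15) < 1e-12))
  expect_true(all(abs(e1$sd - sd(c(0.1, 0.2))) < 1e-12))
  expect_equal(sd(c(0.1, 0.2)), 0.0707, tolerance = 1e-3)
  # idempotence: a field equal to its regional means reproduces them
  vals <- array(NA_real_, d)
  for (ci in which(tab$strain == "eps1")) {
    sel <- !is.na(sm$region) & sm$region == tab$region[ci] &
      sm$level == match(tab$level[ci], sm$level_names)
    vals[sel] <- tab$mean[ci]
  }
  tab3 <- regional_strain_table(mkps(0, 0), sm)  # shape check only
  ps <- mkps(0, 0); ps$eps1 <- vals
  tab4 <- regional_strain_table(ps, sm)
  expect_equal(tab4$mean[tab4$strain == "eps1"], tab$mean[tab$strain == "eps1"],
               tolerance = 1e-12)
})

test_that("empty cells are reported missing, not zero", {
  mask <- annulus_mask(d = c(40, 40, 3))  # single level's worth of slices
  d <- dim(mask)
  ctr <- (d[1:2] - 1) / 2
  mask[, , 1] <- FALSE; mask[, , 3] <- FALSE
  sm <- sectorize(mask, c(ctr[1] + 14, ctr[2]))
  ps <- structure(list(eps1 = array(0.1, d), eps2 = array(0, d),
                       eps3 = array(-0.1, d), alpha = array(0, d),
                       defined = mask, mask = mask),
                  class = "principal_strain_field")
  tab <- regional_strain_table(ps, sm)
  expect_true(any(is.na(tab$mean)))
  expect_true(all(tab$n[is.na(tab$mean)] == 0))
})

test_that("bull's-eye has 22 rings x 12 sectors and averages per cell", {
  mask <- annulus_mask()
  d <- dim(mask)
  ctr <- (d[1:2] - 1) / 2
  sm <- sectorize(mask, c(ctr[1] + 14, ctr[2]))
  be <- bullseye(array(0.37, d), sm)
  expect_equal(dim(be), c(22, 12))
  filled <- !is.na(be)
  expect_true(any(filled))
  expect_true(all(abs(be[filled] - 0.37) < 1e-12))
  # 9 slices cannot fill 22 rings: some rings are flagged missing
  expect_true(any(is.na(be)))
  be8 <- bullseye(array(1, d), sm, n_rings = 8)
  expect_equal(dim(be8), c(8, 12))
})
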