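test_that("ssd matches a brute-force loop and vanishes at the optimum", {
  a <- with_test_seed(11, array(runif(8 * 8 * 8), dim = c(8, 8, 8)))
  b <- with_test_seed(12, array(runif(8 * 8 * 8), dim = c(8, 8, 8)))
  expect_equal(as.numeric(ssd(a, a, c(0, 0, 0))), 0)
  # naive elementwise oracle at zero motion
  expect_equal(as.numeric(ssd(a, b, c(0, 0, 0))), sum((b - a)^2), tolerance = 1e-12)
  # integer shift: zero on the overlap region
  sh <- warp_volume(a, uniform_field(dim(a), c(2, 0, -1)), background = NA)
  region <- !is.na(sh)
  sh[!region] <- 0
  expect_equal(as.numeric(ssd(a, sh, c(2, 0, -1), region)), 0, tolerance = 1e-18)
  expect_error(ssd(a, b, region = array(FALSE, dim(a))), "empty")
})

test_that("gauss-newton step is zero at an optimum and exact on quadratic landscapes", {
  a <- with_test_seed(5, gaussian3d(array(rnorm(16^3), dim = c(16, 16, 16)), 1))
  st <- gauss_newton_step(a, a, c(0, 0, 0))
  expect_lt(sqrt(sum(st$du^2)), 1e-6)
  # quadratic ramp pair offset by 0.3 voxel along x: one step recovers it
  d <- c(17, 9, 9)
  pts <- tagflow3d:::grid_points(d)
  La <- array((pts[, 1] - 8)^2, dim = d)
  Lb <- array((pts[, 1] - 0.3 - 8)^2, dim = d)  # Lb(x) = La(x - 0.3)
  region <- array(FALSE, d); region[3:15, 3:7, 3:7] <- TRUE
  st <- gauss_newton_step(La, Lb, c(0, 0, 0), region)
  expect_equal(st$u[1], 0.3, tolerance = 1e-3)
  expect_lt(abs(st$u[2]), 1e-6)
})

test_that("accepted gauss-newton steps never increase the SSD", {
  for (seed in 1:4) {
    a <- with_test_seed(seed, gaussian3d(array(rnorm(12^3), dim = c(12, 12, 12)), 1))
    b <- with_test_seed(seed + 100, gaussian3d(array(rnorm(12^3), dim = c(12, 12, 12)), 1))
    u <- c(0, 0, 0)
    prev <- Inf
    for (it in 1:5) {
      st <- gauss_newton_step(a, b, u)
      expect_lte(st$ssd_after, st$ssd_before + 1e-12)
      expect_lte(st$ssd_after, prev + 1e-12)
      prev <- st$ssd_after
      u <- st$u
      if (!st$accepted) break
    }
  }
})

test_that("global stage recovers identity, translation, and rotation", {
  ph <- small_phantom()
  v <- ph$seq$data[, , , 1]
  dim(v) <- ph$config$grid_shape
  gt0 <- estimate_global(v, v)
  expect_lt(sqrt(sum(c(gt0$t, gt0$omega)^2)), 1e-3)
  # known translation
  tr <- c(1.5, -2.0, 0.5)
  vb <- warp_volume(v, uniform_field(dim(v), tr))
  gt <- estimate_global(v, vb)
  expect_lt(max(abs(gt$t - tr)), 0.1)
  # known rotation: 3 degrees about z through the center
  th <- 3 * pi / 180
  d <- dim(v)
  ctr <- (d - 1) / 2
  pts <- tagflow3d:::grid_points(d)
  px <- pts[, 1] - ctr[1]; py <- pts[, 2] - ctr[2]
  ub <- cbind(px - (cos(th) * px + sin(th) * py),
              py - (-sin(th) * px + cos(th) * py), 0)
  vr <- warp_volume(v, array(ub, c(d, 3)))  # rotates the image by +th
  gtr <- estimate_global(v, vr)
  expect_lt(abs(gtr$omega[3] * 180 / pi - 3), 0.2)
  expect_lt(max(abs(gtr$omega[1:2])) * 180 / pi, 0.2)
})

test_that("local flow is zero on identical pairs and recovers uniform shifts", {
  ph <- small_phantom()
  v <- ph$seq$data[, , , 1]
  dim(v) <- ph$config$grid_shape
  fl0 <- estimate_flow(v, v)
  mag <- sqrt(rowSums(tagflow3d:::field_matrix(fl0$u)^2))
  expect_lt(quantile(mag, 0.99), 0.05)
  vb <- warp_volume(v, uniform_field(dim(v), c(1, 0, 0)))
  flx <- estimate_flow(v, vb)
  inwall <- which(ph$mask)
  um <- tagflow3d:::field_matrix(flx$u)[inwall, ]
  expect_lt(abs(median(um[, 1]) - 1), 0.1)
  expect_lt(abs(median(um[, 2])), 0.1)
  expect_lt(abs(median(um[, 3])), 0.1)
})

test_that("flow is inverse-consistent and translation-equivariant", {
  ph <- small_phantom()
  a <- ph$seq$data[, , , 2]
  b <- ph$seq$data[, , , 3]
  dim(a) <- dim(b) <- ph$config$grid_shape
  inwall <- which(ph$mask)
  fab <- estimate_flow(a, b)
  fba <- estimate_flow(b, a)
  mab <- apply(tagflow3d:::field_matrix(fab$u)[inwall, ], 2, median)
  mba <- apply(tagflow3d:::field_matrix(fba$u)[inwall, ], 2, median)
  expect_lt(max(abs(mab + mba)), 0.1)
  # translating both inputs identically leaves the relative motion unchanged
  shift <- uniform_field(dim(a), c(3, -2, 1))
  a2 <- warp_volume(a, shift)
  b2 <- warp_volume(b, shift)
  f2 <- estimate_flow(a2, b2)
  d <- dim(a)
  interior <- array(FALSE, d)
  interior[8:(d[1] - 7), 8:(d[2] - 7), 4:(d[3] - 3)] <- TRUE
  keep <- interior & ph$mask
  # compare at corresponding (shifted) voxels
  u1 <- fab$u; u2 <- f2$u
  idx <- which(keep, arr.ind = TRUE)
  idx2 <- idx + matrix(rep(c(3, -2, 1), each = nrow(idx)), ncol = 3)
  ok <- idx2[, 1] >= 1 & idx2[, 1] <= d[1] & idx2[, 2] >= 1 & idx2[, 2] <= d[2] &
    idx2[, 3] >= 1 & idx2[, 3] <= d[3]
  for (a3 in 1:3) {
    v1 <- u1[, , , a3][idx[ok, , drop = FALSE]]
    v2 <- u2[, , , a3][idx2[ok, , drop = FALSE]]
    expect_lt(median(abs(v1 - v2)), 0.05)
  }
})

test_that("flow estimation is deterministic", {
  ph <- small_phantom()
  a <- ph$seq$data[, , , 1]
  b <- ph$seq$data[, , , 2]
  dim(a) <- dim(b) <- ph$config$grid_shape
  f1 <- estimate_flow(a, b)
  f2 <- estimate_flow(a, b)
  expect_identical(f1$u, f2$u)
  expect_identical(f1$valid, f2$valid)
})

test_that("track_sequence integrates flow along trajectories", {
  cfg <- small_config()
  base <- make_lv_phantom(cfg)
  v <- base$seq$data[, , , 1]
  dim(v) <- cfg$grid_shape
  # static sequence: everything stays at zero
  static <- vol_sequence(array(v, c(cfg$grid_shape, 3)), cfg$spacing, c(0, 100, 200))
  fs <- track_sequence(static)
  expect_lt(max(abs(fs$displacements[[3]])), 0.05)
  # uniform +0.5 voxel x-shift per phase accumulates linearly
  frames <- array(0, c(cfg$grid_shape, 4))
  for (p in 1:4)
    frames[, , , p] <- warp_volume(v, uniform_field(cfg$grid_shape, c(0.5 * (p - 1), 0, 0)))
  fit <- track_sequence(vol_sequence(frames, cfg$spacing, cfg$phase_times))
  U <- tagflow3d:::field_matrix(fit$displacements[[4]])[which(base$mask), ]
  expect_lt(abs(median(U[, 1]) - 1.5), 0.15)
  expect_lt(abs(median(U[, 2])), 0.15)
  expect_lt(abs(median(U[, 3])), 0.15)
  expect_error(track_sequence(vol_sequence(v, cfg$spacing)), "2 phases")
})

test_that("integration equals an independent per-voxel trajectory oracle", {
  cfg <- phantom_config(grid_shape = c(16, 16, 8), n_phases = 3,
                        endo_radius = 2.5, epi_radius = 4.5, wall_extent = 6)
  ph <- lv_phantom_sequence(cfg, deformation_model(3, 0.08, 0.8))
  fit <- track_sequence(ph$seq)
  d <- cfg$grid_shape
  # oracle: explicit loop using an independent R trilinear interpolator
  flows <- lapply(fit$flows, function(f) f$u)
  pts <- tagflow3d:::grid_points(d)
  for (v in sample.int(nrow(pts), 40)) {
    U <- c(0, 0, 0)
    for (p in 1:2) {
      pos <- pts[v, ] + U
      inc <- c(trilinear_oracle(array(flows[[p]][, , , 1], d), pos),
               trilinear_oracle(array(flows[[p]][, , , 2], d), pos),
               trilinear_oracle(array(flows[[p]][, , , 3], d), pos))
      inc[is.na(inc)] <- 0
      U <- U + inc
    }
    got <- fit$displacements[[3]][pts[v, 1] + 1, pts[v, 2] + 1, pts[v, 3] + 1, ]
    expect_equal(unname(got), unname(U), tolerance = 1e-6)
  }
})

test_that("slice-wise 2D tracking matches 3D in-plane when motion is in-plane", {
  cfg <- small_config()
  base <- make_lv_phantom(cfg)
  v <- base$seq$data[, , , 1]
  dim(v) <- cfg$grid_shape
  frames <- array(0, c(cfg$grid_shape, 3))
  for (p in 1:3)
    frames[, , , p] <- warp_volume(v, uniform_field(cfg$grid_shape, c(0.4 * (p - 1), -0.3 * (p - 1), 0)))
  seqv <- vol_sequence(frames, cfg$spacing, c(0, 100, 200))
  fit2 <- estimate_flow_2d(seqv)
  fit3 <- track_sequence(seqv)
  expect_true(all(is.na(fit2$displacements[[3]][, , , 3])))
  inwall <- which(base$mask)
  for (a in 1:2) {
    m2 <- median(fit2$displacements[[3]][, , , a][inwall])
    m3 <- median(fit3$displacements[[3]][, , , a][inwall])
    expect_lt(abs(m2 - m3), 0.1)
  }
  # static sequence in 2D mode is also ~0
  st <- estimate_flow_2d(vol_sequence(array(v, c(cfg$grid_shape, 2)), cfg$spacing))
  expect_lt(max(abs(st$displacements[[2]][, , , 1:2])), 0.05)
})

test_that("the tracker object supports the usual model-fit methods", {
  ph <- small_phantom()
  fit <- track_sequence(ph$seq)
  expect_s3_class(fit, "ofm_track")
  expect_output(print(fit), "ofm_track")
  sm <- summary(fit)
  expect_equal(nrow(sm), 4)
  expect_true(all(diff(sm$median_disp_vox) > -0.05))
  cf <- coef(fit)
  expect_equal(dim(cf), c(3, 7))
  rs <- residuals(fit)
  expect_length(rs, 3)
  pr <- predict(fit, positions = cbind(15, 15, 5), phase = 4)
  expect_equal(dim(pr), c(1, 3))
  expect_true(all(is.finite(pr)))
})
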