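test_that("untagged phantom has a bright textured wall, dark cavity, and is reproducible", {
  cfg <- small_config()
  ph <- make_lv_phantom(cfg)
  v <- ph$seq$data[, , , 1]
  expect_true(all(v[ph$mask] > 0))
  expect_true(all(v[ph$mask] <= cfg$M0))
  geo <- tagflow3d:::phantom_geometry(cfg)
  midz <- round((geo$z_apex + geo$z_base) / 2) + 1
  sl <- v[, , midz]
  cav <- sl[!ph$mask[, , midz] & sl > 0 & sl < 0.2]  # cavity voxels are the dim interior
  expect_lt(mean(ph$seq$data[, , , 1][!ph$mask & ph$seq$data[, , , 1] > 0 &
                                        ph$seq$data[, , , 1] < 0.2]),
            0.2 * mean(v[ph$mask]))
  ph2 <- make_lv_phantom(cfg)
  expect_identical(ph$seq$data, ph2$seq$data)
  ph3 <- make_lv_phantom(small_config(texture_seed = 99))
  expect_false(identical(ph$seq$data, ph3$seq$data))
})

test_that("mask volume matches the analytic annulus volume on a 64^3 grid", {
  cfg <- phantom_config(grid_shape = c(64, 64, 64), spacing = c(1, 1, 1),
                        n_phases = 1, endo_radius = 12, epi_radius = 20,
                        wall_extent = 40)
  ph <- make_lv_phantom(cfg)
  analytic <- pi * (cfg$epi_radius^2 - cfg$endo_radius^2) * cfg$wall_extent
  voxel <- sum(ph$mask) * prod(cfg$spacing)
  expect_lt(abs(voxel - analytic) / analytic, 0.10)
})

test_that("impossible geometry is rejected with a message", {
  expect_error(phantom_config(grid_shape = c(16, 16, 16), endo_radius = 10,
                              epi_radius = 30), "exceeds")
  expect_error(phantom_config(endo_radius = 17, epi_radius = 10), "endo_radius")
  expect_error(phantom_config(T1 = -1), "T1")
  expect_error(phantom_config(grid_shape = c(4, 4, 4)), "grid_shape")
})

test_that("third tag normal follows the beta/azimuth convention and is unit length", {
  expect_equal(third_tag_normal(90), c(0, 0, 1), tolerance = 1e-12)
  expect_equal(third_tag_normal(0), c(sqrt(2) / 2, sqrt(2) / 2, 0), tolerance = 1e-12)
  for (b in seq(0, 90, by = 15))
    expect_equal(sqrt(sum(third_tag_normal(b)^2)), 1, tolerance = 1e-12)
  expect_error(third_tag_normal(-5), "beta")
  expect_error(third_tag_normal(120), "beta")
})

test_that("tag field saturates at t = 0 and recovers with T1 relaxation", {
  d <- c(16, 16, 8)
  spec <- tag_spec(normal = c(1, 0, 0), spacing = 6, width = 2)
  f0 <- tag_field(spec, d, t = 0)
  # voxels with x %% 6 == 0 are on stripe centers
  expect_equal(f0[1, 5, 3], 0)
  expect_equal(f0[7, 2, 2], 0)
  expect_equal(f0[4, 5, 3], 1)   # off stripe, exactly 1
  f900 <- tag_field(spec, d, t = 900, T1 = 900)
  expect_equal(f900[1, 5, 3], 1 - exp(-1), tolerance = 1e-12)
  expect_equal(f900[4, 5, 3], 1)
  # monotone non-decreasing in t on stripes, bounded in [0, 1]
  prev <- f0
  for (t in c(50, 150, 400, 2000, 10000)) {
    cur <- tag_field(spec, d, t)
    expect_true(all(cur >= prev - 1e-12))
    expect_true(all(cur >= 0 & cur <= 1))
    prev <- cur
  }
  expect_equal(max(abs(tag_field(spec, d, 1e9) - 1)), 0, tolerance = 1e-9)
})

test_that("tag spec validates its geometry", {
  expect_error(tag_spec(spacing = 6, width = 6), "width")
  expect_error(tag_spec(spacing = 6, width = 0), "width")
  expect_error(tag_spec(normal = c(0, 0, 0)), "normal")
  sp <- tag_spec(normal = c(2, 0, 0))
  expect_equal(sp$normal, c(1, 0, 0))
})

test_that("apply_tags multiplies fields in, darkens stripes, and fades with time", {
  cfg <- small_config(n_phases = 3, phase_times = c(0, 100, 300))
  base <- make_lv_phantom(cfg)
  expect_identical(apply_tags(base$seq, list()), base$seq)
  specs <- list(tag_spec(c(1, 0, 0)), tag_spec(c(0, 1, 0)), tag_spec(beta_deg = 30))
  tagged <- apply_tags(base$seq, specs, T1 = cfg$T1)
  # output never exceeds the base (tag fields are in [0, 1])
  expect_true(all(tagged$data <= base$seq$data + 1e-12))
  # any voxel on an x-stripe is exactly zero at t = 0
  expect_equal(max(abs(tagged$data[1, , , 1])), 0)
  # stripe/background contrast decays as tags fade: t = 300 lower than t = 100
  stripe <- array(tag_field(specs[[1]], cfg$grid_shape, 0) == 0, cfg$grid_shape)
  myo <- base$mask
  contrast <- function(p) {
    fr <- tagged$data[, , , p]
    mean(fr[myo & !stripe]) - mean(fr[myo & stripe])
  }
  expect_gt(contrast(2), contrast(3))
})

test_that("synthetic displacement is zero at fraction 0, linear in fraction, and wrings", {
  cfg <- small_config()
  model <- deformation_model(4, 0.1, 1.5)
  expect_equal(max(abs(synth_displacement(model, cfg, 0))), 0)
  u1 <- synth_displacement(model, cfg, 1)
  for (lam in c(0.25, 0.5, 0.8)) {
    ul <- synth_displacement(model, cfg, lam)
    expect_equal(ul, lam * u1, tolerance = 1e-12)
  }
  # pure longitudinal: base slice moves by -shortening/sz, apex end fixed
  lng <- deformation_model(0, 0, 1.5)
  ul <- synth_displacement(lng, cfg, 1)
  geo <- tagflow3d:::phantom_geometry(cfg)
  expect_equal(max(abs(ul[, , , 1:2])), 0)
  zb <- round(geo$z_base) + 1
  expect_equal(ul[4, 4, zb, 3],
               -1.5 / cfg$spacing[3] * (zb - 1 - geo$z_apex) / (geo$z_base - geo$z_apex),
               tolerance = 1e-12)
  # pure torsion: no through-plane motion; apex and base rotate oppositely
  tor <- deformation_model(4, 0, 0)
  ut <- synth_displacement(tor, cfg, 1)
  expect_equal(max(abs(ut[, , , 3])), 0)
  ctr <- geo$center
  ang_at <- function(z) {
    x <- round(ctr[1]) + 6; y <- round(ctr[2])
    p0 <- c(x, y) - ctr[1:2]
    p1 <- p0 + c(ut[x + 1, y + 1, z + 1, 1], ut[x + 1, y + 1, z + 1, 2])
    atan2(p1[2], p1[1]) - atan2(p0[2], p0[1])
  }
  a_apex <- ang_at(ceiling(geo$z_apex))
  a_base <- ang_at(floor(geo$z_base))
  expect_lt(a_apex * a_base, 0)  # opposite signs: the wringing effect
  expect_equal(a_apex, -a_base, tolerance = 0.02)
})

test_that("backward warp is the identity at zero motion and exact for integer shifts", {
  v <- textured_volume(c(16, 16, 12))
  expect_identical(warp_volume(v, uniform_field(dim(v), c(0, 0, 0))), v)
  sh <- warp_volume(v, uniform_field(dim(v), c(2, -1, 1)), background = -99)
  # output(r) = input(r - u): overlap region matches the shifted input exactly
  expect_equal(sh[3:16, 1:15, 2:12], v[1:14, 2:16, 1:11], tolerance = 1e-14)
  expect_true(all(sh[1:2, , ] == -99))
  expect_error(warp_volume(v, uniform_field(c(8, 8, 8), c(0, 0, 0))), "grid")
})

test_that("warp round trip on the band-limited phantom loses little intensity", {
  cfg <- small_config()
  base <- make_lv_phantom(cfg)$seq$data[, , , 1]
  dim(base) <- cfg$grid_shape
  # interpolation loss scales with image bandwidth; test at the tag scale
  base <- gaussian3d(base, 1)
  d <- cfg$grid_shape
  pts <- tagflow3d:::grid_points(d)
  # smooth displacement, max 1 voxel
  u <- cbind(sin(pts[, 1] / 8) * cos(pts[, 2] / 9),
             cos(pts[, 3] / 5) * sin(pts[, 2] / 7),
             0.5 * sin(pts[, 1] / 10 + pts[, 3] / 6))
  uf <- array(u, c(d, 3))
  fwd <- warp_volume(base, uf)
  back <- warp_volume(fwd, -uf)
  interior <- array(FALSE, d)
  interior[3:(d[1] - 2), 3:(d[2] - 2), 3:(d[3] - 2)] <- TRUE
  expect_lt(mean(abs(back[interior] - base[interior])), 0.02 * cfg$M0)
})

test_that("additive noise has the prescribed level and is reproducible", {
  v <- array(0.5, dim = c(50, 50, 50))
  v[1] <- 2  # max intensity 2 -> sigma = 0.4 at 20%
  expect_identical(add_noise(v, 0), v)
  n1 <- add_noise(v, 20, seed = 3)
  expect_equal(sd(n1 - v), 0.4, tolerance = 0.008)
  expect_identical(n1, add_noise(v, 20, seed = 3))
  expect_false(identical(n1, add_noise(v, 20, seed = 4)))
})

test_that("the assembled phantom exports consistent ground truth", {
  ph <- small_phantom()
  expect_s3_class(ph, "lv_phantom")
  expect_length(ph$truth, 4)
  expect_equal(max(abs(ph$truth[[1]])), 0)
  # warping the observed end-systolic frame back by the exact inverse of the
  # motion recovers the tagged reference frame (interior)
  cfg <- ph$config
  ub <- synth_displacement(ph$model, cfg, 1, type = "backward")
  d <- cfg$grid_shape
  ref <- ph$seq$data[, , , 1]; es <- ph$seq$data[, , , 4]
  dim(ref) <- dim(es) <- d
  # sample the forward-warped frame at deformed positions of masked voxels
  pts <- tagflow3d:::grid_points(d)[which(ph$mask), ]
  fw <- tagflow3d:::field_matrix(ph$truth[[4]])[which(ph$mask), ]
  # account for fading: compare tag-free base instead
  ph0 <- lv_phantom_sequence(cfg, ph$model, tags = FALSE)
  ref0 <- ph0$seq$data[, , , 1]; es0 <- ph0$seq$data[, , , 4]
  dim(ref0) <- dim(es0) <- d
  vals <- tagflow3d:::sample_volume(es0, pts + fw, NA_real_)
  keep <- is.finite(vals)
  expect_gt(mean(keep), 0.95)
  ref_vals <- ref0[which(ph$mask)][keep]
  # agreement is limited by double interpolation of the speckle texture
  expect_gt(cor(vals[keep], ref_vals), 0.75)
  expect_lt(median(abs(vals[keep] - ref_vals)), 0.15)
  # same seed gives bit-identical phantoms
  ph2 <- lv_phantom_sequence(small_config(), deformation_model(4, 0.1, 1.5))
  expect_identical(ph$seq$data, ph2$seq$data)
})
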