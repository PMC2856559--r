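# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small deforming tagged phantom used by most ofm/strain tests
small_config <- function(n_phases = 4, ...) {
  phantom_config(grid_shape = c(32, 32, 12), n_phases = n_phases,
                 endo_radius = 5, epi_radius = 9, wall_extent = 12, ...)
}

small_phantom <- function() {
  cached("small_phantom",
         lv_phantom_sequence(small_config(), deformation_model(4, 0.1, 1.5)))
}

# static textured volume (no tags, no motion) for registration tests
textured_volume <- function(dim = c(24, 24, 16), seed = 42, sigma = 1) {
  v <- with_test_seed(seed, array(rnorm(prod(dim)), dim = dim))
  gaussian3d(v, sigma)
}

with_test_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# independent trilinear interpolation oracle (pure R, no package code)
trilinear_oracle <- function(vol, p) {
  d <- dim(vol)
  if (any(p < 0) || any(p > d - 1)) return(NA_real_)
  i0 <- pmin(floor(p), d - 2)
  f <- p - i0
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[1] else 1 - f[1]) *
         (if (dy) f[2] else 1 - f[2]) *
         (if (dz) f[3] else 1 - f[3])
    acc <- acc + w * vol[i0[1] + dx + 1, i0[2] + dy + 1, i0[3] + dz + 1]
  }
  acc
}

# uniform displacement field helper
uniform_field <- function(dim, u) {
  array(rep(u, each = prod(dim)), dim = c(dim, 3))
}
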