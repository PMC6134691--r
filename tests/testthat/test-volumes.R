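# Map I/O, grid normalization, and the common-volume resize pipeline.

test_that("MRC round-trip preserves grid, spacing, and clamps negatives", {
  set.seed(1)
  g <- array(round(runif(1000), 4), c(10, 10, 10))  # float32-exact values
  g[1, 1, 1] <- 0.5
  m <- density_map(g, spacing = 2, origin = c(1, 2, 3), name = "rt")
  path <- withr::local_tempfile(fileext = ".mrc")
  save_density_map(m, path)
  m2 <- load_density_map(path)
  expect_equal(m2$grid, m$grid, tolerance = 1e-6)
  expect_equal(m2$spacing, c(2, 2, 2))
  expect_equal(m2$origin, c(1, 2, 3), tolerance = 1e-6)

  # negative voxels are clamped at load time
  gneg <- g
  gneg[2, 3, 4] <- -0.5
  shapesearch:::write_mrc(path, gneg, spacing = 1)
  m3 <- load_density_map(path)
  expect_identical(m3$grid[2, 3, 4], 0)
  expect_true(all(m3$grid >= 0))
})

test_that("unreadable or truncated files raise format errors naming the field", {
  path <- withr::local_tempfile(fileext = ".mrc")
  writeBin(raw(100), path)
  expect_error(load_density_map(path), "header")
  # valid header, truncated data
  g <- array(1, c(8, 8, 8))
  shapesearch:::write_mrc(path, g)
  raw_all <- readBin(path, "raw", file.size(path))
  writeBin(raw_all[1:(1024 + 100)], path)
  expect_error(load_density_map(path), "data")
  expect_error(load_density_map(tempfile()), "not found")
})

test_that("anisotropic-spacing maps resample with bounded mass drift", {
  set.seed(2)
  blob <- make_density(shape_spec("sphere", list(radius = 12)))
  # simulate an anisotropic acquisition: subsample z by 2, spacing (1, 1, 2)
  g <- blob$grid[, , seq(1, 100, by = 2)]
  m <- density_map(g, spacing = c(1, 1, 2), name = "aniso")
  norm <- normalize_grid(m)
  expect_equal(dim(norm$grid), rep(100L, 3))
  expect_equal(norm$spacing, c(1, 1, 1))
  expect_lt(abs(total_mass(norm) / total_mass(m) - 1), 0.01)
})

test_that("normalize_grid is the identity on standard grids and conserves mass", {
  m <- fix_map("sphere")
  expect_lt(max(abs(normalize_grid(m)$grid - m$grid)), 1e-9)

  # 50^3 at 2 A -> 100^3 at 1 A with mass ratio in [0.99, 1.01]
  down <- shapesearch:::resample_map(m, scale = 1, out_dim = 50,
                                     out_spacing = 2)
  norm <- normalize_grid(down)
  expect_equal(dim(norm$grid), rep(100L, 3))
  expect_true(abs(total_mass(norm) / total_mass(down) - 1) <= 0.01)

  # sphere radius is preserved by the resampling (half-max isocontour)
  sph <- make_density(shape_spec("sphere", list(radius = 20)))
  small <- shapesearch:::resample_map(sph, scale = 1, out_dim = 50,
                                      out_spacing = 2)
  renorm <- normalize_grid(small)
  expect_lt(abs(halfmax_radius(renorm) - halfmax_radius(sph)), 1)

  empty <- density_map(array(0, c(10, 10, 10)))
  expect_error(normalize_grid(empty), "zero total mass")
})

test_that("rescale_axis_dimension implements D_old * D_ref / V_old^(1/3)", {
  expect_equal(rescale_axis_dimension(125000, D_old = 100, D_ref = 50), 100)
  expect_equal(rescale_axis_dimension(1e6), 50)
  expect_equal(rescale_axis_dimension(8000), 250)
  expect_error(rescale_axis_dimension(0), "positive")
  expect_error(rescale_axis_dimension(-5), "positive")
})

test_that("resize_to_common_volume brings spheres of any radius to a common size", {
  # scale invariance needs true scaled copies: the soft edge is part of the
  # shape, so it scales with the radius (see the methods vignette)
  m10 <- make_density(shape_spec("sphere", list(radius = 10), soft_edge = 1))
  m20 <- make_density(shape_spec("sphere", list(radius = 20), soft_edge = 2))
  resize_one <- function(m) {
    g <- fit_gmm(m, K = 8, seed = 3)
    resize_to_common_volume(m, estimate_volume(g))
  }
  r10 <- resize_one(m10)
  r20 <- resize_one(m20)
  # equal half-max radii within 1 voxel after volume normalization
  expect_lt(abs(halfmax_radius(r10) - halfmax_radius(r20)), 1)
  # near-identity for a map already at the reference volume
  g20 <- fit_gmm(r20, K = 8, seed = 3)
  V <- estimate_volume(g20)
  expect_gt(V, 0.90 * 50^3)
  expect_lt(V, 1.10 * 50^3)
  # idempotency: resizing again changes the estimated volume by < 2%
  r20b <- resize_to_common_volume(r20, V)
  V2 <- estimate_volume(fit_gmm(r20b, K = 8, seed = 3))
  expect_lt(abs(V2 / V - 1), 0.02)
  expect_error(resize_to_common_volume(r20, V_old = 1),
               "implausible")
})

test_that("the resize pipeline is scale invariant (stretched dumbbell)", {
  base <- shape_spec("dumbbell")
  big <- shape_spec("dumbbell", sizes = lapply(base$sizes, `*`, 1.5),
                    soft_edge = 3)
  # K = 12: coarser decompositions of near-degenerate shapes can land in
  # different local optima for the two resamplings
  pipeline_gmm <- function(spec) {
    m <- make_density(spec)
    g <- fit_gmm(m, K = 12, seed = 4)
    r <- resize_to_common_volume(m, estimate_volume(g))
    fit_gmm(r, K = 12, seed = 4)
  }
  gA <- pipeline_gmm(base)
  gB <- pipeline_gmm(big)
  cc <- superpose_gmms(gA, gB, n_starts = 6, seed = 5)$cc
  expect_gte(cc, 0.99)
})
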