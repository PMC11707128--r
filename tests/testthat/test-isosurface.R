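test_that("a field with no iso-crossing yields an empty mesh with a warning", {
  z <- array(0, c(8, 8, 8))
  expect_warning(m <- marching_cubes(z, 0.5), "empty")
  expect_identical(nrow(m$faces), 0L)
  expect_error(marching_cubes(array(0, c(1, 4, 4)), 0.5), "2 samples")
})

test_that("iso-surface of a smoothed ball matches analytic area and volume", {
  r <- 20
  ball <- voxel_ball(48, r)
  sm <- gaussian_smooth(ball, 1.0)
  mesh <- marching_cubes(sm, 0.5)
  expect_lt(abs(mesh_area(mesh) / (4 * pi * r^2) - 1), 0.05)
  expect_lt(abs(mesh_volume(mesh) / (4 / 3 * pi * r^3) - 1), 0.05)
  expect_true(mesh_is_watertight(mesh))
  # enclosed volume is accurate even on the raw binary field
  raw <- marching_cubes(array(as.double(ball), dim = dim(ball)), 0.5)
  expect_lt(abs(mesh_volume(raw) / (4 / 3 * pi * r^3) - 1), 0.05)
})

test_that("iso-surface vertices honour spacing and origin; origin only translates", {
  ball <- gaussian_smooth(voxel_ball(24, 8), 1)
  m0 <- marching_cubes(ball, 0.5, spacing = c(1, 1, 1), origin = c(0, 0, 0))
  m1 <- marching_cubes(ball, 0.5, spacing = c(1, 1, 1), origin = c(10, -4, 2))
  expect_equal(m1$vertices, sweep(m0$vertices, 2, c(10, -4, 2), "+"))
  expect_identical(m1$faces, m0$faces)
  # anisotropic spacing scales the axes
  m2 <- marching_cubes(ball, 0.5, spacing = c(2, 1, 1))
  expect_equal(mesh_volume(m2), 2 * mesh_volume(m0), tolerance = 1e-9)
})

test_that("greedy voxelization counts match box arithmetic exactly", {
  g <- list(shape = c(8L, 8L, 8L), spacing = c(1, 1, 1),
            origin = c(0.5, 0.5, 0.5))
  cube <- mesh_box(c(0, 0, 0), c(4, 4, 4))
  expect_identical(sum(greedy_voxelize(cube, g)$data), 64L)
  # +0.25 voxel shift: boundary voxels partially covered count -> 5 x 4 x 4
  expect_identical(sum(greedy_voxelize(translate_mesh(cube, c(0.25, 0, 0)), g)$data),
                   80L)
})

test_that("greedy mask is a superset of the centre-containment mask", {
  g <- list(shape = c(16L, 16L, 16L), spacing = c(1, 1, 1),
            origin = c(0.5, 0.5, 0.5))
  sph <- mesh_icosphere(radius = 5, center = c(8, 8, 8), subdivisions = 3)
  gr <- greedy_voxelize(sph, g)
  ci <- greedy_voxelize(sph, g, greedy = FALSE)
  expect_true(all(gr$data[ci$data]))
  expect_gt(sum(gr$data), sum(ci$data))
  # random blobs: smoothed random fields meshed at their median
  for (seed in 1:3) {
    fld <- with_seed(seed, array(stats::rnorm(20^3), c(20, 20, 20)))
    fld <- gaussian_smooth(fld, 2.5)
    iso <- stats::quantile(fld, 0.85)
    blob <- marching_cubes(fld, iso, spacing = c(1, 1, 1), origin = c(1, 1, 1))
    gg <- list(shape = c(20L, 20L, 20L), spacing = c(1, 1, 1), origin = c(1, 1, 1))
    grb <- greedy_voxelize(blob, gg)
    cib <- greedy_voxelize(blob, gg, greedy = FALSE)
    expect_true(all(grb$data[cib$data]))
  }
})

test_that("voxelize + mesh round-trip recovers a cube volume within a voxel shell", {
  cube <- mesh_box(c(2, 2, 2), c(18, 18, 18))
  g <- list(shape = c(24L, 24L, 24L), spacing = c(1, 1, 1), origin = c(0, 0, 0))
  mask <- greedy_voxelize(cube, g)
  back <- marching_cubes(array(as.double(mask$data), dim = dim(mask$data)), 0.5,
                         spacing = mask$spacing, origin = mask$origin)
  side <- 16
  shell <- (side + 2)^3 - side^3  # one-voxel shell allowance
  expect_lt(abs(mesh_volume(back) - side^3), shell)
})

test_that("point containment and distances agree with geometry", {
  sph <- mesh_icosphere(radius = 5, center = c(0, 0, 0), subdivisions = 3)
  pts <- rbind(c(0, 0, 0), c(4.9, 0, 0), c(5.1, 0, 0), c(10, 10, 10))
  expect_identical(as.logical(points_in_mesh(pts, sph)),
                   c(TRUE, TRUE, FALSE, FALSE))
  d <- point_mesh_distance(rbind(c(0, 0, 0), c(10, 0, 0)), sph)
  expect_equal(d, c(5, 5), tolerance = 0.01)
})
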