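test_that("mesh Dice: identical, disjoint and half-shifted cubes", {
  c1 <- mesh_box(c(0, 0, 0), c(10, 10, 10))
  expect_equal(mesh_dice(c1, c1, 0.5), 1)
  far <- translate_mesh(c1, c(50, 0, 0))
  expect_equal(mesh_dice(c1, far, 0.5), 0)
  shifted <- translate_mesh(c1, c(5, 0, 0))
  expect_equal(mesh_dice(c1, shifted, 0.5), 0.5, tolerance = 0.02)
  # symmetry is exact (shared grid)
  expect_identical(mesh_dice(c1, shifted, 0.5), mesh_dice(shifted, c1, 0.5))
  empty <- triangle_mesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3))
  expect_equal(mesh_dice(c1, empty), 0)
  expect_error(mesh_dice(empty, empty), "undefined")
})

test_that("mesh Dice converges as the pitch is refined", {
  s1 <- mesh_icosphere(radius = 10, subdivisions = 2)
  s2 <- mesh_icosphere(radius = 10, center = c(3, 0, 0), subdivisions = 2)
  d2 <- mesh_dice(s1, s2, 2)
  d1 <- mesh_dice(s1, s2, 1)
  d05 <- mesh_dice(s1, s2, 0.5)
  expect_lt(abs(d1 - d05), abs(d2 - d1) + 0.005)
})

test_that("parallel sheets 2 mm apart give ASD = HD95 = 2", {
  a <- sheet_mesh(side = 100, z = 0)
  b <- sheet_mesh(side = 100, z = 2)
  expect_equal(asd_symmetric(a, b, 20000, seed = 1), 2, tolerance = 0.01)
  expect_equal(hd95_symmetric(a, b, 20000, seed = 1), 2, tolerance = 0.01)
  expect_equal(asd_symmetric(a, a, 5000, seed = 1), 0, tolerance = 1e-9)
  expect_equal(hd95_symmetric(a, a, 5000, seed = 1), 0, tolerance = 1e-9)
})

test_that("concentric spheres: radial distance, fast path vs brute-force oracle", {
  s10 <- mesh_icosphere(radius = 10, subdivisions = 3)
  s12 <- mesh_icosphere(radius = 12, subdivisions = 3)
  expect_equal(asd_symmetric(s10, s12, 20000, seed = 2), 2, tolerance = 0.02)
  # oracle equivalence: accelerated distances == plain-R O(N*M) distances
  pts <- sample_surface(s12, 1500, seed = 8)$points
  expect_equal(point_mesh_distance(pts, s10),
               point_mesh_distance_brute(pts, s10), tolerance = 1e-10)
})

test_that("hd95 ignores a small bump that dominates hd100", {
  base <- mesh_icosphere(radius = 10, subdivisions = 3)
  bump <- base
  # push vertices in a small polar cap (~2-3% of the area) 4 mm outward
  cap <- bump$vertices[, 3] > 9.65
  bump$vertices[cap, ] <- bump$vertices[cap, ] * (14 / 10)
  ref <- mesh_icosphere(radius = 10.5, subdivisions = 3)
  h95 <- hd95_symmetric(ref, bump, 30000, seed = 3)
  da <- point_mesh_distance(sample_surface(ref, 30000, 3)$points, bump)
  db <- point_mesh_distance(sample_surface(bump, 30000, 4)$points, ref)
  h100 <- max(c(da, db))
  expect_gte(h100, 3)           # the bump dominates the maximum
  expect_lt(h95, 1.0)           # ...but not the 95th percentile
  expect_lte(h95, h100)
  # pooled and max variants agree within sampling noise here
  expect_equal(hd95_symmetric(ref, bump, 30000, seed = 3, method = "max"),
               h95, tolerance = 0.25)
})

test_that("directed distances are consistent with the symmetric average", {
  s10 <- mesh_icosphere(radius = 10, subdivisions = 3)
  s11 <- mesh_icosphere(radius = 11, subdivisions = 3)
  pp <- per_point_distances(s10, s11, 10000, seed = 5)
  expect_length(pp$distances, 10000)
  expect_equal(mean(pp$distances), 1, tolerance = 0.02)
  radii <- sqrt(rowSums(pp$points^2))
  expect_true(all(radii <= 10 + 1e-9))     # points lie on the faceted sphere
  expect_true(all(radii > 10 * cos(0.2)))  # within the chord sagitta
  ident <- per_point_distances(s10, s10, 2000, seed = 5)
  expect_true(all(ident$distances < 1e-9))
  # PLY export with distance attribute
  f <- tempfile(fileext = ".ply")
  write_distance_ply(s10, s11, f)
  expect_true(any(grepl("quality", readLines(f, n = 12))))
})

test_that("surface-distance metrics are symmetric in the two meshes", {
  a <- mesh_icosphere(radius = 8, subdivisions = 2)
  b <- translate_mesh(mesh_box(c(-5, -5, -5), c(5, 5, 5)), c(2, 1, 0))
  expect_equal(asd_symmetric(a, b, 20000, seed = 6),
               asd_symmetric(b, a, 20000, seed = 6), tolerance = 0.05)
  expect_equal(hd95_symmetric(a, b, 20000, seed = 6),
               hd95_symmetric(b, a, 20000, seed = 6), tolerance = 0.1)
})

test_that("evaluate_case reports whole plus one scope per ROI", {
  spec <- tiny_phantom_spec(seed = 21, asymmetry = 0)
  ph <- generate_phantom(spec, 1)
  rois <- default_crest_rois()
  rep <- evaluate_case(ph$mesh, ph$mesh, rois, pitch = 1, n_points = 5000)
  expect_identical(rep$scope, c("whole", "left_roi", "right_roi"))
  expect_equal(rep$dsc, c(1, 1, 1))
  expect_true(all(rep$asd_mm < 1e-9))
  expect_true(all(rep$hd95_mm < 1e-9))
  # a deliberate uniform 1 mm inflation gives ASD near 1 mm
  grown <- scale_mesh(ph$mesh, 1 + 1 / 30, geometric_center(ph$mesh))
  rep2 <- evaluate_case(grown, ph$mesh, NULL, pitch = 1, n_points = 10000)
  expect_lt(rep2$dsc[1], 1)
  expect_gt(rep2$asd_mm[1], 0.2)
})
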