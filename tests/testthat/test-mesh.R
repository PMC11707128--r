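test_that("triangle_mesh validates faces", {
  v <- matrix(rnorm(9), 3, 3)
  expect_error(triangle_mesh(v, rbind(c(1, 2, 4))), "out of range")
  expect_error(triangle_mesh(v, rbind(c(1, 2, 2))), "degenerate")
  m <- triangle_mesh(v, rbind(c(1, 2, 3)))
  expect_s3_class(m, "cs_mesh")
})

test_that("STL round-trips: cube topology and icosphere vertices", {
  cube <- mesh_box(c(0, 0, 0), c(1, 1, 1))
  f <- tempfile(fileext = ".stl")
  write_mesh(cube, f)
  back <- read_mesh(f)
  expect_identical(nrow(back$faces), 12L)
  expect_identical(nrow(back$vertices), 8L)  # welded back from the soup
  expect_equal(mesh_volume(back), 1, tolerance = 1e-6)

  ico <- mesh_icosphere(radius = 7.5, center = c(1, 2, 3), subdivisions = 2)
  f2 <- tempfile(fileext = ".stl")
  write_mesh(ico, f2)
  ico2 <- read_mesh(f2)
  expect_identical(nrow(ico2$faces), nrow(ico$faces))
  expect_equal(sort(as.numeric(ico2$vertices)), sort(as.numeric(ico$vertices)),
               tolerance = 1e-6)

  # ASCII STL and PLY round-trips
  fa <- tempfile(fileext = ".stl")
  write_mesh(cube, fa, ascii = TRUE)
  expect_equal(mesh_volume(read_mesh(fa)), 1, tolerance = 1e-9)
  fp <- tempfile(fileext = ".ply")
  write_mesh(ico, fp)
  expect_equal(mesh_area(read_mesh(fp)), mesh_area(ico), tolerance = 1e-5)
})

test_that("writing an empty mesh is refused and malformed files error", {
  empty <- triangle_mesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3))
  expect_error(write_mesh(empty, tempfile(fileext = ".stl")), "empty")
  bad <- tempfile(fileext = ".stl")
  writeLines("not a mesh at all", bad)
  expect_error(read_mesh(bad), "malformed|truncated")
})

test_that("area, volume and centroid match closed forms", {
  cube <- mesh_box(c(-1, -1, -1), c(1, 1, 1))
  expect_equal(mesh_area(cube), 24)
  expect_equal(mesh_volume(cube), 8)
  expect_equal(geometric_center(cube), c(0, 0, 0))
  moved <- translate_mesh(cube, c(5, -3, 2))
  expect_equal(geometric_center(moved), c(5, -3, 2))
  ico <- mesh_icosphere(radius = 10, subdivisions = 3)
  expect_equal(mesh_area(ico), 4 * pi * 100, tolerance = 0.01)
  expect_equal(mesh_volume(ico), 4 / 3 * pi * 1000, tolerance = 0.015)
  expect_true(mesh_is_watertight(ico))
})

test_that("geometric centre of an L-prism matches a dense sampling oracle", {
  # L-shaped prism = union of two boxes sharing a face; build as one mesh
  b1 <- mesh_box(c(0, 0, 0), c(2, 1, 1))
  b2 <- mesh_box(c(0, 1, 0), c(1, 2, 1))
  joined <- triangle_mesh(rbind(b1$vertices, b2$vertices),
                          rbind(b1$faces, b2$faces + nrow(b1$vertices)))
  ctr <- geometric_center(joined)
  s <- sample_surface(joined, 200000, seed = 9)
  expect_equal(ctr, colMeans(s$points), tolerance = 1e-2)
})

test_that("surface sampling is planar, area-proportional and deterministic", {
  tri <- triangle_mesh(rbind(c(0, 0, 0), c(4, 0, 0), c(0, 3, 0)),
                       rbind(c(1, 2, 3)))
  s <- sample_surface(tri, 1000, seed = 2)
  expect_true(all(abs(s$points[, 3]) < 1e-9))  # plane z = 0
  inside <- s$points[, 1] >= 0 & s$points[, 2] >= 0 &
    s$points[, 1] / 4 + s$points[, 2] / 3 <= 1 + 1e-9
  expect_true(all(inside))

  # two triangles with 3:1 area ratio -> 3:1 point counts within 5%
  two <- triangle_mesh(rbind(c(0, 0, 0), c(6, 0, 0), c(0, 3, 0),
                             c(10, 0, 0), c(13, 0, 0), c(10, 2, 0)),
                       rbind(c(1, 2, 3), c(4, 5, 6)))
  s2 <- sample_surface(two, 40000, seed = 3)
  ratio <- sum(s2$face == 1) / sum(s2$face == 2)
  expect_equal(ratio, 3, tolerance = 0.05)

  expect_identical(sample_surface(two, 500, seed = 11),
                   sample_surface(two, 500, seed = 11))
})

test_that("plane clipping splits crossing triangles and conserves area", {
  cube <- mesh_box(c(0, 0, 0), c(1, 1, 1))
  # plane entirely below the mesh: no-op
  same <- clip_by_plane(cube, c(0, 0, -5), c(0, 0, 1))
  expect_equal(mesh_area(same), 6)
  # mid-plane: half the 4 side faces + the far cap = 4 * 0.5 + 1 = 3
  kept <- clip_by_plane(cube, c(0.5, 0.5, 0.5), c(1, 0, 0))
  expect_equal(mesh_area(kept), 3, tolerance = 1e-9)
  # kept + discarded = original
  disc <- clip_by_plane(cube, c(0.5, 0.5, 0.5), c(-1, 0, 0))
  expect_equal(mesh_area(kept) + mesh_area(disc), 6, tolerance = 1e-9)
  # idempotence
  again <- clip_by_plane(kept, c(0.5, 0.5, 0.5), c(1, 0, 0))
  expect_equal(mesh_area(again), mesh_area(kept), tolerance = 1e-9)
  # oblique plane on a sphere conserves area too
  ico <- mesh_icosphere(radius = 5, subdivisions = 2)
  nrm <- c(1, 2, 2) / 3
  a1 <- mesh_area(clip_by_plane(ico, c(0.5, -0.3, 0.2), nrm))
  a2 <- mesh_area(clip_by_plane(ico, c(0.5, -0.3, 0.2), -nrm))
  expect_equal(a1 + a2, mesh_area(ico), tolerance = 1e-9 * mesh_area(ico))
  # fully negative side -> empty with warning
  expect_warning(out <- clip_by_plane(cube, c(0, 0, 5), c(0, 0, 1)), "empty")
  expect_identical(nrow(out$faces), 0L)
  expect_error(clip_by_plane(cube, c(0, 0, 0), c(1, 1, 0)), "unit")
})

test_that("clipping is translation-equivariant", {
  ico <- mesh_icosphere(radius = 4, subdivisions = 2)
  shift <- c(12, -7, 3)
  nrm <- c(0.6, 0, 0.8)
  a <- clip_by_plane(ico, c(1, 0, 0), nrm)
  b <- clip_by_plane(translate_mesh(ico, shift), c(1, 0, 0) + shift, nrm)
  expect_equal(mesh_area(a), mesh_area(b), tolerance = 1e-9)
  expect_equal(geometric_center(a) + shift, geometric_center(b),
               tolerance = 1e-9)
})
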