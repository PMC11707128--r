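test_that("record -> apply on the reference mesh is an exact inverse", {
  ico <- mesh_icosphere(radius = 20, center = c(5, -3, 10), subdivisions = 2)
  n <- c(0.6, 0, 0.8)
  p <- c(12, -3, 18)
  roi <- record_roi(ico, p, n, side = "left")
  back <- roi_absolute_plane(ico, roi)
  expect_equal(back$point, p, tolerance = 1e-9)
  expect_equal(back$normal, n, tolerance = 1e-12)
  # a plane through the geometric centre has anchor (0, 0, 0)
  roi0 <- record_roi(ico, geometric_center(ico), n, side = "left")
  expect_equal(roi0$anchor, c(0, 0, 0), tolerance = 1e-9)
  # a plane missing the bounding box is refused
  expect_error(record_roi(ico, c(500, 0, 0), n), "does not intersect")
})

test_that("scaled mode follows uniform scaling; translate mode follows shifts", {
  ico <- mesh_icosphere(radius = 20, subdivisions = 2)
  p <- c(9, 2, 14)
  n <- c(0, 0.6, 0.8)
  roi <- record_roi(ico, p, n, side = "left", mode = "scaled")
  big <- scale_mesh(ico, 1.2, geometric_center(ico))
  pl <- roi_absolute_plane(big, roi)
  expect_equal(pl$point - geometric_center(big),
               1.2 * (p - geometric_center(ico)), tolerance = 1e-6)
  # translation equivariance in both modes
  sh <- c(100, -40, 7)
  for (mode in c("scaled", "translate")) {
    r <- record_roi(ico, p, n, side = "left", mode = mode)
    pl2 <- roi_absolute_plane(translate_mesh(ico, sh), r)
    expect_equal(pl2$point, p + sh, tolerance = 1e-6)
  }
  # applying clips to a strict, non-empty subset
  clip <- apply_roi(ico, roi)
  expect_gt(mesh_area(clip), 0)
  expect_lt(mesh_area(clip), mesh_area(ico))
})

test_that("apply_roi on a translated copy yields the translated ROI", {
  spec <- tiny_phantom_spec(seed = 31)
  ph <- generate_phantom(spec, 2)
  roi <- default_crest_rois()$left
  a <- apply_roi(ph$mesh, roi)
  b <- apply_roi(translate_mesh(ph$mesh, c(30, 10, -5)), roi)
  expect_equal(mesh_area(a), mesh_area(b), tolerance = 1e-6)
  expect_equal(geometric_center(b) - geometric_center(a), c(30, 10, -5),
               tolerance = 1e-6)
})

test_that("mirroring is an involution that reflects across the x axis", {
  roi <- roi_definition(c(0.4, 0.1, 0.2), c(0.8, 0, 0.6), side = "left")
  m <- mirror_roi(roi)
  expect_identical(m$side, "right")
  expect_equal(m$normal, c(-0.8, 0, 0.6))
  expect_equal(m$anchor, c(-0.4, 0.1, 0.2))
  expect_equal(mirror_roi(m)[c("anchor", "normal", "side")],
               roi[c("anchor", "normal", "side")])
})

test_that("left and right ROIs mirror on a symmetric phantom", {
  spec <- tiny_phantom_spec(seed = 41, asymmetry = 0, pose_max_deg = 0)
  ph <- generate_phantom(spec, 3)
  rois <- default_crest_rois()
  left <- apply_roi(ph$mesh, rois$left)
  right <- apply_roi(ph$mesh, rois$right)
  expect_gt(mesh_area(left), 0)
  expect_equal(mesh_area(right) / mesh_area(left), 1, tolerance = 0.02)
})

test_that("ROI JSON round-trips", {
  rois <- default_crest_rois()
  f <- tempfile(fileext = ".json")
  write_roi(rois, f)
  back <- read_roi(f)
  expect_length(back, 2)
  expect_equal(back[[1]]$anchor, rois$left$anchor)
  expect_equal(back[[2]]$normal, rois$right$normal)
  expect_identical(back[[2]]$side, "right")
})
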