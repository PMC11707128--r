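test_that("phantom generation is bitwise deterministic per seed pair", {
  spec <- tiny_phantom_spec(seed = 2)
  a <- generate_phantom(spec, 7)
  b <- generate_phantom(spec, 7)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$mesh$vertices, b$mesh$vertices)
  expect_identical(a$mesh$faces, b$mesh$faces)
  c <- generate_phantom(spec, 8)
  expect_false(identical(a$volume$data, c$volume$data))
})

test_that("mesh volume agrees with the bone voxel count", {
  spec <- tiny_phantom_spec(seed = 5)
  ph <- generate_phantom(spec, 1)
  vox_vol <- prod(ph$volume$spacing)
  expect_equal(mesh_volume(ph$mesh) / (sum(ph$bone_voxels) * vox_vol), 1,
               tolerance = 0.1)
  frac <- mean(ph$bone_voxels)
  expect_gt(frac, 0.005)
  expect_lt(frac, 0.15)
  expect_true(mesh_is_watertight(ph$mesh))
})

test_that("intensity model separates bone from tissue", {
  spec <- tiny_phantom_spec(seed = 6)
  ph <- generate_phantom(spec, 2)
  bone_mean <- mean(ph$volume$data[ph$bone_voxels])
  tissue_mean <- mean(ph$volume$data[!ph$bone_voxels])
  expect_gt(bone_mean, 550)
  expect_lt(tissue_mean, 150)
  expect_error(phantom_spec(bone_hu = c(100, 100), tissue_hu = c(40, 90)),
               "separated")
})

test_that("the two rasterization paths are consistent (greedy superset)", {
  spec <- tiny_phantom_spec(seed = 7)
  for (cs in 1:2) {
    ph <- generate_phantom(spec, cs)
    greedy <- greedy_voxelize(ph$mesh, ph$volume)
    expect_true(all(greedy$data[ph$bone_voxels]))
  }
})

test_that("wings mirror on a zero-asymmetry phantom", {
  spec <- tiny_phantom_spec(seed = 8, asymmetry = 0, pose_max_deg = 0)
  ph <- generate_phantom(spec, 1)
  d <- dim(ph$volume$data)
  mirrored <- ph$bone_voxels[d[1]:1, , ]
  agree <- mean(mirrored == ph$bone_voxels)
  expect_gt(agree, 0.999)
})

test_that("cohorts carry a manifest that regenerates identical cases", {
  spec <- tiny_phantom_spec(seed = 9)
  co <- generate_cohort(spec, 5, seed = 100)
  expect_identical(nrow(co$manifest), 5L)
  expect_identical(anyDuplicated(co$manifest$case_seed), 0L)
  expect_true(all(co$manifest[, c("nx", "ny", "nz")] >= 32))
  # regeneration from manifest seeds is identical
  redo <- generate_phantom(spec, co$manifest$case_seed[3])
  expect_identical(redo$volume$data, co$cases[[3]]$volume$data)
  # on-disk cohort: files plus manifest.csv
  dir <- file.path(tempdir(), "cohort_test")
  generate_cohort(spec, 2, seed = 5, dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_length(list.files(dir, pattern = "nii.gz$"), 2)
  expect_length(list.files(dir, pattern = "stl$"), 2)
  back <- read_volume(file.path(dir, "case_0001.nii.gz"))
  regen <- generate_phantom(spec, 6)  # seed 5 + case index 1
  expect_equal(back$data, regen$volume$data, tolerance = 1e-6)
})

test_that("corruption modes modify cases as advertised", {
  spec <- tiny_phantom_spec(seed = 10)
  ph <- generate_phantom(spec, 1)
  cr <- corrupt_case(ph, "crop", crop_fraction = 0.25)
  expect_lt(dim(cr$volume$data)[3], dim(ph$volume$data)[3])
  im <- corrupt_case(ph, "implant")
  expect_gt(max(im$volume$data), max(ph$volume$data))
  expect_gte(max(im$volume$data), 3000)
  ti <- corrupt_case(ph, "tilt", angle_deg = 15)
  # the tilt is about the x axis, so track the second principal axis
  # (the first stays along the bilateral x direction)
  pax <- function(m) {
    v <- sweep(m$vertices, 2, colMeans(m$vertices))
    svd(v)$v[, 2]
  }
  a1 <- pax(ph$mesh); a2 <- pax(ti$mesh)
  ang <- acos(min(1, abs(sum(a1 * a2)))) * 180 / pi
  expect_equal(ang, 15, tolerance = 0.1)
  expect_error(corrupt_case(ph, "melt"))
})
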