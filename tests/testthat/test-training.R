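test_that("400 cases split 0.9/0.1 into 360/40, reproducibly and exhaustively", {
  ids <- sprintf("case%03d", 1:400)
  s <- split_dataset(ids, seed = 4)
  expect_length(s$train, 360)
  expect_length(s$validation, 40)
  expect_identical(s, split_dataset(ids, seed = 4))
  expect_false(identical(s, split_dataset(ids, seed = 5)))
  expect_setequal(c(s$train, s$validation), ids)
  expect_length(intersect(s$train, s$validation), 0)
  # three-way split
  s3 <- split_dataset(1:45, c(train = 30, validation = 5, test = 10) / 45, seed = 1)
  expect_identical(lengths(s3), c(train = 30L, validation = 5L, test = 10L))
  expect_error(split_dataset(1, c(0.9, 0.1)), "too few")
  expect_error(split_dataset(1:10, c(0.5, 0.2)), "sum to 1")
})

drive_scheduler <- function(losses, ...) {
  st <- scheduler_new(train_config(...))
  log <- data.frame()
  for (l in losses) {
    st <- scheduler_step(st, l)
    log <- rbind(log, data.frame(epoch = st$epoch, lr = st$lr,
                                 reduced = st$reduced, stop = st$stop))
    if (st$stop) break
  }
  log
}

test_that("strictly improving losses never reduce the learning rate", {
  log <- drive_scheduler(seq(1, 0.4, length.out = 12))
  expect_true(all(log$lr == 5e-4))
  expect_false(any(log$reduced))
  expect_false(any(log$stop))
})

test_that("a plateau reduces the rate by 10 after exactly 10 epochs and stops after 30", {
  k <- 5L
  losses <- c(seq(1, 0.5, length.out = k), rep(0.5, 40))  # no improvement after epoch k
  log <- drive_scheduler(losses)
  expect_identical(log$epoch[which(log$reduced)], c(k + 10L, k + 20L))
  expect_identical(max(log$epoch), k + 30L)
  expect_true(log$stop[nrow(log)])
  # the rate sequence is non-increasing and each drop is exactly / 10
  expect_true(all(diff(log$lr) <= 0))
  drops <- log$lr[which(log$reduced)]
  expect_equal(drops, 5e-4 / c(10, 100))
})

test_that("improvements below min_delta do not reset the plateau counters", {
  losses <- c(1, 0.5, 0.5 - rep(1e-7, 40) * seq_len(40))
  log <- drive_scheduler(losses)
  expect_identical(log$epoch[which(log$reduced)[1]], 12L)  # 10 stagnant after epoch 2
  expect_identical(max(log$epoch), 32L)
})

test_that("prepare_targets produces binary stage targets consistent with the mesh", {
  spec <- tiny_phantom_spec(seed = 3)
  ph <- generate_phantom(spec, 1)
  p1 <- prepare_targets(ph$mesh, ph$volume, 1L, c(32L, 32L, 32L))
  expect_type(p1$target$data, "logical")
  expect_identical(dim(p1$target$data), c(32L, 32L, 32L))
  expect_true(all(p1$input$data >= 0 & p1$input$data <= 1))
  # greedy superset: native mask >= centres-inside count
  centres <- greedy_voxelize(ph$mesh, ph$volume, greedy = FALSE)
  expect_true(all(p1$native_mask$data[centres$data]))
  # greedy targets dilate thin shells, never shrink them
  vox_vol <- prod(p1$target$spacing)
  expect_gt(sum(p1$target$data) * vox_vol, 0.8 * mesh_volume(ph$mesh))
  # for a compact solid (radius-15-voxel sphere) the resampled stage-1
  # target volume lands within 10% of the mesh volume
  sph <- mesh_icosphere(radius = 15, center = c(32, 32, 32), subdivisions = 3)
  ct <- image_volume(array(0, c(64L, 64L, 64L)), c(1, 1, 1), c(0.5, 0.5, 0.5))
  ps <- prepare_targets(sph, ct, 1L, c(32L, 32L, 32L))
  expect_equal(sum(ps$target$data) * prod(ps$target$spacing),
               mesh_volume(sph), tolerance = 0.1)
  # stage 2 without a box errors; with a box, binary at stage shape
  expect_error(prepare_targets(ph$mesh, ph$volume, 2L, c(32L, 32L, 32L)),
               "roi_box")
  box <- gt_roi_box(p1$native_mask)
  p2 <- prepare_targets(ph$mesh, ph$volume, 2L, c(32L, 32L, 32L), roi_box = box)
  expect_type(p2$target$data, "logical")
  # mesh outside the CT is rejected
  expect_error(prepare_targets(translate_mesh(ph$mesh, c(500, 0, 0)),
                               ph$volume, 1L, c(32L, 32L, 32L)), "outside")
})

test_that("a few epochs of training reduce the validation Dice loss", {
  spec <- tiny_phantom_spec(seed = 11)
  pairs <- lapply(1:6, function(i) {
    ph <- generate_phantom(spec, i)
    p <- prepare_targets(ph$mesh, ph$volume, 1L, c(32L, 32L, 32L))
    list(input = p$input$data, target = p$target$data)
  })
  net <- build_network(unet_config(base_filters = 2), seed = 5)
  init_val <- mean(vapply(5:6, function(i) {
    dice_loss(unet_predict(net, pairs[[i]]$input), pairs[[i]]$target)
  }, numeric(1)))
  fit <- train_stage(net, pairs[1:4], pairs[5:6],
                     train_config(max_epochs = 6L, seed = 2))
  expect_lt(fit$best_val_loss, init_val)
  expect_true(all(diff(fit$history$lr) <= 0))
  expect_identical(fit$history$epoch, seq_len(nrow(fit$history)))
  # returned weights correspond to the minimum validation loss epoch
  expect_equal(fit$best_val_loss, min(fit$history$val_loss))
})
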