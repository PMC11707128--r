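test_that("network output matches input shape with values in (0, 1)", {
  net <- build_network(unet_config(base_filters = 2), seed = 7)
  x <- array(runif(32^3), c(32, 32, 32))
  p <- unet_predict(net, x)
  expect_identical(dim(p), dim(x))
  expect_true(all(p > 0 & p < 1))
  expect_error(unet_predict(net, array(0, c(30, 32, 32))), "divisible by 16")
})

test_that("weight count is input-shape independent and matches the closed form", {
  cfg <- unet_config(base_filters = 8)
  # closed-form layer-by-layer sum for base f = 8, 5 levels:
  # encoder convs (1->f, f->f), (f->2f, 2f->2f), ... bottom (8f->16f, 16f->16f)
  # decoder convs (16f+8f->8f, 8f->8f), ..., (2f+f->f, f->f), out f->1
  f <- 8
  ch <- f * 2^(0:4)
  enc_in <- c(1, ch[1], ch[1], ch[2], ch[2], ch[3], ch[3], ch[4], ch[4], ch[5])
  enc_out <- rep(ch, each = 2)
  dec_in <- c(ch[5] + ch[4], ch[4], ch[4] + ch[3], ch[3],
              ch[3] + ch[2], ch[2], ch[2] + ch[1], ch[1])
  dec_out <- rep(rev(ch[1:4]), each = 2)
  expected <- sum(27 * enc_in * enc_out + enc_out) +
    sum(27 * dec_in * dec_out + dec_out) + (f * 1 + 1)
  expect_identical(unet_param_count(cfg), expected)

  # instantiated weight tensors agree with the count, for any input shape
  net <- build_network(cfg, seed = 1)
  total <- sum(vapply(net$layers, function(p) length(p$W) + length(p$b),
                      numeric(1)))
  expect_identical(total, expected)
})

test_that("same seed gives identical weights, different seeds differ", {
  cfg <- unet_config(base_filters = 2)
  expect_identical(build_network(cfg, seed = 5)$layers,
                   build_network(cfg, seed = 5)$layers)
  expect_false(identical(build_network(cfg, seed = 5)$layers,
                         build_network(cfg, seed = 6)$layers))
  # Glorot bound honoured on the first conv (fan_in 27, fan_out 27 * 2)
  W <- build_network(cfg, seed = 5)$layers$enc1_conv1$W
  expect_true(all(abs(W) <= sqrt(6 / (27 * 1 + 27 * 2))))
})

test_that("soft Dice loss matches its formula and limits", {
  t <- array(0, c(10, 10, 10)); t[1:5, , ] <- 1
  expect_equal(dice_loss(t, t), 0, tolerance = 1e-6)
  expect_equal(dice_loss(1 - t, t), 1, tolerance = 1e-5)
  # pred 0.5 everywhere on a half-filled 1000-voxel grid: DS = 0.5
  expect_equal(dice_loss(array(0.5, c(10, 10, 10)), t), 0.5, tolerance = 1e-5)
  expect_error(dice_loss(array(0.5, c(2, 2, 2)), t), "differ")
  # symmetry for binary arguments (eps-free limit)
  a <- array(0, c(6, 6, 6)); a[1:3, , ] <- 1
  b <- array(0, c(6, 6, 6)); b[2:4, , ] <- 1
  expect_equal(dice_loss(a, b), dice_loss(b, a), tolerance = 1e-9)
})

test_that("dice loss gradient matches finite differences", {
  set.seed(3)
  p <- array(runif(4^3, 0.1, 0.9), c(4, 4, 4))
  t <- array(rbinom(4^3, 1, 0.4), c(4, 4, 4))
  g <- dice_loss_grad(p, t)
  for (i in c(1, 17, 60)) {
    eps <- 1e-6
    pp <- p; pp[i] <- pp[i] + eps
    pm <- p; pm[i] <- pm[i] - eps
    expect_equal(g[i], (dice_loss(pp, t) - dice_loss(pm, t)) / (2 * eps),
                 tolerance = 1e-4)
  }
})

test_that("transfer initialization copies weights and respects the freeze set", {
  cfg <- unet_config(base_filters = 2)
  src <- build_network(cfg, seed = 1)
  dst <- build_network(cfg, seed = 99)
  moved <- transfer_init(dst, src)
  expect_identical(moved$layers, src$layers)

  # config mismatch is refused
  other <- build_network(unet_config(base_filters = 4), seed = 1)
  expect_error(transfer_init(other, src), "incompatible")
  expect_error(transfer_init(dst, src, freeze = "nope"), "unknown layers")

  # freeze-all: one training step leaves every weight unchanged
  x <- array(runif(16^3, 0, 1), c(16, 16, 16))
  t <- array(0, c(16, 16, 16)); t[6:10, 6:10, 6:10] <- 1
  pair <- list(list(input = x, target = t))
  frozen <- transfer_init(dst, src, freeze = names(src$layers))
  fit <- train_stage(frozen, pair, pair,
                     train_config(max_epochs = 1L, seed = 1))
  expect_identical(fit$net$layers, src$layers)

  # freeze-none: at least one weight moves
  fit2 <- train_stage(transfer_init(dst, src), pair, pair,
                      train_config(max_epochs = 1L, seed = 1))
  expect_false(identical(fit2$net$layers, src$layers))
})

test_that("weight manifest and checkpoint round-trip", {
  net <- build_network(unet_config(base_filters = 2), seed = 3)
  man <- weight_manifest(net)
  expect_identical(nrow(man), 2L * length(net$layers))
  f <- tempfile(fileext = ".rds")
  save_network(net, f)
  expect_true(file.exists(paste0(f, ".manifest.json")))
  back <- load_network(f)
  expect_identical(back$layers, net$layers)
  expect_identical(unclass(back$config), unclass(net$config))
  # exported manifest of a transfer target equals the source manifest
  dst <- transfer_init(build_network(unet_config(base_filters = 2), 77), net)
  expect_identical(weight_manifest(dst)$checksum, man$checksum)
})
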