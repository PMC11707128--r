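#' 3D U-Net configuration
#'
#' The network is a fully convolutional 3D U-Net with `levels` resolution
#' levels (default 5, i.e. 4 max-pooling steps): an encoding path of
#' 2 convolutions per level (10 in total) with 3x3x3 kernels, ReLU
#' activations and 2x2x2 max pooling in between, feature maps doubling
#' after every pooling step; and a decoding path of 2x2x2 nearest-neighbour
#' up-sampling, skip concatenation, 2 convolutions per level plus a final
#' 1x1x1 sigmoid output convolution (9 decoder convolutions in total).
#' Input shapes must be divisible by `2^(levels - 1)` (16 for the default)
#' on every axis; the parameter count depends only on the configuration,
#' never on the input shape.
#'
#' @param base_filters feature maps at the first level.
#' @param levels number of resolution levels (`levels - 1` poolings).
#' @param in_channels input channels (1 for CT).
#' @return An object of class `cs_unet_config`.
#' @export
unet_config <- function(base_filters = 16L, levels = 5L, in_channels = 1L) {
  stopifnot(base_filters >= 1, levels >= 2, in_channels >= 1)
  structure(list(base_filters = as.integer(base_filters),
                 levels = as.integer(levels),
                 in_channels = as.integer(in_channels),
                 kernel = c(3L, 3L, 3L), pool = c(2L, 2L, 2L),
                 upsample = c(2L, 2L, 2L)),
            class = "cs_unet_config")
}

level_channels <- function(config, l) config$base_filters * 2L^(l - 1L)

# ordered conv-layer table: name, fan-in channels, fan-out channels, kernel
unet_layer_table <- function(config) {
  L <- config$levels
  rows <- list()
  for (l in seq_len(L)) {
    cin1 <- if (l == 1L) config$in_channels else level_channels(config, l - 1L)
    ch <- level_channels(config, l)
    rows[[length(rows) + 1L]] <- list(name = sprintf("enc%d_conv1", l), cin = cin1, cout = ch, k = 27L)
    rows[[length(rows) + 1L]] <- list(name = sprintf("enc%d_conv2", l), cin = ch, cout = ch, k = 27L)
  }
  for (l in rev(seq_len(L - 1L))) {
    ch <- level_channels(config, l)
    up <- level_channels(config, l + 1L)
    rows[[length(rows) + 1L]] <- list(name = sprintf("dec%d_conv1", l), cin = up + ch, cout = ch, k = 27L)
    rows[[length(rows) + 1L]] <- list(name = sprintf("dec%d_conv2", l), cin = ch, cout = ch, k = 27L)
  }
  rows[[length(rows) + 1L]] <- list(name = "out_conv", cin = config$base_filters, cout = 1L, k = 1L)
  rows
}

#' Number of trainable parameters
#' @param config a [unet_config()].
#' @return integer count of weights + biases.
#' @export
unet_param_count <- function(config) {
  sum(vapply(unet_layer_table(config),
             function(r) r$k * r$cin * r$cout + r$cout, numeric(1)))
}

#' Build a 3D U-Net
#'
#' Instantiates the network of [unet_config()] with Glorot-uniform initial
#' weights (`limit = sqrt(6 / (fan_in + fan_out))`, fans counted over the
#' full 3x3x3 kernel) drawn deterministically from `seed`. Hidden biases
#' start at zero; the output bias starts at `qlogis(fg_prior)` so the
#' initial probability map matches the expected foreground fraction, which
#' skips the long early phase of Dice training that only pushes the
#' background down.
#'
#' @param config a [unet_config()].
#' @param seed integer seed for the weight draw.
#' @param fg_prior expected foreground fraction for the output-bias prior.
#' @return An object of class `cs_unet` (configuration + named weight set).
#' @export
build_network <- function(config, seed = 1L, fg_prior = 0.1) {
  stopifnot(inherits(config, "cs_unet_config"), fg_prior > 0, fg_prior < 1)
  tab <- unet_layer_table(config)
  layers <- with_seed(seed, {
    out <- list()
    for (r in tab) {
      limit <- sqrt(6 / (r$k * r$cin + r$k * r$cout))
      out[[r$name]] <- list(
        W = matrix(stats::runif(r$k * r$cin * r$cout, -limit, limit), r$k * r$cin, r$cout),
        b = numeric(r$cout))
    }
    out$out_conv$b <- rep(stats::qlogis(fg_prior), length(out$out_conv$b))
    out
  })
  structure(list(config = config, layers = layers, frozen = character(0)),
            class = "cs_unet")
}

#' @export
print.cs_unet <- function(x, ...) {
  cat(sprintf("<3D U-Net> base_filters %d, levels %d, %s parameters%s\n",
              x$config$base_filters, x$config$levels,
              format(unet_param_count(x$config), big.mark = ","),
              if (length(x$frozen)) sprintf(" (%d frozen layers)", length(x$frozen)) else ""))
  invisible(x)
}

check_input_shape <- function(config, dims) {
  div <- 2L^(config$levels - 1L)
  if (any(dims %% div != 0L)) {
    stop("input shape (", paste(dims, collapse = "x"),
         ") must be divisible by ", div, " on every axis")
  }
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# forward pass; x: 3D array. Returns probability array, plus caches when
# training (layer inputs/activations, pool argmax, skip features).
unet_forward <- function(net, x, cache = FALSE) {
  cfg <- net$config
  dims <- dim(x)
  check_input_shape(cfg, dims)
  L <- cfg$levels
  cur <- matrix(as.numeric(x), ncol = cfg$in_channels)
  cc <- if (cache) list(convs = list(), pools = list(), skips = list()) else NULL
  skips <- vector("list", L - 1L)
  for (l in seq_len(L)) {
    for (s in 1:2) {
      nm <- sprintf("enc%d_conv%d", l, s)
      p <- net$layers[[nm]]
      y <- .cs_conv_fwd_direct(cur, dims, p$W, p$b)
      a <- y * (y > 0)
      if (cache) cc$convs[[nm]] <- list(input = cur, act = a, dims = dims)
      cur <- a
    }
    if (l < L) {
      skips[[l]] <- list(feat = cur, dims = dims)
      mp <- .cs_maxpool_fwd(cur, dims)
      if (cache) cc$pools[[l]] <- list(amax = mp$amax, n_in = nrow(cur), dims_in = dims)
      cur <- mp$Y
      dims <- dims %/% 2L
    }
  }
  for (l in rev(seq_len(L - 1L))) {
    cur <- .cs_upsample_fwd(cur, dims)
    dims <- dims * 2L
    n_up <- ncol(cur)
    cur <- cbind(cur, skips[[l]]$feat)
    for (s in 1:2) {
      nm <- sprintf("dec%d_conv%d", l, s)
      p <- net$layers[[nm]]
      y <- .cs_conv_fwd_direct(cur, dims, p$W, p$b)
      a <- y * (y > 0)
      if (cache) cc$convs[[nm]] <- list(input = cur, act = a, dims = dims, n_up = n_up)
      cur <- a
    }
  }
  p <- net$layers[["out_conv"]]
  logits <- cur %*% p$W
  logits <- logits + p$b
  prob <- sigmoid(logits)
  if (cache) {
    cc$out <- list(input = cur, prob = prob, dims = dims)
    list(prob = array(prob, dim = dims), cache = cc)
  } else {
    array(prob, dim = dims)
  }
}

# backward pass from d(loss)/d(prob); returns named gradients per layer
unet_backward <- function(net, cache, dprob) {
  cfg <- net$config
  L <- cfg$levels
  grads <- list()
  prob <- cache$out$prob
  dlogits <- matrix(as.numeric(dprob), ncol = 1) * prob * (1 - prob)
  p <- net$layers[["out_conv"]]
  grads[["out_conv"]] <- list(W = crossprod(cache$out$input, dlogits),
                              b = sum(dlogits))
  dcur <- dlogits %*% t(p$W)
  for (l in seq_len(L - 1L)) {
    for (s in 2:1) {
      nm <- sprintf("dec%d_conv%d", l, s)
      cv <- cache$convs[[nm]]
      dy <- dcur * (cv$act > 0)
      bw <- .cs_conv_bwd_direct(cv$input, cv$dims, net$layers[[nm]]$W, dy, TRUE)
      grads[[nm]] <- list(W = bw$dW, b = as.numeric(bw$db))
      dcur <- bw$dX
    }
    cv1 <- cache$convs[[sprintf("dec%d_conv1", l)]]
    n_up <- cv1$n_up
    dskip <- dcur[, (n_up + 1):ncol(dcur), drop = FALSE]
    dup <- dcur[, seq_len(n_up), drop = FALSE]
    ddown <- .cs_upsample_bwd(dup, cv1$dims %/% 2L)
    cache$skip_grad[[l]] <- dskip  # consumed by the encoder sweep below
    dcur <- ddown
  }
  # encoder sweep, bottom level first
  for (l in rev(seq_len(L))) {
    if (l < L) {
      pl <- cache$pools[[l]]
      dpool <- .cs_maxpool_bwd(dcur, pl$amax, pl$n_in)
      dcur <- dpool + cache$skip_grad[[l]]
    }
    for (s in 2:1) {
      nm <- sprintf("enc%d_conv%d", l, s)
      cv <- cache$convs[[nm]]
      dy <- dcur * (cv$act > 0)
      need_dx <- !(l == 1L && s == 1L)
      bw <- .cs_conv_bwd_direct(cv$input, cv$dims, net$layers[[nm]]$W, dy, need_dx)
      grads[[nm]] <- list(W = bw$dW, b = as.numeric(bw$db))
      if (need_dx) dcur <- bw$dX
    }
  }
  grads
}

#' Predict a probability map
#'
#' Runs a forward pass on one volume (batch size 1 throughout, as in
#' training). The output has the same shape as the input with values in
#' (0, 1).
#'
#' @param net a [build_network()] model.
#' @param x 3D numeric array (normalized intensities) or [image_volume()];
#'   every axis must be divisible by `2^(levels - 1)`.
#' @return 3D array of foreground probabilities.
#' @export
unet_predict <- function(net, x) {
  stopifnot(inherits(net, "cs_unet"))
  if (inherits(x, "cs_volume")) x <- x$data
  unet_forward(net, x, cache = FALSE)
}

#' Soft Dice loss
#'
#' `L = 1 - DS` with the soft Dice score
#' `DS = (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)`; the loss lies
#' in `[0, 1]` and is 0 exactly when a binary prediction matches the
#' target. `dice_loss_grad()` returns the gradient with respect to the
#' prediction, used by the training loop.
#'
#' @param pred numeric array of probabilities in `[0, 1]`.
#' @param target binary array (logical or {0, 1}) of the same shape.
#' @param eps numerical stabilizer, keeps the loss defined on empty
#'   targets.
#' @return scalar loss (or gradient array).
#' @export
dice_loss <- function(pred, target, eps = 1e-6) {
  dp <- dim(pred); dt <- dim(target)
  if ((!is.null(dp) && !is.null(dt) && !identical(as.integer(dp), as.integer(dt))) ||
      length(pred) != length(target)) {
    stop("pred and target shapes differ")
  }
  p <- as.numeric(pred); t <- as.numeric(target)
  1 - (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)
}

#' @rdname dice_loss
#' @export
dice_loss_grad <- function(pred, target, eps = 1e-6) {
  p <- as.numeric(pred); t <- as.numeric(target)
  num <- 2 * sum(p * t) + eps
  den <- sum(p) + sum(t) + eps
  g <- -(2 * t * den - num) / den^2
  array(g, dim = dim(pred) %||% length(p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Transfer-learning initialization
#'
#' Copies the complete weight set of `source` into `target` (the two
#' configurations must match; being fully convolutional, the copy works
#' across stage resolutions). Layers named in `freeze` are marked frozen
#' and excluded from gradient updates during [train_stage()]. The default
#' freezes nothing, i.e. the whole network is fine-tuned.
#'
#' @param target,source [build_network()] models with identical configs.
#' @param freeze character vector of layer names to freeze.
#' @return The target network with source weights.
#' @export
transfer_init <- function(target, source, freeze = character(0)) {
  stopifnot(inherits(target, "cs_unet"), inherits(source, "cs_unet"))
  if (!identical(unclass(target$config), unclass(source$config))) {
    stop("incompatible configurations: transfer requires identical architecture")
  }
  bad <- setdiff(freeze, names(target$layers))
  if (length(bad)) stop("unknown layers in freeze set: ", paste(bad, collapse = ", "))
  target$layers <- source$layers
  target$frozen <- freeze
  target
}

#' Weight manifest
#'
#' A framework-neutral description of a network's weight set (layer names,
#' shapes, and order-sensitive checksums), used to validate transfers and
#' record weights in run manifests.
#'
#' @param net a [build_network()] model.
#' @return data.frame with one row per parameter tensor.
#' @export
weight_manifest <- function(net) {
  stopifnot(inherits(net, "cs_unet"))
  rows <- lapply(names(net$layers), function(nm) {
    p <- net$layers[[nm]]
    data.frame(layer = nm,
               param = c("W", "b"),
               shape = c(paste(dim(p$W), collapse = "x"), length(p$b)),
               checksum = c(param_checksum(p$W), param_checksum(p$b)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

param_checksum <- function(x) {
  v <- as.numeric(x)
  sprintf("%.10e", sum(v * seq_along(v)) + sum(v))
}

#' Save / load network weights
#'
#' Weights are stored as an RDS checkpoint next to a JSON manifest
#' (`<path>.manifest.json`) from [weight_manifest()].
#'
#' @param net a [build_network()] model.
#' @param path checkpoint file path (`.rds`).
#' @return `load_network()`: the restored `cs_unet`.
#' @export
save_network <- function(net, path) {
  stopifnot(inherits(net, "cs_unet"))
  saveRDS(list(config = unclass(net$config), layers = net$layers,
               frozen = net$frozen), path)
  jsonlite::write_json(weight_manifest(net), paste0(path, ".manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  raw <- readRDS(path)
  cfg <- unet_config(raw$config$base_filters, raw$config$levels, raw$config$in_channels)
  structure(list(config = cfg, layers = raw$layers,
                 frozen = raw$frozen %||% character(0)),
            class = "cs_unet")
}
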