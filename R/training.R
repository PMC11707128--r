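#' Training configuration
#'
#' Defaults: Adam with batch size 1 and an
#' initial learning rate of 5e-4; the learning rate is divided by 10 after
#' 10 epochs without improvement of the validation loss, and training stops
#' once the validation loss has not decreased for 30 epochs. "Improvement"
#' means a decrease by more than `min_delta` (1e-5). After a reduction the
#' plateau counter for the *learning-rate* criterion restarts, while the
#' early-stop horizon keeps counting from the last actual improvement.
#'
#' @param initial_lr initial Adam learning rate.
#' @param lr_reduce_factor divisor applied to the learning rate on plateau.
#' @param lr_patience_epochs epochs without improvement before a reduction.
#' @param early_stop_epochs epochs without improvement before stopping.
#' @param min_delta minimum loss decrease counted as improvement.
#' @param clip_norm global gradient-norm clip applied before each Adam
#'   update (`Inf` disables); stabilizes full-volume Dice training.
#' @param max_epochs hard cap on the number of epochs.
#' @param shuffle shuffle the training cases each epoch (seeded).
#' @param seed seed for shuffling.
#' @return An object of class `cs_train_config`.
#' @export
train_config <- function(initial_lr = 5e-4, lr_reduce_factor = 10,
                         lr_patience_epochs = 10L, early_stop_epochs = 30L,
                         min_delta = 1e-5, clip_norm = 1.0, max_epochs = 200L,
                         shuffle = TRUE, seed = 1L) {
  stopifnot(initial_lr > 0, lr_reduce_factor > 1,
            lr_patience_epochs >= 1, early_stop_epochs > lr_patience_epochs,
            max_epochs >= 1)
  structure(list(initial_lr = initial_lr, batch_size = 1L,
                 lr_reduce_factor = lr_reduce_factor,
                 lr_patience_epochs = as.integer(lr_patience_epochs),
                 early_stop_epochs = as.integer(early_stop_epochs),
                 min_delta = min_delta, clip_norm = clip_norm,
                 max_epochs = as.integer(max_epochs),
                 shuffle = shuffle, seed = as.integer(seed)),
            class = "cs_train_config")
}

#' Reduce-on-plateau / early-stop scheduler
#'
#' A small state machine driven by one validation loss per epoch.
#' `scheduler_step()` returns the updated state with fields `lr` (rate to
#' use for the *next* epoch), `reduced` (was the rate divided this epoch),
#' `stop` (early-stopping triggered), and `improved`.
#'
#' @param config a [train_config()].
#' @return `scheduler_new()`: initial state list.
#' @export
scheduler_new <- function(config) {
  list(config = config, lr = config$initial_lr, best = Inf,
       since_improve = 0L, since_reduce_event = 0L,
       stop = FALSE, reduced = FALSE, improved = FALSE, epoch = 0L)
}

#' @rdname scheduler_new
#' @param state scheduler state.
#' @param loss validation loss of the finished epoch.
#' @export
scheduler_step <- function(state, loss) {
  cfg <- state$config
  state$epoch <- state$epoch + 1L
  state$reduced <- FALSE
  state$improved <- is.finite(loss) && loss < state$best - cfg$min_delta
  if (state$improved) {
    state$best <- loss
    state$since_improve <- 0L
    state$since_reduce_event <- 0L
  } else {
    state$since_improve <- state$since_improve + 1L
    state$since_reduce_event <- state$since_reduce_event + 1L
    if (state$since_improve >= cfg$early_stop_epochs) {
      state$stop <- TRUE
    } else if (state$since_reduce_event >= cfg$lr_patience_epochs) {
      state$lr <- state$lr / cfg$lr_reduce_factor
      state$reduced <- TRUE
      state$since_reduce_event <- 0L
    }
  }
  state
}

#' Split cases into train / validation (/ test) subsets
#'
#' Random, disjoint and exhaustive split, reproducible per seed. The
#' default 0.9/0.1 fractions mirror a 400-case corpus split into 360
#' training and 40 validation cases. Fractions must sum to 1; subset sizes
#' are `floor(n * fraction)` with any remainder going to the first subset.
#'
#' @param cases vector of case identifiers.
#' @param fractions named or unnamed numeric vector of 2 or 3 fractions
#'   (train, validation, and optionally test).
#' @param seed integer seed.
#' @return Named list of id vectors (`train`, `validation`, `test` if
#'   requested).
#' @export
split_dataset <- function(cases, fractions = c(train = 0.9, validation = 0.1),
                          seed = 1L) {
  stopifnot(length(fractions) %in% c(2L, 3L))
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  n <- length(cases)
  sizes <- pmax(1, floor(n * fractions))
  sizes[1] <- n - sum(sizes[-1])
  if (any(sizes < 1)) stop("too few cases (", n, ") for the requested split")
  perm <- with_seed(seed, sample.int(n))
  nm <- names(fractions)
  if (is.null(nm)) nm <- c("train", "validation", "test")[seq_along(fractions)]
  out <- list()
  at <- 0L
  for (i in seq_along(fractions)) {
    out[[nm[i]]] <- cases[sort(perm[at + seq_len(sizes[i])])]
    at <- at + sizes[i]
  }
  out
}

#' Prepare one training pair at stage resolution
#'
#' Builds the network input and target for one case: the ground-truth mesh
#' is rasterized as a greedy mask at the native CT resolution, then both
#' the windowed CT and the mask are resampled to the stage grid. Stage 2
#' additionally crops both to `roi_box` (native-index box) first. Mask
#' resampling interpolates the {0,1} field trilinearly and re-thresholds at
#' 0.5 so thin cortical shells survive the downsampling.
#'
#' @param mesh ground-truth [triangle_mesh()] in mm patient space.
#' @param ct the native [image_volume()].
#' @param stage 1 or 2.
#' @param stage_shape target grid shape for the stage.
#' @param roi_box native 2 x 3 index box (required for stage 2).
#' @param window HU window for [normalize_intensities()].
#' @return list with `input` ([image_volume()], values in \[0, 1\]),
#'   `target` ([binary_mask()]) and `native_mask`.
#' @export
prepare_targets <- function(mesh, ct, stage = 1L, stage_shape,
                            roi_box = NULL, window = c(-1024, 3071)) {
  stopifnot(inherits(mesh, "cs_mesh"), inherits(ct, "cs_volume"))
  bb <- mesh_bbox(mesh)
  ext <- physical_extent(ct)
  if (any(bb[1, ] < ext[1, ] - 1e-6) || any(bb[2, ] > ext[2, ] + 1e-6)) {
    stop("ground-truth mesh extends outside the CT volume")
  }
  native_mask <- greedy_voxelize(mesh, ct)
  vol <- normalize_intensities(ct, window)
  msk <- native_mask
  if (stage == 2L) {
    if (is.null(roi_box)) stop("stage 2 requires a native-resolution roi_box")
    vol <- crop_to_box(vol, roi_box)
    msk <- crop_to_box(msk, roi_box)
  }
  input <- resample_to_shape(vol, stage_shape, mode = "linear")
  target <- resample_to_shape(msk, stage_shape, mode = "linear")  # + threshold
  list(input = input, target = target, native_mask = native_mask)
}

#' Train one cascade stage
#'
#' Full-volume training with batch size 1: per epoch every training pair is
#' visited once (shuffled), the soft Dice loss is backpropagated, and Adam
#' updates all non-frozen layers. After each epoch the mean validation Dice
#' loss drives the reduce-on-plateau/early-stop scheduler of
#' [train_config()]. The weights of the best validation epoch are returned.
#' No data augmentation is applied.
#'
#' @param net a [build_network()] model (optionally transfer-initialized).
#' @param train_pairs,val_pairs lists of `list(input =, target =)` pairs as
#'   produced by [prepare_targets()] (arrays or volumes/masks).
#' @param config a [train_config()].
#' @param verbose print one line per epoch.
#' @return list with `net` (best-validation weights), `history`
#'   (data.frame: epoch, train_loss, val_loss, lr, seconds) and
#'   `best_epoch`.
#' @export
train_stage <- function(net, train_pairs, val_pairs, config = train_config(),
                        verbose = FALSE) {
  stopifnot(inherits(net, "cs_unet"), inherits(config, "cs_train_config"),
            length(train_pairs) >= 1, length(val_pairs) >= 1)
  as_arr <- function(x) if (inherits(x, "cs_volume")) x$data else x
  tr_x <- lapply(train_pairs, function(p) as_arr(p$input))
  tr_y <- lapply(train_pairs, function(p) {
    y <- as_arr(p$target); storage.mode(y) <- "double"; y
  })
  va_x <- lapply(val_pairs, function(p) as_arr(p$input))
  va_y <- lapply(val_pairs, function(p) {
    y <- as_arr(p$target); storage.mode(y) <- "double"; y
  })
  sched <- scheduler_new(config)
  adam <- adam_new()
  trainable <- setdiff(names(net$layers), net$frozen)
  best <- list(loss = Inf, layers = net$layers, epoch = 0L)
  hist <- list()
  order_seed <- config$seed
  for (epoch in seq_len(config$max_epochs)) {
    t0 <- proc.time()[3]
    idx <- if (config$shuffle) {
      with_seed(order_seed + epoch, sample.int(length(tr_x)))
    } else seq_along(tr_x)
    tl <- 0
    for (i in idx) {
      fw <- unet_forward(net, tr_x[[i]], cache = TRUE)
      loss <- dice_loss(fw$prob, tr_y[[i]])
      if (!is.finite(loss)) {
        stop("non-finite training loss at epoch ", epoch, ", case ", i)
      }
      tl <- tl + loss
      dprob <- dice_loss_grad(fw$prob, tr_y[[i]])
      grads <- clip_gradients(unet_backward(net, fw$cache, dprob),
                              config$clip_norm)
      upd <- adam_step(net$layers, grads, adam, sched$lr, trainable)
      net$layers <- upd$params
      adam <- upd$state
    }
    vl <- mean(vapply(seq_along(va_x), function(i) {
      dice_loss(unet_forward(net, va_x[[i]]), va_y[[i]])
    }, numeric(1)))
    if (!is.finite(vl)) stop("non-finite validation loss at epoch ", epoch)
    lr_used <- sched$lr
    sched <- scheduler_step(sched, vl)
    if (vl < best$loss) best <- list(loss = vl, layers = net$layers, epoch = epoch)
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = tl / length(tr_x),
                                val_loss = vl, lr = lr_used,
                                seconds = proc.time()[3] - t0)
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f  lr %.2e%s", epoch,
                      tl / length(tr_x), vl, lr_used,
                      if (sched$reduced) "  [lr reduced]" else ""))
    }
    if (sched$stop) break
  }
  net$layers <- best$layers
  list(net = net, history = do.call(rbind, hist), best_epoch = best$epoch,
       best_val_loss = best$loss)
}

clip_gradients <- function(grads, clip_norm) {
  if (!is.finite(clip_norm)) return(grads)
  total <- sqrt(sum(vapply(grads, function(g) sum(g$W^2) + sum(g$b^2), numeric(1))))
  if (total <= clip_norm) return(grads)
  f <- clip_norm / total
  lapply(grads, function(g) list(W = g$W * f, b = g$b * f))
}

adam_new <- function(beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(m = list(), v = list(), t = 0L, beta1 = beta1, beta2 = beta2, eps = eps)
}

adam_step <- function(params, grads, state, lr, trainable = names(params)) {
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  bc1 <- 1 - b1^state$t; bc2 <- 1 - b2^state$t
  for (nm in trainable) {
    g <- grads[[nm]]
    if (is.null(g)) next
    for (pn in c("W", "b")) {
      key <- paste0(nm, ".", pn)
      gv <- g[[pn]]
      m <- state$m[[key]]
      v <- state$v[[key]]
      if (is.null(m)) { m <- gv * 0; v <- gv * 0 }
      m <- b1 * m + (1 - b1) * gv
      v <- b2 * v + (1 - b2) * gv^2
      state$m[[key]] <- m
      state$v[[key]] <- v
      params[[nm]][[pn]] <- params[[nm]][[pn]] - lr * (m / bc1) / (sqrt(v / bc2) + state$eps)
    }
  }
  list(params = params, state = state)
}

#' Export a training history as CSV
#' @param history data.frame from [train_stage()].
#' @param path output file.
#' @export
write_history <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}
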