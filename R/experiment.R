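#' Ground-truth ROI box for stage-2 training
#'
#' The stage-2 training crop around a case's ground-truth mask: its tight
#' native bounding box expanded by `margin` of the extent per side and
#' clamped to the volume. (At inference time the crop comes from the
#' stage-1 prediction instead; the two networks are trained separately.)
#'
#' @param native_mask greedy ground-truth [binary_mask()] at CT
#'   resolution.
#' @param margin fractional margin per side.
#' @return 2 x 3 integer index box.
#' @export
gt_roi_box <- function(native_mask, margin = 0.1) {
  roi_from_mask(native_mask, native_mask, margin)
}

#' Desk-scale end-to-end experiment on phantoms
#'
#' The full segmentation pipeline at desk scale: generate a phantom cohort, split
#' it, train the stage-2 network from Glorot initialization, train the
#' stage-1 network transfer-initialized from the stage-2 weights, run the
#' two-stage pipeline plus post-processing on the held-out test phantoms,
#' and evaluate mesh metrics (whole + left/right transplant ROI) as well
#' as per-stage volumetric Dice against the greedy ground-truth masks.
#'
#' Defaults mirror the clinical-scale configuration at reduced scale: 45 cases split
#' 30/5/10, tiny networks (`base_filters = 4`) at stage shapes 48x48x48
#' and 64x48x48.
#'
#' @param n_train,n_val,n_test cohort split sizes.
#' @param base_filters network width.
#' @param stage1_shape,stage2_shape stage grid shapes (divisible by 16).
#' @param max_epochs2 epoch cap for stage 2 (trained from Glorot init).
#' @param max_epochs1 epoch cap for stage 1 (transfer-initialized from the
#'   trained stage-2 weights, hence fewer epochs).
#' @param n_points surface samples per mesh for distance metrics.
#' @param pitch mesh-Dice grid pitch, mm.
#' @param seed master seed (phantoms, weights, sampling).
#' @param spec optional [phantom_spec()] override.
#' @param verbose print progress.
#' @return list with `per_case` (mesh metrics long table), `summary`
#'   (cohort table), `stage_dice` (per-case stage-1/stage-2 volumetric
#'   Dice), `voxel_mm` (per-case mean voxel size), `history1`, `history2`,
#'   and the trained networks.
#' @export
run_desk_experiment <- function(n_train = 30L, n_val = 5L, n_test = 10L,
                                base_filters = 4L,
                                stage1_shape = c(48L, 48L, 48L),
                                stage2_shape = c(64L, 48L, 48L),
                                max_epochs2 = 22L, max_epochs1 = 12L,
                                n_points = 2e4,
                                pitch = 1.0, seed = 1L, spec = NULL,
                                verbose = FALSE) {
  n_all <- n_train + n_val + n_test
  if (is.null(spec)) spec <- phantom_spec(seed = seed)
  pcfg <- pipeline_config(stage1_shape = stage1_shape, stage2_shape = stage2_shape)
  say <- function(...) if (verbose) message(sprintf(...))

  say("generating %d phantoms", n_all)
  split <- split_dataset(seq_len(n_all),
                         c(train = n_train, validation = n_val, test = n_test) / n_all,
                         seed = seed + 17L)
  fit_ids <- c(split$train, split$validation)
  pairs1 <- list(); pairs2 <- list()
  test_cases <- list()
  for (i in seq_len(n_all)) {
    ph <- generate_phantom(spec, i)
    if (i %in% fit_ids) {
      p1 <- prepare_targets(ph$mesh, ph$volume, 1L, stage1_shape)
      box <- gt_roi_box(p1$native_mask, margin = 0.1)
      p2 <- prepare_targets(ph$mesh, ph$volume, 2L, stage2_shape, roi_box = box)
      pairs1[[as.character(i)]] <- list(input = p1$input$data, target = p1$target$data)
      pairs2[[as.character(i)]] <- list(input = p2$input$data, target = p2$target$data)
    } else {
      test_cases[[as.character(i)]] <- ph
    }
  }
  pick <- function(pairs, ids) pairs[as.character(ids)]

  ucfg <- unet_config(base_filters = base_filters)

  say("training stage 2 (Glorot init)")
  net2 <- build_network(ucfg, seed = seed + 101L)
  fit2 <- train_stage(net2, pick(pairs2, split$train), pick(pairs2, split$validation),
                      train_config(max_epochs = max_epochs2, seed = seed + 29L),
                      verbose = verbose)

  say("training stage 1 (transfer init from stage 2)")
  net1 <- build_network(ucfg, seed = seed + 202L)
  net1 <- transfer_init(net1, fit2$net)
  fit1 <- train_stage(net1, pick(pairs1, split$train), pick(pairs1, split$validation),
                      train_config(max_epochs = max_epochs1, seed = seed + 37L),
                      verbose = verbose)

  say("evaluating %d held-out phantoms", length(test_cases))
  rois <- default_crest_rois()
  per_case <- list(); stage_rows <- list()
  pred_meshes <- list()
  for (id in names(test_cases)) {
    ph <- test_cases[[id]]
    seg <- run_pipeline(ph$volume, fit1$net, fit2$net, pcfg)
    pred_meshes[[id]] <- seg$mesh
    gt_native <- greedy_voxelize(ph$mesh, ph$volume)
    d <- vol_shape(ph$volume)
    s1_native <- resample_to_shape(seg$stage1_mask, d, mode = "nearest")
    dice1 <- dice_coefficient(s1_native$data, gt_native$data)
    box <- seg$roi_box
    box_shape <- box[2, ] - box[1, ] + 1L
    s2_crop <- resample_to_shape(seg$stage2_mask, box_shape, mode = "nearest")
    s2_native <- array(FALSE, dim = d)
    s2_native[box[1, 1]:box[2, 1], box[1, 2]:box[2, 2], box[1, 3]:box[2, 3]] <-
      s2_crop$data
    dice2 <- dice_coefficient(s2_native, gt_native$data)
    stage_rows[[id]] <- data.frame(case_id = id, stage1_dice = dice1,
                                   stage2_dice = dice2,
                                   voxel_mm = mean(ph$volume$spacing))
    mc <- evaluate_case(seg$mesh, ph$mesh, rois, pitch = pitch,
                        n_points = n_points, seed = seed + 31L)
    per_case[[id]] <- cbind(case_id = id, mc)
    say("  case %s: dice1 %.3f dice2 %.3f whole DSC %.3f ASD %.2f", id,
        dice1, dice2, mc$dsc[1], mc$asd_mm[1])
  }
  per_case <- do.call(rbind, per_case)
  stage_dice <- do.call(rbind, stage_rows)
  list(per_case = per_case, summary = summarize_cohort(per_case),
       stage_dice = stage_dice,
       history1 = fit1$history, history2 = fit2$history,
       net1 = fit1$net, net2 = fit2$net, split = split,
       pred_meshes = pred_meshes, test_cases = test_cases)
}
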