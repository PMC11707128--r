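#' Volumetric Dice of two binary arrays
#'
#' `2|A n B| / (|A| + |B|)` on voxel grids of identical shape; the overlap
#' measure used for mask-level comparisons (e.g. stage-1 vs stage-2
#' predictions against the greedy ground-truth mask).
#'
#' @param a,b logical arrays (or [binary_mask()]s) of identical shape.
#' @return Dice fraction in `[0, 1]` (`NaN` if both are empty).
#' @export
dice_coefficient <- function(a, b) {
  if (inherits(a, "cs_mask")) a <- a$data
  if (inherits(b, "cs_mask")) b <- b$data
  stopifnot(identical(dim(a), dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}

#' Evaluate matched prediction/truth mesh pairs
#'
#' Runs [evaluate_case()] for every id and stacks the per-case, per-scope
#' rows into one long table.
#'
#' @param pred_meshes,truth_meshes named lists of [triangle_mesh()]es with
#'   matching names (unmatched ids are skipped with a warning).
#' @param roi_defs list of [roi_definition()]s applied to every case.
#' @param pitch,n_points,seed forwarded to [evaluate_case()].
#' @return data.frame with columns `case_id`, `scope`, `dsc`, `asd_mm`,
#'   `hd95_mm`, `n_sample_points`.
#' @export
evaluate_cohort <- function(pred_meshes, truth_meshes, roi_defs = NULL,
                            pitch = 0.5, n_points = 1e5, seed = 1L) {
  ids <- intersect(names(pred_meshes), names(truth_meshes))
  missing <- setdiff(union(names(pred_meshes), names(truth_meshes)), ids)
  if (length(missing)) {
    warning("skipping unmatched case ids: ", paste(missing, collapse = ", "))
  }
  if (!length(ids)) stop("no matching case ids between predictions and truths")
  rows <- lapply(ids, function(id) {
    r <- evaluate_case(pred_meshes[[id]], truth_meshes[[id]], roi_defs,
                       pitch = pitch, n_points = n_points, seed = seed)
    cbind(case_id = id, r)
  })
  do.call(rbind, rows)
}

#' Cohort summary statistics
#'
#' Summarizes a per-case metric table into mean, standard deviation,
#' minimum, 25% percentile, median, 75% percentile and maximum per metric
#' and scope (percentiles with linear interpolation, quantile type 7). One
#' row per metric x scope combination.
#'
#' @param per_case data.frame from [evaluate_cohort()].
#' @return data.frame with columns `metric`, `scope`, `mean`, `std`,
#'   `min`, `p25`, `median`, `p75`, `max`, `n`.
#' @export
summarize_cohort <- function(per_case) {
  metrics <- c(dsc = "dsc", asd = "asd_mm", hd95 = "hd95_mm")
  rows <- list()
  for (mi in seq_along(metrics)) {
    col <- metrics[mi]
    for (sc in unique(per_case$scope)) {
      x <- per_case[per_case$scope == sc, col, drop = TRUE]
      x <- x[is.finite(x)]
      if (!length(x)) next
      q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = names(metrics)[mi], scope = sc,
        mean = mean(x), std = stats::sd(x), min = min(x),
        p25 = q[1], median = q[2], p75 = q[3], max = max(x),
        n = length(x))
    }
  }
  do.call(rbind, rows)
}

#' Default transplant-ROI cutting planes
#'
#' A mirror-symmetric left/right pair of oblique planes isolating the
#' upper outer crest region of each phantom wing, recorded in normalized
#' (scaled) coordinates. On clinical data the reference plane would come
#' from a specialist-defined landmark plane via [record_roi()]; for the
#' phantom experiments these package defaults play that role.
#'
#' @return list of two [roi_definition()]s (left, right).
#' @export
default_crest_rois <- function() {
  n <- c(0.8, 0, 0.6)
  n <- n / sqrt(sum(n^2))
  left <- roi_definition(anchor = c(0.42, 0, 0.18), normal = n,
                         side = "left", mode = "scaled")
  list(left = left, right = mirror_roi(left))
}
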