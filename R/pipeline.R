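#' Pipeline configuration
#'
#' Shapes default to the cascade's working resolutions: the first stage
#' segments the whole field of view at 160 x 160 x 224, the second
#' re-segments the cropped region of interest at 256 x 144 x 144. Both must
#' be divisible by 16 per axis. Post-processing follows mask -> one-voxel
#' binary erosion -> Gaussian smoothing (`gaussian_sigma`, voxel units) ->
#' iso-surface extraction at `iso_value`.
#'
#' @param stage1_shape,stage2_shape grid shapes of the two stages.
#' @param binarize_threshold probability cut for mask binarization.
#' @param roi_margin fractional margin added around the stage-1 bounding
#'   box on every side.
#' @param erosion_iterations one-voxel-layer erosions before smoothing.
#' @param gaussian_sigma smoothing width in voxels.
#' @param iso_value iso-surface level on the smoothed {0,1} field.
#' @param window HU window used to normalize the CT.
#' @return An object of class `cs_pipeline_config`.
#' @export
pipeline_config <- function(stage1_shape = c(160L, 160L, 224L),
                            stage2_shape = c(256L, 144L, 144L),
                            binarize_threshold = 0.5, roi_margin = 0.05,
                            erosion_iterations = 1L, gaussian_sigma = 1.0,
                            iso_value = 0.5, window = c(-1024, 3071)) {
  stage1_shape <- as.integer(stage1_shape); stage2_shape <- as.integer(stage2_shape)
  stopifnot(length(stage1_shape) == 3L, length(stage2_shape) == 3L,
            binarize_threshold > 0, binarize_threshold < 1, roi_margin >= 0,
            erosion_iterations >= 0, gaussian_sigma >= 0)
  if (any(c(stage1_shape, stage2_shape) %% 16L != 0L)) {
    stop("stage shapes must be divisible by 16 on every axis")
  }
  structure(list(stage1_shape = stage1_shape, stage2_shape = stage2_shape,
                 binarize_threshold = binarize_threshold, roi_margin = roi_margin,
                 erosion_iterations = as.integer(erosion_iterations),
                 gaussian_sigma = gaussian_sigma, iso_value = iso_value,
                 window = window),
            class = "cs_pipeline_config")
}

#' Stage-1 segmentation of the whole field of view
#'
#' Normalizes the CT, resamples it to the stage-1 grid, predicts with the
#' first-stage network and binarizes at the configured threshold.
#'
#' @param ct native [image_volume()] (HU).
#' @param net1 first-stage [build_network()] model.
#' @param config a [pipeline_config()].
#' @return A [binary_mask()] at stage-1 geometry.
#' @export
stage1_segment <- function(ct, net1, config = pipeline_config()) {
  vol <- resample_to_shape(normalize_intensities(ct, config$window),
                           config$stage1_shape, mode = "linear")
  prob <- unet_predict(net1, vol)
  m <- prob > config$binarize_threshold
  if (!any(m)) stop("bone not found: stage-1 prediction is empty")
  binary_mask(m, vol$spacing, vol$origin)
}

#' Region of interest around a stage-1 mask
#'
#' Maps the tight bounding box of the stage-1 foreground into native CT
#' voxel indices (via physical coordinates), expands it by `margin` of the
#' box extent on every side and clamps to the volume bounds.
#'
#' @param mask non-empty [binary_mask()] at stage-1 geometry.
#' @param ct the native [image_volume()].
#' @param margin fraction per axis.
#' @return 2 x 3 integer matrix of 1-based inclusive native indices.
#' @export
roi_from_mask <- function(mask, ct, margin = 0.05) {
  stopifnot(inherits(mask, "cs_mask"))
  idx <- which(mask$data, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask has no region of interest")
  imin <- apply(idx, 2, min); imax <- apply(idx, 2, max)
  lo <- mask$origin + (imin - 1) * mask$spacing - mask$spacing / 2
  hi <- mask$origin + (imax - 1) * mask$spacing + mask$spacing / 2
  ext <- hi - lo
  lo <- lo - margin * ext
  hi <- hi + margin * ext
  d <- vol_shape(ct)
  i_lo <- pmin(pmax(floor((lo - ct$origin) / ct$spacing + 1.5), 1), d)
  i_hi <- pmin(pmax(floor((hi - ct$origin) / ct$spacing + 1.5), 1), d)
  box <- rbind(as.integer(i_lo), as.integer(i_hi))
  rownames(box) <- c("first", "last")
  box
}

#' Stage-2 segmentation of the cropped region of interest
#'
#' Crops the normalized CT to `roi_box`, resamples the crop to the stage-2
#' grid, predicts and binarizes. The returned mask carries the crop's
#' physical origin and the resampled spacing, so meshes extracted from it
#' land in patient mm coordinates.
#'
#' @param ct native [image_volume()].
#' @param roi_box 2 x 3 native index box from [roi_from_mask()].
#' @param net2 second-stage [build_network()] model.
#' @param config a [pipeline_config()].
#' @return A [binary_mask()] at stage-2 crop geometry.
#' @export
stage2_segment <- function(ct, roi_box, net2, config = pipeline_config()) {
  crop <- crop_to_box(normalize_intensities(ct, config$window), roi_box)
  vol <- resample_to_shape(crop, config$stage2_shape, mode = "linear")
  prob <- unet_predict(net2, vol)
  m <- prob > config$binarize_threshold
  if (!any(m)) stop("bone not found: stage-2 prediction is empty")
  binary_mask(m, vol$spacing, vol$origin)
}

#' Binary erosion (one voxel layer per iteration)
#'
#' 6-connected erosion; voxels outside the volume count as background.
#'
#' @param mask a [binary_mask()] or logical array.
#' @param iterations number of erosion passes.
#' @return Same type as `mask`.
#' @export
erode_mask <- function(mask, iterations = 1L) {
  m <- if (inherits(mask, "cs_mask")) mask$data else mask
  d <- dim(m)
  shift_and <- function(a) {
    out <- a
    pad <- function(x, axis, from) {
      y <- array(FALSE, dim = d)
      n <- d[axis]
      if (n < 2) return(y)
      src <- lapply(d, seq_len); dst <- src
      if (from > 0) { src[[axis]] <- 2:n; dst[[axis]] <- 1:(n - 1) }
      else { src[[axis]] <- 1:(n - 1); dst[[axis]] <- 2:n }
      y[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
      y
    }
    for (axis in 1:3) out <- out & pad(a, axis, 1) & pad(a, axis, -1)
    out
  }
  for (i in seq_len(iterations)) m <- shift_and(m)
  if (inherits(mask, "cs_mask")) binary_mask(m, mask$spacing, mask$origin) else m
}

#' Separable Gaussian smoothing of a 3D field
#'
#' Truncated-at-3-sigma separable kernel applied along each axis; the field
#' is treated as zero outside the grid (appropriate for {0,1} occupancy
#' fields whose foreground is interior).
#'
#' @param x 3D numeric array (logical is coerced).
#' @param sigma standard deviation in voxels.
#' @return 3D numeric array.
#' @export
gaussian_smooth <- function(x, sigma = 1.0) {
  if (is.logical(x)) { x <- array(as.double(x), dim = dim(x)) }
  if (sigma <= 0) return(x)
  d <- dim(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  smooth_axis <- function(a, axis) {
    n <- d[axis]
    Km <- matrix(0, n, n)
    for (o in seq(-r, r)) {
      i <- seq_len(n)
      j <- i + o
      ok <- j >= 1 & j <= n
      Km[cbind(i[ok], j[ok])] <- Km[cbind(i[ok], j[ok])] + k[o + r + 1]
    }
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    res <- Km %*% matrix(ap, nrow = n)
    aperm(array(res, dim = dp), order(perm))
  }
  for (axis in 1:3) x <- smooth_axis(x, axis)
  x
}

#' Post-process a binary mask into a surface mesh
#'
#' The binary stage-2 output is eroded by one layer of voxels (compensating
#' the dilation introduced by greedy mask generation), smoothed with a
#' Gaussian filter, and converted to a triangle mesh by marching cubes at
#' `iso_value`. Small disconnected parts are retained. If erosion removes
#' all foreground, an empty mesh is returned with a warning.
#'
#' @param mask a [binary_mask()] (stage-2 geometry in the full pipeline).
#' @param config a [pipeline_config()].
#' @return A [triangle_mesh()] in mm patient coordinates.
#' @export
postprocess_mask <- function(mask, config = pipeline_config()) {
  stopifnot(inherits(mask, "cs_mask"))
  er <- erode_mask(mask, config$erosion_iterations)
  if (!any(er$data)) {
    warning("mask empty after erosion; returning an empty mesh")
    return(triangle_mesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3)))
  }
  sm <- gaussian_smooth(er$data, config$gaussian_sigma)
  marching_cubes(sm, iso = config$iso_value, spacing = mask$spacing,
                 origin = mask$origin)
}

#' Run the full two-stage segmentation pipeline
#'
#' Stage-1 whole-field segmentation, ROI extraction around its foreground,
#' stage-2 segmentation of the crop, and post-processing into a surface
#' mesh. Deterministic given the weights and input.
#'
#' @param ct native [image_volume()] (HU).
#' @param net1,net2 trained stage networks.
#' @param config a [pipeline_config()].
#' @return An object of class `cs_segmentation`: list with `stage1_mask`,
#'   `roi_box`, `stage2_mask`, `mesh`.
#' @export
run_pipeline <- function(ct, net1, net2, config = pipeline_config()) {
  s1 <- stage1_segment(ct, net1, config)
  box <- roi_from_mask(s1, ct, config$roi_margin)
  s2 <- stage2_segment(ct, box, net2, config)
  mesh <- postprocess_mask(s2, config)
  structure(list(stage1_mask = s1, roi_box = box, stage2_mask = s2, mesh = mesh),
            class = "cs_segmentation")
}

#' @export
print.cs_segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> roi [%s]-[%s], mesh: %d faces\n",
              paste(x$roi_box[1, ], collapse = ","),
              paste(x$roi_box[2, ], collapse = ","), n_faces(x$mesh)))
  invisible(x)
}
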