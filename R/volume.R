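#' Image volumes and binary masks
#'
#' A `cs_volume` is a scalar intensity grid (Hounsfield units for CT input)
#' together with its voxel geometry: per-axis spacing in mm and the physical
#' position (mm) of the *first* voxel centre. The physical centre of voxel
#' `(i, j, k)` (1-based) is `origin + (c(i, j, k) - 1) * spacing`, and each
#' voxel occupies the axis-aligned box `centre +/- spacing / 2`. Axes are
#' ordered (x, y, z) with x and y the in-plane CT axes. Only axis-aligned
#' acquisitions are supported.
#'
#' @param data 3D numeric array of intensities.
#' @param spacing numeric length-3, mm per voxel along each axis; all > 0.
#' @param origin numeric length-3, mm position of the first voxel centre.
#' @return An object of class `cs_volume`.
#' @seealso [binary_mask()], [read_volume()], [resample_to_shape()]
#' @export
image_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  data <- as.array(data)
  storage.mode(data) <- "double"
  stopifnot(length(dim(data)) == 3L, all(dim(data) >= 1L))
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 positive finite numbers (mm)")
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("`origin` must be 3 finite numbers (mm)")
  }
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "cs_volume")
}

#' @description `binary_mask()` carries a boolean occupancy grid with the
#'   same geometry model; it is the segmentation carrier at every stage.
#' @rdname image_volume
#' @export
binary_mask <- function(data, spacing, origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (is.numeric(data)) {
    if (!all(data %in% c(0, 1))) stop("mask values must be strictly 0/1")
    data <- array(data > 0.5, dim = dim(data))
  }
  stopifnot(is.logical(data), length(dim(data)) == 3L)
  v <- image_volume(array(0, dim = dim(data)), spacing, origin)
  structure(list(data = data, spacing = v$spacing, origin = v$origin),
            class = c("cs_mask", "cs_volume"))
}

#' @export
print.cs_volume <- function(x, ...) {
  kind <- if (inherits(x, "cs_mask")) "binary mask" else "image volume"
  cat(sprintf("<%s> %s voxels, spacing (%s) mm, origin (%s) mm\n",
              kind, paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = ", "),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

vol_shape <- function(v) dim(v$data)

#' Physical extent of a grid
#'
#' Returns the axis-aligned physical bounding box covered by the voxel
#' *boxes* of a volume (not just the centres), as a 2 x 3 matrix
#' (rows: min, max; columns: x, y, z), in mm.
#'
#' @param v a [image_volume()] or [binary_mask()].
#' @return 2 x 3 numeric matrix.
#' @export
physical_extent <- function(v) {
  lo <- v$origin - v$spacing / 2
  hi <- v$origin + (vol_shape(v) - 1) * v$spacing + v$spacing / 2
  rbind(min = lo, max = hi)
}

#' Read / write volumes as NIfTI
#'
#' `read_volume()` reads a `.nii` / `.nii.gz` file; intensities are returned
#' untouched and spacing/origin are taken from the header (sform, falling
#' back to pixdim). `write_volume()` writes the volume with its geometry in
#' an axis-aligned sform. `read_mask()`/`write_mask()` are the strict-binary
#' variants ({0, 1} voxel values on disk).
#'
#' @param path file path to a NIfTI image.
#' @return `read_volume()`: a [image_volume()]; `read_mask()`: a
#'   [binary_mask()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable NIfTI file: ", path,
                                           " (", conditionMessage(e), ")"))
  d <- dim(img)
  if (length(d) != 3L) stop("expected a 3D volume, got ", length(d), " dims")
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0)) stop("missing or invalid voxel spacing in header")
  xf <- RNifti::xform(img)
  org <- if (is.matrix(xf)) as.numeric(xf[1:3, 4]) else c(0, 0, 0)
  image_volume(array(as.numeric(img), dim = d), sp, org)
}

#' @rdname read_volume
#' @param v volume (or mask) to write.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "cs_volume"))
  dat <- if (is.logical(v$data)) array(as.integer(v$data), dim = dim(v$data)) else v$data
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- v$spacing
  m <- diag(c(v$spacing, 1))
  m[1:3, 4] <- v$origin
  img <- RNifti::`qform<-`(img, structure(m, code = 2L))
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  if (!all(v$data %in% c(0, 1))) stop("mask file contains values other than {0, 1}")
  binary_mask(v$data > 0.5, v$spacing, v$origin)
}

#' @rdname read_volume
#' @export
write_mask <- function(v, path) {
  stopifnot(inherits(v, "cs_mask"))
  write_volume(v, path)
}

#' Window-and-rescale CT intensities
#'
#' Clips intensities to `[window[1], window[2]]` HU and maps the window
#' affinely onto `[0, 1]`. The default window spans the full 12-bit CT range
#' (-1024 to 3071 HU), preserving bone/soft-tissue contrast without
#' saturating metal.
#'
#' @param v a [image_volume()].
#' @param window numeric length-2, `(lo, hi)` in HU with `lo < hi`.
#' @return A [image_volume()] with values in `[0, 1]` (spacing/origin kept).
#' @export
normalize_intensities <- function(v, window = c(-1024, 3071)) {
  stopifnot(inherits(v, "cs_volume"))
  if (length(window) != 2L || !all(is.finite(window)) || window[1] >= window[2]) {
    stop("`window` must be (lo, hi) with lo < hi")
  }
  x <- pmin(pmax(v$data, window[1]), window[2])
  image_volume((x - window[1]) / (window[2] - window[1]), v$spacing, v$origin)
}

#' Resample a grid to a fixed shape
#'
#' Resamples a volume (trilinear) or a mask onto a grid with
#' `target_shape` voxels per axis covering the same physical extent: the
#' output spacing along axis `i` is `spacing[i] * dim[i] / target_shape[i]`
#' and the voxel-box extent of the grid is preserved exactly. Masks use
#' `mode = "nearest"` by default; `mode = "linear"` on a mask interpolates
#' the {0,1} field and re-thresholds at 0.5, which avoids aliasing holes in
#' thin cortical structures when downsampling training targets.
#'
#' @param v a [image_volume()] or [binary_mask()].
#' @param target_shape integer length-3, all positive.
#' @param mode `"linear"` or `"nearest"`; default `"linear"` for volumes,
#'   `"nearest"` for masks.
#' @return Same class as `v`, with shape `target_shape`.
#' @export
resample_to_shape <- function(v, target_shape,
                              mode = if (inherits(v, "cs_mask")) "nearest" else "linear") {
  stopifnot(inherits(v, "cs_volume"))
  target_shape <- as.integer(target_shape)
  if (length(target_shape) != 3L || any(target_shape < 1L)) {
    stop("`target_shape` must be 3 positive integers")
  }
  mode <- match.arg(mode, c("linear", "nearest"))
  din <- vol_shape(v)
  sp_out <- v$spacing * din / target_shape
  # cell-centred alignment: shared physical extent [origin - s/2, ...]
  org_out <- v$origin - v$spacing / 2 + sp_out / 2
  src <- if (is.logical(v$data)) array(as.double(v$data), dim = din) else v$data
  out <- .cs_resample(as.numeric(src), din, v$spacing, v$origin,
                      target_shape, sp_out, org_out, mode == "nearest")
  out <- array(out, dim = target_shape)
  if (inherits(v, "cs_mask")) {
    binary_mask(out > 0.5, sp_out, org_out)
  } else {
    image_volume(out, sp_out, org_out)
  }
}

#' Crop a grid to an index box
#'
#' @param v a [image_volume()] or [binary_mask()].
#' @param box 2 x 3 integer matrix (rows: first, last; 1-based inclusive
#'   voxel indices per axis), e.g. `rbind(c(1, 1, 1), dim(v$data))`.
#' @return Same class as `v`; the origin shifts by
#'   `(box[1, ] - 1) * spacing`, spacing is unchanged.
#' @export
crop_to_box <- function(v, box) {
  stopifnot(inherits(v, "cs_volume"))
  box <- matrix(as.integer(box), 2, 3)
  d <- vol_shape(v)
  if (any(box[1, ] < 1L) || any(box[2, ] > d) || any(box[1, ] > box[2, ])) {
    stop("crop box out of bounds or empty")
  }
  dat <- v$data[box[1, 1]:box[2, 1], box[1, 2]:box[2, 2], box[1, 3]:box[2, 3], drop = FALSE]
  org <- v$origin + (box[1, ] - 1) * v$spacing
  if (inherits(v, "cs_mask")) binary_mask(dat, v$spacing, org)
  else image_volume(dat, v$spacing, org)
}
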