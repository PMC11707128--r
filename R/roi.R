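#' Transplant-ROI cutting planes
#'
#' The transplant-relevant crest region is isolated by an oblique cutting
#' plane. A plane is *recorded* on a reference bone relative to that bone's
#' geometric (surface-area) centre and *applied* to other bones by
#' reconstructing an absolute plane from each target's own centre. Two
#' normalization modes exist: `"scaled"` (default) additionally divides the
#' centre offset componentwise by the mesh bounding-box half-extents, so
#' the plane scales with bone size; `"translate"` stores the raw mm offset
#' and only follows the centre. The normal is stored in absolute
#' orientation (unit length).
#'
#' @param anchor length-3 normalized anchor (centre-relative offset,
#'   divided by half-extents in `"scaled"` mode).
#' @param normal length-3 unit normal; the kept (crest) side is the
#'   positive side.
#' @param side `"left"` or `"right"`.
#' @param mode `"scaled"` or `"translate"`.
#' @return An object of class `cs_roi`.
#' @export
roi_definition <- function(anchor, normal, side = c("left", "right"),
                           mode = c("scaled", "translate")) {
  side <- match.arg(side)
  mode <- match.arg(mode)
  anchor <- as.numeric(anchor); normal <- as.numeric(normal)
  stopifnot(length(anchor) == 3L, length(normal) == 3L)
  nn <- sqrt(sum(normal^2))
  if (abs(nn - 1) > 1e-9) stop("plane normal must be unit length")
  if (identical(mode, "scaled") && any(abs(anchor) > 2)) {
    stop("normalized anchor outside the sanity bound [-2, 2]")
  }
  structure(list(anchor = anchor, normal = normal, side = side, mode = mode),
            class = "cs_roi")
}

mesh_half_extents <- function(mesh) {
  bb <- mesh_bbox(mesh)
  he <- (bb[2, ] - bb[1, ]) / 2
  if (any(he <= 0)) stop("degenerate mesh: zero extent along an axis")
  he
}

#' Record a cutting plane on a reference bone
#'
#' Stores `point` as an offset from the reference mesh's geometric centre
#' (componentwise divided by the bounding-box half-extents in `"scaled"`
#' mode). Applying the definition back to the same mesh recovers the
#' absolute plane exactly.
#'
#' @param reference_mesh the reference [triangle_mesh()].
#' @param point length-3, a point on the plane (mm, absolute).
#' @param normal length-3 unit normal (kept side positive).
#' @param side `"left"` or `"right"`.
#' @param mode `"scaled"` or `"translate"`.
#' @return A [roi_definition()].
#' @export
record_roi <- function(reference_mesh, point, normal, side = c("left", "right"),
                       mode = c("scaled", "translate")) {
  stopifnot(inherits(reference_mesh, "cs_mesh"))
  mode <- match.arg(mode)
  point <- as.numeric(point); normal <- as.numeric(normal)
  bb <- mesh_bbox(reference_mesh)
  sd_corners <- apply(as.matrix(expand.grid(bb[, 1], bb[, 2], bb[, 3])), 1,
                      function(p) sum((p - point) * normal))
  if (all(sd_corners > 0) || all(sd_corners < 0)) {
    stop("cutting plane does not intersect the mesh bounding box")
  }
  ctr <- geometric_center(reference_mesh)
  off <- point - ctr
  anchor <- if (identical(mode, "scaled")) off / mesh_half_extents(reference_mesh) else off
  roi_definition(anchor, normal, side, mode)
}

#' Absolute plane of a ROI definition on a target bone
#' @param mesh target [triangle_mesh()].
#' @param roi a [roi_definition()].
#' @return list with `point` and `normal` (mm, absolute).
#' @export
roi_absolute_plane <- function(mesh, roi) {
  stopifnot(inherits(roi, "cs_roi"), inherits(mesh, "cs_mesh"))
  ctr <- geometric_center(mesh)
  off <- if (identical(roi$mode, "scaled")) roi$anchor * mesh_half_extents(mesh) else roi$anchor
  list(point = ctr + off, normal = roi$normal)
}

#' Apply a ROI definition to a bone
#'
#' Reconstructs the absolute plane from the target's geometric centre (and
#' half-extents in `"scaled"` mode) and clips the mesh to the positive
#' (crest) side. Equivariant to rigid translation, and in `"scaled"` mode
#' to uniform scaling about the centre.
#'
#' @param target_mesh [triangle_mesh()] to clip.
#' @param roi a [roi_definition()].
#' @param plane optional pre-computed absolute plane (list `point`,
#'   `normal`), e.g. the ground-truth bone's plane reused for the
#'   prediction so both are clipped identically.
#' @return The clipped [triangle_mesh()] (empty with a warning if nothing
#'   lies on the positive side).
#' @export
apply_roi <- function(target_mesh, roi, plane = NULL) {
  stopifnot(inherits(target_mesh, "cs_mesh"))
  if (mesh_is_empty(target_mesh)) stop("cannot apply a ROI to an empty mesh")
  if (is.null(plane)) plane <- roi_absolute_plane(target_mesh, roi)
  out <- clip_by_plane(target_mesh, plane$point, plane$normal)
  if (mesh_is_empty(out)) warning("ROI clip is empty for side '", roi$side, "'")
  out
}

#' Mirror a ROI definition across the mid-sagittal axis
#'
#' Reflects anchor and normal across the first (x) axis and flips the
#' side label; mirroring twice is the identity.
#'
#' @param roi a [roi_definition()].
#' @return A [roi_definition()] for the opposite side.
#' @export
mirror_roi <- function(roi) {
  stopifnot(inherits(roi, "cs_roi"))
  refl <- function(v) c(-v[1], v[2], v[3])
  roi_definition(refl(roi$anchor), refl(roi$normal),
                 side = if (identical(roi$side, "left")) "right" else "left",
                 mode = roi$mode)
}

#' Read / write ROI definitions as JSON
#' @param roi a [roi_definition()] (or for files, a list of them).
#' @param path JSON file path.
#' @export
write_roi <- function(roi, path) {
  if (inherits(roi, "cs_roi")) roi <- list(roi)
  payload <- lapply(roi, function(r) {
    list(anchor = r$anchor, normal = r$normal, side = r$side, mode = r$mode)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi
#' @export
read_roi <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(raw)) raw <- split(raw, seq_len(nrow(raw)))
  out <- lapply(seq_along(raw), function(i) {
    r <- raw[[i]]
    roi_definition(unlist(r$anchor), unlist(r$normal), r$side[[1]], r$mode[[1]])
  })
  if (length(out) == 1L) out[[1]] else out
}
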