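#' Extract an iso-surface from a scalar grid
#'
#' Marching cubes over a uniform tetrahedral (Kuhn) decomposition of each
#' grid cell: grid vertices are classified against `iso`, crossing edges are
#' interpolated linearly, and the resulting triangles are welded into an
#' indexed mesh with outward orientation (normals point from values above
#' `iso` towards values below). Vertices are returned in mm patient
#' coordinates (`origin + index * spacing`). A field with no iso-crossing
#' yields an empty mesh with a warning.
#'
#' Like any midpoint iso-surfacer, running this directly on a raw {0,1}
#' mask produces a staircase surface with inflated area; the segmentation
#' pipeline therefore always smooths masks (see [postprocess_mask()])
#' before meshing.
#'
#' @param field a [image_volume()], [binary_mask()] or 3D numeric array.
#' @param iso iso-value; the surface separates values above from below.
#' @param spacing,origin grid geometry, used only when `field` is a bare
#'   array.
#' @return A [triangle_mesh()].
#' @export
marching_cubes <- function(field, iso = 0.5, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (inherits(field, "cs_volume")) {
    spacing <- field$spacing
    origin <- field$origin
    field <- field$data
  }
  stopifnot(length(dim(field)) == 3L)
  if (any(dim(field) < 2L)) stop("field needs at least 2 samples per axis")
  dat <- as.numeric(field)
  res <- .cs_marching_tets(dat, dim(field), iso)
  if (nrow(res$faces) == 0L) {
    warning("no iso-crossing at iso = ", iso, "; returning an empty mesh")
    return(triangle_mesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3)))
  }
  verts <- sweep(sweep(res$vertices, 2, as.numeric(spacing), "*"),
                 2, as.numeric(origin), "+")
  triangle_mesh(verts, res$faces)
}

#' Greedy mesh-to-voxel rasterization
#'
#' Builds the training mask for a ground-truth surface: a voxel is set iff
#' its axis-aligned box (`centre +/- spacing / 2`) has a positive-measure
#' intersection with the mesh interior or surface. This is a superset of
#' the centre-containment mask ("greedy" labelling), implemented as an
#' exact triangle-box separating-axis test for surface voxels plus parity
#' ray casting of voxel centres for the interior. Voxels that merely touch
#' the surface in a zero-volume set (e.g. a face lying exactly on a voxel
#' boundary) are not set.
#'
#' @param mesh a closed, orientable [triangle_mesh()] in mm.
#' @param geometry a [image_volume()]/[binary_mask()] providing the target
#'   grid, or a list with `shape`, `spacing`, `origin`.
#' @param greedy if `FALSE`, plain centre-containment voxelization instead.
#' @return A [binary_mask()] on the requested grid.
#' @export
greedy_voxelize <- function(mesh, geometry, greedy = TRUE) {
  stopifnot(inherits(mesh, "cs_mesh"))
  if (mesh_is_empty(mesh)) stop("cannot voxelize an empty mesh")
  g <- as_geometry(geometry)
  inside <- .cs_grid_inside(mesh$vertices, mesh$faces, g$shape, g$spacing, g$origin)
  set <- if (greedy) {
    inside | .cs_surface_voxels(mesh$vertices, mesh$faces, g$shape, g$spacing, g$origin)
  } else {
    inside
  }
  binary_mask(array(set, dim = g$shape), g$spacing, g$origin)
}

as_geometry <- function(geometry) {
  if (inherits(geometry, "cs_volume")) {
    list(shape = dim(geometry$data), spacing = geometry$spacing, origin = geometry$origin)
  } else {
    stopifnot(is.list(geometry), all(c("shape", "spacing", "origin") %in% names(geometry)))
    list(shape = as.integer(geometry$shape), spacing = as.numeric(geometry$spacing),
         origin = as.numeric(geometry$origin))
  }
}

#' Point-in-mesh and point-to-mesh queries
#'
#' `points_in_mesh()` tests containment by parity ray casting;
#' `point_mesh_distance()` returns the exact unsigned distance from each
#' point to the closest triangle of the mesh (uniform-grid accelerated).
#'
#' @param points n x 3 matrix, mm.
#' @param mesh a [triangle_mesh()].
#' @return logical / numeric vector of length n.
#' @export
points_in_mesh <- function(points, mesh) {
  stopifnot(inherits(mesh, "cs_mesh"))
  points <- matrix(as.numeric(points), ncol = 3)
  if (mesh_is_empty(mesh)) return(rep(FALSE, nrow(points)))
  .cs_points_in_mesh(points, mesh$vertices, mesh$faces)
}

#' @rdname points_in_mesh
#' @export
point_mesh_distance <- function(points, mesh) {
  stopifnot(inherits(mesh, "cs_mesh"))
  if (mesh_is_empty(mesh)) stop("distance to an empty mesh is undefined")
  points <- matrix(as.numeric(points), ncol = 3)
  .cs_point_mesh_dist(points, mesh$vertices, mesh$faces)
}
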