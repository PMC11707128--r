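#' Triangle meshes
#'
#' A `cs_mesh` holds vertices (N x 3, mm, patient space) and triangle faces
#' (M x 3, 1-based vertex indices). Faces with a repeated vertex index are
#' rejected. Ground-truth surfaces are expected to be watertight;
#' post-processed pipeline outputs may contain small disconnected parts,
#' which are kept throughout (check with [mesh_is_watertight()]).
#'
#' @param vertices N x 3 numeric matrix (mm).
#' @param faces M x 3 integer matrix of 1-based vertex indices.
#' @return An object of class `cs_mesh`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) > 0) {
    if (min(faces) < 1L || max(faces) > nrow(vertices)) {
      stop("face indices out of range")
    }
    if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] | faces[, 1] == faces[, 3])) {
      stop("degenerate face: repeated vertex index within a face")
    }
  }
  structure(list(vertices = vertices, faces = faces), class = "cs_mesh")
}

#' @export
print.cs_mesh <- function(x, ...) {
  cat(sprintf("<triangle mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

n_faces <- function(mesh) nrow(mesh$faces)

mesh_is_empty <- function(mesh) n_faces(mesh) == 0L

face_corners <- function(mesh) {
  list(a = mesh$vertices[mesh$faces[, 1], , drop = FALSE],
       b = mesh$vertices[mesh$faces[, 2], , drop = FALSE],
       c = mesh$vertices[mesh$faces[, 3], , drop = FALSE])
}

row_cross <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Surface area, per-face areas, enclosed volume and centroid
#'
#' `mesh_volume()` uses the divergence theorem (signed tetrahedra against
#' the origin); it is meaningful for closed, consistently oriented meshes
#' and returns the absolute value. `geometric_center()` is the area-weighted
#' centroid of the surface, which stays well defined for the small
#' disconnected or open fragments that post-processing can produce.
#'
#' @param mesh a [triangle_mesh()].
#' @return `mesh_area()`/`mesh_volume()`: scalar mm^2 / mm^3;
#'   `face_areas()`: numeric vector; `geometric_center()`: length-3 mm.
#' @export
face_areas <- function(mesh) {
  if (mesh_is_empty(mesh)) return(numeric(0))
  fc <- face_corners(mesh)
  0.5 * sqrt(rowSums(row_cross(fc$b - fc$a, fc$c - fc$a)^2))
}

#' @rdname face_areas
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh))

#' @rdname face_areas
#' @export
mesh_volume <- function(mesh) {
  if (mesh_is_empty(mesh)) return(0)
  fc <- face_corners(mesh)
  abs(sum(rowSums(fc$a * row_cross(fc$b, fc$c))) / 6)
}

#' @rdname face_areas
#' @export
geometric_center <- function(mesh) {
  if (mesh_is_empty(mesh)) stop("geometric center of an empty mesh is undefined")
  ar <- face_areas(mesh)
  fc <- face_corners(mesh)
  centroids <- (fc$a + fc$b + fc$c) / 3
  tot <- sum(ar)
  if (tot <= 0) stop("mesh has zero surface area")
  as.numeric(colSums(centroids * ar) / tot)
}

#' Mesh bounding box
#' @param mesh a [triangle_mesh()].
#' @return 2 x 3 matrix (rows min, max) in mm.
#' @export
mesh_bbox <- function(mesh) {
  if (nrow(mesh$vertices) == 0) stop("empty mesh has no bounding box")
  rbind(min = apply(mesh$vertices, 2, min), max = apply(mesh$vertices, 2, max))
}

#' Watertightness check
#'
#' A mesh is reported watertight when every edge is shared by exactly two
#' faces with opposite orientation. Reported, not enforced: post-processing
#' "may lead to small, disconnected parts" which remain valid input for the
#' evaluation metrics.
#'
#' @param mesh a [triangle_mesh()].
#' @return logical.
#' @export
mesh_is_watertight <- function(mesh) {
  if (mesh_is_empty(mesh)) return(FALSE)
  f <- mesh$faces
  he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key_dir <- paste(he[, 1], he[, 2])
  key_und <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  if (anyDuplicated(key_dir)) return(FALSE)       # repeated directed edge
  cnt <- table(key_und)
  all(cnt == 2L)
}

#' Connected components of a mesh
#'
#' Counts face-connected components (faces sharing a vertex are connected);
#' post-processing can split a mask into small disconnected fragments,
#' which are all retained and reported.
#'
#' @param mesh a [triangle_mesh()].
#' @return integer component count (0 for an empty mesh).
#' @export
mesh_component_count <- function(mesh) {
  if (mesh_is_empty(mesh)) return(0L)
  nv <- nrow(mesh$vertices)
  parent <- seq_len(nv)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  f <- mesh$faces
  for (r in seq_len(nrow(f))) {
    a <- find(f[r, 1]); b <- find(f[r, 2]); c <- find(f[r, 3])
    parent[b] <- a
    parent[find(c)] <- a
  }
  used <- unique(as.integer(mesh$faces))
  length(unique(vapply(used, find, integer(1))))
}

#' Rigid/affine helpers
#'
#' Convenience transforms used by the phantom generator and tests;
#' `rotation_matrix()` builds the rotation by `angle` radians about `axis`.
#'
#' @param mesh a [triangle_mesh()].
#' @param shift length-3 translation, mm.
#' @return A transformed [triangle_mesh()] (or 3 x 3 matrix).
#' @export
translate_mesh <- function(mesh, shift) {
  triangle_mesh(sweep(mesh$vertices, 2, as.numeric(shift), "+"), mesh$faces)
}

#' @rdname translate_mesh
#' @param factor scalar scale factor.
#' @param center length-3 fixed point of the scaling, mm.
#' @export
scale_mesh <- function(mesh, factor, center = c(0, 0, 0)) {
  v <- sweep(mesh$vertices, 2, as.numeric(center))
  triangle_mesh(sweep(v * factor, 2, as.numeric(center), "+"), mesh$faces)
}

#' @rdname translate_mesh
#' @param R 3 x 3 rotation matrix.
#' @export
rotate_mesh <- function(mesh, R, center = c(0, 0, 0)) {
  v <- sweep(mesh$vertices, 2, as.numeric(center))
  triangle_mesh(sweep(v %*% t(R), 2, as.numeric(center), "+"), mesh$faces)
}

#' @rdname translate_mesh
#' @param axis 1, 2 or 3 (x, y, z).
#' @param angle radians.
#' @export
rotation_matrix <- function(axis, angle) {
  cth <- cos(angle); sth <- sin(angle)
  R <- diag(3)
  ax <- setdiff(1:3, axis)
  R[ax[1], ax[1]] <- cth; R[ax[2], ax[2]] <- cth
  R[ax[1], ax[2]] <- -sth; R[ax[2], ax[1]] <- sth
  R
}

#' Sample points on a mesh surface
#'
#' Draws `n_points` random points with expected density proportional to
#' triangle area (triangle chosen by area-weighted multinomial, position by
#' uniform barycentric coordinates). Deterministic for a given `seed`; the
#' caller's RNG state is left untouched.
#'
#' @param mesh a non-empty [triangle_mesh()].
#' @param n_points number of points, >= 1.
#' @param seed integer RNG seed.
#' @return list with `points` (n x 3, mm), `face` (triangle index of each
#'   point) and `weights` (equal area weights summing to the surface area).
#' @export
sample_surface <- function(mesh, n_points, seed = 1L) {
  if (mesh_is_empty(mesh)) stop("cannot sample an empty mesh")
  stopifnot(n_points >= 1)
  ar <- face_areas(mesh)
  tot <- sum(ar)
  if (tot <= 0) stop("mesh has zero surface area")
  with_seed(seed, {
    fi <- sample.int(length(ar), n_points, replace = TRUE, prob = ar)
    r1 <- sqrt(stats::runif(n_points))
    r2 <- stats::runif(n_points)
  })
  fc <- face_corners(mesh)
  a <- fc$a[fi, , drop = FALSE]; b <- fc$b[fi, , drop = FALSE]; c <- fc$c[fi, , drop = FALSE]
  pts <- (1 - r1) * a + r1 * (1 - r2) * b + r1 * r2 * c
  list(points = pts, face = fi, weights = rep(tot / n_points, n_points))
}

#' Clip a mesh by a plane
#'
#' Keeps the part of the surface on the positive side of the plane
#' (`dot(x - point, normal) > 0`); triangles crossing the plane are split at
#' the intersection, so kept + discarded area equals the original area.
#' Disconnected fragments on the positive side are all retained. Clipping
#' twice with the same plane is a no-op.
#'
#' @param mesh a [triangle_mesh()].
#' @param point length-3, a point on the plane (mm).
#' @param normal length-3 unit normal; the kept side.
#' @return A [triangle_mesh()] (possibly empty, with a warning).
#' @export
clip_by_plane <- function(mesh, point, normal) {
  point <- as.numeric(point); normal <- as.numeric(normal)
  nn <- sqrt(sum(normal^2))
  if (abs(nn - 1) > 1e-9) stop("plane normal must be unit length")
  if (mesh_is_empty(mesh)) return(mesh)
  sd <- as.numeric(sweep(mesh$vertices, 2, point) %*% normal)
  keep_v <- sd > 0
  f <- mesh$faces
  fs <- matrix(keep_v[f], ncol = 3)
  npos <- rowSums(fs)
  out_v <- list(mesh$vertices)
  nv <- nrow(mesh$vertices)
  out_f <- list(f[npos == 3L, , drop = FALSE])

  cross_idx <- which(npos == 1L | npos == 2L)
  if (length(cross_idx)) {
    newv <- list(); newf <- list()
    for (fi in cross_idx) {
      idx <- f[fi, ]
      s <- sd[idx]
      pos <- which(s > 0)
      if (length(pos) == 1L) {
        # one vertex kept: a smaller triangle
        a <- pos; o <- setdiff(1:3, a)
        # preserve orientation: rotate so `a` is first
        ord <- c(a, if (a == 1) c(2, 3) else if (a == 2) c(3, 1) else c(1, 2))
        ia <- idx[ord[1]]; ib <- idx[ord[2]]; ic <- idx[ord[3]]
        ta <- sd[ia] / (sd[ia] - sd[ib])
        tb <- sd[ia] / (sd[ia] - sd[ic])
        pab <- mesh$vertices[ia, ] + ta * (mesh$vertices[ib, ] - mesh$vertices[ia, ])
        pac <- mesh$vertices[ia, ] + tb * (mesh$vertices[ic, ] - mesh$vertices[ia, ])
        newv[[length(newv) + 1L]] <- rbind(pab, pac)
        newf[[length(newf) + 1L]] <- c(ia, nv + 1L, nv + 2L)
        nv <- nv + 2L
      } else {
        # two vertices kept: a quad, split into two triangles
        a <- setdiff(1:3, pos)  # the dropped vertex
        ord <- c(a, if (a == 1) c(2, 3) else if (a == 2) c(3, 1) else c(1, 2))
        ia <- idx[ord[1]]; ib <- idx[ord[2]]; ic <- idx[ord[3]]
        tb <- sd[ia] / (sd[ia] - sd[ib])
        tc <- sd[ia] / (sd[ia] - sd[ic])
        pab <- mesh$vertices[ia, ] + tb * (mesh$vertices[ib, ] - mesh$vertices[ia, ])
        pac <- mesh$vertices[ia, ] + tc * (mesh$vertices[ic, ] - mesh$vertices[ia, ])
        newv[[length(newv) + 1L]] <- rbind(pab, pac)
        newf[[length(newf) + 1L]] <- rbind(c(nv + 1L, ib, ic),
                                           c(nv + 1L, ic, nv + 2L))
        nv <- nv + 2L
      }
    }
    out_v <- c(out_v, newv)
    out_f <- c(out_f, lapply(newf, function(x) matrix(x, ncol = 3)))
  }
  V <- do.call(rbind, out_v)
  Fm <- do.call(rbind, out_f)
  if (is.null(Fm) || nrow(Fm) == 0L) {
    warning("plane clip produced an empty mesh")
    return(triangle_mesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3)))
  }
  # drop unreferenced vertices
  used <- sort(unique(as.integer(Fm)))
  remap <- integer(nrow(V)); remap[used] <- seq_along(used)
  triangle_mesh(V[used, , drop = FALSE], matrix(remap[Fm], ncol = 3))
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
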