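#' Volumetric Dice between two surface meshes
#'
#' Both meshes are voxelized by centre containment on one shared grid
#' covering their joint bounding box at the given pitch, and the Dice
#' similarity coefficient `2|A n B| / (|A| + |B|)` of the two occupancy
#' sets is returned. Using a single shared grid makes the measure exactly
#' symmetric.
#'
#' For region-of-interest comparisons pass `halfspace`: both meshes are
#' voxelized *whole* (the parity inside test needs closed surfaces) and
#' the overlap is restricted to voxel centres on the positive side of the
#' plane — the volumetric Dice of `solid n halfspace`.
#'
#' @param a,b orientable [triangle_mesh()]es (mm).
#' @param pitch voxel edge length of the comparison grid, mm.
#' @param halfspace optional list with `point` and unit `normal` (mm);
#'   restricts the comparison to the positive side.
#' @return Dice fraction in `[0, 1]` (`NA` if the restricted region is
#'   empty for both).
#' @export
mesh_dice <- function(a, b, pitch = 0.5, halfspace = NULL) {
  stopifnot(inherits(a, "cs_mesh"), inherits(b, "cs_mesh"), pitch > 0)
  if (mesh_is_empty(a) && mesh_is_empty(b)) {
    stop("Dice between two empty meshes is undefined")
  }
  if (mesh_is_empty(a) || mesh_is_empty(b)) return(0)
  bb <- rbind(pmin(mesh_bbox(a)[1, ], mesh_bbox(b)[1, ]),
              pmax(mesh_bbox(a)[2, ], mesh_bbox(b)[2, ]))
  lo <- bb[1, ] - pitch
  hi <- bb[2, ] + pitch
  shape <- pmax(2L, as.integer(ceiling((hi - lo) / pitch)))
  geom <- list(shape = shape, spacing = rep(pitch, 3), origin = lo + pitch / 2)
  ina <- .cs_grid_inside(a$vertices, a$faces, geom$shape, geom$spacing, geom$origin)
  inb <- .cs_grid_inside(b$vertices, b$faces, geom$shape, geom$spacing, geom$origin)
  if (!is.null(halfspace)) {
    keep <- halfspace_mask(geom, halfspace)
    ina <- ina & keep
    inb <- inb & keep
  }
  na <- sum(ina); nb <- sum(inb)
  if (na + nb == 0) {
    if (!is.null(halfspace)) return(NA_real_)
    stop("no interior voxels at this pitch; decrease `pitch`")
  }
  2 * sum(ina & inb) / (na + nb)
}

halfspace_mask <- function(geom, halfspace) {
  ax <- lapply(1:3, function(i) {
    geom$origin[i] + (seq_len(geom$shape[i]) - 1) * geom$spacing[i]
  })
  ctr <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  as.vector(sweep(ctr, 2, as.numeric(halfspace$point)) %*%
              as.numeric(halfspace$normal) > 0)
}

# directed surface distances: samples on `from`, exact distances to `to`
directed_distances <- function(from, to, n_points, seed) {
  s <- sample_surface(from, n_points, seed)
  list(points = s$points, d = point_mesh_distance(s$points, to))
}

#' Symmetric surface-distance metrics
#'
#' `n_points` random surface points are drawn on each mesh
#' (area-weighted, seeded) and measured by *exact* point-to-triangle
#' distance against the full opposing surface. The symmetric average
#' surface distance pools both directions:
#' `ASD = (sum_A d(p, B) + sum_B d(q, A)) / (|A| + |B|)`.
#' The symmetric 95% Hausdorff distance is, by default, the 95th
#' percentile of the *pooled* directed distances; `method = "max"` gives
#' the alternative reading `max` of the two one-sided 95th percentiles.
#'
#' @param a,b non-empty [triangle_mesh()]es.
#' @param n_points samples per surface.
#' @param seed RNG seed for the surface sampling.
#' @return distance in mm.
#' @export
asd_symmetric <- function(a, b, n_points = 1e5, seed = 1L) {
  check_pair(a, b)
  da <- directed_distances(a, b, n_points, seed)$d
  db <- directed_distances(b, a, n_points, seed + 1L)$d
  (sum(da) + sum(db)) / (length(da) + length(db))
}

#' @rdname asd_symmetric
#' @param percentile percentile of the distance distribution (0.95).
#' @param method `"pooled"` (default) or `"max"`.
#' @export
hd95_symmetric <- function(a, b, n_points = 1e5, seed = 1L,
                           percentile = 0.95, method = c("pooled", "max")) {
  check_pair(a, b)
  method <- match.arg(method)
  da <- directed_distances(a, b, n_points, seed)$d
  db <- directed_distances(b, a, n_points, seed + 1L)$d
  if (identical(method, "pooled")) {
    stats::quantile(c(da, db), percentile, names = FALSE, type = 7)
  } else {
    max(stats::quantile(da, percentile, names = FALSE, type = 7),
        stats::quantile(db, percentile, names = FALSE, type = 7))
  }
}

check_pair <- function(a, b) {
  stopifnot(inherits(a, "cs_mesh"), inherits(b, "cs_mesh"))
  if (mesh_is_empty(a) || mesh_is_empty(b)) {
    stop("surface distances require two non-empty meshes")
  }
}

#' Directed per-point distances for colour mapping
#'
#' Distances from prediction-surface samples to the ground-truth surface,
#' with their coordinates, e.g. for colour-scale display of the surface
#' deviation. `write_distance_ply()` exports them as an ASCII PLY with a
#' scalar `quality` attribute on the prediction mesh vertices.
#'
#' @param pred,truth non-empty [triangle_mesh()]es.
#' @param n_points number of samples on the prediction surface.
#' @param seed RNG seed.
#' @return list with `points` (n x 3 mm) and `distances` (mm).
#' @export
per_point_distances <- function(pred, truth, n_points = 1e5, seed = 1L) {
  check_pair(pred, truth)
  dd <- directed_distances(pred, truth, n_points, seed)
  list(points = dd$points, distances = dd$d)
}

#' @rdname per_point_distances
#' @param path output `.ply` path.
#' @export
write_distance_ply <- function(pred, truth, path) {
  check_pair(pred, truth)
  d <- point_mesh_distance(pred$vertices, truth)
  write_ply(pred, path, scalar = d, scalar_name = "quality")
  invisible(path)
}

#' Evaluate one case: whole bone and left/right transplant ROI
#'
#' Computes Dice, symmetric average surface distance and symmetric 95%
#' Hausdorff distance between a predicted and a ground-truth mesh, on the
#' whole surfaces and restricted to each transplant ROI. For every ROI the
#' absolute cutting plane is derived from the *ground-truth* mesh and the
#' same plane is applied to both meshes, so the comparison region is
#' identical by construction. An empty ROI clip flags that scope's metrics
#' as `NA`.
#'
#' @param pred_mesh,truth_mesh non-empty [triangle_mesh()]es.
#' @param roi_defs list of [roi_definition()]s (typically left + right).
#' @param pitch Dice comparison-grid pitch, mm.
#' @param n_points surface samples per mesh for the distance metrics.
#' @param seed RNG seed.
#' @return data.frame with one row per scope (`whole`, then one per ROI
#'   side) and columns `scope`, `dsc`, `asd_mm`, `hd95_mm`,
#'   `n_sample_points`.
#' @export
evaluate_case <- function(pred_mesh, truth_mesh, roi_defs = NULL,
                          pitch = 0.5, n_points = 1e5, seed = 1L) {
  check_pair(pred_mesh, truth_mesh)
  one <- function(p, t, scope) {
    if (mesh_is_empty(p) || mesh_is_empty(t)) {
      return(data.frame(scope = scope, dsc = NA_real_, asd_mm = NA_real_,
                        hd95_mm = NA_real_, n_sample_points = 0L))
    }
    data.frame(scope = scope,
               dsc = if (scope == "whole") mesh_dice(p, t, pitch) else NA_real_,
               asd_mm = asd_symmetric(p, t, n_points, seed),
               hd95_mm = hd95_symmetric(p, t, n_points, seed),
               n_sample_points = as.integer(n_points))
  }
  rows <- list(one(pred_mesh, truth_mesh, "whole"))
  for (roi in roi_defs) {
    plane <- roi_absolute_plane(truth_mesh, roi)
    pr <- suppressWarnings(clip_by_plane(pred_mesh, plane$point, plane$normal))
    tr <- suppressWarnings(clip_by_plane(truth_mesh, plane$point, plane$normal))
    row <- one(pr, tr, paste0(roi$side, "_roi"))
    if (!mesh_is_empty(pr) && !mesh_is_empty(tr)) {
      # Dice needs closed solids: voxelize whole meshes, restrict to the
      # ROI half-space (clipped surfaces are open along the cut)
      row$dsc <- mesh_dice(pred_mesh, truth_mesh, pitch, halfspace = plane)
    }
    rows[[length(rows) + 1L]] <- row
  }
  do.call(rbind, rows)
}

#' Brute-force point-to-mesh distance (reference implementation)
#'
#' Plain-R O(N x M) exact point-to-triangle distance with no spatial
#' acceleration, independent of the compiled query path; intended as a
#' testing oracle on small meshes.
#'
#' @param points n x 3 matrix, mm.
#' @param mesh a non-empty [triangle_mesh()].
#' @return numeric vector of distances, mm.
#' @export
point_mesh_distance_brute <- function(points, mesh) {
  stopifnot(inherits(mesh, "cs_mesh"), !mesh_is_empty(mesh))
  P <- matrix(as.numeric(points), ncol = 3)
  best <- rep(Inf, nrow(P))
  fc <- face_corners(mesh)
  for (f in seq_len(n_faces(mesh))) {
    d2 <- point_triangle_d2_vec(P, fc$a[f, ], fc$b[f, ], fc$c[f, ])
    best <- pmin(best, d2)
  }
  sqrt(best)
}

# vectorized Ericson closest-point-on-triangle squared distance
point_triangle_d2_vec <- function(P, a, b, c) {
  n <- nrow(P)
  ab <- b - a; ac <- c - a; bc <- c - b
  ap <- sweep(P, 2, a)
  d1 <- ap %*% ab; d2 <- ap %*% ac
  bp <- sweep(P, 2, b)
  d3 <- bp %*% ab; d4 <- bp %*% ac
  cp <- sweep(P, 2, c)
  d5 <- cp %*% ab; d6 <- cp %*% ac
  vc <- d1 * d4 - d3 * d2
  vb <- d5 * d2 - d1 * d6
  va <- d3 * d6 - d5 * d4
  Q <- matrix(NA_real_, n, 3)
  done <- rep(FALSE, n)
  set_q <- function(mask, qmat) {
    m <- mask & !done
    Q[m, ] <<- qmat[m, , drop = FALSE]
    done <<- done | m
  }
  set_q(d1 <= 0 & d2 <= 0, matrix(a, n, 3, byrow = TRUE))
  set_q(d3 >= 0 & d4 <= d3, matrix(b, n, 3, byrow = TRUE))
  t_ab <- as.numeric(d1 / (d1 - d3))
  set_q(vc <= 0 & d1 >= 0 & d3 <= 0,
        sweep(outer(t_ab, ab), 2, a, "+"))
  set_q(d6 >= 0 & d5 <= d6, matrix(c, n, 3, byrow = TRUE))
  t_ac <- as.numeric(d2 / (d2 - d6))
  set_q(vb <= 0 & d2 >= 0 & d6 <= 0,
        sweep(outer(t_ac, ac), 2, a, "+"))
  t_bc <- as.numeric((d4 - d3) / ((d4 - d3) + (d5 - d6)))
  set_q(va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0,
        sweep(outer(t_bc, bc), 2, b, "+"))
  denom <- as.numeric(1 / (va + vb + vc))
  v <- as.numeric(vb) * denom; w <- as.numeric(vc) * denom
  set_q(rep(TRUE, n), sweep(outer(v, ab) + outer(w, ac), 2, a, "+"))
  rowSums((P - Q)^2)
}
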