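#' Pelvis phantom specification
#'
#' The phantom generator stands in for a clinical CT corpus: each case is a
#' bilateral pair of thin-walled, curved crest-like shells ("iliac wings")
#' plus a central sacrum-like block, embedded in a soft-tissue background
#' with CT-like intensities and noise. Volume shapes, voxel spacings,
#' aspect ratios, and structure sizes vary per case (seeded), emulating the
#' variability of routine pelvic CT acquisitions. Geometry is
#' parametric-analytic: the bone is the zero level set of an implicit
#' field, the ground-truth mesh is extracted from that field, and voxel
#' intensities are assigned from the same field, so mask and mesh are
#' consistent by construction.
#'
#' Intensity defaults: tissue ~ N(40, 15) HU, cortical-like bone
#' ~ N(700, 100) HU, additive acquisition noise sigma = 20 HU. The bone and
#' tissue distributions are separated by >= 3 pooled standard deviations
#' (validated here), which keeps tiny desk-scale networks learnable.
#'
#' @param volume_shape base grid shape (voxels); per-case jitter
#'   `shape_jitter` is added/subtracted uniformly.
#' @param spacing base voxel spacing mm; jittered by `+/- spacing_jitter`
#'   (fractional).
#' @param bone_hu,tissue_hu `c(mean, sd)` in HU.
#' @param noise_sigma additive Gaussian noise, HU.
#' @param pose_max_deg maximal axial rotation of the whole bone structure.
#' @param asymmetry fractional left/right parameter jitter (0 gives an
#'   exactly mirror-symmetric phantom).
#' @param seed cohort-level base seed.
#' @return An object of class `cs_phantom_spec`.
#' @export
phantom_spec <- function(volume_shape = c(84L, 84L, 60L),
                         shape_jitter = c(8L, 8L, 6L),
                         spacing = c(1.3, 1.3, 1.8), spacing_jitter = 0.2,
                         bone_hu = c(700, 100), tissue_hu = c(40, 15),
                         noise_sigma = 20, pose_max_deg = 8,
                         asymmetry = 0.08, seed = 1L) {
  pooled <- sqrt((bone_hu[2]^2 + tissue_hu[2]^2) / 2)
  if ((bone_hu[1] - tissue_hu[1]) < 3 * pooled) {
    stop("bone and tissue intensity distributions must be separated by >= 3 pooled sd")
  }
  stopifnot(all(volume_shape >= 32L), all(spacing > 0), noise_sigma >= 0,
            asymmetry >= 0)
  structure(list(volume_shape = as.integer(volume_shape),
                 shape_jitter = as.integer(shape_jitter),
                 spacing = spacing, spacing_jitter = spacing_jitter,
                 bone_hu = bone_hu, tissue_hu = tissue_hu,
                 noise_sigma = noise_sigma, pose_max_deg = pose_max_deg,
                 asymmetry = asymmetry, seed = as.integer(seed)),
            class = "cs_phantom_spec")
}

case_rng_seed <- function(spec_seed, case_seed) {
  as.integer((as.numeric(spec_seed) * 7919 + as.numeric(case_seed) * 104729) %% 2147483629)
}

# implicit bone field on the phantom grid, in normalized FOV coordinates
phantom_field <- function(shape, spacing, params) {
  ax <- lapply(1:3, function(i) (seq_len(shape[i]) - 1) * spacing[i])
  ctr <- vapply(1:3, function(i) (shape[i] - 1) * spacing[i] / 2, numeric(1))
  half <- vapply(1:3, function(i) shape[i] * spacing[i] / 2, numeric(1))
  qx <- (ax[[1]] - ctr[1]) / half[1]
  qy <- (ax[[2]] - ctr[2]) / half[2]
  qz <- (ax[[3]] - ctr[3]) / half[3]
  Q <- as.matrix(expand.grid(x = qx, y = qy, z = qz))
  Rz <- rotation_matrix(3, params$pose_rad)
  Qp <- Q %*% Rz  # rotate the structure by rotating sample coords inversely
  field <- rep(-1, nrow(Q))
  for (side in c(-1, 1)) {
    w <- if (side < 0) params$left else params$right
    Ry <- rotation_matrix(2, side * w$tilt_rad)
    loc <- sweep(Qp, 2, c(side * w$cx, w$cy, w$cz)) %*% Ry
    u <- sweep(loc, 2, w$radii, "/")
    r <- sqrt(rowSums(u^2))
    f_shell <- w$thickness - abs(r - 1)
    f_cut <- u[, 3] + w$cut  # keep the upper (cranial) part of the shell
    field <- pmax(field, pmin(f_shell, f_cut))
  }
  s <- params$sacrum
  ds <- abs(sweep(Qp, 2, s$center))
  f_box <- pmin(s$half[1] - ds[, 1], s$half[2] - ds[, 2], s$half[3] - ds[, 3])
  field <- pmax(field, f_box / min(s$half))
  array(field, dim = shape)
}

draw_case_params <- function(spec) {
  # caller seeds the RNG
  jit <- function(x, f) x * stats::runif(length(x), 1 - f, 1 + f)
  base_wing <- list(cx = stats::runif(1, 0.26, 0.32),
                    cy = stats::runif(1, -0.06, 0.06),
                    cz = stats::runif(1, 0.0, 0.08),
                    radii = c(stats::runif(1, 0.19, 0.25),
                              stats::runif(1, 0.23, 0.29),
                              stats::runif(1, 0.26, 0.33)),
                    thickness = stats::runif(1, 0.17, 0.23),
                    cut = stats::runif(1, 0.10, 0.20),
                    tilt_rad = stats::runif(1, 0.15, 0.35))
  a <- spec$asymmetry
  per_side <- function() {
    w <- base_wing
    w$radii <- jit(w$radii, a)
    w$thickness <- jit(w$thickness, a)
    w$cx <- jit(w$cx, a)
    w$tilt_rad <- jit(w$tilt_rad, a)
    w
  }
  list(left = per_side(), right = per_side(),
       sacrum = list(center = c(0, stats::runif(1, -0.16, -0.07),
                                stats::runif(1, -0.13, -0.03)),
                     half = c(stats::runif(1, 0.09, 0.13),
                              stats::runif(1, 0.11, 0.14),
                              stats::runif(1, 0.16, 0.21))),
       pose_rad = if (spec$pose_max_deg > 0) {
         stats::runif(1, -1, 1) * spec$pose_max_deg * pi / 180
       } else 0)
}

#' Generate one phantom case
#'
#' Deterministic per `(spec$seed, case_seed)`: draws per-case grid shape,
#' spacing and structure parameters, extracts the ground-truth mesh from
#' the implicit bone field, and fills the volume with tissue/bone
#' intensities plus noise. If a parameter draw produces a bone volume
#' fraction outside `[0.5%, 15%]` of the volume the draw is retried with
#' the next sub-seed (bounded).
#'
#' @param spec a [phantom_spec()].
#' @param case_seed integer case identifier/seed.
#' @return list with `volume` ([image_volume()], HU), `mesh`
#'   (ground-truth [triangle_mesh()], mm), `bone_voxels` (logical array
#'   used to build the intensities) and `case_seed`.
#' @export
generate_phantom <- function(spec, case_seed = 1L) {
  stopifnot(inherits(spec, "cs_phantom_spec"))
  for (attempt in 0:9) {
    rs <- case_rng_seed(spec$seed, case_seed + 1000000L * attempt)
    out <- with_seed(rs, {
      shape <- spec$volume_shape +
        vapply(spec$shape_jitter, function(j) {
          if (j > 0) sample(seq(-j, j), 1) else 0L
        }, numeric(1))
      shape <- as.integer(pmax(shape, 32L))
      spacing <- spec$spacing * stats::runif(3, 1 - spec$spacing_jitter,
                                             1 + spec$spacing_jitter)
      params <- draw_case_params(spec)
      field <- phantom_field(shape, spacing, params)
      bone <- field > 0
      frac <- mean(bone)
      if (frac < 0.005 || frac > 0.15) {
        NULL
      } else {
        mesh <- marching_cubes(field, iso = 0, spacing = spacing,
                               origin = c(0, 0, 0))
        n <- length(field)
        hu <- stats::rnorm(n, spec$tissue_hu[1], spec$tissue_hu[2])
        nb <- sum(bone)
        hu[bone] <- stats::rnorm(nb, spec$bone_hu[1], spec$bone_hu[2])
        hu <- hu + stats::rnorm(n, 0, spec$noise_sigma)
        list(volume = image_volume(array(hu, dim = shape), spacing),
             mesh = mesh, bone_voxels = bone, case_seed = case_seed)
      }
    })
    if (!is.null(out)) return(out)
  }
  stop("could not draw a valid phantom for case_seed ", case_seed)
}

#' Generate a phantom cohort
#'
#' `n` cases with distinct case seeds plus a manifest; with `dir` set, the
#' volumes (NIfTI), ground-truth meshes (binary STL) and `manifest.csv`
#' are written to disk. A cohort regenerated from the manifest's seeds is
#' identical.
#'
#' @param spec a [phantom_spec()].
#' @param n number of cases.
#' @param seed offset added to the case index to form case seeds.
#' @param dir optional output directory.
#' @return list with `cases` (list of [generate_phantom()] results; `NULL`
#'   elements when `dir` is used) and `manifest` (data.frame).
#' @export
generate_cohort <- function(spec, n, seed = 0L, dir = NULL) {
  stopifnot(n >= 1)
  keep <- is.null(dir)
  if (!keep) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cases <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cs <- as.integer(seed) + i
    ph <- generate_phantom(spec, cs)
    id <- sprintf("case_%04d", i)
    rows[[i]] <- data.frame(case_id = id, case_seed = cs,
                            nx = dim(ph$volume$data)[1], ny = dim(ph$volume$data)[2],
                            nz = dim(ph$volume$data)[3],
                            sx = ph$volume$spacing[1], sy = ph$volume$spacing[2],
                            sz = ph$volume$spacing[3])
    if (keep) {
      cases[[i]] <- ph
    } else {
      write_volume(ph$volume, file.path(dir, paste0(id, ".nii.gz")))
      write_mesh(ph$mesh, file.path(dir, paste0(id, ".stl")))
    }
  }
  manifest <- do.call(rbind, rows)
  if (!keep) utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                              row.names = FALSE)
  list(cases = cases, manifest = manifest)
}

#' Corrupt a phantom case
#'
#' Emulates the acquisition problems that motivated dataset exclusion in
#' clinical practice: `"implant"` inserts a metal-bright cylinder next to
#' the bone, `"tilt"` rigidly rotates volume and mesh about the x axis,
#' `"crop"` truncates the caudal (low-z) slices. Intended for robustness
#' testing, never for default training cohorts.
#'
#' @param case a [generate_phantom()] result.
#' @param mode `"implant"`, `"tilt"` or `"crop"`.
#' @param angle_deg tilt angle (mode `"tilt"`).
#' @param crop_fraction fraction of caudal slices removed (mode `"crop"`).
#' @return A modified case (same structure).
#' @export
corrupt_case <- function(case, mode = c("implant", "tilt", "crop"),
                         angle_deg = 15, crop_fraction = 0.25) {
  mode <- match.arg(mode)
  v <- case$volume
  if (identical(mode, "implant")) {
    d <- vol_shape(v)
    cx <- v$origin[1] + (d[1] - 1) * v$spacing[1] * 0.80
    cy <- v$origin[2] + (d[2] - 1) * v$spacing[2] * 0.50
    xs <- v$origin[1] + (seq_len(d[1]) - 1) * v$spacing[1]
    ys <- v$origin[2] + (seq_len(d[2]) - 1) * v$spacing[2]
    r2 <- outer((xs - cx)^2, (ys - cy)^2, "+")
    hit <- r2 <= (4 * max(v$spacing[1:2]))^2
    dat <- v$data
    for (k in seq_len(d[3])) dat[, , k][hit] <- 3000
    case$volume <- image_volume(dat, v$spacing, v$origin)
  } else if (identical(mode, "tilt")) {
    ctr <- v$origin + (vol_shape(v) - 1) * v$spacing / 2
    R <- rotation_matrix(1, angle_deg * pi / 180)
    d <- vol_shape(v)
    g <- as.matrix(expand.grid(x = v$origin[1] + (seq_len(d[1]) - 1) * v$spacing[1],
                               y = v$origin[2] + (seq_len(d[2]) - 1) * v$spacing[2],
                               z = v$origin[3] + (seq_len(d[3]) - 1) * v$spacing[3]))
    src <- sweep(sweep(g, 2, ctr) %*% R, 2, ctr, "+")  # inverse-rotated samples
    idx <- sweep(sweep(src, 2, v$origin), 2, v$spacing, "/")
    dat <- array(0, dim = d)
    dat[] <- trilinear_lookup(v$data, idx)
    case$volume <- image_volume(dat, v$spacing, v$origin)
    case$mesh <- rotate_mesh(case$mesh, R, ctr)
    case$bone_voxels <- NULL  # no longer grid-aligned
  } else {
    d <- vol_shape(v)
    keep <- max(2L, ceiling(d[3] * (1 - crop_fraction)))
    box <- rbind(c(1L, 1L, d[3] - keep + 1L), d)
    case$volume <- crop_to_box(v, box)
    if (!is.null(case$bone_voxels)) {
      case$bone_voxels <- case$bone_voxels[, , (d[3] - keep + 1L):d[3], drop = FALSE]
    }
  }
  case
}

# clamp-at-edge trilinear lookup at scattered fractional 0-based indices
trilinear_lookup <- function(arr, idx) {
  d <- dim(arr)
  u <- pmin(pmax(idx[, 1], 0), d[1] - 1)
  v <- pmin(pmax(idx[, 2], 0), d[2] - 1)
  w <- pmin(pmax(idx[, 3], 0), d[3] - 1)
  i0 <- pmin(floor(u), max(d[1] - 2, 0)); fx <- u - i0
  j0 <- pmin(floor(v), max(d[2] - 2, 0)); fy <- v - j0
  k0 <- pmin(floor(w), max(d[3] - 2, 0)); fz <- w - k0
  i1 <- pmin(i0 + 1, d[1] - 1); j1 <- pmin(j0 + 1, d[2] - 1); k1 <- pmin(k0 + 1, d[3] - 1)
  g <- function(i, j, k) arr[cbind(i + 1, j + 1, k + 1)]
  c00 <- g(i0, j0, k0) * (1 - fx) + g(i1, j0, k0) * fx
  c10 <- g(i0, j1, k0) * (1 - fx) + g(i1, j1, k0) * fx
  c01 <- g(i0, j0, k1) * (1 - fx) + g(i1, j0, k1) * fx
  c11 <- g(i0, j1, k1) * (1 - fx) + g(i1, j1, k1) * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  c0 * (1 - fz) + c1 * fz
}
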