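# shared fixtures, built in code at test time

# unit-spacing voxelized ball of radius r in an n^3 grid (logical array)
voxel_ball <- function(n, r) {
  ax <- seq_len(n) - (n + 1) / 2
  array(outer(outer(ax^2, ax^2, "+"), ax^2, "+") <= r^2, dim = c(n, n, n))
}

# two parallel square sheets (z = 0 and z = gap), each side mm wide,
# triangulated as grids so sampling is well-conditioned
sheet_mesh <- function(side = 100, z = 0, cells = 8) {
  s <- seq(0, side, length.out = cells + 1)
  g <- as.matrix(expand.grid(x = s, y = s))
  verts <- cbind(g, z)
  idx <- function(i, j) (j - 1) * (cells + 1) + i
  faces <- do.call(rbind, lapply(seq_len(cells), function(i) {
    do.call(rbind, lapply(seq_len(cells), function(j) {
      rbind(c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
            c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
    }))
  }))
  triangle_mesh(verts, faces)
}

# small phantom spec for fast tests
tiny_phantom_spec <- function(seed = 1L, ...) {
  phantom_spec(volume_shape = c(64L, 64L, 48L), shape_jitter = c(4L, 4L, 3L),
               seed = seed, ...)
}
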