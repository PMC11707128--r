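#' Read and write triangle meshes (STL / PLY)
#'
#' Formats are selected by file extension: `.stl` (binary by default,
#' ASCII detected automatically on read) and `.ply` (ASCII). Meshes are
#' always in mm. STL stores a bare triangle soup, so `read_mesh()` welds
#' exactly coincident vertices back into an indexed mesh; round-trips are
#' lossless within float32 (the STL on-disk precision).
#'
#' @param path file path ending in `.stl` or `.ply`.
#' @return `read_mesh()`: a [triangle_mesh()].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = read_stl(path),
         ply = read_ply(path),
         stop("unsupported mesh format: .", ext, " (use .stl or .ply)"))
}

#' @rdname read_mesh
#' @param mesh a non-empty [triangle_mesh()].
#' @param ascii write ASCII STL instead of binary.
#' @export
write_mesh <- function(mesh, path, ascii = FALSE) {
  stopifnot(inherits(mesh, "cs_mesh"))
  if (mesh_is_empty(mesh)) stop("refusing to write an empty mesh")
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = if (ascii) write_stl_ascii(mesh, path) else write_stl_binary(mesh, path),
         ply = write_ply(mesh, path),
         stop("unsupported mesh format: .", ext, " (use .stl or .ply)"))
  invisible(path)
}

weld_vertices <- function(tri_coords, faces_per_row = 3L) {
  # tri_coords: (3 * n_tri) x 3, consecutive rows are one triangle
  key <- paste(tri_coords[, 1], tri_coords[, 2], tri_coords[, 3], sep = "|")
  uid <- match(key, key)
  verts <- tri_coords[!duplicated(key), , drop = FALSE]
  idx <- match(key[uid], key[!duplicated(key)])
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  ok <- faces[, 1] != faces[, 2] & faces[, 2] != faces[, 3] & faces[, 1] != faces[, 3]
  triangle_mesh(verts, faces[ok, , drop = FALSE])
}

read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", 80)
  if (length(head) < 80) stop("malformed STL: truncated header")
  lead <- rawToChar(head[1:5])
  size <- file.size(path)
  ntri_guess <- readBin(con, "integer", 1, size = 4, endian = "little")
  is_binary <- identical(size, 84 + 50 * as.numeric(ntri_guess))
  if (!is_binary && identical(tolower(lead), "solid")) {
    close(con); on.exit(NULL)
    return(read_stl_ascii(path))
  }
  if (!is_binary) stop("malformed STL file: ", path)
  n <- ntri_guess
  if (n < 1) stop("malformed STL: no triangles")
  rec <- readBin(con, "raw", 50 * n)
  m <- matrix(rec, nrow = 50)
  coords <- matrix(0, 3 * n, 3)
  for (tr in 0:2) {  # skip 12 bytes of normal, then 3 vertices of 12 bytes
    block <- m[(13 + 12 * tr):(24 + 12 * tr), , drop = FALSE]
    vals <- readBin(as.raw(block), "numeric", size = 4, n = 3 * n, endian = "little")
    coords[seq(tr + 1, 3 * n, by = 3), ] <- matrix(vals, ncol = 3, byrow = TRUE)
  }
  weld_vertices(coords)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0 || length(vl) %% 3 != 0) stop("malformed ASCII STL: ", path)
  nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x) as.numeric(x[2:4])))
  if (anyNA(nums)) stop("malformed ASCII STL: non-numeric vertex")
  weld_vertices(nums)
}

write_stl_binary <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(sprintf("%-80s", "crestseg binary STL")), con)
  fc <- face_corners(mesh)
  n <- n_faces(mesh)
  writeBin(as.integer(n), con, size = 4, endian = "little")
  nrm <- row_cross(fc$b - fc$a, fc$c - fc$a)
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  dat <- cbind(nrm, fc$a, fc$b, fc$c)  # n x 12 floats
  payload <- writeBin(as.numeric(t(dat)), raw(), size = 4, endian = "little")
  payload <- matrix(payload, nrow = 48)
  rec <- rbind(payload, matrix(as.raw(0), 2, n))  # attribute byte count = 0
  writeBin(as.raw(rec), con)
}

write_stl_ascii <- function(mesh, path) {
  fc <- face_corners(mesh)
  nrm <- row_cross(fc$b - fc$a, fc$c - fc$a)
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  n <- n_faces(mesh)
  out <- character(7 * n + 2)
  out[1] <- "solid crestseg"
  fmt <- function(m) sprintf("%.9g %.9g %.9g", m[, 1], m[, 2], m[, 3])
  base <- 1 + 7 * (seq_len(n) - 1)
  out[base + 1] <- paste("facet normal", fmt(nrm))
  out[base + 2] <- "  outer loop"
  out[base + 3] <- paste("    vertex", fmt(fc$a))
  out[base + 4] <- paste("    vertex", fmt(fc$b))
  out[base + 5] <- paste("    vertex", fmt(fc$c))
  out[base + 6] <- "  endloop"
  out[base + 7] <- "endfacet"
  out[7 * n + 2] <- "endsolid crestseg"
  writeLines(out, path)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3 || trimws(lines[1]) != "ply") stop("malformed PLY: ", path)
  hdr_end <- match("end_header", trimws(lines))
  if (is.na(hdr_end)) stop("malformed PLY: no end_header")
  hdr <- trimws(lines[1:hdr_end])
  if (!any(grepl("^format ascii", hdr))) stop("only ASCII PLY is supported")
  el <- grep("^element ", hdr)
  nv <- nf <- 0L
  for (i in el) {
    parts <- strsplit(hdr[i], "\\s+")[[1]]
    if (parts[2] == "vertex") nv <- as.integer(parts[3])
    if (parts[2] == "face") nf <- as.integer(parts[3])
  }
  if (nv < 1) stop("malformed PLY: no vertices")
  body <- lines[(hdr_end + 1):length(lines)]
  vrows <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  verts <- do.call(rbind, lapply(vrows, function(x) as.numeric(x[1:3])))
  frows <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  faces <- do.call(rbind, lapply(frows, function(x) {
    k <- as.integer(x[1])
    if (k != 3L) stop("only triangle faces are supported in PLY input")
    as.integer(x[2:4]) + 1L
  }))
  if (is.null(faces)) faces <- matrix(integer(0), 0, 3)
  triangle_mesh(verts, faces)
}

write_ply <- function(mesh, path, scalar = NULL, scalar_name = "quality") {
  n <- nrow(mesh$vertices)
  hdr <- c("ply", "format ascii 1.0", "comment crestseg",
           sprintf("element vertex %d", n),
           "property float x", "property float y", "property float z")
  vmat <- mesh$vertices
  if (!is.null(scalar)) {
    stopifnot(length(scalar) == n)
    hdr <- c(hdr, sprintf("property float %s", scalar_name))
    vmat <- cbind(vmat, scalar)
  }
  hdr <- c(hdr, sprintf("element face %d", n_faces(mesh)),
           "property list uchar int vertex_indices", "end_header")
  vtxt <- apply(vmat, 1, function(r) paste(sprintf("%.9g", r), collapse = " "))
  ftxt <- apply(mesh$faces - 1L, 1, function(r) paste(c(3L, r), collapse = " "))
  writeLines(c(hdr, vtxt, ftxt), path)
}

#' Mesh primitives
#'
#' `mesh_box()` builds an axis-aligned box (12 triangles, outward
#' orientation); `mesh_icosphere()` builds a geodesic sphere by repeated
#' subdivision of an icosahedron. Both are used heavily by the test-suite
#' oracles and the worked examples.
#'
#' @param lo,hi opposite box corners, mm.
#' @return A [triangle_mesh()].
#' @export
mesh_box <- function(lo = c(0, 0, 0), hi = c(1, 1, 1)) {
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  stopifnot(all(hi > lo))
  g <- as.matrix(expand.grid(c(lo[1], hi[1]), c(lo[2], hi[2]), c(lo[3], hi[3])))
  # vertex order: x fastest (1: lll, 2: hll, 3: lhl, 4: hhl, 5: llh, ...)
  quads <- rbind(
    c(1, 3, 4, 2),  # z = lo, outward -z
    c(5, 6, 8, 7),  # z = hi
    c(1, 2, 6, 5),  # y = lo
    c(3, 7, 8, 4),  # y = hi
    c(1, 5, 7, 3),  # x = lo
    c(2, 4, 8, 6))  # x = hi
  faces <- do.call(rbind, lapply(seq_len(nrow(quads)), function(i) {
    q <- quads[i, ]
    rbind(q[c(1, 2, 3)], q[c(1, 3, 4)])
  }))
  triangle_mesh(g, faces)
}

#' @rdname mesh_box
#' @param radius sphere radius, mm.
#' @param center sphere centre, mm.
#' @param subdivisions number of 4-to-1 triangle subdivisions (0 gives the
#'   raw icosahedron, each step quadruples the face count).
#' @export
mesh_icosphere <- function(radius = 1, center = c(0, 0, 0), subdivisions = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    edge_id <- new.env(hash = TRUE)
    vlist <- v
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- edge_id[[key]]
      if (!is.null(hit)) return(hit)
      vlist <<- rbind(vlist, (vlist[i, ] + vlist[j, ]) / 2)
      edge_id[[key]] <- nrow(vlist)
      nrow(vlist)
    }
    nf <- matrix(0L, 0, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- vlist; f <- nf
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  triangle_mesh(sweep(v, 2, as.numeric(center), "+"), f)
}
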