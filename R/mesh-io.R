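# Readers and writers for the three standard surface-model exchange formats
# (STL, PLY, OBJ).  Meshes are cleaned on load (facet-soup vertex merge) and
# written with outward-oriented faces.  Units are millimetres by contract.

#' Load a surface mesh from file
#'
#' Supports STL (binary and ASCII), PLY (ASCII and binary little-endian) and
#' Wavefront OBJ.  The mesh is cleaned on load: duplicate vertices within
#' 1e-6 mm are merged and degenerate faces dropped; the closedness flag is
#' computed.
#'
#' @param path Path to the mesh file.
#' @param format One of `"stl"`, `"ply"`, `"obj"`; inferred from the file
#'   extension when missing.
#' @return A `surface_mesh`.
#' @export
load_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  raw <- switch(format,
    stl = read_stl(path),
    ply = read_ply(path),
    obj = read_obj(path),
    stop("unsupported mesh format: ", format))
  if (is.null(raw$vertices) || nrow(raw$vertices) == 0)
    stop("empty mesh in ", path)
  surface_mesh(raw$vertices, raw$faces)
}

#' Write a surface mesh to file
#'
#' @param mesh A `surface_mesh`.
#' @param path Output path.
#' @param format One of `"stl"`, `"ply"`, `"obj"`; inferred from the
#'   extension when missing.
#' @param binary Write the binary variant where the format has one
#'   (binary STL, binary little-endian PLY).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL, binary = FALSE) {
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  switch(format,
    stl = write_stl(mesh, path, binary),
    ply = write_ply(mesh, path, binary),
    obj = write_obj(mesh, path),
    stop("unsupported mesh format: ", format))
  invisible(path)
}

# --------------------------------------------------------------------------
# STL
# --------------------------------------------------------------------------

read_stl <- function(path) {
  n <- file.size(path)
  is_binary <- FALSE
  if (n >= 84) {
    con <- file(path, "rb")
    header <- readBin(con, "raw", 80)
    count <- readBin(con, "integer", 1, size = 4, endian = "little")
    close(con)
    if (!is.na(count) && n == 84 + 50 * as.numeric(count)) is_binary <- TRUE
  }
  if (is_binary) read_stl_binary(path) else read_stl_ascii(path)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  count <- readBin(con, "integer", 1, size = 4, endian = "little")
  rec <- readBin(con, "raw", 50 * count)
  # each record: 12 float32 (normal + 3 vertices) + uint16 attribute
  idx <- rep(seq_len(count) - 1, each = 48) * 50 +
    rep(seq_len(48), times = count)
  floats <- readBin(rec[idx], "numeric", n = 12 * count, size = 4,
                    endian = "little")
  m <- matrix(floats, ncol = 12, byrow = TRUE)
  verts <- rbind_interleave(m[, 4:6, drop = FALSE], m[, 7:9, drop = FALSE],
                            m[, 10:12, drop = FALSE])
  faces <- matrix(seq_len(3 * count), ncol = 3, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

rbind_interleave <- function(a, b, c_) {
  n <- nrow(a)
  out <- matrix(0, 3 * n, 3)
  out[seq(1, 3 * n, 3), ] <- a
  out[seq(2, 3 * n, 3), ] <- b
  out[seq(3, 3 * n, 3), ] <- c_
  out
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0 || length(vl) %% 3 != 0)
    stop("malformed ASCII STL: ", path)
  nums <- lapply(strsplit(trimws(vl), "\\s+"),
                 function(x) as.numeric(x[2:4]))
  verts <- do.call(rbind, nums)
  faces <- matrix(seq_len(nrow(verts)), ncol = 3, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

write_stl <- function(mesh, path, binary = FALSE) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a
  nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  len <- pmax(sqrt(nx^2 + ny^2 + nz^2), 1e-30)
  nrm <- cbind(nx, ny, nz) / len
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0, 80)), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    block <- t(cbind(nrm, a, b, c_))
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(block[, i]), con, size = 4, endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  } else {
    fmt <- function(p) sprintf("%.9g %.9g %.9g", p[, 1], p[, 2], p[, 3])
    txt <- c("solid femcoord",
             paste0("  facet normal ", fmt(nrm), "\n",
                    "    outer loop\n",
                    "      vertex ", fmt(a), "\n",
                    "      vertex ", fmt(b), "\n",
                    "      vertex ", fmt(c_), "\n",
                    "    endloop\n",
                    "  endfacet"),
             "endsolid femcoord")
    writeLines(txt, path)
  }
  invisible(path)
}

# --------------------------------------------------------------------------
# PLY
# --------------------------------------------------------------------------

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readLines(con, 1)
    if (length(line) == 0) stop("unterminated PLY header")
    header <- c(header, line)
    if (trimws(line) == "end_header") break
  }
  fmt_line <- grep("^format", header, value = TRUE)[1]
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1]][2]
  nv <- as.integer(sub(".*element vertex\\s+", "",
                       grep("element vertex", header, value = TRUE)[1]))
  nf <- as.integer(sub(".*element face\\s+", "",
                       grep("element face", header, value = TRUE)[1]))
  # vertex property layout (only leading x, y, z are used)
  vstart <- grep("element vertex", header)
  vend <- grep("element face", header)
  vprops <- grep("^property", header[vstart:vend], value = TRUE)
  vtypes <- vapply(strsplit(trimws(vprops), "\\s+"), `[`, "", 2)
  if (fmt == "ascii") {
    vlines <- readLines(con, nv)
    verts <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"),
                                   function(x) as.numeric(x[1:3])))
    flines <- readLines(con, nf)
    faces <- do.call(rbind, lapply(strsplit(trimws(flines), "\\s+"),
                                   function(x) {
      k <- as.integer(x[1])
      if (k != 3) stop("only triangular PLY faces are supported")
      as.integer(x[2:4]) + 1L
    }))
  } else if (fmt == "binary_little_endian") {
    sz <- function(tp) switch(tp, float = 4L, float32 = 4L, double = 8L,
                              float64 = 8L, stop("vertex type ", tp))
    sizes <- vapply(vtypes, sz, 1L)
    verts <- matrix(0, nv, 3)
    for (i in seq_len(nv)) {
      row <- numeric(length(sizes))
      for (j in seq_along(sizes))
        row[j] <- readBin(con, "numeric", 1, size = sizes[j],
                          endian = "little")
      verts[i, ] <- row[1:3]
    }
    faces <- matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      k <- readBin(con, "integer", 1, size = 1, signed = FALSE)
      if (k != 3) stop("only triangular PLY faces are supported")
      faces[i, ] <- readBin(con, "integer", 3, size = 4,
                            endian = "little") + 1L
    }
  } else stop("unsupported PLY format: ", fmt)
  list(vertices = verts, faces = faces)
}

write_ply <- function(mesh, path, binary = FALSE) {
  v <- mesh$vertices
  f <- mesh$faces
  header <- c("ply",
              if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
              "comment femcoord surface model [mm]",
              paste("element vertex", nrow(v)),
              "property double x", "property double y", "property double z",
              paste("element face", nrow(f)),
              "property list uchar int vertex_indices",
              "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con)
    writeBin(as.numeric(t(v)), con, size = 8, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.raw(3), con)
      writeBin(as.integer(f[i, ] - 1L), con, size = 4, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    writeLines(sprintf("%.12g %.12g %.12g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L),
               con)
  }
  invisible(path)
}

# --------------------------------------------------------------------------
# OBJ
# --------------------------------------------------------------------------

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                 function(x) as.numeric(x[2:4])))
  faces <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(x) {
    ids <- vapply(strsplit(x[-1], "/"), `[`, "", 1)
    if (length(ids) != 3) stop("only triangular OBJ faces are supported")
    as.integer(ids)
  }))
  list(vertices = verts, faces = faces)
}

write_obj <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# femcoord surface model [mm]", con)
  writeLines(sprintf("v %.12g %.12g %.12g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  invisible(path)
}
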