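# ASCII STL and PLY mesh I/O (minimal, sufficient for phantom meshes).

#' Write a mesh to ASCII STL
#' @param mesh a \code{surface_mesh}.
#' @param path output file path (.stl).
#' @param name solid name embedded in the file.
#' @export
write_stl <- function(mesh, path, name = "segment") {
  stopifnot(inherits(mesh, "surface_mesh"))
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("solid", name), con)
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; d <- v[f[i, 3], ]
    e1 <- b - a; e2 <- d - a
    nrm <- c(e1[2] * e2[3] - e1[3] * e2[2],
             e1[3] * e2[1] - e1[1] * e2[3],
             e1[1] * e2[2] - e1[2] * e2[1])
    nn <- sqrt(sum(nrm^2)); if (nn > 0) nrm <- nrm / nn
    writeLines(c(
      sprintf("  facet normal %.9g %.9g %.9g", nrm[1], nrm[2], nrm[3]),
      "    outer loop",
      sprintf("      vertex %.9g %.9g %.9g", a[1], a[2], a[3]),
      sprintf("      vertex %.9g %.9g %.9g", b[1], b[2], b[3]),
      sprintf("      vertex %.9g %.9g %.9g", d[1], d[2], d[3]),
      "    endloop",
      "  endfacet"), con)
  }
  writeLines(paste("endsolid", name), con)
  invisible(path)
}

#' Read an ASCII STL mesh
#'
#' Vertices repeated across facets are merged exactly (by coordinate
#' string), so a mesh written by \code{\link{write_stl}} round-trips.
#'
#' @param path an ASCII STL file.
#' @return A \code{surface_mesh}.
#' @export
read_stl <- function(path) {
  lines <- readLines(path)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0 || length(vl) %% 3 != 0)
    stop("read_stl: not a valid ASCII STL file: ", path)
  xyz <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
    as.numeric(p[2:4])))
  key <- apply(xyz, 1, paste, collapse = ",")
  uk <- !duplicated(key)
  verts <- xyz[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  surface_mesh(verts, faces)
}

#' Write a mesh to ASCII PLY
#' @param mesh a \code{surface_mesh}.
#' @param path output file path (.ply).
#' @export
write_ply <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(v)),
               "property float x", "property float y", "property float z",
               paste("element face", nrow(f)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(path)
}

#' Read an ASCII PLY mesh
#' @param path an ASCII PLY file with vertex and face elements.
#' @return A \code{surface_mesh}.
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3 || trimws(lines[1]) != "ply" ||
      !grepl("ascii", lines[2]))
    stop("read_ply: not an ASCII PLY file: ", path)
  hend <- match("end_header", trimws(lines))
  if (is.na(hend)) stop("read_ply: missing end_header")
  head <- lines[seq_len(hend)]
  nv <- as.integer(sub("element vertex\\s+", "",
                       grep("^element vertex", head, value = TRUE)[1]))
  nf <- as.integer(sub("element face\\s+", "",
                       grep("^element face", head, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) stop("read_ply: missing element counts")
  body <- lines[(hend + 1):length(lines)]
  vparts <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  verts <- do.call(rbind, lapply(vparts, function(p) as.numeric(p[1:3])))
  fparts <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  faces <- do.call(rbind, lapply(fparts, function(p) {
    if (as.integer(p[1]) != 3L) stop("read_ply: only triangle faces supported")
    as.integer(p[2:4]) + 1L
  }))
  surface_mesh(verts, faces)
}

#' Read a mesh file (STL or PLY, by extension)
#' @param path file path ending in .stl or .ply.
#' @return A \code{surface_mesh}.
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = read_stl(path),
         ply = read_ply(path),
         stop("read_mesh: unsupported extension '", ext, "'"))
}

#' Write a mesh file (STL or PLY, by extension)
#' @param mesh a \code{surface_mesh}.
#' @param path file path ending in .stl or .ply.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = write_stl(mesh, path),
         ply = write_ply(mesh, path),
         stop("write_mesh: unsupported extension '", ext, "'"))
}
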