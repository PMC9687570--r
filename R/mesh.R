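#' Triangle mesh
#'
#' A minimal triangle-mesh container: an `m x 3` numeric matrix of vertex
#' coordinates in millimetres and an `nf x 3` integer matrix of 1-based
#' vertex indices, one row per triangular face. All meshes synthesized from
#' one morphable model share the same face list and vertex semantics.
#'
#' @param vertices numeric matrix (or coercible) with 3 columns, millimetres.
#' @param faces integer matrix with 3 columns of 1-based vertex indices.
#' @return an object of class `triangle_mesh`.
#' @examples
#' m <- triangle_mesh(rbind(c(0,0,0), c(1,0,0), c(0,1,0)), rbind(c(1,2,3)))
#' n_vertices(m)
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  if (ncol(vertices) != 3L)
    stop("'vertices' must have 3 columns (x, y, z)", call. = FALSE)
  if (!all(is.finite(vertices)))
    stop("mesh vertices contain non-finite coordinates", call. = FALSE)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(faces) != 3L)
    stop("'faces' must have 3 columns of vertex indices", call. = FALSE)
  m <- nrow(vertices)
  if (nrow(faces) > 0L) {
    if (min(faces) < 1L || max(faces) > m)
      stop("face indices out of range [1, ", m, "]", call. = FALSE)
    degen <- faces[, 1L] == faces[, 2L] | faces[, 1L] == faces[, 3L] |
      faces[, 2L] == faces[, 3L]
    if (any(degen))
      stop("degenerate faces (repeated vertex index): rows ",
           paste(utils::head(which(degen), 5L), collapse = ", "),
           call. = FALSE)
  }
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat("triangle_mesh:", nrow(x$vertices), "vertices,",
      nrow(x$faces), "faces\n")
  rng <- apply(x$vertices, 2L, range)
  cat(sprintf("  bbox [mm]: x %.2f..%.2f  y %.2f..%.2f  z %.2f..%.2f\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  invisible(x)
}

#' @rdname triangle_mesh
#' @param mesh a `triangle_mesh`.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

is_triangle_mesh <- function(x) inherits(x, "triangle_mesh")

stopifnot_mesh <- function(mesh) {
  if (!is_triangle_mesh(mesh))
    stop("expected a 'triangle_mesh' object", call. = FALSE)
  invisible(mesh)
}

#' Per-vertex unit normals
#'
#' Area-weighted average of incident face normals, normalised to unit
#' length. Isolated vertices (no incident face) get a zero normal.
#'
#' @param mesh a `triangle_mesh`.
#' @return an `m x 3` matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  stopifnot_mesh(mesh)
  V <- mesh$vertices
  F <- mesh$faces
  N <- matrix(0, nrow(V), 3L)
  if (nrow(F) == 0L) return(N)
  a <- V[F[, 1L], , drop = FALSE]
  b <- V[F[, 2L], , drop = FALSE]
  c <- V[F[, 3L], , drop = FALSE]
  e1 <- b - a
  e2 <- c - a
  # cross product rows; magnitude = 2 * face area, so this is area weighting
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  for (k in 1:3) {
    N[, 1] <- N[, 1] + unname(tapply_add(fn[, 1], F[, k], nrow(V)))
    N[, 2] <- N[, 2] + unname(tapply_add(fn[, 2], F[, k], nrow(V)))
    N[, 3] <- N[, 3] + unname(tapply_add(fn[, 3], F[, k], nrow(V)))
  }
  len <- sqrt(rowSums(N^2))
  ok <- len > 0
  N[ok, ] <- N[ok, , drop = FALSE] / len[ok]
  N
}

# sum values into bins 1..n (faster, simpler than tapply for this use)
tapply_add <- function(values, bins, n) {
  out <- numeric(n)
  agg <- rowsum(values, bins)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

## ---- mesh file I/O (ASCII OBJ / PLY / STL) --------------------------------
## No mesh-I/O package ships with this R stack, so the three classic ASCII
## formats are read and written directly. STL stores soup triangles and
## destroys shared vertex indexing, so STL input is only meant for validation
## reference meshes, never for building a corpus.

#' Read a triangle mesh from OBJ, PLY (ASCII) or STL (ASCII)
#'
#' The format is chosen from the file extension (`.obj`, `.ply`, `.stl`).
#' Quad faces in OBJ files are fan-triangulated. STL files yield one vertex
#' per triangle corner with exact duplicates merged; because STL has no
#' shared indexing, meshes read from STL must not be used as corpus members
#' of [build_morphable_model()].
#'
#' @param path file path.
#' @param scale multiply coordinates on read (e.g. 1000 for metres to mm).
#' @return a `triangle_mesh`.
#' @export
read_mesh <- function(path, scale = 1) {
  ext <- tolower(tools::file_ext(path))
  mesh <- switch(ext,
    obj = read_obj(path),
    ply = read_ply(path),
    stl = read_stl(path),
    stop("unsupported mesh format: '.", ext, "'", call. = FALSE))
  if (scale != 1)
    mesh <- triangle_mesh(mesh$vertices * scale, mesh$faces)
  mesh
}

#' Write a triangle mesh to OBJ, PLY (ASCII) or STL (ASCII)
#'
#' @param mesh a `triangle_mesh`.
#' @param path output path; extension selects the format.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  stopifnot_mesh(mesh)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    obj = write_obj(mesh, path),
    ply = write_ply(mesh, path),
    stl = write_stl(mesh, path),
    stop("unsupported mesh format: '.", ext, "'", call. = FALSE))
  invisible(path)
}

read_obj <- function(path) {
  ln <- readLines(path, warn = FALSE)
  vl <- ln[startsWith(ln, "v ")]
  fl <- ln[startsWith(ln, "f ")]
  V <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
                             function(p) as.numeric(p[1:3])))
  faces <- list()
  for (f in fl) {
    idx <- vapply(strsplit(trimws(sub("^f", "", f)), "\\s+")[[1]],
                  function(tok) as.integer(strsplit(tok, "/")[[1]][1]), 1L)
    if (length(idx) < 3L) stop("OBJ face with <3 vertices", call. = FALSE)
    for (j in seq_len(length(idx) - 2L))       # fan triangulation
      faces[[length(faces) + 1L]] <- c(idx[1L], idx[j + 1L], idx[j + 2L])
  }
  triangle_mesh(V, do.call(rbind, faces))
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
}

read_ply <- function(path) {
  ln <- readLines(path, warn = FALSE)
  if (!startsWith(ln[1], "ply")) stop("not a PLY file", call. = FALSE)
  fmt <- grep("^format", ln, value = TRUE)[1]
  if (!grepl("ascii", fmt))
    stop("only ASCII PLY is supported", call. = FALSE)
  hdr_end <- which(ln == "end_header")[1]
  nv <- as.integer(sub(".*vertex\\s+", "", grep("^element vertex", ln, value = TRUE)[1]))
  nf <- as.integer(sub(".*face\\s+", "", grep("^element face", ln, value = TRUE)[1]))
  body <- ln[(hdr_end + 1L):length(ln)]
  V <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                             function(p) as.numeric(p[1:3])))
  F <- do.call(rbind, lapply(strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"),
                             function(p) as.integer(p[2:4]) + 1L))
  triangle_mesh(V, F)
}

write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               paste("element face", nrow(mesh$faces)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                     mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
}

read_stl <- function(path) {
  ln <- readLines(path, warn = FALSE)
  if (!grepl("^\\s*solid", ln[1]))
    stop("only ASCII STL is supported", call. = FALSE)
  vl <- grep("^\\s*vertex", ln, value = TRUE)
  P <- do.call(rbind, lapply(strsplit(trimws(sub("vertex", "", vl)), "\\s+"),
                             function(p) as.numeric(p[1:3])))
  if (nrow(P) %% 3L != 0L) stop("corrupt STL: vertex count not multiple of 3",
                                call. = FALSE)
  key <- apply(P, 1L, function(r) paste(sprintf("%.9g", r), collapse = "_"))
  uid <- match(key, unique(key))
  V <- P[!duplicated(key), , drop = FALSE]
  F <- matrix(uid, ncol = 3L, byrow = TRUE)
  triangle_mesh(V, F)
}

write_stl <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid morphfit", con)
  V <- mesh$vertices
  for (i in seq_len(nrow(mesh$faces))) {
    tri <- V[mesh$faces[i, ], , drop = FALSE]
    e1 <- tri[2, ] - tri[1, ]
    e2 <- tri[3, ] - tri[1, ]
    n <- c(e1[2] * e2[3] - e1[3] * e2[2],
           e1[3] * e2[1] - e1[1] * e2[3],
           e1[1] * e2[2] - e1[2] * e2[1])
    nl <- sqrt(sum(n^2))
    if (nl > 0) n <- n / nl
    writeLines(c(sprintf("  facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
                 "    outer loop",
                 sprintf("      vertex %.9g %.9g %.9g",
                         tri[, 1], tri[, 2], tri[, 3]),
                 "    endloop", "  endfacet"), con)
  }
  writeLines("endsolid morphfit", con)
}
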