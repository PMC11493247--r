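#' Triangle mesh
#'
#' Constructs a triangle mesh in world coordinates (millimetres).  Template
#' meshes must be watertight (every edge shared by exactly two triangles);
#' use [validate_mesh()] with `template = TRUE` to enforce this together with
#' a self-intersection scan.
#'
#' @param vertices numeric matrix, one row per vertex, three columns (mm).
#' @param triangles integer matrix, one row per triangle, three 1-based
#'   vertex indices.
#' @param id character identifier.
#' @return an object of class `triangle_mesh` with fields `vertices`,
#'   `triangles`, `id`.
#' @export
triangle_mesh <- function(vertices, triangles, id = "mesh") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(triangles) != 3L) stop("triangles must have 3 columns")
  if (nrow(vertices) < 4L) stop("a mesh needs at least 4 vertices")
  if (anyNA(vertices) || any(!is.finite(vertices))) stop("non-finite vertex")
  if (min(triangles) < 1L || max(triangles) > nrow(vertices))
    stop("triangle index out of range")
  structure(list(vertices = vertices, triangles = triangles,
                 id = as.character(id)),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh '%s'> %d vertices, %d triangles\n",
              x$id, nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

# Undirected edge table with multiplicities: rows (min, max) per triangle edge.
mesh_edges <- function(triangles) {
  e <- rbind(triangles[, c(1L, 2L)], triangles[, c(2L, 3L)],
             triangles[, c(3L, 1L)])
  cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
}

#' Watertightness test
#'
#' A mesh is watertight when every undirected edge is used by exactly two
#' triangles.
#'
#' @param mesh a [triangle_mesh()].
#' @return logical scalar.
#' @export
is_watertight <- function(mesh) {
  e <- mesh_edges(mesh$triangles)
  tab <- table(paste(e[, 1L], e[, 2L]))
  all(tab == 2L)
}

#' Validate a mesh
#'
#' Checks index validity and, for template meshes, watertightness, degenerate
#' triangles, and pairwise self-intersection (edge-piercing test; coplanar
#' overlaps are not detected).
#'
#' @param mesh a [triangle_mesh()].
#' @param template if `TRUE` apply the strict template-mesh requirements.
#' @return the mesh, invisibly; errors on violation.
#' @export
validate_mesh <- function(mesh, template = TRUE) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (template) {
    if (!is_watertight(mesh))
      stop(sprintf("mesh '%s' is not watertight", mesh$id))
    a <- mesh$vertices[mesh$triangles[, 1L], , drop = FALSE]
    b <- mesh$vertices[mesh$triangles[, 2L], , drop = FALSE]
    cc <- mesh$vertices[mesh$triangles[, 3L], , drop = FALSE]
    n <- cross3(b - a, cc - a)
    areas <- 0.5 * sqrt(rowSums(n^2))
    if (any(areas < 1e-12))
      stop(sprintf("degenerate (zero-area) triangle %d in mesh '%s'",
                   which.min(areas), mesh$id))
    hit <- cpp_self_intersections(mesh$vertices, mesh$triangles - 1L)
    if (length(hit))
      stop(sprintf("mesh '%s' self-intersects (triangles %d and %d)",
                   mesh$id, hit[1L] + 1L, hit[2L] + 1L))
  }
  invisible(mesh)
}

# Row-wise cross product of n x 3 matrices.
cross3 <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

#' FFD cage
#'
#' A coarse closed control polyhedron enclosing a template mesh.  Faces may be
#' arbitrary polygons; they are triangulated fan-wise internally for geometric
#' queries, while the graph Laplacian of the fitting stage uses the original
#' polygon edge graph.
#'
#' @param vertices numeric matrix `N_c x 3` (mm), `N_c >= 8`.
#' @param faces list of integer vectors (1-based vertex loops, length >= 3).
#' @param id character identifier.
#' @return an object of class `cage` with fields `vertices`, `faces`,
#'   `triangles` (fan triangulation), `edges` (unique polygon edges).
#' @export
cage <- function(vertices, faces, id = "cage") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) stop("cage vertices must have 3 columns")
  if (nrow(vertices) < 8L) stop("a cage needs at least 8 vertices")
  faces <- lapply(faces, as.integer)
  if (any(vapply(faces, length, 1L) < 3L)) stop("cage faces need >= 3 vertices")
  idxs <- unlist(faces)
  if (min(idxs) < 1L || max(idxs) > nrow(vertices))
    stop("cage face index out of range")
  tris <- do.call(rbind, lapply(faces, function(f) {
    if (length(f) == 3L) matrix(f, 1L) else
      cbind(f[1L], f[seq(2L, length(f) - 1L)], f[seq(3L, length(f))])
  }))
  storage.mode(tris) <- "integer"
  tri_face <- rep(seq_along(faces), vapply(faces, length, 1L) - 2L)
  e <- do.call(rbind, lapply(faces, function(f) {
    cbind(f, c(f[-1L], f[1L]))
  }))
  e <- unique(cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L])))
  storage.mode(e) <- "integer"
  obj <- structure(list(vertices = vertices, faces = faces, triangles = tris,
                        triangle_face = tri_face, edges = e,
                        id = as.character(id)),
                   class = "cage")
  tri_mesh <- triangle_mesh(vertices, tris, id = id)
  if (!is_watertight(tri_mesh))
    stop(sprintf("cage '%s' is not closed (watertight after triangulation)",
                 id))
  if (any(tabulate(as.vector(e), nrow(vertices)) == 0L))
    stop("cage has an isolated vertex")
  obj
}

#' @export
print.cage <- function(x, ...) {
  cat(sprintf("<cage '%s'> %d vertices, %d faces\n",
              x$id, nrow(x$vertices), length(x$faces)))
  invisible(x)
}

# The cage surface as a triangle soup (no minimum-vertex constraint).
cage_surface <- function(cg, vertices = cg$vertices) {
  list(vertices = vertices, triangles = cg$triangles)
}

#' Read a mesh from OBJ or PLY (ASCII)
#'
#' @param path file path ending in `.obj` or `.ply`.
#' @param validate validate as a template mesh (watertight, no
#'   self-intersections).
#' @return a [triangle_mesh()]; polygonal faces are fan-triangulated.
#' @export
read_mesh <- function(path, validate = TRUE) {
  raw <- read_poly_file(path)
  tris <- do.call(rbind, lapply(raw$faces, function(f) {
    if (length(f) == 3L) matrix(f, 1L) else
      cbind(f[1L], f[seq(2L, length(f) - 1L)], f[seq(3L, length(f))])
  }))
  m <- triangle_mesh(raw$vertices, tris,
                     id = sub("\\.(obj|ply)$", "", basename(path),
                              ignore.case = TRUE))
  if (validate) validate_mesh(m, template = TRUE)
  m
}

#' Read a cage from OBJ or PLY (ASCII)
#'
#' @inheritParams read_mesh
#' @return a [cage()]; closure is validated on read.
#' @export
read_cage <- function(path) {
  raw <- read_poly_file(path)
  cage(raw$vertices, raw$faces,
       id = sub("\\.(obj|ply)$", "", basename(path), ignore.case = TRUE))
}

read_poly_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         obj = read_obj_file(path),
         ply = read_ply_file(path),
         stop("unsupported mesh format: ", ext))
}

read_obj_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  verts <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
                                 function(x) as.numeric(x[1:3])))
  faces <- lapply(strsplit(trimws(sub("^f", "", fl)), "\\s+"), function(x) {
    as.integer(vapply(strsplit(x, "/"), `[[`, "", 1L))
  })
  list(vertices = verts, faces = faces)
}

read_ply_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hend <- match("end_header", trimws(lines))
  if (is.na(hend)) stop("not an ASCII PLY file (no end_header)")
  header <- lines[seq_len(hend)]
  if (!any(grepl("^format ascii", header))) stop("only ASCII PLY is supported")
  nv <- as.integer(sub("element vertex\\s+", "",
                       grep("^element vertex", header, value = TRUE)))
  nf <- as.integer(sub("element face\\s+", "",
                       grep("^element face", header, value = TRUE)))
  body <- lines[seq(hend + 1L, length.out = nv + nf)]
  verts <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                                 function(x) as.numeric(x[1:3])))
  faces <- lapply(strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"), function(x) {
    n <- as.integer(x[1L])
    as.integer(x[1L + seq_len(n)]) + 1L
  })
  list(vertices = verts, faces = faces)
}

#' Write a mesh or cage to OBJ or PLY (ASCII)
#'
#' The format is chosen from the file extension.
#'
#' @param x a [triangle_mesh()] or [cage()].
#' @param path destination path ending in `.obj` or `.ply`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(x, path) {
  if (inherits(x, "cage")) {
    verts <- x$vertices
    faces <- x$faces
  } else {
    verts <- x$vertices
    faces <- lapply(seq_len(nrow(x$triangles)), function(i) x$triangles[i, ])
  }
  ext <- tolower(tools::file_ext(path))
  fmt_row <- function(v) sprintf("%.9g %.9g %.9g", v[1L], v[2L], v[3L])
  vtxt <- apply(verts, 1L, fmt_row)
  if (ext == "obj") {
    ftxt <- vapply(faces, function(f) paste(f, collapse = " "), "")
    writeLines(c(paste("v", vtxt), paste("f", ftxt)), path)
  } else if (ext == "ply") {
    ftxt <- vapply(faces, function(f)
      paste(c(length(f), f - 1L), collapse = " "), "")
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(verts)),
                 "property double x", "property double y", "property double z",
                 sprintf("element face %d", length(faces)),
                 "property list uchar int vertex_indices", "end_header",
                 vtxt, ftxt), path)
  } else stop("unsupported mesh format: ", ext)
  invisible(path)
}
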