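#' Rasterize a cage onto a binding grid
#'
#' Discretizes the cage interior on a regular axis-aligned grid, the classic
#' construction for harmonic coordinates.  Cells whose center lies within half
#' a cell diagonal of the cage surface are tagged `BOUNDARY` and receive
#' Dirichlet data: the barycentric interpolation of cage-vertex indicator
#' functions at the closest point on the cage surface.  A flood fill from the
#' grid border tags `EXTERIOR`; the rest is `INTERIOR`.
#'
#' @param cage a [cage()] (closed; validated at construction).
#' @param resolution number of cells along the longest bounding-box axis
#'   (default 64, minimum 16).
#' @param margin number of extra cells around the bounding box (default 2),
#'   so the exterior flood fill surrounds the cage completely.
#' @return an object of class `binding_grid` with fields `dims`, `origin`
#'   (center of cell (1,1,1), mm), `h` (cell size, mm), `tags` (0 interior,
#'   1 boundary, 2 exterior), `bvalues` (per-cell boundary weights, one column
#'   per cage vertex).
#' @export
rasterize_cage <- function(cage, resolution = 64L, margin = 2L) {
  stopifnot(inherits(cage, "cage"))
  if (resolution < 16L) stop("resolution must be >= 16")
  bmin <- apply(cage$vertices, 2L, min)
  bmax <- apply(cage$vertices, 2L, max)
  extent <- bmax - bmin
  h <- max(extent) / resolution
  dims <- as.integer(ceiling(extent / h)) + 1L + 2L * margin
  origin <- bmin - margin * h
  seed <- colMeans(cage$vertices)
  tg <- cpp_tag_grid(cage$vertices, cage$triangles - 1L, dims, origin, h, seed)
  if (tg$n_interior == 0)
    stop("no interior cells; raise the grid resolution")
  if (tg$n_reached < tg$n_interior)
    stop(sprintf(paste0("interior is disconnected at resolution %d ",
                        "(%d of %d cells reachable); raise the resolution"),
                 resolution, tg$n_reached, tg$n_interior))
  # Dirichlet data: generalized barycentric (mean-value) interpolation of the
  # cage-vertex indicator functions over the *polygon face* containing the
  # closest point.  Interpolating over fan triangles instead would bias the
  # weights toward the fan diagonal and break the symmetry of, e.g., a cube.
  ncell <- prod(dims)
  nc <- nrow(cage$vertices)
  bvalues <- matrix(0, ncell, nc)
  corners <- cage$triangles[tg$btri + 1L, , drop = FALSE]
  foot <- tg$bbary[, 1L] * cage$vertices[corners[, 1L], , drop = FALSE] +
    tg$bbary[, 2L] * cage$vertices[corners[, 2L], , drop = FALSE] +
    tg$bbary[, 3L] * cage$vertices[corners[, 3L], , drop = FALSE]
  face_of <- cage$triangle_face[tg$btri + 1L]
  rows <- tg$bcell + 1L
  for (f in unique(face_of)) {
    sel <- which(face_of == f)
    fv <- cage$faces[[f]]
    poly <- cage$vertices[fv, , drop = FALSE]
    # orthonormal in-plane basis from the face
    e1 <- poly[2L, ] - poly[1L, ]
    e1 <- e1 / sqrt(sum(e1^2))
    nrm <- colSums(cross3(poly - poly[rep(1L, nrow(poly)), ],
                          poly[c(2:nrow(poly), 1L), ] - poly))
    nrm <- nrm / sqrt(sum(nrm^2))
    e2 <- c(nrm[2] * e1[3] - nrm[3] * e1[2], nrm[3] * e1[1] - nrm[1] * e1[3],
            nrm[1] * e1[2] - nrm[2] * e1[1])
    p2 <- cbind((foot[sel, , drop = FALSE] %*% e1), foot[sel, , drop = FALSE] %*% e2)
    v2 <- cbind(poly %*% e1, poly %*% e2)
    w <- poly_mean_value(v2, p2)
    for (s in seq_along(fv)) {
      ij <- cbind(rows[sel], fv[s])
      bvalues[ij] <- bvalues[ij] + w[, s]
    }
  }
  structure(list(dims = dims, origin = origin, h = h, tags = tg$tags,
                 bvalues = bvalues, resolution = as.integer(resolution),
                 margin = as.integer(margin)),
            class = "binding_grid")
}

#' @export
print.binding_grid <- function(x, ...) {
  cat(sprintf("<binding_grid> %d x %d x %d cells, h = %.4g mm (%d interior)\n",
              x$dims[1], x$dims[2], x$dims[3], x$h, sum(x$tags == 0L)))
  invisible(x)
}

#' Solve the harmonic weight fields on a binding grid
#'
#' For each cage vertex, solves Laplace's equation (6-neighbour stencil) on
#' the interior cells with the rasterized boundary weights as Dirichlet data.
#' The resulting fields are non-negative and sum to one at every non-exterior
#' cell up to discretization and solver tolerance.
#'
#' @param grid a [rasterize_cage()] result.
#' @param tol conjugate-gradient relative residual tolerance (default 1e-8).
#' @param maxit iteration cap per field.
#' @return an object of class `harmonic_fields` with `fields` (per-cell
#'   values, one column per cage vertex) and `residual` (worst relative
#'   residual over all fields).
#' @export
solve_harmonic_weights <- function(grid, tol = 1e-8, maxit = 20000L) {
  stopifnot(inherits(grid, "binding_grid"))
  sol <- cpp_solve_laplace(grid$dims, grid$tags, grid$bvalues, tol,
                           as.integer(maxit))
  if (sol$residual > 100 * tol)
    stop(sprintf("harmonic solve did not converge (relative residual %.3g)",
                 sol$residual))
  structure(list(fields = sol$fields, residual = sol$residual, tol = tol),
            class = "harmonic_fields")
}

#' Bind a mesh to a cage via harmonic coordinates
#'
#' Samples the harmonic weight fields at every mesh vertex with trilinear
#' interpolation and renormalizes each row to sum exactly to one (this removes
#' discretization drift and makes the deformation exactly translation
#' invariant).  The binding is validated: non-negativity up to `-1e-3`, and
#' reconstruction of the rest mesh from the rest cage within one grid-cell
#' diagonal.
#'
#' @param mesh a [triangle_mesh()] whose vertices all lie inside the cage.
#' @param grid the [rasterize_cage()] result.
#' @param fields the [solve_harmonic_weights()] result.
#' @param cage the [cage()] the grid was built from.
#' @return an object of class `harmonic_binding` with `weights`
#'   (`N_m x N_c`) and a `provenance` record.
#' @export
bind_mesh <- function(mesh, grid, fields, cage) {
  stopifnot(inherits(mesh, "triangle_mesh"), inherits(grid, "binding_grid"),
            inherits(fields, "harmonic_fields"), inherits(cage, "cage"))
  v <- mesh$vertices
  ijk <- round(sweep(v, 2L, grid$origin) / grid$h)
  bad <- which(ijk[, 1] < 0 | ijk[, 2] < 0 | ijk[, 3] < 0 |
                 ijk[, 1] >= grid$dims[1] | ijk[, 2] >= grid$dims[2] |
                 ijk[, 3] >= grid$dims[3])
  if (length(bad) == 0L) {
    lin <- 1L + ijk[, 1] + grid$dims[1] * (ijk[, 2] + grid$dims[2] * ijk[, 3])
    bad <- which(grid$tags[lin] == 2L)
  }
  if (length(bad))
    stop(sprintf("mesh vertex %d lies outside the cage (exterior cell)",
                 bad[1L]))
  w <- cpp_trilinear_sample(grid$dims, grid$origin, grid$h, fields$fields,
                            grid$tags, v)
  if (min(w) < -1e-3)
    stop(sprintf("negative harmonic weight %.3g exceeds tolerance", min(w)))
  rs <- rowSums(w)
  if (any(abs(rs - 1) > 1e-3))
    stop(sprintf("weight row sum %.4f violates partition of unity",
                 rs[which.max(abs(rs - 1))]))
  w <- w / rs
  recon <- w %*% cage$vertices
  err <- sqrt(rowSums((recon - v)^2))
  diag_len <- grid$h * sqrt(3)
  if (max(err) > diag_len)
    stop(sprintf("reconstruction error %.4g mm exceeds one cell diagonal %.4g",
                 max(err), diag_len))
  structure(list(weights = w,
                 provenance = list(resolution = grid$resolution, h = grid$h,
                                   solver_tol = fields$tol,
                                   solver_residual = fields$residual,
                                   max_reconstruction_error = max(err),
                                   mesh_hash = content_hash(mesh),
                                   cage_hash = content_hash(cage))),
            class = "harmonic_binding")
}

#' @export
print.harmonic_binding <- function(x, ...) {
  cat(sprintf(paste0("<harmonic_binding> %d x %d weights (resolution %d, ",
                     "max reconstruction error %.3g mm)\n"),
              nrow(x$weights), ncol(x$weights), x$provenance$resolution,
              x$provenance$max_reconstruction_error))
  invisible(x)
}

#' Bind a template in one call
#'
#' Convenience wrapper: rasterize, solve, sample, and attach the binding.
#'
#' @param template an unbound [template_model()].
#' @param resolution grid resolution along the longest axis (default 64).
#' @param tol harmonic solver tolerance.
#' @return the [template_model()] with its `binding` populated.
#' @export
bind_template <- function(template, resolution = 64L, tol = 1e-8) {
  grid <- rasterize_cage(template$cage, resolution = resolution)
  fields <- solve_harmonic_weights(grid, tol = tol)
  binding <- bind_mesh(template$mesh, grid, fields, template$cage)
  template_model(template$mesh, template$cage, binding)
}

# Mean-value coordinates of 2D points inside (or on) a polygon.
# v2: m x 2 polygon vertices, p2: n x 2 query points on the polygon's plane.
# Returns n x m non-negative weights summing to 1; points on a vertex get the
# indicator, points on an edge the linear interpolation of its endpoints.
poly_mean_value <- function(v2, p2) {
  m <- nrow(v2)
  n <- nrow(p2)
  diam <- max(dist(v2))
  tolv <- 1e-9 * diam
  r <- A <- D <- matrix(0, n, m)
  for (i in seq_len(m)) {
    di <- sweep(p2, 2L, v2[i, ], `-`)
    r[, i] <- sqrt(rowSums(di^2))
  }
  nxt <- c(2:m, 1L)
  for (i in seq_len(m)) {
    ui <- sweep(-p2, 2L, v2[i, ], `+`)         # v_i - p
    uj <- sweep(-p2, 2L, v2[nxt[i], ], `+`)    # v_{i+1} - p
    A[, i] <- 0.5 * (ui[, 1L] * uj[, 2L] - ui[, 2L] * uj[, 1L])
    D[, i] <- rowSums(ui * uj)
  }
  w <- matrix(0, n, m)
  on_vertex <- r < tolv
  special <- rowSums(on_vertex) > 0L
  on_edge <- abs(A) < tolv * diam & D < 0 & !special
  edge_rows <- rowSums(on_edge) > 0L
  generic <- !(special | edge_rows)
  if (any(generic)) {
    g <- which(generic)
    tanh2 <- matrix(0, length(g), m)
    for (i in seq_len(m))
      tanh2[, i] <- (r[g, i] * r[g, nxt[i]] - D[g, i]) / (2 * A[g, i])
    prv <- c(m, 1:(m - 1L))
    for (i in seq_len(m))
      w[g, i] <- (tanh2[, prv[i]] + tanh2[, i]) / r[g, i]
  }
  if (any(edge_rows)) {
    for (q in which(edge_rows)) {
      i <- which(on_edge[q, ])[1L]
      j <- nxt[i]
      w[q, i] <- r[q, j] / (r[q, i] + r[q, j])
      w[q, j] <- 1 - w[q, i]
    }
  }
  if (any(special)) {
    for (q in which(special)) w[q, which.min(r[q, ])] <- 1
  }
  w / rowSums(w)
}

# Content hash for cache invalidation: geometry rounded to nm so that
# format round-trips do not spuriously invalidate.
content_hash <- function(x) {
  if (inherits(x, "triangle_mesh"))
    rlang::hash(list(round(x$vertices, 6), x$triangles))
  else if (inherits(x, "cage"))
    rlang::hash(list(round(x$vertices, 6), x$faces))
  else rlang::hash(x)
}

#' Write / read a binding cache
#'
#' The binding is computed once per template and cached in a compressed
#' container together with content hashes of the mesh and cage; reading with
#' a mismatching mesh or cage fails, forcing a rebind.
#'
#' @param binding a `harmonic_binding`.
#' @param path cache file path (conventionally `.rds`).
#' @return `write_binding`: `path` invisibly; `read_binding`: the binding.
#' @export
write_binding <- function(binding, path) {
  stopifnot(inherits(binding, "harmonic_binding"))
  saveRDS(binding, path, compress = "gzip")
  invisible(path)
}

#' @rdname write_binding
#' @param mesh,cage if supplied, verified against the cached content hashes.
#' @export
read_binding <- function(path, mesh = NULL, cage = NULL) {
  binding <- readRDS(path)
  if (!inherits(binding, "harmonic_binding")) stop("not a binding cache")
  if (!is.null(mesh) && !identical(content_hash(mesh),
                                   binding$provenance$mesh_hash))
    stop("binding cache is stale: mesh content hash changed")
  if (!is.null(cage) && !identical(content_hash(cage),
                                   binding$provenance$cage_hash))
    stop("binding cache is stale: cage content hash changed")
  binding
}
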