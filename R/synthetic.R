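# Synthetic phantom generation: parametric templates, box-lattice cages,
# ground-truth deformation sequences and constraint curves sampled from
# ground-truth surfaces.  Everything is deterministic under a recorded seed,
# and ground-truth targets are generated *through the cage* so that perfect
# fitting is representable and recovery tests isolate algorithmic error.

#' Icosphere mesh
#'
#' Subdivided icosahedron projected to a sphere; watertight by construction.
#'
#' @param radius sphere radius (mm).
#' @param subdivisions midpoint-subdivision depth (3 gives 642 vertices).
#' @param center length-3 center (mm).
#' @return a [triangle_mesh()].
#' @export
icosphere <- function(radius = 20, subdivisions = 3L, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    midcache <- new.env(parent = emptyenv())
    nv <- nrow(v)
    newf <- matrix(0L, 0L, 3L)
    vlist <- list(v)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      if (!is.null(midcache[[key]])) return(midcache[[key]])
      nv <<- nv + 1L
      vlist[[length(vlist) + 1L]] <<- (v[i, ] + v[j, ]) / 2
      midcache[[key]] <- nv
      nv
    }
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1L]; b <- f[t, 2L]; c3 <- f[t, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      newf <- rbind(newf, c(a, ab, ca), c(b, bc, ab), c(c3, ca, bc),
                    c(ab, bc, ca))
    }
    v <- do.call(rbind, vlist)
    f <- newf
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  v <- sweep(v, 2L, center, `+`)
  triangle_mesh(v, f, id = "icosphere")
}

#' Ellipsoid mesh
#'
#' @param semi_axes length-3 semi-axes (mm).
#' @param subdivisions icosphere subdivision depth.
#' @param center length-3 center.
#' @return a [triangle_mesh()].
#' @export
ellipsoid_mesh <- function(semi_axes = c(24, 20, 16), subdivisions = 3L,
                           center = c(0, 0, 0)) {
  m <- icosphere(1, subdivisions)
  m$vertices <- sweep(sweep(m$vertices, 2L, semi_axes, `*`), 2L, center, `+`)
  m$id <- "ellipsoid"
  m
}

#' Capsule mesh (cylinder with hemispherical caps)
#'
#' Built on a UV sphere split at the equator, with the two hemispheres pushed
#' apart along z by the cylinder length; exactly two umbilic cap regions.
#'
#' @param radius capsule radius (mm).
#' @param length cylinder (straight section) length (mm).
#' @param n_ring latitude rows (odd, so no row sits on the equator).
#' @param n_seg longitude segments.
#' @return a [triangle_mesh()].
#' @export
capsule_mesh <- function(radius = 10, length = 30, n_ring = 15L, n_seg = 24L) {
  if (n_ring %% 2L == 0L) n_ring <- n_ring + 1L
  theta <- seq(0, pi, length.out = n_ring + 2L)[2:(n_ring + 1L)]
  verts <- rbind(c(0, 0, radius + length / 2))
  for (th in theta) {
    shift <- if (th < pi / 2) length / 2 else -length / 2
    ring <- cbind(radius * sin(th) * cos(2 * pi * (0:(n_seg - 1L)) / n_seg),
                  radius * sin(th) * sin(2 * pi * (0:(n_seg - 1L)) / n_seg),
                  radius * cos(th) + shift)
    verts <- rbind(verts, ring)
  }
  verts <- rbind(verts, c(0, 0, -radius - length / 2))
  np <- nrow(verts)
  ringv <- function(r) 1L + (r - 1L) * n_seg + (1:n_seg)  # vertices of row r
  f <- NULL
  top <- ringv(1L)
  for (s in 1:n_seg)
    f <- rbind(f, c(1L, top[s], top[s %% n_seg + 1L]))
  for (r in 1:(n_ring - 1L)) {
    a <- ringv(r); b <- ringv(r + 1L)
    for (s in 1:n_seg) {
      s2 <- s %% n_seg + 1L
      f <- rbind(f, c(a[s], b[s], b[s2]), c(a[s], b[s2], a[s2]))
    }
  }
  bot <- ringv(n_ring)
  for (s in 1:n_seg)
    f <- rbind(f, c(np, bot[s %% n_seg + 1L], bot[s]))
  triangle_mesh(verts, f, id = "capsule")
}

#' Tube mesh along a (possibly bent) circular-arc centerline
#'
#' A tube of the given radius swept along an arc in the xz-plane, with flat
#' fan caps.  `bend_angle = 0` gives a straight tube along z.  This is the
#' out-of-model fixture for the characterized failure mode: a strongly bent
#' target cannot be reached from a straight template by closest-point
#' association alone.
#'
#' @param radius tube radius (mm).
#' @param length centerline arc length (mm).
#' @param bend_angle total bend of the centerline (radians).
#' @param n_len rings along the centerline.
#' @param n_seg segments around the tube.
#' @return a [triangle_mesh()].
#' @export
tube_mesh <- function(radius = 6, length = 60, bend_angle = 0, n_len = 24L,
                      n_seg = 16L) {
  s <- seq(0, 1, length.out = n_len + 1L)
  if (abs(bend_angle) < 1e-9) {
    cen <- cbind(0, 0, (s - 0.5) * length)
    tan_ <- matrix(rep(c(0, 0, 1), each = n_len + 1L), ncol = 3L)
    n1 <- matrix(rep(c(1, 0, 0), each = n_len + 1L), ncol = 3L)
  } else {
    R <- length / bend_angle
    psi <- (s - 0.5) * bend_angle
    cen <- cbind(R * (1 - cos(psi)), 0, R * sin(psi))
    tan_ <- cbind(sin(psi), 0, cos(psi))
    n1 <- cbind(cos(psi), 0, -sin(psi))
  }
  n2 <- matrix(rep(c(0, 1, 0), each = n_len + 1L), ncol = 3L)
  ang <- 2 * pi * (0:(n_seg - 1L)) / n_seg
  verts <- NULL
  for (r in 1:(n_len + 1L)) {
    ring <- cen[rep(r, n_seg), ] + radius * (outer(cos(ang), n1[r, ]) +
                                               outer(sin(ang), n2[r, ]))
    verts <- rbind(verts, ring)
  }
  v_start <- nrow(verts) + 1L
  verts <- rbind(verts, cen[1L, ], cen[n_len + 1L, ])
  ringv <- function(r) (r - 1L) * n_seg + (1:n_seg)
  f <- NULL
  for (r in 1:n_len) {
    a <- ringv(r); b <- ringv(r + 1L)
    for (q in 1:n_seg) {
      q2 <- q %% n_seg + 1L
      f <- rbind(f, c(a[q], b[q], b[q2]), c(a[q], b[q2], a[q2]))
    }
  }
  a <- ringv(1L)
  for (q in 1:n_seg) f <- rbind(f, c(v_start, a[q %% n_seg + 1L], a[q]))
  b <- ringv(n_len + 1L)
  for (q in 1:n_seg) f <- rbind(f, c(v_start + 1L, b[q], b[q %% n_seg + 1L]))
  triangle_mesh(verts, f, id = if (abs(bend_angle) < 1e-9) "tube" else
    "bent_tube")
}

#' Box-lattice cage
#'
#' An axis-aligned box with each face subdivided into a quad lattice: the
#' standard coarse control structure for FFD.  `subdivisions = c(1,1,1)`
#' gives the plain 8-vertex box.
#'
#' @param bmin,bmax box corners (mm).
#' @param subdivisions cells per axis, length 3.
#' @return a [cage()].
#' @export
box_lattice_cage <- function(bmin, bmax, subdivisions = c(1L, 1L, 1L)) {
  s <- pmax(as.integer(subdivisions), 1L)
  gx <- seq(bmin[1], bmax[1], length.out = s[1] + 1L)
  gy <- seq(bmin[2], bmax[2], length.out = s[2] + 1L)
  gz <- seq(bmin[3], bmax[3], length.out = s[3] + 1L)
  grid <- expand.grid(i = seq_along(gx), j = seq_along(gy), k = seq_along(gz))
  on_surf <- grid$i %in% c(1L, s[1] + 1L) | grid$j %in% c(1L, s[2] + 1L) |
    grid$k %in% c(1L, s[3] + 1L)
  grid <- grid[on_surf, ]
  verts <- cbind(gx[grid$i], gy[grid$j], gz[grid$k])
  key <- paste(grid$i, grid$j, grid$k)
  vid <- setNames(seq_len(nrow(grid)), key)
  faces <- list()
  quad <- function(a, b, c3, d) faces[[length(faces) + 1L]] <<- c(a, b, c3, d)
  id <- function(i, j, k) vid[[paste(i, j, k)]]
  for (j in 1:s[2]) for (i in 1:s[1]) {
    quad(id(i, j, 1L), id(i, j + 1L, 1L), id(i + 1L, j + 1L, 1L),
         id(i + 1L, j, 1L))                                   # z = min
    quad(id(i, j, s[3] + 1L), id(i + 1L, j, s[3] + 1L),
         id(i + 1L, j + 1L, s[3] + 1L), id(i, j + 1L, s[3] + 1L))  # z = max
  }
  for (k in 1:s[3]) for (i in 1:s[1]) {
    quad(id(i, 1L, k), id(i + 1L, 1L, k), id(i + 1L, 1L, k + 1L),
         id(i, 1L, k + 1L))                                   # y = min
    quad(id(i, s[2] + 1L, k), id(i, s[2] + 1L, k + 1L),
         id(i + 1L, s[2] + 1L, k + 1L), id(i + 1L, s[2] + 1L, k))  # y = max
  }
  for (k in 1:s[3]) for (j in 1:s[2]) {
    quad(id(1L, j, k), id(1L, j, k + 1L), id(1L, j + 1L, k + 1L),
         id(1L, j + 1L, k))                                   # x = min
    quad(id(s[1] + 1L, j, k), id(s[1] + 1L, j + 1L, k),
         id(s[1] + 1L, j + 1L, k + 1L), id(s[1] + 1L, j, k + 1L))  # x = max
  }
  cage(verts, faces, id = "box_lattice")
}

#' Phantom specification
#'
#' The stated world of the synthetic fixtures: base shape and size, cage
#' style, frame count, ground-truth motion amplitudes, the curve-sampling
#' plan, and control-point jitter emulating imprecise clicks.
#'
#' @param shape one of "sphere", "ellipsoid", "capsule", "bent_tube".
#' @param size named list of shape parameters (defaults per shape: sphere
#'   `radius = 20`; ellipsoid `semi_axes = c(24, 20, 16)`; capsule
#'   `radius = 10, length = 30`; bent_tube `radius = 6, length = 60,
#'   bend_angle`).
#' @param cage_subdivisions box-lattice cells per axis (default `c(1,1,1)`,
#'   the 8-vertex box).
#' @param clearance fractional cage clearance around the mesh bounding box
#'   (default 0.15, comfortably above the required 5%).
#' @param n_frames frames `T` (default 5).
#' @param motion list: `translation_mm` (peak smooth translation, default 5),
#'   `scale_amp` (peak relative scale change, default 0.08), `offset_mm`
#'   (peak low-frequency cage-vertex offset, default 1.5).
#' @param planes list of [cross_section_plane()] for curve sampling (default:
#'   the three orthogonal center planes).
#' @param n_control control points per sampled curve (default 8).
#' @param jitter_mm control-point jitter amplitude (default 0.3).
#' @param seed integer seed; fully determines all generated outputs.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = "sphere", size = list(),
                         cage_subdivisions = c(1L, 1L, 1L), clearance = 0.15,
                         n_frames = 5L, motion = list(),
                         planes = NULL, n_control = 8L, jitter_mm = 0.3,
                         seed = 1L) {
  shape <- match.arg(shape, c("sphere", "ellipsoid", "capsule", "bent_tube"))
  defaults <- switch(shape,
                     sphere = list(radius = 20),
                     ellipsoid = list(semi_axes = c(24, 20, 16)),
                     capsule = list(radius = 10, length = 30),
                     bent_tube = list(radius = 6, length = 60, bend_angle = 0))
  size <- modifyList(defaults, size)
  motion <- modifyList(list(translation_mm = 5, scale_amp = 0.08,
                            offset_mm = 1.5), motion)
  if (is.null(planes))
    planes <- list(cross_section_plane("XY", 0), cross_section_plane("YZ", 0),
                   cross_section_plane("ZX", 0))
  structure(list(shape = shape, size = size,
                 cage_subdivisions = as.integer(cage_subdivisions),
                 clearance = clearance, n_frames = as.integer(n_frames),
                 motion = motion, planes = planes,
                 n_control = as.integer(n_control), jitter_mm = jitter_mm,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate the template (mesh + cage) for a phantom spec
#'
#' @param spec a [phantom_spec()].
#' @return an unbound [template_model()]; the cage is a box lattice with the
#'   spec's clearance around the mesh bounding box.
#' @export
make_template <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  mesh <- switch(spec$shape,
                 sphere = icosphere(spec$size$radius, 3L),
                 ellipsoid = ellipsoid_mesh(spec$size$semi_axes, 3L),
                 capsule = capsule_mesh(spec$size$radius, spec$size$length),
                 bent_tube = tube_mesh(spec$size$radius, spec$size$length,
                                       spec$size$bend_angle))
  bmin <- apply(mesh$vertices, 2L, min)
  bmax <- apply(mesh$vertices, 2L, max)
  pad <- spec$clearance * (bmax - bmin)
  cg <- box_lattice_cage(bmin - pad, bmax + pad, spec$cage_subdivisions)
  inside <- sweep(mesh$vertices, 2L, bmin - pad, `>=`) &
    sweep(mesh$vertices, 2L, bmax + pad, `<=`)
  if (!all(inside)) stop("cage fails to enclose the mesh")
  template_model(mesh, cg)
}

#' Ground-truth deformation sequence
#'
#' Applies the spec's smooth time-varying similarity plus seeded
#' low-frequency per-vertex offsets to the cage, frame by frame, and computes
#' the target meshes through the harmonic binding — so every target is
#' exactly representable by the cage.  Frame 0 is the rest pose.
#'
#' @param template a bound [template_model()].
#' @param spec the [phantom_spec()].
#' @return list with `cages` (per-frame `N_c x 3` matrices) and `meshes`
#'   (per-frame target [triangle_mesh()]).
#' @export
make_ground_truth_sequence <- function(template, spec) {
  stopifnot(inherits(template, "template_model"))
  if (is.null(template$binding)) stop("template must be bound")
  rng <- local({set.seed(spec$seed); list(
    dir = {d <- stats::rnorm(3); d / sqrt(sum(d^2))},
    amp = matrix(stats::runif(9, -1, 1), 3L),
    freq = matrix(stats::runif(9, 0.4, 1.0), 3L),
    phase = matrix(stats::runif(9, 0, 2 * pi), 3L))})
  C0 <- template$cage$vertices
  bmin <- apply(C0, 2L, min); ext <- apply(C0, 2L, max) - bmin
  xhat <- sweep(sweep(C0, 2L, bmin), 2L, ext, `/`)
  centroid <- colMeans(C0)
  T_ <- spec$n_frames
  cages <- meshes <- vector("list", T_)
  for (t in seq_len(T_) - 1L) {
    tau <- if (T_ > 1L) t / (T_ - 1L) else 0
    w <- sin(pi * tau)
    s <- 1 + spec$motion$scale_amp * w
    tr <- spec$motion$translation_mm * w * rng$dir
    C <- sweep(s * sweep(C0, 2L, centroid), 2L, centroid + tr, `+`)
    # low-frequency offsets: two seeded sinusoids per axis over the cage box
    off <- matrix(0, nrow(C0), 3L)
    for (d in 1:3)
      for (m in 1:3)
        off[, d] <- off[, d] + rng$amp[d, m] *
          sin(2 * pi * rng$freq[d, m] * xhat[, m] + rng$phase[d, m])
    off <- off / max(1e-9, max(abs(off))) * spec$motion$offset_mm * w
    C <- C + off
    mesh_t <- deform_mesh(template, C)
    cb_min <- apply(C, 2L, min); cb_max <- apply(C, 2L, max)
    ok <- sweep(mesh_t$vertices, 2L, cb_min, `>=`) &
      sweep(mesh_t$vertices, 2L, cb_max, `<=`)
    if (!all(ok)) stop("ground-truth deformation ejects the mesh from the cage")
    cages[[t + 1L]] <- C
    meshes[[t + 1L]] <- mesh_t
  }
  list(cages = cages, meshes = meshes)
}

# ---------------------------------------------------------------------------
# Cross-section loops of a watertight mesh

#' Planar cross-section loops of a mesh
#'
#' Intersects a watertight mesh with an axis-aligned plane and chains the
#' per-triangle intersection segments into closed loops, ordered along each
#' loop.  If a vertex lies numerically on the plane, the offset is nudged by
#' a tiny deterministic epsilon.
#'
#' @param mesh a watertight [triangle_mesh()].
#' @param plane a [cross_section_plane()].
#' @return list of loops, each an `n x 2` matrix of in-plane (u,v) points.
#' @export
cross_section_loops <- function(mesh, plane) {
  ax <- plane_normal_axis(plane)
  offset <- plane$offset_mm
  d <- mesh$vertices[, ax] - offset
  scale <- max(abs(d), 1e-9)
  if (any(abs(d) < 1e-9 * scale)) {
    offset <- offset + 1e-7 * scale
    d <- mesh$vertices[, ax] - offset
  }
  tris <- mesh$triangles
  sgn <- sign(d)
  crossing <- which(apply(matrix(sgn[tris], ncol = 3L), 1L, function(s)
    length(unique(s)) > 1L))
  if (length(crossing) == 0L)
    stop("plane misses the mesh: no cross-section loop")
  # per crossing triangle: the two cut edges, keyed by sorted vertex pair
  seg_from <- seg_to <- character(length(crossing))
  pts <- new.env(parent = emptyenv())
  edge_cut <- function(i, j) {
    key <- paste(min(i, j), max(i, j))
    if (is.null(pts[[key]])) {
      t0 <- d[i] / (d[i] - d[j])
      pts[[key]] <- mesh$vertices[i, ] + t0 * (mesh$vertices[j, ] -
                                                 mesh$vertices[i, ])
    }
    key
  }
  for (q in seq_along(crossing)) {
    tv <- tris[crossing[q], ]
    e <- list(c(tv[1], tv[2]), c(tv[2], tv[3]), c(tv[3], tv[1]))
    cut <- Filter(function(p) sgn[p[1]] != sgn[p[2]], e)
    keys <- vapply(cut, function(p) edge_cut(p[1], p[2]), "")
    seg_from[q] <- keys[1L]
    seg_to[q] <- keys[2L]
  }
  # chain: each edge key appears in exactly two segments (watertight mesh)
  adj <- split(c(seq_along(crossing), seq_along(crossing)),
               c(seg_from, seg_to))
  visited <- logical(length(crossing))
  loops <- list()
  for (start in seq_along(crossing)) {
    if (visited[start]) next
    loop_keys <- character(0)
    cur <- start
    key <- seg_from[cur]
    repeat {
      visited[cur] <- TRUE
      loop_keys <- c(loop_keys, key)
      key <- if (seg_from[cur] == key) seg_to[cur] else seg_from[cur]
      nxt <- setdiff(adj[[key]], cur)
      nxt <- nxt[!visited[nxt]]
      if (length(nxt) == 0L) break
      cur <- nxt[1L]
    }
    loop3d <- do.call(rbind, lapply(loop_keys, function(k) pts[[k]]))
    loops[[length(loops) + 1L]] <- plane_project(plane, loop3d)
  }
  loops
}

loop_perimeter <- function(uv) {
  sum(sqrt(rowSums((uv - uv[c(2:nrow(uv), 1L), , drop = FALSE])^2)))
}

#' Sample constraint curves from a ground-truth surface
#'
#' For each plane of the plan, intersects the target surface, takes the
#' largest closed loop, subsamples it at `n_control` equally spaced arc-length
#' positions, and adds seeded uniform jitter — emulating a user clicking
#' control points on the boundary of the target organ.
#'
#' @param mesh a watertight [triangle_mesh()] (the ground-truth target).
#' @param planes list of [cross_section_plane()].
#' @param n_control control points per curve (>= 3).
#' @param frame 0-based frame index stored on the curves (or `NULL`).
#' @param jitter_mm uniform jitter amplitude per coordinate (mm).
#' @param seed integer seed for the jitter (no jitter when 0).
#' @param id_prefix identifier prefix for the generated curves.
#' @return list of [curve_constraint()] objects (closed).
#' @export
sample_constraint_curves <- function(mesh, planes, n_control = 8L,
                                     frame = NULL, jitter_mm = 0,
                                     seed = 1L, id_prefix = "gt") {
  stopifnot(n_control >= 3L)
  if (jitter_mm > 0) set.seed(seed)
  out <- vector("list", length(planes))
  for (i in seq_along(planes)) {
    loops <- cross_section_loops(mesh, planes[[i]])
    loop <- loops[[which.max(vapply(loops, loop_perimeter, 0))]]
    arc <- c(0, cumsum(sqrt(rowSums(diff(rbind(loop, loop[1L, ]))^2))))
    L <- arc[length(arc)]
    pos <- L * (0:(n_control - 1L)) / n_control
    closed_loop <- rbind(loop, loop[1L, ])
    cp <- cbind(approx(arc, closed_loop[, 1L], xout = pos, ties = "ordered")$y,
                approx(arc, closed_loop[, 2L], xout = pos, ties = "ordered")$y)
    if (jitter_mm > 0)
      cp <- cp + matrix(runif(length(cp), -jitter_mm, jitter_mm), ncol = 2L)
    out[[i]] <- curve_constraint(sprintf("%s_%s%g_f%s", id_prefix,
                                         planes[[i]]$axis,
                                         planes[[i]]$offset_mm,
                                         if (is.null(frame)) "s" else frame),
                                 planes[[i]], cp, closed = TRUE, frame = frame)
  }
  out
}

#' Rasterize ground-truth label volumes
#'
#' @param meshes list of watertight target meshes (one per frame).
#' @param grid a [reference_grid()].
#' @return list of `label_volume` objects.
#' @export
rasterize_phantom_labels <- function(meshes, grid) {
  lapply(meshes, voxelize_mesh, grid = grid)
}

#' Build a complete synthetic segmentation job with ground truth
#'
#' Generates the template, binds it, creates the ground-truth sequence,
#' samples jittered constraint curves from every ground-truth frame, sizes a
#' reference grid around the motion, and assembles a [segmentation_job()].
#'
#' @param spec a [phantom_spec()].
#' @param resolution harmonic-binding grid resolution.
#' @param spacing_mm label-grid voxel spacing (default 1 mm).
#' @param params [fitting_parameters()] for the job.
#' @param interval resampling interval (mm).
#' @return list with `job`, `template`, `ground_truth` (cages + meshes +
#'   labels), `grid`, and the `spec` (manifest of every parameter).
#' @export
make_phantom_job <- function(spec, resolution = 48L, spacing_mm = 1.0,
                             params = fitting_parameters(), interval = 1.0) {
  template <- bind_template(make_template(spec), resolution = resolution)
  gt <- make_ground_truth_sequence(template, spec)
  curves <- list()
  for (t in seq_len(spec$n_frames) - 1L) {
    cvs <- sample_constraint_curves(gt$meshes[[t + 1L]], spec$planes,
                                    n_control = spec$n_control, frame = t,
                                    jitter_mm = spec$jitter_mm,
                                    seed = spec$seed + t)
    curves <- c(curves, cvs)
  }
  allv <- do.call(rbind, lapply(gt$meshes, `[[`, "vertices"))
  bmin <- floor(apply(allv, 2L, min) - 2)
  bmax <- ceiling(apply(allv, 2L, max) + 2)
  grid <- reference_grid(ceiling((bmax - bmin) / spacing_mm) + 1L,
                         rep(spacing_mm, 3L), bmin)
  job <- segmentation_job(template, spec$n_frames, curves = curves,
                          params = params, grid = grid, interval = interval)
  list(job = job, template = template,
       ground_truth = c(gt, list(labels = rasterize_phantom_labels(gt$meshes,
                                                                   grid))),
       grid = grid, spec = spec)
}
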