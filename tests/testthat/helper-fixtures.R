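# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# Axis-aligned unit-cube triangle mesh (12 triangles, watertight, outward).
cube_mesh <- function(lo = c(0, 0, 0), hi = c(1, 1, 1)) {
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  # vertex order: (x fastest) 1:(0,0,0) 2:(1,0,0) 3:(0,1,0) 4:(1,1,0)
  #               5:(0,0,1) 6:(1,0,1) 7:(0,1,1) 8:(1,1,1)
  f <- rbind(c(1, 3, 2), c(2, 3, 4),    # z = lo
             c(5, 6, 7), c(6, 8, 7),    # z = hi
             c(1, 2, 5), c(2, 6, 5),    # y = lo
             c(3, 7, 4), c(4, 7, 8),    # y = hi
             c(1, 5, 3), c(3, 5, 7),    # x = lo
             c(2, 4, 6), c(4, 8, 6))    # x = hi
  triangle_mesh(v, f, id = "cube")
}

# The standard binding fixture: icosphere radius 20 in a 46 mm cube cage.
sphere_cube_cage <- function() {
  cached("sphere_cube_cage",
         box_lattice_cage(c(-23, -23, -23), c(23, 23, 23)))
}

sphere_template <- function(resolution = 32L, subdivisions = 2L) {
  key <- sprintf("sphere_template_%d_%d", resolution, subdivisions)
  cached(key, bind_template(
    template_model(icosphere(20, subdivisions), sphere_cube_cage()),
    resolution = resolution))
}

# Uniform points on an axis-aligned ellipse polyline (dense), as a 3D matrix.
ellipse_contour <- function(a, b, plane, n = 64) {
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  pl <- cbind(a * cos(th), b * sin(th))
  poly <- structure(list(points = plane_lift_test(plane, pl), closed = TRUE,
                         plane = plane, id = "ellipse"),
                    class = "curve_polyline")
  L <- sum(sqrt(rowSums(diff(rbind(poly$points, poly$points[1, ]))^2)))
  resample_equal_interval(poly, interval = L / n)
}

# In-plane lift mirroring the package convention (kept separate so curve
# tests do not depend on the internal helper they verify).
plane_lift_test <- function(plane, uv) {
  o <- plane$offset_mm
  switch(plane$axis,
         XY = cbind(uv[, 1], uv[, 2], o),
         YZ = cbind(o, uv[, 1], uv[, 2]),
         ZX = cbind(uv[, 2], o, uv[, 1]))
}

# Three orthogonal contours of the (24, 20, 16) ellipsoid, 64 samples each:
# the shape-recovery fixture.
ellipsoid_contours <- function(n = 64) {
  p1 <- ellipse_contour(24, 20, cross_section_plane("XY", 0), n)
  p2 <- ellipse_contour(20, 16, cross_section_plane("YZ", 0), n)
  p3 <- ellipse_contour(16, 24, cross_section_plane("ZX", 0), n)
  constraint_point_set(rbind(p1$points, p2$points, p3$points),
                       c(p1$source, p2$source, p3$source))
}

# Independent closest-point-on-triangle oracle: candidate enumeration
# (interior critical point, the three edge projections, the three vertices).
oracle_closest_point <- function(V, F, q) {
  best <- Inf
  foot <- NULL
  for (t in seq_len(nrow(F))) {
    a <- V[F[t, 1], ]; b <- V[F[t, 2], ]; cc <- V[F[t, 3], ]
    cand <- list(a, b, cc)
    # interior: solve the 2x2 normal equations of min |a + u*e1 + v*e2 - q|
    e1 <- b - a; e2 <- cc - a
    G <- rbind(c(sum(e1 * e1), sum(e1 * e2)), c(sum(e1 * e2), sum(e2 * e2)))
    if (abs(det(G)) > 1e-14) {
      uv <- solve(G, c(sum(e1 * (q - a)), sum(e2 * (q - a))))
      if (uv[1] >= 0 && uv[2] >= 0 && sum(uv) <= 1)
        cand <- c(cand, list(a + uv[1] * e1 + uv[2] * e2))
    }
    for (e in list(list(a, b), list(b, cc), list(cc, a))) {
      d <- e[[2]] - e[[1]]
      s <- sum((q - e[[1]]) * d) / sum(d * d)
      s <- min(max(s, 0), 1)
      cand <- c(cand, list(e[[1]] + s * d))
    }
    for (p in cand) {
      dd <- sum((q - p)^2)
      if (dd < best) { best <- dd; foot <- p }
    }
  }
  list(foot = foot, dist = sqrt(best))
}

# Independent dense oracle for the regularized cage update: stacked
# least-squares [sqrt(alpha) W; sqrt(beta) I; sqrt(gamma) L] solved per axis
# with qr.solve.
oracle_cage_update <- function(W, cage0, targets, alpha, beta, gamma, L) {
  nc <- nrow(cage0)
  A <- rbind(sqrt(alpha) * W, sqrt(beta) * diag(nc), sqrt(gamma) * L)
  out <- matrix(0, nc, 3)
  for (ax in 1:3) {
    b <- c(sqrt(alpha) * targets[, ax], sqrt(beta) * cage0[, ax],
           sqrt(gamma) * as.numeric(L %*% cage0[, ax]))
    out[, ax] <- qr.solve(A, b)
  }
  out
}

# A synthetic binding with hand-set weights (rows sum to 1), for small
# fitting instances that do not need a real harmonic solve.
synthetic_binding <- function(W) {
  structure(list(weights = W, provenance = list(synthetic = TRUE)),
            class = "harmonic_binding")
}

random_fitting_instance <- function(seed) {
  set.seed(seed)
  cg <- if (seed %% 2 == 0)
    box_lattice_cage(c(0, 0, 0), c(10, 10, 10))            # 8 vertices
  else box_lattice_cage(c(0, 0, 0), c(20, 10, 10), c(2, 1, 1))  # 12 vertices
  nc <- nrow(cg$vertices)
  nm <- 8L
  W <- matrix(runif(nm * nc), nm, nc)
  W <- W / rowSums(W)
  verts <- W %*% cg$vertices
  tris <- matrix(0L, 6L, 3L)
  for (i in 1:6) tris[i, ] <- sample(nm, 3L)
  np <- sample(5:50, 1L)
  tri_id <- sample(6L, np, replace = TRUE)
  bary <- matrix(runif(np * 3), np, 3)
  bary <- bary / rowSums(bary)
  targets <- matrix(runif(np * 3, 0, 12), np, 3)
  foot <- bary[, 1] * verts[tris[tri_id, 1], , drop = FALSE] +
    bary[, 2] * verts[tris[tri_id, 2], , drop = FALSE] +
    bary[, 3] * verts[tris[tri_id, 3], , drop = FALSE]
  assoc <- structure(list(triangle = tri_id, bary = bary, foot = foot,
                          dist = sqrt(rowSums((foot - targets)^2))),
                     class = "closest_point_association")
  list(cage = cg, binding = synthetic_binding(W), triangles = tris,
       assoc = assoc, targets = constraint_point_set(targets))
}
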