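#' Axis-aligned cross-section plane
#'
#' One of the three orthogonal cross-sections on which constraint curves are
#' drawn.  In-plane (u,v) axes are the two world axes of the plane in
#' ascending order: XY -> (x,y) with offset along z, YZ -> (y,z) with offset
#' along x, ZX -> (z,x) with offset along y.
#'
#' @param axis one of "XY", "YZ", "ZX".
#' @param offset_mm position of the plane along its orthogonal axis (mm).
#' @return an object of class `cross_section_plane`.
#' @export
cross_section_plane <- function(axis, offset_mm) {
  axis <- match.arg(axis, c("XY", "YZ", "ZX"))
  structure(list(axis = axis, offset_mm = as.numeric(offset_mm)),
            class = "cross_section_plane")
}

# Lift in-plane (u,v) points to 3D world coordinates (exactly on the plane).
plane_lift <- function(plane, uv) {
  uv <- as.matrix(uv)
  o <- plane$offset_mm
  switch(plane$axis,
         XY = cbind(uv[, 1L], uv[, 2L], o),
         YZ = cbind(o, uv[, 1L], uv[, 2L]),
         ZX = cbind(uv[, 2L], o, uv[, 1L]))
}

# Project world points to in-plane (u,v) coordinates.
plane_project <- function(plane, xyz) {
  xyz <- as.matrix(xyz)
  switch(plane$axis,
         XY = xyz[, c(1L, 2L), drop = FALSE],
         YZ = xyz[, c(2L, 3L), drop = FALSE],
         ZX = xyz[, c(3L, 1L), drop = FALSE])
}

# 1-based index of the world axis orthogonal to the plane.
plane_normal_axis <- function(plane) {
  switch(plane$axis, XY = 3L, YZ = 1L, ZX = 2L)
}

#' Planar curve constraint
#'
#' An ordered set of control points on a cross-section plane, interpolated by
#' a kappa-curve.  At least three distinct control points are required.
#'
#' @param id character identifier.
#' @param plane a [cross_section_plane()].
#' @param control_points `n x 2` matrix of in-plane (u,v) points (mm),
#'   `n >= 3`.
#' @param closed logical; is the curve a closed loop?
#' @param frame 0-based frame index, or `NULL` for a curve used outside a
#'   sequence (shared curves carry keyframes instead, see [shared_curve()]).
#' @return an object of class `curve_constraint`.
#' @export
curve_constraint <- function(id, plane, control_points, closed = TRUE,
                             frame = NULL) {
  stopifnot(inherits(plane, "cross_section_plane"))
  cp <- as.matrix(control_points)
  storage.mode(cp) <- "double"
  if (ncol(cp) != 2L) stop("control points must be n x 2 (in-plane)")
  if (nrow(cp) < 3L)
    stop("under-specified curve: need at least 3 control points")
  if (anyDuplicated(round(cp, 9)))
    stop("degenerate curve: duplicate control points")
  structure(list(id = as.character(id), plane = plane, control_points = cp,
                 closed = isTRUE(closed),
                 frame = if (is.null(frame)) NULL else as.integer(frame)),
            class = "curve_constraint")
}

#' Shared curve with temporal keyframes
#'
#' A constraint curve duplicated across all frames of a sequence.  Its shape
#' is given at explicit keyframes (frames the user edited) and linearly
#' interpolated in between; outside the keyframe range the nearest keyframe
#' is held constant.  All keyframes must have the same number of control
#' points so interpolation is pointwise.
#'
#' @param id character identifier.
#' @param plane a [cross_section_plane()].
#' @param keyframes named list: names are 0-based frame indices, values
#'   `n x 2` control-point matrices of a common `n >= 3`.
#' @param closed logical closed flag shared by all keyframes.
#' @return an object of class `shared_curve`.
#' @export
shared_curve <- function(id, plane, keyframes, closed = TRUE) {
  stopifnot(inherits(plane, "cross_section_plane"), length(keyframes) >= 1L)
  tt <- as.integer(names(keyframes))
  if (anyNA(tt)) stop("keyframe names must be frame indices")
  keyframes <- lapply(keyframes, function(m) {
    m <- as.matrix(m); storage.mode(m) <- "double"; m
  })
  counts <- vapply(keyframes, nrow, 1L)
  if (length(unique(counts)) != 1L)
    stop("shared-curve keyframes must all have the same control-point count")
  if (counts[1L] < 3L) stop("shared curve needs at least 3 control points")
  ord <- order(tt)
  structure(list(id = as.character(id), plane = plane,
                 keyframes = setNames(keyframes[ord], tt[ord]),
                 closed = isTRUE(closed)),
            class = "shared_curve")
}

#' Realize a shared curve at a frame
#'
#' Keyframes are returned verbatim; between two keyframes each control point
#' is the pointwise linear blend with weight `(t - t0) / (t1 - t0)`; before
#' the first and after the last keyframe the nearest keyframe is held.
#'
#' @param shared a [shared_curve()].
#' @param t 0-based frame index.
#' @param n_frames total number of frames in the sequence.
#' @return a [curve_constraint()] for frame `t`.
#' @export
realize_shared_curve <- function(shared, t, n_frames) {
  stopifnot(inherits(shared, "shared_curve"))
  if (t < 0 || t >= n_frames) stop("frame index out of range")
  keys <- as.integer(names(shared$keyframes))
  if (t <= keys[1L]) {
    cp <- shared$keyframes[[1L]]
  } else if (t >= keys[length(keys)]) {
    cp <- shared$keyframes[[length(keys)]]
  } else if (t %in% keys) {
    cp <- shared$keyframes[[match(t, keys)]]
  } else {
    i1 <- findInterval(t, keys)
    t0 <- keys[i1]; t1 <- keys[i1 + 1L]
    w <- (t - t0) / (t1 - t0)
    cp <- (1 - w) * shared$keyframes[[i1]] + w * shared$keyframes[[i1 + 1L]]
  }
  curve_constraint(shared$id, shared$plane, cp, shared$closed, frame = t)
}

# ---------------------------------------------------------------------------
# kappa-curve interpolation
#
# Piecewise quadratic Beziers through the control points, with each control
# point the curvature extremum of its own segment, G1 joints on the segments
# between consecutive middle control points, and joint parameters chosen to
# equalize curvature across joints.  Computed by the standard local/global
# fixed-point iteration: (i) joint ratios lambda from square-rooted triangle
# areas, (ii) extremal parameters t from the closed form for quadratics,
# (iii) a (cyclic) tridiagonal solve for the middle control points so every
# input point is interpolated.

bezier_eval <- function(c0, c1, c2, t) {
  outer((1 - t)^2, c0) + outer(2 * t * (1 - t), c1) + outer(t^2, c2)
}

kappa_curve_2d <- function(P, closed, tol = 1e-6, maxit = 50L) {
  n <- nrow(P)
  area <- function(a, b, c)
    abs((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])) / 2
  # Parameter at which the segment from c0 to c2 must interpolate p so that
  # p is the curvature extremum: substituting the interpolation constraint
  # into the extremum condition gives a cubic in t with a single [0,1] root
  # (e = c0 - p, D = c2 - c0):
  #   |D|^2 t^3 + 3<e,D> t^2 + (2|e|^2 - <e,D>) t - |e|^2 = 0.
  ext_t <- function(c0, c2, p) {
    e <- c0 - p
    D <- c2 - c0
    co <- c(-sum(e * e), 2 * sum(e * e) - sum(e * D), 3 * sum(e * D),
            sum(D * D))
    if (all(abs(co) < 1e-14)) return(0.5)
    roots <- polyroot(co)
    real <- Re(roots[abs(Im(roots)) < 1e-7 * max(1, Mod(roots))])
    real <- real[real > -1e-9 & real < 1 + 1e-9]
    rt <- if (length(real)) real[which.min(abs(real - 0.5))] else 0.5
    min(max(rt, 1e-4), 1 - 1e-4)
  }
  if (closed) {
    s <- n                       # one segment per control point
    m <- P                       # middle control points, initialized at P
    lam <- rep(0.5, s)           # joint ratio between segment i and i+1
    ip1 <- c(2:s, 1L); im1 <- c(s, 1:(s - 1L))
    for (iter in seq_len(maxit)) {
      q <- (1 - lam) * m + lam * m[ip1, , drop = FALSE]  # joints q_i
      c0 <- q[im1, , drop = FALSE]
      # lambda update from curvature equality at the joints
      A1 <- vapply(1:s, function(i) area(c0[i, ], m[i, ], m[ip1[i], ]), 0)
      A2 <- vapply(1:s, function(i)
        area(m[i, ], m[ip1[i], ], q[ip1[i], ]), 0)
      den <- sqrt(A1) + sqrt(A2)
      lam <- ifelse(den > 1e-12, sqrt(A1) / den, 0.5)
      q <- (1 - lam) * m + lam * m[ip1, , drop = FALSE]
      c0 <- q[im1, , drop = FALSE]
      tpar <- vapply(1:s, function(i) ext_t(c0[i, ], q[i, ], P[i, ]), 0)
      # interpolation system: P_i = (1-t)^2 q_{i-1} + 2t(1-t) m_i + t^2 q_i
      M <- matrix(0, s, s)
      for (i in 1:s) {
        ti <- tpar[i]
        M[i, im1[i]] <- M[i, im1[i]] + (1 - ti)^2 * (1 - lam[im1[i]])
        M[i, i] <- M[i, i] + (1 - ti)^2 * lam[im1[i]] + 2 * ti * (1 - ti) +
          ti^2 * (1 - lam[i])
        M[i, ip1[i]] <- M[i, ip1[i]] + ti^2 * lam[i]
      }
      m_new <- solve(M, P)
      delta <- max(abs(m_new - m))
      m <- m_new
      if (delta < tol) break
    }
    q <- (1 - lam) * m + lam * m[ip1, , drop = FALSE]
    list(c0 = q[im1, , drop = FALSE], c1 = m, c2 = q, tpar = tpar)
  } else {
    s <- n - 2L                  # segments for interior points p_2..p_{n-1}
    Pi <- P[2:(n - 1L), , drop = FALSE]
    m <- Pi
    if (s == 1L) {
      # single segment with pinned ends
      ti <- ext_t(P[1, ], P[3, ], P[2, ])
      m[1, ] <- (Pi[1, ] - (1 - ti)^2 * P[1, ] - ti^2 * P[3, ]) /
        (2 * ti * (1 - ti))
      return(list(c0 = P[1, , drop = FALSE], c1 = m,
                  c2 = P[3, , drop = FALSE], tpar = ti))
    }
    lam <- rep(0.5, s - 1L)      # joints between consecutive segments
    for (iter in seq_len(maxit)) {
      q <- (1 - lam) * m[1:(s - 1L), , drop = FALSE] +
        lam * m[2:s, , drop = FALSE]
      c0 <- rbind(P[1, ], q)
      c2 <- rbind(q, P[n, ])
      A1 <- vapply(1:(s - 1L), function(i) area(c0[i, ], m[i, ], m[i + 1L, ]), 0)
      A2 <- vapply(1:(s - 1L), function(i)
        area(m[i, ], m[i + 1L, ], c2[i + 1L, ]), 0)
      den <- sqrt(A1) + sqrt(A2)
      lam <- ifelse(den > 1e-12, sqrt(A1) / den, 0.5)
      q <- (1 - lam) * m[1:(s - 1L), , drop = FALSE] +
        lam * m[2:s, , drop = FALSE]
      c0 <- rbind(P[1, ], q)
      c2 <- rbind(q, P[n, ])
      tpar <- vapply(1:s, function(i) ext_t(c0[i, ], c2[i, ], Pi[i, ]), 0)
      M <- matrix(0, s, s)
      rhs <- Pi
      for (i in 1:s) {
        ti <- tpar[i]
        # c0 term
        if (i == 1L) {
          rhs[i, ] <- rhs[i, ] - (1 - ti)^2 * P[1, ]
        } else {
          M[i, i - 1L] <- M[i, i - 1L] + (1 - ti)^2 * (1 - lam[i - 1L])
          M[i, i] <- M[i, i] + (1 - ti)^2 * lam[i - 1L]
        }
        M[i, i] <- M[i, i] + 2 * ti * (1 - ti)
        # c2 term
        if (i == s) {
          rhs[i, ] <- rhs[i, ] - ti^2 * P[n, ]
        } else {
          M[i, i] <- M[i, i] + ti^2 * (1 - lam[i])
          M[i, i + 1L] <- M[i, i + 1L] + ti^2 * lam[i]
        }
      }
      m_new <- solve(M, rhs)
      delta <- max(abs(m_new - m))
      m <- m_new
      if (delta < tol) break
    }
    q <- (1 - lam) * m[1:(s - 1L), , drop = FALSE] +
      lam * m[2:s, , drop = FALSE]
    list(c0 = rbind(P[1, ], q), c1 = m, c2 = rbind(q, P[n, ]), tpar = tpar)
  }
}

# Centripetal Catmull-Rom fallback (debugging aid to isolate curve-model
# effects); returns the same Bezier-segment structure via a cubic-to-... no:
# we sample it directly, so it returns a dense polyline instead.
catmull_rom_2d <- function(P, closed, samples_per_segment) {
  n <- nrow(P)
  idx <- if (closed) function(i) ((i - 1L) %% n) + 1L else
    function(i) min(max(i, 1L), n)
  segs <- if (closed) n else n - 1L
  out <- NULL
  for (i in seq_len(segs)) {
    p0 <- P[idx(i - 1L), ]; p1 <- P[idx(i), ]
    p2 <- P[idx(i + 1L), ]; p3 <- P[idx(i + 2L), ]
    tk <- function(a, b) sqrt(sqrt(sum((b - a)^2)))
    t0 <- 0; t1 <- t0 + max(tk(p0, p1), 1e-9)
    t2 <- t1 + max(tk(p1, p2), 1e-9); t3 <- t2 + max(tk(p2, p3), 1e-9)
    tt <- seq(t1, t2, length.out = samples_per_segment + 1L)
    if (i < segs || closed) tt <- tt[-length(tt)]
    seg <- t(vapply(tt, function(s) {
      A1 <- (t1 - s) / (t1 - t0) * p0 + (s - t0) / (t1 - t0) * p1
      A2 <- (t2 - s) / (t2 - t1) * p1 + (s - t1) / (t2 - t1) * p2
      A3 <- (t3 - s) / (t3 - t2) * p2 + (s - t2) / (t3 - t2) * p3
      B1 <- (t2 - s) / (t2 - t0) * A1 + (s - t0) / (t2 - t0) * A2
      B2 <- (t3 - s) / (t3 - t1) * A2 + (s - t1) / (t3 - t1) * A3
      (t2 - s) / (t2 - t1) * B1 + (s - t1) / (t2 - t1) * B2
    }, numeric(2)))
    out <- rbind(out, seg)
  }
  out
}

#' Interpolate a constraint curve into a dense polyline
#'
#' Fits the kappa-curve through the control points (piecewise quadratic
#' Beziers whose middle control points are optimized by fixed-point iteration
#' so that every control point is the curvature extremum of its segment) and
#' samples it densely.  The result passes through every control point in
#' order and is G1-continuous; closed curves wrap.
#'
#' @param constraint a [curve_constraint()].
#' @param samples_per_segment dense samples per Bezier segment (default 64).
#' @param method `"kappa"` (default) or `"catmullrom"` (centripetal
#'   Catmull-Rom fallback, useful to isolate curve-model effects).
#' @param tol fixed-point tolerance on middle control points (mm).
#' @param maxit fixed-point iteration cap.
#' @return an object of class `curve_polyline`: `points` (`n x 3`, world mm,
#'   exactly on the plane), `closed`, `plane`, `id`.
#' @export
interpolate_curve <- function(constraint, samples_per_segment = 64L,
                              method = c("kappa", "catmullrom"),
                              tol = 1e-6, maxit = 50L) {
  stopifnot(inherits(constraint, "curve_constraint"))
  method <- match.arg(method)
  P <- constraint$control_points
  closed <- constraint$closed
  d <- sqrt(rowSums((P - P[c(2:nrow(P), 1L), , drop = FALSE])^2))
  if (!closed) d <- d[-length(d)]
  if (any(d < 1e-12)) stop("degenerate curve: duplicate consecutive points")
  if (method == "kappa") {
    bez <- kappa_curve_2d(P, closed, tol = tol, maxit = maxit)
    s <- nrow(bez$c1)
    pts <- NULL
    for (i in seq_len(s)) {
      # include the interpolation parameter so every control point is a
      # polyline vertex (the interpolation property holds exactly)
      tt <- sort(unique(c(seq(0, 1, length.out = samples_per_segment + 1L),
                          bez$tpar[i])))
      if (i < s || closed) tt <- tt[-length(tt)]
      pts <- rbind(pts, bezier_eval(bez$c0[i, ], bez$c1[i, ], bez$c2[i, ], tt))
    }
  } else {
    pts <- catmull_rom_2d(P, closed, samples_per_segment)
  }
  structure(list(points = plane_lift(constraint$plane, pts), closed = closed,
                 plane = constraint$plane, id = constraint$id),
            class = "curve_polyline")
}

#' Resample a polyline at equal arc-length intervals
#'
#' Emits points at arc-length positions `0, d, 2d, ...` along the polyline.
#' For closed curves the last sample is dropped when it falls within `d/2` of
#' the start, so wrap-around spacing stays near `d`.
#'
#' @param polyline a `curve_polyline` from [interpolate_curve()], or a plain
#'   `n x 3` matrix (treated as open).
#' @param interval sampling interval `d` in mm (default 1).
#' @return a `constraint_point_set`: `points` (`N_p x 3`), `source` (curve id
#'   per point), `n` (`N_p`).
#' @export
resample_equal_interval <- function(polyline, interval = 1.0) {
  if (is.matrix(polyline))
    polyline <- structure(list(points = polyline, closed = FALSE,
                               plane = NULL, id = "polyline"),
                          class = "curve_polyline")
  stopifnot(interval > 0)
  pts <- polyline$points
  if (polyline$closed) pts <- rbind(pts, pts[1L, ])
  seg <- sqrt(rowSums(diff(pts)^2))
  arc <- c(0, cumsum(seg))
  L <- arc[length(arc)]
  if (interval >= L) {
    warning("interval >= curve length; returning endpoints only")
    out <- pts[c(1L, nrow(pts)), , drop = FALSE]
    return(constraint_point_set(out, rep(polyline$id, nrow(out))))
  }
  if (polyline$closed) {
    pos <- interval * seq(0L, floor((L - 1e-9 * L) / interval))
    gap <- L - pos[length(pos)]
    if (gap < interval / 2) pos <- pos[-length(pos)]
  } else {
    pos <- interval * seq(0L, floor(L / interval + 1e-9))
  }
  out <- cbind(approx(arc, pts[, 1L], xout = pos, ties = "ordered")$y,
               approx(arc, pts[, 2L], xout = pos, ties = "ordered")$y,
               approx(arc, pts[, 3L], xout = pos, ties = "ordered")$y)
  constraint_point_set(out, rep(polyline$id, nrow(out)))
}

#' Constraint point set
#'
#' The resampled constraint points that drive the cage fitting.
#'
#' @param points `N_p x 3` matrix of world positions (mm).
#' @param source character vector of source curve identifiers, one per point.
#' @return an object of class `constraint_point_set`.
#' @export
constraint_point_set <- function(points, source = rep("?", nrow(points))) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L, length(source) == nrow(points))
  structure(list(points = points, source = as.character(source),
                 n = nrow(points)),
            class = "constraint_point_set")
}

#' @export
print.constraint_point_set <- function(x, ...) {
  cat(sprintf("<constraint_point_set> %d points from %d curve(s)\n",
              x$n, length(unique(x$source))))
  invisible(x)
}

#' Assemble all constraint points for one frame
#'
#' Realizes every shared curve at frame `t`, merges with the frame-local
#' curves of `t`, interpolates each with the kappa-curve, resamples at equal
#' intervals, and concatenates into one constraint point set.
#'
#' @param curves list of frame-local [curve_constraint()] objects (their
#'   `frame` field selects the frame they apply to).
#' @param shared list of [shared_curve()] objects (apply to every frame).
#' @param t 0-based frame index.
#' @param n_frames total frame count.
#' @param interval resampling interval `d` in mm (default 1).
#' @param samples_per_segment dense samples per curve segment.
#' @param method curve model passed to [interpolate_curve()].
#' @return a `constraint_point_set`.
#' @export
collect_frame_constraints <- function(curves, shared, t, n_frames,
                                      interval = 1.0,
                                      samples_per_segment = 64L,
                                      method = "kappa") {
  local <- Filter(function(cv) !is.null(cv$frame) && cv$frame == t, curves)
  realized <- lapply(shared, realize_shared_curve, t = t, n_frames = n_frames)
  all_curves <- c(local, realized)
  if (length(all_curves) == 0L)
    stop(sprintf("no constraint curves apply to frame %d", t))
  sets <- lapply(all_curves, function(cv) {
    resample_equal_interval(
      interpolate_curve(cv, samples_per_segment = samples_per_segment,
                        method = method),
      interval = interval)
  })
  constraint_point_set(do.call(rbind, lapply(sets, `[[`, "points")),
                       unlist(lapply(sets, `[[`, "source")))
}

# ---------------------------------------------------------------------------
# Curve-constraint JSON interchange
#
# {frames: N,
#  curves: [{id, plane: {axis, offset_mm}, closed, frame,
#            control_points_mm: [[u,v],...]}, ...],
#  shared_curves: [{id, plane, closed, keyframes: {"t": [[u,v],...]}}, ...]}

#' Read / write the curve-constraint JSON format
#'
#' @param path JSON file path.
#' @return `read_curves_json`: list with `frames` (count), `curves` (list of
#'   [curve_constraint()]), `shared` (list of [shared_curve()]).
#' @export
read_curves_json <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = FALSE)
  parse_plane <- function(p) cross_section_plane(p$axis, p$offset_mm)
  parse_cp <- function(lst)
    do.call(rbind, lapply(lst, function(x) as.numeric(unlist(x))))
  curves <- lapply(js$curves, function(cv) {
    curve_constraint(cv$id, parse_plane(cv$plane), parse_cp(cv$control_points_mm),
                     closed = isTRUE(cv$closed), frame = cv$frame)
  })
  shared <- lapply(js$shared_curves, function(sc) {
    shared_curve(sc$id, parse_plane(sc$plane),
                 lapply(sc$keyframes, parse_cp), closed = isTRUE(sc$closed))
  })
  list(frames = as.integer(js$frames), curves = curves, shared = shared)
}

#' @rdname read_curves_json
#' @param frames total frame count of the sequence.
#' @param curves list of [curve_constraint()] objects.
#' @param shared list of [shared_curve()] objects.
#' @export
write_curves_json <- function(path, frames, curves = list(), shared = list()) {
  enc_plane <- function(p) list(axis = p$axis, offset_mm = p$offset_mm)
  enc_cp <- function(m) lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
  js <- list(
    frames = as.integer(frames),
    curves = lapply(curves, function(cv)
      list(id = cv$id, plane = enc_plane(cv$plane), closed = cv$closed,
           frame = cv$frame, control_points_mm = enc_cp(cv$control_points))),
    shared_curves = lapply(shared, function(sc)
      list(id = sc$id, plane = enc_plane(sc$plane), closed = sc$closed,
           keyframes = lapply(sc$keyframes, enc_cp))))
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
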