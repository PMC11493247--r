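test_that("kappa interpolation passes through control points in order", {
  # property over several seeded closed and open configurations
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(4:10, 1)
    th <- sort(runif(n, 0, 2 * pi))
    P <- (8 + runif(n, -2, 2)) * cbind(cos(th), sin(th))
    for (closed in c(TRUE, FALSE)) {
      cv <- curve_constraint("p", cross_section_plane("XY", 3), P, closed)
      pl <- interpolate_curve(cv)
      err <- vapply(seq_len(n), function(k)
        min(sqrt(rowSums(sweep(pl$points[, 1:2, drop = FALSE], 2, P[k, ])^2))),
        0)
      expect_lt(max(err), 1e-6)
      expect_true(all(pl$points[, 3] == 3))   # planarity is exact
    }
  }
})

test_that("equilateral-triangle curve has 3-fold symmetry", {
  P <- 10 * rbind(c(0, 1), c(-sqrt(3) / 2, -0.5), c(sqrt(3) / 2, -0.5))
  pl <- interpolate_curve(curve_constraint("t", cross_section_plane("XY", 0),
                                           P, TRUE),
                          samples_per_segment = 128)
  R120 <- matrix(c(cos(2 * pi / 3), sin(2 * pi / 3),
                   -sin(2 * pi / 3), cos(2 * pi / 3)), 2, 2)
  rotated <- pl$points[, 1:2] %*% t(R120)
  # rotated curve coincides with the original as a point set
  d <- vapply(seq_len(nrow(rotated)), function(i)
    min(sqrt(rowSums(sweep(pl$points[, 1:2], 2, rotated[i, ])^2))), 0)
  expect_lt(max(d), 0.02)
})

test_that("collinear control points give a straight segment", {
  P <- cbind(c(0, 1, 2.5, 4), c(0, 2, 5, 8))
  pl <- interpolate_curve(curve_constraint("l", cross_section_plane("YZ", 1),
                                           P, FALSE))
  expect_lt(max(abs(pl$points[, 3] - 2 * pl$points[, 2])), 1e-6)
  expect_true(all(pl$points[, 1] == 1))
})

test_that("kappa curve through 8 circle points stays near the circle", {
  th <- 2 * pi * (0:7) / 8
  pl <- interpolate_curve(curve_constraint("c", cross_section_plane("XY", 0),
                                           10 * cbind(cos(th), sin(th)), TRUE))
  r <- sqrt(rowSums(pl$points[, 1:2]^2))
  expect_lt(max(abs(r - 10)), 0.2)
})

test_that("degenerate curves are rejected", {
  pl <- cross_section_plane("XY", 0)
  expect_error(curve_constraint("x", pl, rbind(c(0, 0), c(1, 1))), "3 control")
  expect_error(curve_constraint("x", pl, rbind(c(0, 0), c(1, 1), c(0, 0))),
               "duplicate")
})

test_that("equal-interval resampling matches arithmetic expectations", {
  seg <- cbind(seq(0, 10, length.out = 101), 0, 0)
  r <- resample_equal_interval(seg, 2)
  expect_equal(r$n, 6L)
  expect_equal(r$points[, 1], seq(0, 10, by = 2))

  sq <- structure(list(points = rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0),
                                      c(0, 10, 0)),
                       closed = TRUE, plane = NULL, id = "sq"),
                  class = "curve_polyline")
  rs <- resample_equal_interval(sq, 5)
  expect_equal(rs$n, 8L)
  sp <- sqrt(rowSums((rs$points - rs$points[c(2:8, 1), ])^2))
  expect_equal(sp, rep(5, 8))

  th <- seq(0, 2 * pi, length.out = 2001)[-2001]
  circ <- structure(list(points = cbind(10 * cos(th), 10 * sin(th), 0),
                         closed = TRUE, plane = NULL, id = "c"),
                    class = "curve_polyline")
  rc <- resample_equal_interval(circ, 1)
  expect_true(rc$n %in% c(62L, 63L))
  spc <- sqrt(rowSums(diff(rc$points)^2))   # excluding the wrap gap
  expect_lt(max(abs(spc - 1)), 0.01)

  expect_warning(r1 <- resample_equal_interval(seg, 50), "endpoints")
  expect_equal(r1$n, 2L)
})

test_that("shared curves interpolate keyframes linearly in time", {
  pl <- cross_section_plane("ZX", -4)
  kf0 <- rbind(c(0, 0), c(5, 0), c(5, 5))
  kf10 <- rbind(c(10, 0), c(15, 0), c(15, 5))
  sc <- shared_curve("s", pl, list("0" = kf0, "10" = kf10))
  mid <- realize_shared_curve(sc, 5, 20)
  expect_identical(mid$control_points, (kf0 + kf10) / 2)  # exact to 1e-12
  expect_identical(realize_shared_curve(sc, 0, 20)$control_points, kf0)
  expect_identical(realize_shared_curve(sc, 10, 20)$control_points, kf10)
  expect_identical(realize_shared_curve(sc, 15, 20)$control_points, kf10)

  single <- shared_curve("s1", pl, list("3" = kf0))
  for (t in c(0, 3, 7))
    expect_identical(realize_shared_curve(single, t, 8)$control_points, kf0)

  expect_error(shared_curve("bad", pl, list("0" = kf0, "5" = kf10[1:2, ])),
               "3 control|same control-point count")
  expect_error(shared_curve("bad", pl,
                            list("0" = kf0, "5" = rbind(kf10, c(9, 9)))),
               "same control-point count")
  expect_error(realize_shared_curve(sc, 25, 20), "range")
})

test_that("shared-curve realization is continuous and piecewise linear in t", {
  pl <- cross_section_plane("XY", 0)
  set.seed(3)
  kf <- list("0" = matrix(runif(8), 4), "6" = matrix(runif(8), 4),
             "9" = matrix(runif(8), 4))
  sc <- shared_curve("s", pl, kf)
  # exact linearity inside each keyframe interval
  for (tt in list(c(0, 3, 6), c(6, 7.5, 9))) {
    a <- realize_shared_curve(sc, tt[1], 10)$control_points
    m <- realize_shared_curve(sc, tt[2], 10)$control_points
    b <- realize_shared_curve(sc, tt[3], 10)$control_points
    expect_equal(m, (a + b) / 2, tolerance = 1e-12)
  }
  eps <- 1e-6
  d <- max(abs(realize_shared_curve(sc, 3 + eps, 10)$control_points -
                 realize_shared_curve(sc, 3, 10)$control_points))
  expect_lt(d, 1e-5)
})

test_that("collect_frame_constraints merges local and shared curves", {
  pl <- cross_section_plane("XY", 0)
  th <- 2 * pi * (0:5) / 6
  local <- curve_constraint("loc", pl, 10 * cbind(cos(th), sin(th)),
                            TRUE, frame = 2)
  sc <- shared_curve("sh", cross_section_plane("YZ", 0),
                     list("0" = 8 * cbind(cos(th), sin(th))))
  both <- collect_frame_constraints(list(local), list(sc), 2, 5)
  only_shared <- collect_frame_constraints(list(local), list(sc), 1, 5)
  local_only <- collect_frame_constraints(list(local), list(), 2, 5)
  expect_equal(both$n, only_shared$n + local_only$n)
  expect_gt(only_shared$n, 0)          # shared curves exist in all frames
  expect_error(collect_frame_constraints(list(local), list(), 1, 5),
               "no constraint curves")
  # resampled spacing uniform within 1% (per curve, excluding the wrap gap)
  pts <- local_only$points
  sp <- sqrt(rowSums(diff(pts)^2))
  expect_lt(max(abs(sp - 1)), 0.01)
})

test_that("catmull-rom fallback also interpolates its control points", {
  set.seed(4)
  th <- sort(runif(6, 0, 2 * pi))
  P <- 9 * cbind(cos(th), sin(th))
  pl <- interpolate_curve(curve_constraint("cr", cross_section_plane("XY", 0),
                                           P, TRUE),
                          method = "catmullrom")
  err <- vapply(seq_len(6), function(k)
    min(sqrt(rowSums(sweep(pl$points[, 1:2], 2, P[k, ])^2))), 0)
  expect_lt(max(err), 1e-9)   # control points are polyline vertices
})

test_that("curve-constraint JSON round-trips", {
  pl <- cross_section_plane("ZX", 12.5)
  th <- 2 * pi * (0:4) / 5
  cv <- curve_constraint("c1", pl, 7 * cbind(cos(th), sin(th)), TRUE,
                         frame = 3)
  sc <- shared_curve("s1", cross_section_plane("XY", -3),
                     list("0" = cbind(c(0, 1, 2), c(0, 1, 0)),
                          "4" = cbind(c(1, 2, 3), c(0, 1, 0))),
                     closed = FALSE)
  path <- withr::local_tempfile(fileext = ".json")
  write_curves_json(path, 10, curves = list(cv), shared = list(sc))
  back <- read_curves_json(path)
  expect_identical(back$frames, 10L)
  expect_equal(back$curves[[1]]$control_points, cv$control_points)
  expect_identical(back$curves[[1]]$frame, 3L)
  expect_identical(back$curves[[1]]$plane$axis, "ZX")
  expect_equal(back$shared[[1]]$keyframes, sc$keyframes)
  expect_false(back$shared[[1]]$closed)
})
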