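test_that("closest_point_on_mesh handles vertex, face and oracle cases", {
  m <- cube_mesh(c(0, 0, 0), c(2, 2, 2))
  at_vertex <- closest_point_on_mesh(m, m$vertices[8, ])
  expect_equal(at_vertex$dist, 0)
  expect_equal(sort(at_vertex$bary[1, ]), c(0, 0, 1))

  # orthogonal projection onto a face centroid
  tri <- m$triangles[1, ]
  centroid <- colMeans(m$vertices[tri, ])
  q <- centroid - c(0, 0, 1)                   # z = lo face, outward is -z
  hit <- closest_point_on_mesh(m, q)
  expect_equal(hit$foot[1, ], centroid, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(hit$bary[1, ], rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(hit$dist, 1)
})

test_that("closest points match the brute-force oracle on random queries", {
  set.seed(42)
  mesh <- tube_mesh(5, 30, 0.8, n_len = 10, n_seg = 9)   # 198 triangles
  mesh$vertices <- mesh$vertices + matrix(rnorm(length(mesh$vertices), 0, 0.1),
                                          nrow(mesh$vertices))
  q <- matrix(runif(3 * 40, -10, 35), ncol = 3)
  res <- closest_point_on_mesh(mesh, q)
  for (i in seq_len(nrow(q))) {
    o <- oracle_closest_point(mesh$vertices, mesh$triangles, q[i, ])
    expect_lt(abs(res$dist[i] - o$dist), 1e-9)
    expect_lt(max(abs(res$foot[i, ] - o$foot)), 1e-9)
  }
  # barycentric representation reconstructs the footpoint exactly
  tri <- mesh$triangles[res$triangle, ]
  recon <- res$bary[, 1] * mesh$vertices[tri[, 1], ] +
    res$bary[, 2] * mesh$vertices[tri[, 2], ] +
    res$bary[, 3] * mesh$vertices[tri[, 3], ]
  expect_lt(max(abs(recon - res$foot)), 1e-12)
  expect_true(all(res$bary >= 0) && max(abs(rowSums(res$bary) - 1)) < 1e-12)
})

test_that("degenerate triangles are reported", {
  bad <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(0, 1, 0)),
                       rbind(c(1, 2, 3), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)))
  expect_error(closest_point_on_mesh(bad, c(0, 0, 1)), "degenerate")
})

test_that("graph Laplacian is degree-normalized with zero row sums", {
  cg <- sphere_cube_cage()
  L <- as.matrix(graph_laplacian(cg))
  expect_equal(diag(L), rep(1, 8))
  expect_equal(rowSums(L), rep(0, 8))
  offdiag <- L - diag(8)
  expect_true(all(offdiag[offdiag != 0] == -1 / 3))   # cube valence 3
  expect_equal(rowSums(offdiag != 0), rep(3, 8), ignore_attr = TRUE)
  # translation invariance
  expect_equal(as.matrix(L %*% sweep(cg$vertices, 2, c(7, -2, 3), `+`)),
               as.matrix(L %*% cg$vertices), tolerance = 1e-12)
})

test_that("cage update is a fixed point on zero residuals and obeys beta limit", {
  inst <- random_fitting_instance(1)
  L <- graph_laplacian(inst$cage)
  zero_t <- constraint_point_set(inst$assoc$foot)
  for (par in list(fitting_parameters(), fitting_parameters(2, 0.5, 1))) {
    upd <- solve_cage_update(inst$binding, inst$cage$vertices, inst$assoc,
                             zero_t, par, L, inst$triangles)
    expect_lt(max(abs(upd - inst$cage$vertices)), 1e-6)
  }
  stiff <- fitting_parameters(1, 1e9, 5)
  upd <- solve_cage_update(inst$binding, inst$cage$vertices, inst$assoc,
                           inst$targets, stiff, L, inst$triangles)
  expect_lt(max(abs(upd - inst$cage$vertices)), 1e-6)
})

test_that("sparse cage update matches the dense normal-equations oracle", {
  for (seed in 1:20) {
    inst <- random_fitting_instance(seed)
    L <- graph_laplacian(inst$cage)
    par <- fitting_parameters()
    upd <- solve_cage_update(inst$binding, inst$cage$vertices, inst$assoc,
                             inst$targets, par, L, inst$triangles)
    A <- inst$binding$weights
    tri <- inst$triangles[inst$assoc$triangle, , drop = FALSE]
    W <- inst$assoc$bary[, 1] * A[tri[, 1], , drop = FALSE] +
      inst$assoc$bary[, 2] * A[tri[, 2], , drop = FALSE] +
      inst$assoc$bary[, 3] * A[tri[, 3], , drop = FALSE]
    oracle <- oracle_cage_update(W, inst$cage$vertices, inst$targets$points,
                                 par$alpha, par$beta, par$gamma, as.matrix(L))
    expect_lt(max(abs(upd - oracle)), 1e-9)
  }
})

test_that("cage update validates its inputs", {
  inst <- random_fitting_instance(2)
  L <- graph_laplacian(inst$cage)
  empty <- constraint_point_set(matrix(0, 0, 3), character(0))
  expect_error(solve_cage_update(inst$binding, inst$cage$vertices, inst$assoc,
                                 empty, fitting_parameters(), L,
                                 inst$triangles),
               "length|no constraint")
  bad <- inst$targets
  bad$points[1, 1] <- NaN
  expect_error(solve_cage_update(inst$binding, inst$cage$vertices, inst$assoc,
                                 bad, fitting_parameters(), L,
                                 inst$triangles),
               "non-finite")
  expect_error(fitting_parameters(alpha = 0), "alpha")
})

test_that("fitting leaves the cage fixed when constraints lie on the surface", {
  tmpl <- sphere_template()
  set.seed(5)
  dirs <- matrix(rnorm(300), ncol = 3)
  surf <- closest_point_on_mesh(deform_mesh(tmpl), 30 * dirs /
                                  sqrt(rowSums(dirs^2)))$foot
  fit <- fit_template_to_curves(tmpl, frame_state(0, tmpl$cage$vertices),
                                constraint_point_set(surf))
  expect_lt(max(abs(fit$state$cage_vertices - tmpl$cage$vertices)), 1e-6)
  expect_lt(fit$diagnostics$final_mean, 1e-7)
})

test_that("the quadratic objective descends at every solve step", {
  tmpl <- sphere_template()
  cps <- ellipsoid_contours(32)
  L <- graph_laplacian(tmpl$cage)
  cage0 <- tmpl$cage$vertices
  par <- fitting_parameters()
  for (it in 1:6) {
    mesh_t <- deform_mesh(tmpl, cage0)
    assoc <- closest_point_on_mesh(mesh_t, cps$points)
    before <- curvecage:::cage_objective(tmpl$binding, cage0, cage0, assoc,
                                         cps, par, L, tmpl$mesh$triangles)
    cage1 <- solve_cage_update(tmpl$binding, cage0, assoc, cps, par, L,
                               tmpl$mesh$triangles)
    after <- curvecage:::cage_objective(tmpl$binding, cage1, cage0, assoc,
                                        cps, par, L, tmpl$mesh$triangles)
    expect_lte(after, before + 1e-9)
    cage0 <- cage1
  }
})

test_that("fitting is rigidly equivariant and deterministic", {
  tmpl <- sphere_template()
  cps <- ellipsoid_contours(32)
  par <- fitting_parameters(iterations = 8)
  base <- fit_template_to_curves(tmpl, frame_state(0, tmpl$cage$vertices),
                                 cps, par)
  R <- rotation_about(c(1, 2, 3), 0.7)
  tv <- c(3, -2, 5)
  moved_state <- frame_state(0, sweep(tmpl$cage$vertices %*% t(R), 2, tv, `+`))
  moved_cps <- constraint_point_set(sweep(cps$points %*% t(R), 2, tv, `+`),
                                    cps$source)
  moved <- fit_template_to_curves(tmpl, moved_state, moved_cps, par)
  expect_lt(max(abs(moved$state$cage_vertices -
                      sweep(base$state$cage_vertices %*% t(R), 2, tv, `+`))),
            1e-6)
  again <- fit_template_to_curves(tmpl, frame_state(0, tmpl$cage$vertices),
                                  cps, par)
  expect_identical(again$diagnostics, base$diagnostics)   # bit-identical
})

test_that("halving the resampling interval roughly doubles the data term", {
  # consequence of using the cost exactly as written (no N_p normalization)
  tmpl <- sphere_template()
  th <- 2 * pi * (0:7) / 8
  cv <- curve_constraint("c", cross_section_plane("XY", 0),
                         22 * cbind(cos(th), sin(th)), TRUE, frame = 0)
  n1 <- collect_frame_constraints(list(cv), list(), 0, 1, interval = 1)$n
  n2 <- collect_frame_constraints(list(cv), list(), 0, 1, interval = 0.5)$n
  expect_gt(n2 / n1, 1.9)
  expect_lt(n2 / n1, 2.1)
})
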