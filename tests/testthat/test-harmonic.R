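test_that("rasterize_cage partitions the grid and sets barycentric data", {
  cg <- sphere_cube_cage()
  g <- rasterize_cage(cg, 32)
  tab <- tabulate(g$tags + 1L, 3L)
  expect_identical(sum(tab), length(g$tags))          # partition of the grid
  expect_true(all(tab > 0L))
  bs <- rowSums(g$bvalues)[g$tags == 1L]
  expect_lt(max(abs(bs - 1)), 1e-12)                  # partition of unity
  expect_true(min(g$bvalues) >= 0)

  # boundary cells adjacent to each cube corner put weight ~1 on that vertex
  for (j in seq_len(8)) {
    corner <- cg$vertices[j, ]
    ijk <- round((corner - g$origin) / g$h)
    lin <- 1 + ijk[1] + g$dims[1] * (ijk[2] + g$dims[2] * ijk[3])
    expect_identical(g$tags[lin], 1L)
    expect_gt(g$bvalues[lin, j], 0.99)
  }
  expect_error(rasterize_cage(cg, 8), ">= 16")
})

test_that("harmonic fields are a partition of unity obeying the maximum principle", {
  cg <- sphere_cube_cage()
  g <- rasterize_cage(cg, 32)
  f <- solve_harmonic_weights(g)
  inside <- g$tags != 2L
  sums <- rowSums(f$fields[inside, ])
  expect_lt(max(abs(sums - 1)), 1e-3)
  expect_gt(min(f$fields[inside, ]), -1e-3)
  expect_lt(max(f$fields[inside, ]), 1 + 1e-3)
})

test_that("solved fields match a dense direct solve on a coarse grid", {
  cg <- sphere_cube_cage()
  g <- rasterize_cage(cg, 16)
  f <- solve_harmonic_weights(g)
  # independent dense solve of the same 6-neighbour Laplace problem
  dims <- g$dims
  interior <- which(g$tags == 0L)
  idx_of <- integer(length(g$tags))
  idx_of[interior] <- seq_along(interior)
  n <- length(interior)
  A <- matrix(0, n, n)
  b <- matrix(0, n, ncol(g$bvalues))
  steps <- c(1L, -1L, dims[1], -dims[1], dims[1] * dims[2], -dims[1] * dims[2])
  for (u in seq_len(n)) {
    A[u, u] <- 6
    for (s in steps) {
      nb <- interior[u] + s
      if (g$tags[nb] == 0L) A[u, idx_of[nb]] <- A[u, idx_of[nb]] - 1
      else if (g$tags[nb] == 1L) b[u, ] <- b[u, ] + g$bvalues[nb, ]
    }
  }
  dense <- solve(A, b)
  expect_lt(max(abs(dense - f$fields[interior, ])), 1e-6)

  # interior cell adjacent to a cage corner: dominant weight on that vertex
  corner_cell <- round((cg$vertices[1, ] - g$origin) / g$h)
  probe <- corner_cell + c(2, 2, 2)   # just inside the boundary layer
  lin <- 1 + probe[1] + dims[1] * (probe[2] + dims[2] * probe[3])
  expect_identical(g$tags[lin], 0L)
  expect_gt(f$fields[lin, 1], 0.5)
  expect_true(all(f$fields[lin, -1] < 0.5))
})

test_that("bind_mesh has symmetric center weights and linear precision", {
  cg <- sphere_cube_cage()
  g <- rasterize_cage(cg, 32)
  f <- solve_harmonic_weights(g)
  tet <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                       rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4)))
  b <- bind_mesh(tet, g, f, cg)
  expect_lt(max(abs(b$weights[1, ] - 1 / 8)), 1e-2)   # cube-center symmetry
  expect_equal(rowSums(b$weights), rep(1, 4))

  # a vertex just inside a cage corner gets (near-)indicator weights
  near <- triangle_mesh(rbind(cg$vertices[1, ] * 0.97,
                              c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                        rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4)))
  bn <- bind_mesh(near, g, f, cg)
  expect_gt(bn$weights[1, 1], 0.8)

  # linear precision: any affine map of the cage maps the mesh affinely
  tmpl <- sphere_template()
  M <- matrix(c(1.2, 0.1, 0, -0.2, 0.9, 0.05, 0, 0.1, 1.1), 3, 3)
  tv <- c(4, -2, 1)
  mapped <- tmpl$binding$weights %*%
    (sweep(tmpl$cage$vertices %*% t(M), 2, tv, `+`))
  direct <- sweep(deform_mesh(tmpl)$vertices %*% t(M), 2, tv, `+`)
  expect_lt(max(abs(mapped - direct)), 1e-9)
})

test_that("bind_mesh rejects vertices outside the cage", {
  cg <- sphere_cube_cage()
  g <- rasterize_cage(cg, 32)
  f <- solve_harmonic_weights(g)
  out <- triangle_mesh(rbind(c(40, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                       rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4)))
  expect_error(bind_mesh(out, g, f, cg), "outside the cage")
})

test_that("binding cache round-trips and detects stale content", {
  tmpl <- sphere_template()
  path <- withr::local_tempfile(fileext = ".rds")
  write_binding(tmpl$binding, path)
  b2 <- read_binding(path, mesh = tmpl$mesh, cage = tmpl$cage)
  expect_equal(b2$weights, tmpl$binding$weights)
  other <- icosphere(21, 2)
  expect_error(read_binding(path, mesh = other), "stale")
})
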