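test_that("deform_mesh reproduces rest pose and commutes with similarities", {
  tmpl <- sphere_template()
  rest <- tmpl$mesh$vertices
  cg <- tmpl$cage$vertices
  tol <- tmpl$binding$provenance$h * sqrt(3)  # one cell diagonal

  expect_lt(max(abs(deform_mesh(tmpl)$vertices - rest)), tol)

  # translation is exact relative to the reconstructed rest mesh (rows sum
  # to 1 exactly after renormalization); relative to the original vertices it
  # inherits the linear-precision tolerance
  recon <- deform_mesh(tmpl)$vertices
  shifted <- deform_mesh(tmpl, sweep(cg, 2, c(5, 0, 0), `+`))$vertices
  expect_lt(max(abs(shifted - sweep(recon, 2, c(5, 0, 0), `+`))), 1e-9)
  expect_lt(max(abs(shifted - sweep(rest, 2, c(5, 0, 0), `+`))), tol)

  R <- rotation_about(c(1, 1, 0), 0.5)
  rotated <- deform_mesh(tmpl, cg %*% t(R))$vertices
  expect_lt(max(abs(rotated - rest %*% t(R))), tol)

  tr <- similarity_transform(rotation_about(c(0, 0, 1), 0.3), 1.5, c(1, 2, 3))
  via_cage <- deform_mesh(tmpl, transform_points(tr, cg))$vertices
  expect_lt(max(abs(via_cage - transform_points(tr, rest))), 2 * tol)
})

test_that("deform_mesh is affine in the cage and preserves topology", {
  tmpl <- sphere_template()
  cg <- tmpl$cage$vertices
  set.seed(11)
  cg2 <- cg + matrix(rnorm(length(cg)), nrow(cg))
  A <- 0.3
  mix <- deform_mesh(tmpl, A * cg + (1 - A) * cg2)
  expect_lt(max(abs(mix$vertices -
                      (A * deform_mesh(tmpl, cg)$vertices +
                         (1 - A) * deform_mesh(tmpl, cg2)$vertices))), 1e-9)
  expect_identical(mix$triangles, tmpl$mesh$triangles)
})

test_that("deform_mesh validates dimensions and binding", {
  tmpl <- sphere_template()
  expect_error(deform_mesh(tmpl, tmpl$cage$vertices[-1, ]), "dimension|N_c")
  unbound <- template_model(tmpl$mesh, tmpl$cage)
  expect_error(deform_mesh(unbound), "not bound")
})

test_that("apply_alignment applies similarities to the cage", {
  tmpl <- sphere_template()
  expect_equal(apply_alignment(tmpl, similarity_transform()),
               tmpl$cage$vertices)
  doubled <- apply_alignment(tmpl, similarity_transform(scale = 2))
  expect_equal(doubled, 2 * tmpl$cage$vertices)
  bb <- apply(deform_mesh(tmpl, doubled)$vertices, 2, range)
  bb0 <- apply(deform_mesh(tmpl)$vertices, 2, range)
  expect_equal(bb, 2 * bb0, tolerance = 1e-6)
  expect_error(similarity_transform(scale = 0), "positive")
  expect_error(similarity_transform(scale = -1), "positive")
})

test_that("one alignment is copied to all frames", {
  tmpl <- sphere_template()
  tr <- similarity_transform(translation = c(4, -1, 2))
  states <- init_frame_states(tmpl, 4L, tr)
  expect_identical(vapply(states, `[[`, 1L, "frame"), 0:3)
  for (st in states)
    expect_equal(st$cage_vertices, apply_alignment(tmpl, tr))
})

test_that("set_cage_vertices edits selected vertices only", {
  tmpl <- sphere_template()
  st <- frame_state(0, tmpl$cage$vertices)
  expect_identical(set_cage_vertices(st, list()), st)

  st2 <- set_cage_vertices(st, list("1" = st$cage_vertices[1, ] + c(2, 0, 0)))
  moved <- which(rowSums(abs(deform_mesh(tmpl, st2$cage_vertices)$vertices -
                               deform_mesh(tmpl, st$cage_vertices)$vertices))
                 > 1e-12)
  touched <- which(tmpl$binding$weights[, 1] > 1e-12)
  expect_true(all(moved %in% touched))

  n <- nrow(st$cage_vertices)
  edits <- lapply(seq_len(n), function(i) st$cage_vertices[i, ] + c(1, 2, 3))
  names(edits) <- seq_len(n)
  st3 <- set_cage_vertices(st, edits)
  expect_equal(st3$cage_vertices,
               apply_alignment(tmpl, similarity_transform(translation = c(1, 2, 3))))
  expect_error(set_cage_vertices(st, list("99" = c(0, 0, 0))), "index")
})

test_that("mesh validation catches open, degenerate and self-intersecting meshes", {
  cm <- cube_mesh()
  expect_true(is_watertight(cm))
  open_mesh <- triangle_mesh(cm$vertices, cm$triangles[-1, ])
  expect_false(is_watertight(open_mesh))
  expect_error(validate_mesh(open_mesh), "watertight")

  # two interpenetrating cubes as one mesh: watertight but self-intersecting
  c2 <- cube_mesh(c(0.3, 0.3, 0.3), c(1.3, 1.3, 1.3))
  both <- triangle_mesh(rbind(cm$vertices, c2$vertices),
                        rbind(cm$triangles, c2$triangles + 8L))
  expect_true(is_watertight(both))
  expect_error(validate_mesh(both), "self-intersect")
})

test_that("cage construction validates closure and coarseness", {
  expect_error(cage(cube_mesh()$vertices, list(c(1, 2, 3))), "closed|8")
  cg <- sphere_cube_cage()
  expect_equal(nrow(cg$vertices), 8L)
  expect_equal(length(cg$faces), 6L)
  expect_equal(nrow(cg$edges), 12L)
  expect_error(template_model(cube_mesh(),
                              box_lattice_cage(c(-1, -1, -1), c(2, 2, 2),
                                               c(2, 2, 2))),
               "coarser")
})

test_that("OBJ and PLY round-trips preserve geometry and polygon faces", {
  m <- icosphere(10, 1)
  for (ext in c("obj", "ply")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_mesh(m, path)
    m2 <- read_mesh(path)
    expect_equal(m2$vertices, m$vertices, tolerance = 1e-7)
    expect_identical(m2$triangles, m$triangles)
  }
  cg <- box_lattice_cage(c(0, 0, 0), c(2, 3, 4), c(2, 1, 1))
  for (ext in c("obj", "ply")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_mesh(cg, path)
    cg2 <- read_cage(path)
    expect_equal(cg2$vertices, cg$vertices, tolerance = 1e-7)
    expect_identical(lapply(cg2$faces, as.integer), lapply(cg$faces, as.integer))
  }
})
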