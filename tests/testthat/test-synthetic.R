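test_that("make_template builds enclosed, watertight phantoms deterministically", {
  sp <- phantom_spec(seed = 3)
  tm <- make_template(sp)
  expect_gte(nrow(tm$mesh$vertices), 500L)
  expect_equal(nrow(tm$cage$vertices), 8L)
  bmin <- apply(tm$cage$vertices, 2, min)
  bmax <- apply(tm$cage$vertices, 2, max)
  expect_true(all(sweep(tm$mesh$vertices, 2, bmin, `>`) &
                    sweep(tm$mesh$vertices, 2, bmax, `<`)))
  tm2 <- make_template(phantom_spec(seed = 3))
  expect_identical(tm$mesh$vertices, tm2$mesh$vertices)

  caps <- capsule_mesh(10, 30)
  expect_true(is_watertight(caps))
  expect_true(is_watertight(tube_mesh(6, 60, 1.2)))
  expect_silent(validate_mesh(caps))
  # exactly two umbilic cap apices (the two poles)
  expect_equal(sum(abs(abs(caps$vertices[, 3]) - (10 + 15)) < 1e-9), 2L)
})

test_that("ground truth sequences follow the prescribed motion", {
  sp0 <- phantom_spec(seed = 5, motion = list(translation_mm = 0,
                                              scale_amp = 0, offset_mm = 0))
  tmpl <- bind_template(make_template(sp0), resolution = 24)
  gt0 <- make_ground_truth_sequence(tmpl, sp0)
  for (m in gt0$meshes)
    expect_lt(max(abs(m$vertices - deform_mesh(tmpl)$vertices)), 1e-12)

  # pure translation: mesh translates exactly with the cage (linear precision)
  spt <- phantom_spec(seed = 5, motion = list(translation_mm = 4,
                                              scale_amp = 0, offset_mm = 0))
  gtt <- make_ground_truth_sequence(tmpl, spt)
  for (t in seq_along(gtt$cages)) {
    shift <- gtt$cages[[t]][1, ] - tmpl$cage$vertices[1, ]
    expect_lt(max(abs(gtt$cages[[t]] -
                        sweep(tmpl$cage$vertices, 2, shift, `+`))), 1e-9)
    expect_lt(max(abs(gtt$meshes[[t]]$vertices -
                        sweep(deform_mesh(tmpl)$vertices, 2, shift, `+`))),
              1e-9)
  }

  sp <- phantom_spec(seed = 5)
  gt1 <- make_ground_truth_sequence(tmpl, sp)
  gt2 <- make_ground_truth_sequence(tmpl, sp)
  expect_identical(gt1$cages, gt2$cages)     # seed determinism
})

test_that("cross-section curves track analytic sections of the sphere", {
  sp <- icosphere(20, 3)
  # z = 0: great circle radius 20; z = 10: radius sqrt(300).  Mesh sections
  # run along chords, so allow the facet sagitta (~0.07 mm at depth 3).
  cv0 <- sample_constraint_curves(sp, list(cross_section_plane("XY", 0)),
                                  n_control = 8)[[1]]
  r0 <- sqrt(rowSums(cv0$control_points^2))
  expect_true(all(r0 <= 20 + 1e-9 & r0 >= 20 - 0.1))
  cv10 <- sample_constraint_curves(sp, list(cross_section_plane("XY", 10)),
                                   n_control = 8)[[1]]
  r10 <- sqrt(rowSums(cv10$control_points^2))
  expect_true(all(r10 <= sqrt(300) + 1e-9 & r10 >= sqrt(300) - 0.15))
  expect_error(sample_constraint_curves(sp, list(cross_section_plane("XY", 30))),
               "misses")
})

test_that("control-point jitter is bounded and reproducible", {
  sp <- icosphere(20, 2)
  planes <- list(cross_section_plane("ZX", 0))
  a <- sample_constraint_curves(sp, planes, 8, jitter_mm = 0.5, seed = 9)[[1]]
  b <- sample_constraint_curves(sp, planes, 8, jitter_mm = 0.5, seed = 9)[[1]]
  clean <- sample_constraint_curves(sp, planes, 8)[[1]]
  expect_identical(a$control_points, b$control_points)
  dev <- abs(a$control_points - clean$control_points)
  expect_lte(max(dev), 0.5)
  expect_gt(max(dev), 0)
})

test_that("phantom labels score overlap correctly", {
  g <- reference_grid(c(30, 12, 12), c(1, 1, 1), c(-0.5, -0.5, -0.5))
  labs <- rasterize_phantom_labels(list(cube_mesh(c(0, 0, 0), c(10, 10, 10)),
                                        cube_mesh(c(5, 0, 0), c(15, 10, 10))),
                                   g)
  expect_equal(dice_coefficient(labs[[1]], labs[[1]]), 1.0)
  expect_equal(dice_coefficient(labs[[1]], labs[[2]]), 0.5)
})

test_that("bent-tube fixture is out of model while straight tube is in model", {
  straight <- tube_mesh(6, 60, 0)
  bent <- tube_mesh(6, 60, 2.0944)
  expect_true(is_watertight(straight) && is_watertight(bent))
  # the bend moves the tube ends far from the straight template
  expect_gt(max(bent$vertices[, 1]) - max(straight$vertices[, 1]), 10)
})
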