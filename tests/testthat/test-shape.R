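test_that("caliper diameter matches exhaustive search and known geometry", {
  set.seed(21)
  # random small meshes vs brute force
  for (rep in 1:3) {
    semi <- sort(runif(3, 2, 8), decreasing = TRUE)
    ph <- make_phantom("ellipsoid", semi,
                       grid_shape = rep(2 * ceiling(max(semi)) + 6, 3),
                       orientation = random_rotation_test(rep))
    mesh <- build_lesion_mesh(first_lesion(ph), ph)
    md <- max_diameter(mesh)
    expect_equal(md$length, brute_diameter(mesh$vertices), tolerance = 1e-12)
  }
  # radius-5 sphere sampled on the surface: antipodal pair ~ 10
  sph_mesh <- structure(
    list(vertices = 5 * wmhshape:::fibonacci_directions(400),
         faces = matrix(c(1, 2, 3), 1), lesion_id = 1L),
    class = "lesion_mesh")
  expect_equal(max_diameter(sph_mesh)$length, 10, tolerance = 0.05)
  # ellipsoid semi-axes (21, 5, 5) -> ~ 42
  ph2 <- make_phantom("ellipsoid", c(21, 5, 5), grid_shape = c(48, 16, 16))
  mesh2 <- build_lesion_mesh(first_lesion(ph2), ph2)
  md2 <- max_diameter(mesh2)
  expect_equal(md2$length, 42, tolerance = 0.05)
  # scaling by 3: length x3, direction unchanged
  md3 <- max_diameter(scale_mesh(mesh2, 3))
  expect_equal(md3$length, 3 * md2$length, tolerance = 1e-12)
  expect_equal(abs(sum(md3$direction * md2$direction)), 1, tolerance = 1e-9)
})

test_that("extreme-point reduction agrees with the exact caliper", {
  ph <- make_phantom("ellipsoid", c(12, 7, 5), grid_shape = c(30, 30, 30),
                     orientation = random_rotation_test(4))
  mesh <- build_lesion_mesh(first_lesion(ph), ph)
  exact <- max_diameter(mesh, exact_max_vertices = 1e6)$length
  reduced <- max_diameter(mesh, exact_max_vertices = 4)$length
  expect_equal(reduced, exact, tolerance = 0.005)
})

test_that("min orthogonal diameter: sphere, box calipers, rotation invariance", {
  ph <- ball_phantom(5, odd_grid = FALSE)
  mesh <- build_lesion_mesh(first_lesion(ph), ph)
  expect_equal(min_orthogonal_diameter(mesh, c(1, 0, 0)), 10,
               tolerance = 0.05)
  # axis-aligned box 10 x 4 x 2, axis = x -> min in-plane extent 2
  bx <- make_phantom("box", c(10, 4, 2), grid_shape = c(16, 10, 8))
  bmesh <- build_lesion_mesh(first_lesion(bx), bx)
  expect_equal(min_orthogonal_diameter(bmesh, c(1, 0, 0)), 2,
               tolerance = 0.15)
  # rotating mesh and axis together leaves the value unchanged (up to the
  # angular grid; a smooth shape keeps the grid error quadratic)
  ell <- make_phantom("ellipsoid", c(10, 6, 4), grid_shape = c(26, 26, 26))
  emesh <- build_lesion_mesh(first_lesion(ell), ell)
  rot <- rotation_about(c(1, 2, 0.5), 0.71)
  expect_equal(
    min_orthogonal_diameter(rotate_mesh(emesh, rot), as.vector(rot %*% c(1, 0, 0))),
    min_orthogonal_diameter(emesh, c(1, 0, 0)), tolerance = 5e-3)
  # degenerate: all vertices on the axis line
  line_mesh <- structure(list(vertices = cbind(seq(0, 5, 0.5), 0, 0),
                              faces = matrix(c(1, 2, 3), 1)),
                         class = "lesion_mesh")
  expect_error(min_orthogonal_diameter(line_mesh, c(1, 0, 0)), "degenerate")
})

test_that("1-degree angular grid agrees with a 0.1-degree oracle within 1%", {
  set.seed(33)
  for (rep in 1:3) {
    semi <- sort(runif(3, 3, 9), decreasing = TRUE)
    ph <- make_phantom("ellipsoid", semi,
                       grid_shape = rep(2 * ceiling(max(semi)) + 6, 3),
                       orientation = random_rotation_test(rep))
    mesh <- build_lesion_mesh(first_lesion(ph), ph)
    axis <- max_diameter(mesh)$direction
    d1 <- min_orthogonal_diameter(mesh, axis, step_deg = 1)
    d01 <- min_orthogonal_diameter(mesh, axis, step_deg = 0.1)
    expect_equal(d1, d01, tolerance = 0.01)
    expect_gte(d1, d01)  # coarser grid can only overestimate the minimum
  }
})

test_that("eccentricity: sphere ~ 1, strongly elongated ellipsoid ~ 4.2", {
  ph <- ball_phantom(10)
  mesh <- build_lesion_mesh(first_lesion(ph), ph)
  ecc_sphere <- eccentricity(mesh)
  expect_equal(ecc_sphere, 1, tolerance = 0.1)
  expect_gte(ecc_sphere, 1 - 1e-9)

  ph2 <- make_phantom("ellipsoid", c(21, 5, 5), grid_shape = c(48, 16, 16))
  mesh2 <- build_lesion_mesh(first_lesion(ph2), ph2)
  expect_equal(eccentricity(mesh2), 4.2, tolerance = 0.3 / 4.2)

  # scale invariance (exact) and rotation invariance (1-degree grid)
  expect_equal(eccentricity(scale_mesh(mesh2, 3.7)), eccentricity(mesh2),
               tolerance = 1e-9)
  rot <- rotation_about(c(0.3, 1, 0.2), 1.1)
  expect_equal(eccentricity(rotate_mesh(mesh2, rot)), eccentricity(mesh2),
               tolerance = 2e-3)
})

test_that("stretching an ellipsoid never decreases eccentricity", {
  eccs <- vapply(c(8, 10, 12, 14), function(a) {
    ph <- make_phantom("ellipsoid", c(a, 4, 4), grid_shape = c(2 * a + 6, 14, 14))
    eccentricity(build_lesion_mesh(first_lesion(ph), ph))
  }, numeric(1))
  expect_true(all(diff(eccs) > -1e-9))
})

test_that("compactness measures match closed forms and respect their bounds", {
  # digital cube: compactness3 ~ 1, compactness1 ~ 1/216
  cb <- make_phantom("box", c(10, 10, 10), grid_shape = c(16, 16, 16))
  cmesh <- build_lesion_mesh(first_lesion(cb), cb)
  cf <- compactness_features(cmesh)
  expect_equal(cf$compactness3, 1, tolerance = 0.15)
  expect_equal(cf$compactness2, 1, tolerance = 0.15)
  expect_equal(cf$compactness1, 1 / 216, tolerance = 0.15)

  # large digital ball: compactness1 approaches the isoperimetric bound from below
  ph <- ball_phantom(10)
  bf <- compactness_features(build_lesion_mesh(first_lesion(ph), ph))
  bound <- 1 / (36 * pi)
  expect_lt(bf$compactness1, bound + 1e-6)
  expect_gt(bf$compactness1, 0.7 * bound)

  # every convex phantom: c1 under the isoperimetric bound, c2/c3 in (0, 1]
  shapes <- list(
    ball_phantom(6),
    make_phantom("ellipsoid", c(10, 4, 3), grid_shape = c(26, 14, 12)),
    make_phantom("box", c(8, 6, 2), grid_shape = c(14, 12, 8)),
    make_phantom("rod", c(14, 2.5), grid_shape = c(20, 10, 10)))
  for (ph in shapes) {
    cf <- compactness_features(build_lesion_mesh(first_lesion(ph), ph))
    expect_lte(cf$compactness1, 1 / (36 * pi) + 1e-6)
    expect_gt(cf$compactness1, 0)
    expect_gt(cf$compactness2, 0)
    expect_lte(cf$compactness2, 1)
    expect_gt(cf$compactness3, 0)
    expect_lte(cf$compactness3, 1)
  }
})

test_that("shape ratios are invariant under uniform scaling of the grid", {
  for (sc in c(0.5, 2)) {
    ph1 <- make_phantom("ellipsoid", c(9, 5, 4), grid_shape = c(24, 16, 14))
    ph2 <- make_phantom("ellipsoid", c(9, 5, 4) * sc,
                        grid_shape = c(24, 16, 14),
                        spacing = c(1, 1, 1) * sc)
    m1 <- build_lesion_mesh(first_lesion(ph1), ph1)
    m2 <- build_lesion_mesh(first_lesion(ph2), ph2)
    c1 <- compactness_features(m1)
    c2 <- compactness_features(m2)
    expect_equal(eccentricity(m1), eccentricity(m2), tolerance = 1e-6)
    expect_equal(c1$compactness2, c2$compactness2, tolerance = 1e-6)
    expect_equal(c1$compactness3, c2$compactness3, tolerance = 1e-6)
  }
})

test_that("box-counting dimension: line ~ 1, cube surface ~ 2, tiny lesion undefined", {
  line <- voxset(cbind(seq_len(64), 1L, 1L))
  fd_line <- fractal_dimension(line)
  expect_true(fd_line$defined)
  expect_equal(fd_line$fd, 1, tolerance = 0.25)

  cube <- make_phantom("box", c(32, 32, 32), grid_shape = c(38, 38, 38))
  fd_cube <- fractal_dimension(first_lesion(cube))
  expect_true(fd_cube$defined)
  expect_equal(fd_cube$fd, 2, tolerance = 0.3 / 2)

  tiny <- voxset(cbind(seq_len(5), 1L, 1L))
  fd_tiny <- fractal_dimension(tiny)
  expect_false(fd_tiny$defined)
  expect_true(is.na(fd_tiny$fd))
})

test_that("principal curvatures match analytic surfaces", {
  # quadratic 'ball' image: isophote through radius-6 voxel has k1 = k2 = 1/6
  n <- 21; c0 <- 11
  co <- seq_len(n) - c0
  a <- -(outer(outer(co^2, co^2, "+"), co^2, "+"))
  v <- volume_grid(array(a, c(n, n, n)), c(1, 1, 1))
  pc <- principal_curvatures(v, c(c0 + 6, c0, c0))
  expect_true(pc$defined)
  expect_equal(pc$k1, 1 / 6, tolerance = 0.3)
  expect_equal(pc$k2, 1 / 6, tolerance = 0.3)
  expect_gte(pc$k1, pc$k2)

  # flat blurred interface: both curvatures ~ 0
  half <- array(0, c(21, 21, 21))
  half[, , 1:10] <- 1
  vh <- volume_grid(half, c(1, 1, 1))
  ph <- principal_curvatures(vh, c(11, 11, 10))
  expect_lt(abs(ph$k1), 0.05)
  expect_lt(abs(ph$k2), 0.05)

  # deep inside a constant region (away from the interface and the volume
  # edge): zero gradient -> flagged undefined
  pc0 <- principal_curvatures(vh, c(11, 11, 5))
  expect_false(pc0$defined)
  expect_true(is.na(pc0$k1))

  # analytic saddle (F = x^2 - y^2 on the diagonal): k1 = -k2
  sa <- outer(outer(co^2, -co^2, "+"), rep(0, n), "+")
  vs <- volume_grid(array(sa, c(n, n, n)), c(1, 1, 1))
  ps <- principal_curvatures(vs, c(c0 + 4, c0 + 4, c0))
  expect_equal(ps$k1 + ps$k2, 0, tolerance = 0.02)
  expect_gt(ps$k1, 0)
})

test_that("shape index and curvedness behave like a sphere on a digital ball", {
  ph <- ball_phantom(6)
  les <- first_lesion(ph)
  shell <- lesion_boundary_voxels(les)
  sc <- shape_index_curvedness(les, ph, at = shell)
  expect_equal(abs(sc$shape_index), 1, tolerance = 0.15)
  expect_equal(sc$curvedness, sqrt(2) / 6, tolerance = 0.3)
  expect_true(all(sc$si >= -1 & sc$si <= 1))
  expect_true(all(sc$cv >= 0))

  # saddle limit: k1 = -k2 gives shape index 0 (checked via the saddle image)
  n <- 21; c0 <- 11
  co <- seq_len(n) - c0
  sa <- outer(outer(co^2, -co^2, "+"), rep(0, n), "+")
  vs <- volume_grid(array(sa, c(n, n, n)), c(1, 1, 1))
  saddle_vox <- voxset(matrix(c(c0 + 4, c0 + 4, c0), 1))
  scs <- shape_index_curvedness(saddle_vox, vs, image = vs)
  expect_equal(scs$shape_index, 0, tolerance = 0.02)

  # intensity scaling leaves the shape index unchanged
  ph5 <- ph
  ph5$data <- ph$data * 5
  ph5$is_binary <- FALSE
  sc5 <- shape_index_curvedness(les, ph, image = ph5, at = shell)
  sc1 <- shape_index_curvedness(les, ph, image = new_img(ph), at = shell)
  expect_equal(sc5$shape_index, sc1$shape_index, tolerance = 1e-9)

  # no defined voxel -> flagged undefined
  deep <- voxset(matrix(c(9, 9, 9), 1))
  flat <- volume_grid(array(1, c(17, 17, 17)), c(1, 1, 1))
  scd <- shape_index_curvedness(deep, flat, image = flat)
  expect_true(is.na(scd$shape_index))
  expect_equal(scd$n_defined, 0L)
})
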