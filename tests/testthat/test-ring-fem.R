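test_that("ring mesh has the requested structure and area", {
  mesh <- build_ring_mesh(rep_geometry(), c(96, 4))
  expect_equal(nrow(mesh$conn), 96 * 4)
  expect_equal(nrow(mesh$nodes), 96 * 5)
  r <- sqrt(rowSums(mesh$nodes^2))
  expect_true(all(r >= 75 - 1e-9 & r <= 90 + 1e-9))
  expect_equal(max(r), 90)
  # mid-surface diameter is D - t
  expect_equal(min(r) + max(r), 180 - 15)
})

test_that("mesh area approaches the annulus area", {
  mesh <- build_ring_mesh(rep_geometry(), c(192, 8))
  exact <- pi / 4 * (180^2 - (180 - 30)^2)
  expect_equal(mesh_area(mesh), exact, tolerance = 0.005)
  expect_error(cylinder_geometry(20, 180, 90), "invalid-geometry")
})

test_that("mesh construction is deterministic", {
  m1 <- build_ring_mesh(rep_geometry(), c(96, 4))
  m2 <- build_ring_mesh(rep_geometry(), c(96, 4))
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$conn, m2$conn)
})

test_that("zero narrowing produces zero force", {
  mesh <- build_ring_mesh(rep_geometry(), c(96, 4))
  sol <- solve_diametral_compression(mesh, hydrogel(), contact_config(),
                                     max_narrowing = 0)
  expect_equal(sol$curve$force, 0)
})

test_that("plate forces balance and work equals stored energy", {
  mesh <- build_ring_mesh(rep_geometry(), c(96, 4))
  sol <- solve_diametral_compression(mesh, hydrogel(), contact_config(),
                                     max_narrowing = 18, n_steps = 10)
  s <- sol$solution
  expect_lt(max(abs(s$force_right - s$force_left)) / max(s$force_right), 1e-6)
  expect_equal(s$external_work_fJ, tail(s$strain_energy_fJ, 1),
               tolerance = 0.01)
  expect_true(all(diff(sol$curve$force) > 0))
})

test_that("compression produces contralateral elastic expansion", {
  mesh <- build_ring_mesh(rep_geometry(), c(96, 4))
  sol <- solve_diametral_compression(mesh, hydrogel(), contact_config(),
                                     max_narrowing = 18, n_steps = 10)
  expect_gt(tail(sol$solution$y_diameter, 1), 180)
})

test_that("small-displacement stiffness is rate (increment-count) independent", {
  mesh <- build_ring_mesh(rep_geometry(), c(96, 4))
  ks <- vapply(c(4L, 16L), function(n) {
    sol <- solve_diametral_compression(mesh, hydrogel(), contact_config(),
                                       max_narrowing = 3.6, n_steps = n)
    extract_stiffness(sol$curve)
  }, numeric(1))
  expect_equal(ks[1], ks[2], tolerance = 0.005)
})

test_that("point-load thin ring matches the classical bending solution", {
  # geometry chosen so the centroidal ring has t/D = 0.02 exactly
  geom <- suppressWarnings(cylinder_geometry(50, 204, 4))
  mesh <- build_ring_mesh(geom, c(96, 4))
  k_ref <- ring_closed_form_k(80, 50, 4, 200)
  sol <- solve_diametral_compression(mesh, material_model(80, nu = 0.5),
                                     contact_config("point_load"),
                                     max_narrowing = 1, n_steps = 4,
                                     formulation = "plane_stress")
  expect_equal(extract_stiffness(sol$curve, window = 0.005, D = 204), k_ref,
               tolerance = 0.03)
  # plane strain carries the plate modulus E / (1 - nu^2)
  sol2 <- solve_diametral_compression(mesh, hydrogel(),
                                      contact_config("point_load"),
                                      max_narrowing = 1, n_steps = 4)
  expect_equal(extract_stiffness(sol2$curve, window = 0.005, D = 204),
               ring_closed_form_k(80 / (1 - 0.4995^2), 50, 4, 200),
               tolerance = 0.03)
})

test_that("stiffness changes under mesh refinement stay below 2%", {
  for (g in list(c(20, 180, 15), c(20, 220, 5), c(20, 140, 25))) {
    geom <- cylinder_geometry(g[1], g[2], g[3])
    ks <- vapply(list(c(96L, 4L), c(192L, 8L)), function(r) {
      mesh <- build_ring_mesh(geom, r)
      sol <- solve_diametral_compression(mesh, hydrogel(), contact_config(),
                                         max_narrowing = 0.02 * g[2],
                                         n_steps = 4)
      extract_stiffness(sol$curve)
    }, numeric(1))
    expect_equal(ks[2] / ks[1], 1, tolerance = 0.02)
  }
})

test_that("extract_stiffness and linearity_limit behave on synthetic curves", {
  geom <- rep_geometry()
  d <- seq(0, 36, by = 0.9)
  lin <- fd_curve(d, 7 * d, geometry = geom)
  expect_equal(extract_stiffness(lin), 7, tolerance = 1e-12)
  expect_equal(linearity_limit(lin), 20)  # full curve extent, 36/180
  soft <- fd_curve(d, 7 * d * (1 - 4 * d / 180), geometry = geom)
  # secant = k (1 - 4 d / D): 10% deviation crossed just above d/D = 2.5%
  expect_lt(linearity_limit(soft), 5)
  expect_error(extract_stiffness(fd_curve(c(0, 10), c(0, 1), geom)),
               "insufficient-data")
})
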