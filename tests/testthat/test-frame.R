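test_that("imperfect pinned column peaks at the Euler load", {
  L <- 200
  xs <- seq(0, L, length.out = 41)
  shape <- frame_shape(cbind(xs, 0.002 * L * sin(pi * xs / L)),
                       section_width = 4, depth = 10)
  cv <- solve_frame_compression(shape, material_model(80, nu = 0.5),
                                end_shortening = 2, n_steps = 100)
  P_euler <- pi^2 * 80 * (10 * 4^3 / 12) / L^2
  expect_equal(max(cv$force), P_euler, tolerance = 0.05)
})

test_that("peak force decreases with initial bar curvature", {
  L <- 200
  xs <- seq(0, L, length.out = 41)
  m <- material_model(80, nu = 0.5)
  peaks <- vapply(c(0.01, 0.02, 0.05), function(rise) {
    sh <- frame_shape(cbind(xs, rise * L * sin(pi * xs / L)), 4, 10)
    max(solve_frame_compression(sh, m, 0.03 * L, n_steps = 30)$force)
  }, numeric(1))
  expect_true(all(diff(peaks) < 0))
})

test_that("zero end shortening carries zero force; slenderness is checked", {
  xs <- seq(0, 100, length.out = 11)
  sh <- frame_shape(cbind(xs, 0.2 * sin(pi * xs / 100)), 4, 10)
  cv <- solve_frame_compression(sh, material_model(80, nu = 0.5), 0)
  expect_equal(max(abs(cv$force)), 0)
  expect_warning(frame_shape(cbind(c(0, 10), c(0, 0)), 4, 10), "slender")
})

test_that("V-spring response is strongly nonlinear at relevant deflections", {
  # shallow V between two anchor points: end shortening drives the apex
  half <- 85
  xs <- seq(-half, half, length.out = 41)
  vshape <- frame_shape(cbind(xs, -0.15 * half * (1 - abs(xs) / half)),
                        section_width = 6, depth = 20)
  cv <- solve_frame_compression(vshape, material_model(80, nu = 0.5),
                                end_shortening = 20, n_steps = 40)
  k0 <- cv$force[2] / cv$narrowing[2]
  sec <- cv$force[-1] / cv$narrowing[-1]
  # secant stiffness drifts far from the initial tangent well before 12% of span
  expect_gt(max(abs(sec / k0 - 1)), 0.3)
})
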