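test_that("trajectories saturate at the plateau with the right sign", {
  tr <- make_trajectory(s_max = 10, tau = 45, width0 = 180,
                        times = c(0, 1e5))
  expect_equal(tail(tr$trace$width, 1), 0.9 * 180, tolerance = 1e-6)
  widen <- make_trajectory(s_max = 10, tau = 45, width0 = 180,
                           times = seq(0, 240, 30), mode = "widening")
  comp <- make_trajectory(s_max = 10, tau = 45, width0 = 180,
                          times = seq(0, 240, 30))
  expect_equal(widen$trace$width - 180, -(comp$trace$width - 180),
               tolerance = 1e-12)
})

test_that("default trajectory reaches the ~100 nN force scale", {
  k <- predict_stiffness(rep_geometry(), 80)  # 7.15 nN/um at alpha = 7.718
  tr <- make_trajectory(k = k, times = seq(0, 600, 30))
  plateau <- tail(tr$truth$force, 1)
  expect_gt(plateau, 90)
  expect_lt(plateau, 115)
})

test_that("generators are pure functions of parameters and seed", {
  a <- make_trajectory(noise_sd = 0.5, seed = 3)
  b <- make_trajectory(noise_sd = 0.5, seed = 3)
  expect_identical(a, b)
  co1 <- make_cohort(n = 4, variability = 0.15, seed = 9, noise_sd = 0.3)
  co2 <- make_cohort(n = 4, variability = 0.15, seed = 9, noise_sd = 0.3)
  expect_identical(co1, co2)
  af1 <- make_afm_curve(noise = 0.01, seed = 5)
  af2 <- make_afm_curve(noise = 0.01, seed = 5)
  expect_identical(af1, af2)
  mv1 <- render_movie(a$trace, photon_scale = 100, gauss_sd = 0.01, seed = 4,
                      ring_thickness = 8)
  mv2 <- render_movie(a$trace, photon_scale = 100, gauss_sd = 0.01, seed = 4,
                      ring_thickness = 8)
  expect_identical(mv1$stack$frames, mv2$stack$frames)
})

test_that("ground truth is never contaminated by noise", {
  noisy <- make_trajectory(noise_sd = 2, seed = 11, k = 7.15)
  clean <- make_trajectory(noise_sd = 0, k = 7.15)
  expect_identical(noisy$truth, clean$truth)
})

test_that("cohorts honour their declared variability structure", {
  same <- make_cohort(n = 5, variability = 0, seed = 2)
  ws <- vapply(same, function(x) tail(x$trace$width, 1), numeric(1))
  expect_equal(max(ws) - min(ws), 0)
  co <- make_cohort(n = 10, variability = 0.15, seed = 21)
  plateau <- vapply(co, function(x) tail(x$truth$strain, 1), numeric(1))
  # n = 10 at 15% lognormal spread keeps the cohort mean within 10% of nominal
  expect_equal(mean(plateau), 8 * (1 - exp(-480 / 45)), tolerance = 0.10)
  expect_gt(sd(plateau), 0)
})

test_that("degenerate generator inputs error cleanly", {
  expect_error(make_trajectory(tau = 0), "invalid-argument")
  expect_error(make_afm_curve(E_kPa = -5), "invalid-argument")
  expect_error(deformation_trace(numeric(0), numeric(0)), "invalid-trace")
  wide <- deformation_trace(0, 60)
  expect_error(render_movie(wide, margin_px = -60), "invalid-render")
})

test_that("AFM generator round-trips through the Hertz fit", {
  af <- make_afm_curve(E_kPa = 25, theta = 20, contact_point = 0.1)
  fit <- fit_hertz_pyramidal(af$curve)
  expect_equal(pa_to_kpa(fit$E_est), 25, tolerance = 1e-3)
})

test_that("rendered movies close the loop with the imaging module", {
  tr <- make_trajectory(s_max = 8, tau = 45, width0 = 60,
                        times = seq(0, 120, 60))
  mv <- render_movie(tr$trace, ring_thickness = 8, blur_sd = 1)
  est <- extract_trace(mv$stack, register = FALSE, method = "fixed")
  # bounding-rectangle reading of a ~95 px sensor: 2 px quantization bound
  expect_lt(max(abs(est$width - tr$trace$width)), 2 * 0.59)
})
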