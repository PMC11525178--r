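test_that("material_model derives consistent neo-Hookean constants", {
  m <- material_model(80, nu = 0.4995)
  expect_equal(m$E, 80e3)
  expect_equal(m$mu, 80e3 / (2 * 1.4995), tolerance = 1e-12)
  expect_equal(m$c10, m$mu / 2, tolerance = 1e-12)
  expect_error(material_model(-1), "invalid-argument")
  expect_error(material_model(80, nu = 0.7), "invalid-argument")
})

test_that("incompressible uniaxial stress matches the closed form", {
  m <- material_model(80, nu = 0.5)
  expect_equal(neo_hookean_uniaxial(1, m), 0)
  # hand evaluation of (80/3) (1.2 - 1.2^-2) kPa
  expect_equal(pa_to_kpa(neo_hookean_uniaxial(1.2, m)), 13.48148,
               tolerance = 1e-6)
  # small-strain slope is E (central difference at lambda = 1)
  h <- 1e-6
  slope <- (neo_hookean_uniaxial(1 + h, m) - neo_hookean_uniaxial(1 - h, m)) / (2 * h)
  expect_equal(slope, 80e3, tolerance = 1e-3)
  expect_error(neo_hookean_uniaxial(0, m), "invalid-argument")
  expect_error(neo_hookean_uniaxial(1.1, material_model(80, nu = 0.4995)),
               "unsupported-configuration")
})

test_that("uniaxial stress is odd-symmetric in log-stretch near lambda = 1", {
  m <- material_model(40, nu = 0.5)
  eps <- 1e-4
  s_plus <- neo_hookean_uniaxial(1 + eps, m)
  s_minus <- neo_hookean_uniaxial(1 / (1 + eps), m)
  expect_equal(s_plus, -s_minus, tolerance = 10 * eps)  # O(eps^2) relative
})

test_that("linearity_deviation separates linear from curved records", {
  lin <- make_stress_strain(80, "linear", max_strain = 0.2, n = 50)
  expect_equal(linearity_deviation(lin, 0.2), 0, tolerance = 1e-12)
  nh <- make_stress_strain(80, "neo_hookean", max_strain = 0.2, n = 200)
  expect_lt(linearity_deviation(nh, 0.20), 0.05)
  # best line through stress = strain^2 on [0, 1] is strain - 1/6, whose
  # worst residual is exactly 1/6 of the peak stress
  quad <- make_stress_strain(80, "quadratic", max_strain = 1, n = 2001)
  expect_equal(linearity_deviation(quad, 1), 1 / 6, tolerance = 1e-3)
  expect_gt(linearity_deviation(quad, 1), 0.1)
  few <- stress_strain_record(c(0, 0.1, 0.2), c(0, 1, 2))
  expect_error(linearity_deviation(few, 0.2), "insufficient-data")
})

test_that("Hertz fit inverts its forward model across the working range", {
  for (E in c(5, 30, 80)) {
    for (theta in c(10, 20, 40)) {
      af <- make_afm_curve(E_kPa = E, theta = theta, contact_point = 0.25)
      fit <- fit_hertz_pyramidal(af$curve)
      expect_equal(pa_to_kpa(fit$E_est), E, tolerance = 1e-3)
      expect_equal(fit$contact_point, 0.25, tolerance = 1e-3)
    }
  }
})

test_that("Hertz fit tolerates multiplicative noise and flags degeneracy", {
  af <- make_afm_curve(E_kPa = 80, theta = 20, contact_point = 0.2,
                       noise = 0.01, seed = 42)
  fit <- fit_hertz_pyramidal(af$curve)
  expect_equal(pa_to_kpa(fit$E_est), 80, tolerance = 0.02)
  flat <- afm_curve(seq(0, 2, length.out = 50), rep(0, 50))
  expect_error(fit_hertz_pyramidal(flat), "degenerate-curve")
})

test_that("uniaxial modulus: exact on linear data, analytic on neo-Hookean", {
  lin <- make_stress_strain(80, "linear", max_strain = 0.2, n = 50)
  expect_equal(pa_to_kpa(fit_uniaxial_modulus(lin, c(0, 0.2))), 80,
               tolerance = 1e-12)
  nh <- make_stress_strain(80, "neo_hookean", max_strain = 0.2, n = 201)
  est <- pa_to_kpa(fit_uniaxial_modulus(nh, c(0, 0.05)))
  strains <- nh$strain[nh$strain <= 0.05]
  expect_equal(est, nh_origin_slope_oracle(80, strains[strains > 0]),
               tolerance = 1e-10)
  expect_equal(est, 80, tolerance = 0.05)
  expect_error(fit_uniaxial_modulus(nh, c(0.5, 0.6)), "insufficient-data")
})

test_that("uniaxial modulus converges to E as the window shrinks", {
  nh <- make_stress_strain(80, "neo_hookean", max_strain = 0.2, n = 2001)
  errs <- vapply(c(0.10, 0.05, 0.01), function(w) {
    abs(pa_to_kpa(fit_uniaxial_modulus(nh, c(0, w))) - 80)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 80 * 0.01)
})
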