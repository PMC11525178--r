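test_that("width-to-strain arithmetic and sign convention", {
  tr <- deformation_trace(c(0, 30, 60), c(180, 162, 198))
  expect_equal(widths_to_strain(tr), c(0, 10, -10))
  expect_error(deformation_trace(c(10, 20), c(180, 170)), "start at 0")
  expect_error(deformation_trace(c(0, 30), c(180, -1)), "positive")
})

test_that("force follows F = k * narrowing with a 20% validity flag", {
  tr <- deformation_trace(c(0, 30, 60), c(180, 172, 140))
  f <- strain_to_force(tr, k = 7.15)
  expect_equal(as.numeric(f), 7.15 * c(0, 8, 40))
  expect_equal(as.numeric(f)[2], 57.2)
  # 40/180 = 22% strain: value returned but flagged out of the linear range
  expect_equal(attr(f, "valid"), c(TRUE, TRUE, FALSE))
  expect_error(strain_to_force(tr, k = -1), "invalid-argument")
})

test_that("trapezoidal elastic energy matches calculus oracles", {
  # linear loading to 15 um at 7.15 nN/um: 1/2 k d^2 = 0.804 pJ
  d <- seq(0, 15, length.out = 51)
  en <- elastic_energy(7.15 * d, d)
  expect_equal(tail(en, 1), 0.5 * 7.15 * 15^2 / 1000, tolerance = 0.005)
  expect_equal(en[1], 0)
  # quadratic force law F = c d^2 integrates to c d^3 / 3
  d2 <- seq(0, 10, length.out = 101)
  en2 <- elastic_energy(0.3 * d2^2, d2)
  expect_equal(tail(en2, 1), 0.3 * 10^3 / 3 / 1000, tolerance = 0.005)
  expect_equal(elastic_energy(numeric(0), numeric(0)), numeric(0))
  expect_error(elastic_energy(1:3, 1:2), "invalid-input")
})

test_that("max impulse captures the force generated per 60-min window", {
  t <- seq(0, 240, by = 30)
  mk <- function(force) {
    p <- structure(list(times = t, force = force, strain = force, valid = TRUE),
                   class = "force_profile")
    p
  }
  expect_equal(max_impulse(mk(rep(25, length(t)))), 0)
  expect_equal(max_impulse(mk(1 * t)), 3600)
  # 50 nN rise within the first hour, flat afterwards
  rise <- pmin(t / 60, 1) * 50
  expect_equal(max_impulse(mk(rise)), 3000)
  expect_equal(max_impulse(mk(rise)), impulse_scan_oracle(t, rise),
               tolerance = 1e-9)
  short <- structure(list(times = c(0, 30), force = c(0, 1), valid = TRUE),
                     class = "force_profile")
  expect_error(max_impulse(short), "insufficient-data")
})

test_that("ATP equivalent conversion is exact arithmetic", {
  expect_equal(atp_equivalent(1), 1e7)
  expect_equal(atp_equivalent(0), 0)
  expect_equal(atp_equivalent(0.8), 8e6)
  expect_error(atp_equivalent(-0.1), "invalid-argument")
})

test_that("pipeline is linear in narrowing and symmetric under mirroring", {
  t <- seq(0, 240, by = 30)
  w0 <- 180
  d <- 14 * (1 - exp(-t / 45))
  tr1 <- deformation_trace(t, w0 - d)
  tr3 <- deformation_trace(t, w0 - 3 * d)
  p1 <- force_profile(tr1, k = 7.15)
  p3 <- force_profile(tr3, k = 7.15)
  expect_equal(p3$force, 3 * p1$force, tolerance = 1e-12)
  expect_equal(p3$energy, 9 * p1$energy, tolerance = 1e-12)
  mirrored <- deformation_trace(t, w0 + d)
  pm <- force_profile(mirrored, k = 7.15)
  expect_equal(pm$force, -p1$force, tolerance = 1e-12)
  expect_equal(pm$energy, p1$energy, tolerance = 1e-12)
})

test_that("cohort mean and CI follow the t distribution", {
  t <- seq(0, 120, by = 30)
  mk <- function(scale) force_profile(
    deformation_trace(t, 180 - scale * (1 - exp(-t / 45)) * 10), k = 7.15)
  identical10 <- lapply(rep(1, 10), mk)
  cs <- cohort_profile(identical10)
  expect_equal(cs$mean, identical10[[1]]$force, tolerance = 1e-12)
  expect_equal(cs$ci_high - cs$ci_low, rep(0, length(t)), tolerance = 1e-12)

  scales <- seq(0.8, 1.2, length.out = 10)
  varied <- lapply(scales, mk)
  cs2 <- cohort_profile(varied)
  forces <- vapply(varied, function(p) p$force[3], numeric(1))
  # frozen t quantile: qt(0.975, 9) = 2.262157
  half <- 2.262157 * sd(forces) / sqrt(10)
  expect_equal(cs2$ci_high[3] - cs2$mean[3], half, tolerance = 1e-5)
  expect_warning(cohort_profile(varied[1]), "single")
})

test_that("two-group comparison matches the pooled-variance formula", {
  a <- c(1, 2, 3)
  b <- c(11, 12, 13)
  same <- compare_groups(a, a)
  expect_equal(same$p.value, 1)
  shifted <- compare_groups(a, b)
  expect_lt(shifted$p.value, 0.05)
  # hand-computed pooled-SE t statistic
  sp <- sqrt(((2) * var(a) + (2) * var(b)) / 4)
  t_hand <- (mean(a) - mean(b)) / (sp * sqrt(1 / 3 + 1 / 3))
  expect_equal(unname(shifted$statistic), t_hand, tolerance = 1e-10)
  expect_error(compare_groups(1, b), "insufficient-data")
  # rank test needs n = 5 per group before p can cross 0.05 at all
  mw <- compare_groups(1:5, 11:15, method = "mann-whitney")
  expect_lt(mw$p.value, 0.05)
})
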