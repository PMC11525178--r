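fake_records <- function(alpha = 5, jitter = 0, seed = 1) {
  g <- expand.grid(H_um = c(20, 60), D_um = c(140, 220), t_um = c(5, 25),
                   E_kPa = c(5, 80))
  x <- g$H_um * (g$t_um / g$D_um)^3 * g$E_kPa
  k <- alpha * x
  if (jitter > 0) k <- k * withr::with_seed(seed, exp(rnorm(length(k), 0, jitter)))
  cbind(g, k_nN_per_um = k, status = "ok")
}

test_that("fit_alpha is exact on records generated from the law", {
  fit <- fit_alpha(fake_records(alpha = 5))
  expect_equal(fit$alpha, 5, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$max_rel_residual, 0, tolerance = 1e-10)
})

test_that("closed-form alpha agrees with an independent numeric optimizer", {
  rec <- fake_records(alpha = 7.7, jitter = 0.2)
  fit <- fit_alpha(rec)
  x <- rec$H_um * (rec$t_um / rec$D_um)^3 * rec$E_kPa
  rss <- function(a) sum((rec$k_nN_per_um - a * x)^2)
  opt <- optimize(rss, c(0.1 * fit$alpha, 10 * fit$alpha), tol = 1e-12)
  expect_equal(fit$alpha, opt$minimum, tolerance = 1e-7)
})

test_that("fit_alpha is scale-equivariant and validates input", {
  rec <- fake_records(alpha = 7.7, jitter = 0.2)
  a1 <- fit_alpha(rec)$alpha
  rec2 <- rec
  rec2$k_nN_per_um <- 3 * rec2$k_nN_per_um
  expect_equal(fit_alpha(rec2)$alpha, 3 * a1, tolerance = 1e-12)
  expect_error(fit_alpha(rec[1, , drop = FALSE]), "insufficient-data")
  bad <- rec
  bad$k_nN_per_um[1] <- -1
  expect_error(fit_alpha(bad), "invalid-record")
})

test_that("relative weighting matches its own normal equation", {
  rec <- fake_records(alpha = 7.7, jitter = 0.3)
  fit <- fit_alpha(rec, weighting = "relative")
  x <- rec$H_um * (rec$t_um / rec$D_um)^3 * rec$E_kPa
  rss <- function(a) sum(((rec$k_nN_per_um - a * x) / rec$k_nN_per_um)^2)
  opt <- optimize(rss, c(1, 20), tol = 1e-12)
  expect_equal(fit$alpha, opt$minimum, tolerance = 1e-7)
})

test_that("predict_stiffness applies the parametric law with exact units", {
  geom <- rep_geometry()
  expect_equal(predict_stiffness(geom, 80, alpha = 0), 0)
  k <- predict_stiffness(geom, 80, alpha = 7.718)
  expect_equal(k, 7.718 * 20 * (15 / 180)^3 * 80, tolerance = 1e-12)
  expect_equal(k, 7.1466, tolerance = 1e-4)
  # cubic thickness law: doubling t multiplies k by 8 exactly
  g2 <- suppressWarnings(cylinder_geometry(20, 180, 30))
  expect_equal(predict_stiffness(g2, 80, alpha = 7.718) / k, 8,
               tolerance = 1e-12)
  expect_warning(predict_stiffness(geom, 200), "outside")
})

test_that("single-cell sweep runs, caches, and resumes identically", {
  cache <- withr::local_tempdir()
  sw1 <- run_sweep(H = 20, D = 180, t = 15, E_kPa = 80, cache_dir = cache)
  expect_equal(nrow(sw1), 1L)
  expect_gt(sw1$k_nN_per_um, 0)
  expect_length(list.files(cache), 1L)
  sw2 <- run_sweep(H = 20, D = 180, t = 15, E_kPa = 80, cache_dir = cache)
  expect_equal(sw2$k_nN_per_um, sw1$k_nN_per_um, tolerance = 1e-12)
  expect_error(run_sweep(H = numeric(0)), "empty parameter grid")
})
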