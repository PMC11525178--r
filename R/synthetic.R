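#' Synthetic sensor deformation trajectory
#'
#' Generates a saturating-exponential strain history
#' `s(t) = s_max * (1 - exp(-t / tau))`, the canonical rise-to-plateau shape
#' of medial compression during fold apposition; `widening` mode mirrors it
#' (negative strain) to emulate anti-closure stretching under ROCK
#' inhibition. Gaussian width noise emulates measurement scatter. Ground
#' truth (noise-free widths, strain and force) is always returned alongside
#' and is never contaminated by noise. A `piecewise_linear` profile is
#' available for edge-case tests.
#'
#' @param s_max plateau strain in % (default 8, which with the default
#'   geometry and stiffness corresponds to a plateau force of ~100 nN).
#' @param tau time constant in minutes (default 45: most of the rise within
#'   one to two hours).
#' @param mode `"compressive"` or `"widening"`.
#' @param noise_sd width noise SD in um (default 0).
#' @param seed optional RNG seed; the generator is a pure function of
#'   (parameters, seed).
#' @param width0 printed width in um.
#' @param times sample times in minutes.
#' @param k optional stiffness (nN/um) for the ground-truth force.
#' @param profile `"saturating"` (default) or `"piecewise_linear"` (linear
#'   rise to `s_max` at `3 * tau`, then flat).
#' @return List with `trace` (a [deformation_trace()], noisy) and `truth`
#'   (noise-free `width`, `strain`, and `force` when `k` is given).
#' @export
make_trajectory <- function(s_max = 8, tau = 45,
                            mode = c("compressive", "widening"),
                            noise_sd = 0, seed = NULL,
                            width0 = 180, times = seq(0, 480, by = 30),
                            k = NULL,
                            profile = c("saturating", "piecewise_linear")) {
  mode <- match.arg(mode); profile <- match.arg(profile)
  if (tau <= 0) .err("invalid-argument", "tau must be positive")
  if (noise_sd < 0) .err("invalid-argument", "noise_sd must be >= 0")
  s <- if (profile == "saturating") s_max * (1 - exp(-times / tau)) else
    pmin(s_max, s_max * times / (3 * tau))
  if (mode == "widening") s <- -s
  width_true <- width0 * (1 - s / 100)
  width <- if (noise_sd > 0) {
    noise <- if (is.null(seed)) rnorm(length(times), 0, noise_sd) else
      withr::with_seed(seed, rnorm(length(times), 0, noise_sd))
    width_true + noise
  } else width_true
  truth <- list(width = width_true, strain = s,
                force = if (!is.null(k)) k * (width0 - width_true))
  list(trace = deformation_trace(times, width, width0 = width0),
       truth = truth)
}

#' Synthetic embryo cohort
#'
#' Per-embryo plateau strain and time constant are drawn lognormally around
#' the nominal values (the lognormal keeps both positive and matches the
#' right-skewed spread seen across embryos), then each embryo gets its own
#' trajectory. Byte-identical output for a fixed seed.
#'
#' @param n number of embryos (default 10, the cohort size per group).
#' @param variability lognormal SD (sdlog) applied to `s_max` and `tau`
#'   (default 0.15); 0 makes all embryos identical.
#' @param seed RNG seed.
#' @param ... trajectory parameters passed to [make_trajectory()]
#'   (`s_max`, `tau`, `mode`, `noise_sd`, `width0`, `times`, `k`).
#' @return List of [make_trajectory()] results (each with `trace` and
#'   `truth`).
#' @export
make_cohort <- function(n = 10, variability = 0.15, seed = NULL, ...) {
  if (n < 1) .err("invalid-argument", "n must be >= 1")
  args <- list(...)
  s_max <- if (is.null(args$s_max)) 8 else args$s_max
  tau <- if (is.null(args$tau)) 45 else args$tau
  draw <- function() {
    if (variability == 0) {
      cbind(s = rep(s_max, n), tau = rep(tau, n))
    } else {
      # meanlog offset keeps the expected value at the nominal parameter
      cbind(s = rlnorm(n, log(s_max) - variability^2 / 2, variability),
            tau = rlnorm(n, log(tau) - variability^2 / 2, variability))
    }
  }
  pars <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  lapply(seq_len(n), function(i) {
    a <- args
    a$s_max <- pars[i, 1]; a$tau <- pars[i, 2]
    a$seed <- if (is.null(seed)) NULL else seed + i
    do.call(make_trajectory, a)
  })
}

#' Render a deformation trace as a synthetic time-lapse movie
#'
#' Draws one anti-aliased elliptical annulus per frame: the x-extent follows
#' the trace width, while the y-extent bulges by `bulge` times the strain to
#' mimic the contralateral elastic expansion of a compressed ring. Optional
#' Gaussian blur, Poisson photon noise, Gaussian read noise and scripted
#' drift (applied as a sub-pixel shift of the annulus center) emulate live
#' confocal acquisition. All randomness is seeded; the scripted widths and
#' drift are returned as ground truth.
#'
#' @param trace a [deformation_trace()] (scripted widths).
#' @param pixel_size um/px (default 0.59).
#' @param ring_thickness annulus wall thickness in um.
#' @param blur_sd Gaussian blur SD in px (0 disables).
#' @param photon_scale mean photon count at unit intensity for Poisson noise
#'   (0 disables).
#' @param gauss_sd additive Gaussian noise SD (intensity units; 0 disables).
#' @param drift per-frame center drift: `NULL`, a length-2 per-frame step in
#'   px (accumulated), or a T x 2 matrix of absolute px offsets.
#' @param bulge perpendicular expansion per unit strain (default 0.3).
#' @param margin_px extra frame margin in px.
#' @param seed RNG seed.
#' @return List with `stack` (an [image_stack()]) and `truth` (scripted
#'   widths in um and drift in px).
#' @export
render_movie <- function(trace, pixel_size = 0.59, ring_thickness = 15,
                         blur_sd = 1, photon_scale = 0, gauss_sd = 0,
                         drift = NULL, bulge = 0.3, margin_px = 12,
                         seed = NULL) {
  stopifnot(inherits(trace, "deformation_trace"))
  widths <- trace$width
  if (anyNA(widths)) .err("invalid-render", "trace has gaps")
  nT <- length(widths)
  strain <- widths_to_strain(trace)
  b_axis <- trace$width0 * (1 + bulge * pmax(strain, 0) / 100) / 2
  a_axis <- widths / 2

  if (is.null(drift)) {
    drift_px <- matrix(0, nT, 2)
  } else if (is.matrix(drift)) {
    stopifnot(nrow(drift) == nT, ncol(drift) == 2)
    drift_px <- drift
  } else {
    stopifnot(length(drift) == 2)
    drift_px <- cbind((seq_len(nT) - 1) * drift[1], (seq_len(nT) - 1) * drift[2])
  }

  ext_um <- max(a_axis, b_axis) + max(abs(drift_px)) * pixel_size
  half_px <- ceiling(ext_um / pixel_size) + margin_px
  npx <- 2L * half_px + 1L
  if (2 * max(a_axis, b_axis) / pixel_size > npx)
    .err("invalid-render", "widths do not fit the frame")

  block_mean <- function(m, ss) {
    # average ss x ss blocks
    for (ax in 1:2) {
      idx <- seq(1, nrow(m), by = ss)
      acc <- m[idx, , drop = FALSE]
      for (o in seq_len(ss - 1)) acc <- acc + m[idx + o, , drop = FALSE]
      m <- t(acc / ss)
    }
    m
  }
  render <- function() {
    ss <- 4L  # supersampling factor
    base <- (seq_len(npx * ss) - 0.5) / ss - (npx / 2)  # px coords from center
    lapply(seq_len(nT), function(ti) {
      cx <- drift_px[ti, 2]; cy <- drift_px[ti, 1]
      xs <- (base - cx) * pixel_size
      ys <- (base - cy) * pixel_size
      a_o <- a_axis[ti]; b_o <- b_axis[ti]
      a_i <- max(a_o - ring_thickness, 0.5)
      b_i <- max(b_o - ring_thickness, 0.5)
      X2 <- matrix(xs^2, npx * ss, npx * ss, byrow = TRUE)
      Y2 <- matrix(ys^2, npx * ss, npx * ss)
      inside <- (X2 / a_o^2 + Y2 / b_o^2 <= 1) & (X2 / a_i^2 + Y2 / b_i^2 >= 1)
      m <- matrix(as.numeric(inside), npx * ss, npx * ss)
      m <- block_mean(m, ss)
      if (blur_sd > 0)
        m <- EBImage::imageData(EBImage::gblur(EBImage::Image(m), sigma = blur_sd))
      if (photon_scale > 0)
        m <- matrix(rpois(length(m), pmax(m, 0) * photon_scale) / photon_scale,
                    nrow(m), ncol(m))
      if (gauss_sd > 0)
        m <- m + matrix(rnorm(length(m), 0, gauss_sd), nrow(m), ncol(m))
      pmax(m, 0)
    })
  }
  frames <- if (is.null(seed)) render() else withr::with_seed(seed, render())
  dt <- if (length(trace$times) > 1) diff(trace$times)[1] else 30
  list(stack = image_stack(frames, pixel_size = pixel_size, time_step = dt),
       truth = list(width = widths, drift_px = drift_px))
}

#' Synthetic AFM indentation curve
#'
#' Forward pyramidal-contact model plus seeded multiplicative Gaussian noise.
#'
#' @param E_kPa sample Young's modulus in kPa.
#' @param theta tip half-angle, degrees.
#' @param contact_point contact-point offset in um.
#' @param noise multiplicative noise SD (e.g. 0.01 for 1%).
#' @param seed RNG seed.
#' @param max_depth maximum indentation depth, um.
#' @param n number of samples.
#' @param nu Poisson ratio (default 0.5).
#' @param prefactor pyramid constant (default 0.7453).
#' @return List with `curve` (an [afm_curve()]) and `truth` (`E_kPa`,
#'   `contact_point`, noise-free force).
#' @export
make_afm_curve <- function(E_kPa = 80, theta = 20, contact_point = 0,
                           noise = 0, seed = NULL, max_depth = 2, n = 200,
                           nu = 0.5, prefactor = 0.7453) {
  if (E_kPa <= 0) .err("invalid-argument", "E must be positive")
  depth <- seq(0, max_depth, length.out = n)
  f_true <- hertz_pyramid_force(depth, kpa_to_pa(E_kPa), theta, contact_point,
                                nu = nu, prefactor = prefactor)
  f <- if (noise > 0) {
    mult <- if (is.null(seed)) rnorm(n, 1, noise) else
      withr::with_seed(seed, rnorm(n, 1, noise))
    f_true * mult
  } else f_true
  list(curve = afm_curve(depth, f, tip_half_angle = theta),
       truth = list(E_kPa = E_kPa, contact_point = contact_point,
                    force = f_true))
}

#' Synthetic uniaxial stress-strain record
#'
#' @param E_kPa Young's modulus in kPa.
#' @param model `"linear"`, `"neo_hookean"` (incompressible uniaxial
#'   closed form) or `"quadratic"` (stress = strain^2, in kPa; a deliberately
#'   nonlinear record for tests).
#' @param max_strain largest nominal strain.
#' @param n number of samples (including strain 0).
#' @param noise_sd additive stress noise SD in kPa.
#' @param seed RNG seed.
#' @return A [stress_strain_record()].
#' @export
make_stress_strain <- function(E_kPa = 80, model = c("linear", "neo_hookean",
                                                     "quadratic"),
                               max_strain = 0.2, n = 100, noise_sd = 0,
                               seed = NULL) {
  model <- match.arg(model)
  strain <- seq(0, max_strain, length.out = n)
  stress <- switch(model,
    linear = E_kPa * strain,
    neo_hookean = pa_to_kpa(neo_hookean_uniaxial(1 + strain,
                                                 material_model(E_kPa, nu = 0.5))),
    quadratic = strain^2
  )
  if (noise_sd > 0) {
    eps <- if (is.null(seed)) rnorm(n, 0, noise_sd) else
      withr::with_seed(seed, rnorm(n, 0, noise_sd))
    stress <- stress + eps
  }
  stress_strain_record(strain, stress, units = "kPa")
}
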