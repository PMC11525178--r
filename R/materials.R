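#' Hyperelastic material description
#'
#' Bundles Young's modulus and Poisson ratio with the derived neo-Hookean
#' constants: shear modulus `mu = E / (2 (1 + nu))` and `c10 = mu / 2`.
#' The hydrogel sensors are nearly incompressible; `nu = 0.4995` is the
#' default used by the plane-strain ring model, while closed-form uniaxial
#' expressions require the fully incompressible `nu = 0.5`.
#'
#' @param E Young's modulus, in the unit named by `units`.
#' @param nu Poisson ratio in `[0, 0.5]`.
#' @param units `"kPa"` (default, the package's I/O unit) or `"Pa"`.
#' @return An object of class `material_model` with fields `E`, `nu`, `mu`,
#'   `c10` (all moduli in Pa) and `E_kPa` for convenience.
#' @examples
#' m <- material_model(80)          # 80 kPa hydrogel
#' m$mu / m$E                       # 1 / (2 (1 + nu))
#' @export
material_model <- function(E, nu = 0.4995, units = c("kPa", "Pa")) {
  units <- match.arg(units)
  E_pa <- if (units == "kPa") kpa_to_pa(E) else E
  if (!is.numeric(E_pa) || length(E_pa) != 1L || !is.finite(E_pa) || E_pa <= 0)
    .err("invalid-argument", "Young's modulus must be a single positive number")
  if (!is.numeric(nu) || length(nu) != 1L || nu < 0 || nu > 0.5)
    .err("invalid-argument", "Poisson ratio must lie in [0, 0.5]")
  mu <- E_pa / (2 * (1 + nu))
  structure(
    list(E = E_pa, nu = nu, mu = mu, c10 = mu / 2, E_kPa = pa_to_kpa(E_pa)),
    class = "material_model"
  )
}

#' @method print material_model
#' @export
print.material_model <- function(x, ...) {
  cat(sprintf("material_model: E = %g kPa, nu = %g, mu = %g kPa, c10 = %g kPa\n",
              x$E_kPa, x$nu, pa_to_kpa(x$mu), pa_to_kpa(x$c10)))
  invisible(x)
}

#' Incompressible neo-Hookean nominal stress in uniaxial loading
#'
#' For an incompressible neo-Hookean solid stretched uniaxially by
#' `lambda`, the nominal (first Piola-Kirchhoff) stress is
#' `mu * (lambda - lambda^-2)`, whose slope at `lambda = 1` is exactly `E`.
#'
#' @param lambda_ stretch ratio(s), > 0 (1 = undeformed).
#' @param material a [material_model()] with `nu = 0.5` (the closed form is
#'   only defined for the incompressible case).
#' @return Nominal stress in Pa (same sign convention as the stretch:
#'   positive in tension).
#' @export
neo_hookean_uniaxial <- function(lambda_, material) {
  if (any(!is.finite(lambda_)) || any(lambda_ <= 0))
    .err("invalid-argument", "stretch ratio must be positive")
  if (!inherits(material, "material_model"))
    .err("invalid-argument", "material must be a material_model")
  if (abs(material$nu - 0.5) > 1e-12)
    .err("unsupported-configuration",
         "closed-form uniaxial stress requires nu = 0.5 (got %g)", material$nu)
  material$mu * (lambda_ - lambda_^(-2))
}

#' Nominal stress-strain record
#'
#' @param strain nominal strain (dimensionless, signed; negative = compression).
#' @param stress nominal stress, in the unit named by `units`.
#' @param units `"kPa"` (default) or `"Pa"`.
#' @return An object of class `stress_strain_record` with `strain` and
#'   `stress` (Pa).
#' @export
stress_strain_record <- function(strain, stress, units = c("kPa", "Pa")) {
  units <- match.arg(units)
  if (length(strain) != length(stress))
    .err("invalid-input", "strain and stress must have equal lengths")
  if (!(any(strain == 0) || (min(strain) < 0 && max(strain) > 0)))
    .err("invalid-input", "strain must contain 0 or bracket it")
  stress_pa <- if (units == "kPa") kpa_to_pa(stress) else stress
  structure(list(strain = as.numeric(strain), stress = as.numeric(stress_pa)),
            class = "stress_strain_record")
}

#' Deviation of a stress-strain record from linearity
#'
#' Fits a least-squares line to the record inside `[0, strain_limit]` and
#' reports the worst residual relative to the largest stress in the window.
#' Used to substantiate that the hydrogel "follows a linear stress-strain
#' profile" over the working strain range.
#'
#' @param record a [stress_strain_record()].
#' @param strain_limit upper strain bound of the assessment window.
#' @return Maximum relative deviation from the best-fit line (dimensionless).
#' @export
linearity_deviation <- function(record, strain_limit) {
  stopifnot(inherits(record, "stress_strain_record"))
  sel <- record$strain >= 0 & record$strain <= strain_limit
  if (sum(sel) < 5L)
    .err("insufficient-data", "need at least 5 points within [0, %g]", strain_limit)
  s <- record$strain[sel]; sig <- record$stress[sel]
  fit <- lm(sig ~ s)
  max(abs(fit$residuals)) / max(abs(sig))
}

#' AFM indentation curve
#'
#' @param depth indentation depth in um (non-negative, strictly increasing).
#' @param force measured load in nN.
#' @param tip_half_angle indenter half-angle in degrees, in (0, 90).
#' @param spring_constant cantilever spring constant in N/m (nominal 0.2;
#'   metadata only, the fit operates on the calibrated force channel).
#' @return An object of class `afm_curve`.
#' @export
afm_curve <- function(depth, force, tip_half_angle = 20, spring_constant = 0.2) {
  if (length(depth) != length(force))
    .err("invalid-input", "depth and force must have equal lengths")
  if (any(diff(depth) <= 0))
    .err("invalid-input", "depth must be strictly increasing")
  if (any(depth < 0)) .err("invalid-input", "depth must be non-negative")
  if (tip_half_angle <= 0 || tip_half_angle >= 90)
    .err("invalid-input", "tip_half_angle must be in (0, 90) degrees")
  structure(list(depth = as.numeric(depth), force = as.numeric(force),
                 tip_half_angle = tip_half_angle,
                 spring_constant = spring_constant),
            class = "afm_curve")
}

# forward pyramidal-contact model: depth um, E Pa -> force nN
hertz_pyramid_force <- function(depth_um, E_pa, theta_deg, contact_point_um = 0,
                                nu = 0.5, prefactor = 0.7453) {
  d <- pmax(depth_um - contact_point_um, 0) * 1e-6           # m
  f_n <- prefactor * E_pa / (1 - nu^2) * tan(theta_deg * pi / 180) * d^2
  f_n * 1e9                                                   # nN
}

#' Fit the pyramidal Hertz model to an AFM force curve
#'
#' Least-squares fit of `F = c * E / (1 - nu^2) * tan(theta) * (d - d0)^2`
#' with Young's modulus `E` and the contact point `d0` estimated jointly:
#' `d0` is profiled (for fixed `d0`, `E` has a closed-form solution), starting
#' from the depth at which the force first exceeds three times the pre-contact
#' noise level. The pyramid constant `c = 0.7453` is the standard four-sided
#' pyramidal-indenter approximation; it is exposed because vendor software may
#' use a paraboloid variant instead.
#'
#' @param curve an [afm_curve()].
#' @param nu Poisson ratio assumed for the sample (default 0.5, the common
#'   choice for PEG hydrogels).
#' @param prefactor pyramid contact constant (default 0.7453).
#' @return An object of class `hertz_fit` with `E_est` (Pa), `contact_point`
#'   (um) and `rms_residual` (nN).
#' @export
fit_hertz_pyramidal <- function(curve, nu = 0.5, prefactor = 0.7453) {
  stopifnot(inherits(curve, "afm_curve"))
  d <- curve$depth; f <- curve$force
  if (all(f == 0)) .err("degenerate-curve", "force is identically zero")

  theta <- curve$tip_half_angle
  shape <- function(d0) pmax(d - d0, 0)^2  # um^2; unit factors fold into E
  # E closed form given d0 (units handled after)
  rss <- function(d0) {
    x <- shape(d0)
    if (sum(x > 0) < 10L) return(Inf)
    a <- sum(f * x) / sum(x^2)
    if (!is.finite(a) || a <= 0) return(Inf)
    sum((f - a * x)^2)
  }

  # initial guess: first depth where force exceeds 3x pre-contact noise SD
  n0 <- max(5L, floor(length(f) * 0.1))
  noise_sd <- sd(f[seq_len(n0)])
  thr <- 3 * max(noise_sd, .Machine$double.eps)
  idx <- which(f > thr)
  d0_init <- if (length(idx)) d[idx[1]] else d[1]

  lo <- min(d); hi <- d[max(1L, length(d) - 10L)]
  span <- max(hi - lo, .Machine$double.eps)
  lo2 <- max(lo, d0_init - 0.25 * span)
  hi2 <- min(hi, d0_init + 0.25 * span)
  if (hi2 <= lo2) { lo2 <- lo; hi2 <- hi }
  opt <- optimize(rss, interval = c(lo2, hi2), tol = 1e-10)
  if (!is.finite(opt$objective))
    .err("convergence-failure",
         "contact-point profile failed (fewer than 10 post-contact points?)")

  d0 <- opt$minimum
  x <- shape(d0)
  a <- sum(f * x) / sum(x^2)                      # nN / um^2
  # F[nN] = c E/(1-nu^2) tan(theta) (d[m])^2 * 1e9  =>  a = c E tan /(1-nu^2) * 1e-12 * 1e9
  E_pa <- a * (1 - nu^2) / (prefactor * tan(theta * pi / 180)) * 1e3
  if (!is.finite(E_pa) || E_pa <= 0)
    .err("convergence-failure", "fit did not yield a positive modulus")
  resid <- f - a * x
  structure(list(E_est = E_pa, contact_point = d0,
                 rms_residual = sqrt(mean(resid^2)),
                 nu = nu, prefactor = prefactor, n = length(f)),
            class = "hertz_fit")
}

#' @method print hertz_fit
#' @export
print.hertz_fit <- function(x, ...) {
  cat(sprintf("hertz_fit: E = %.4g kPa, contact point = %.4g um, rms residual = %.3g nN\n",
              pa_to_kpa(x$E_est), x$contact_point, x$rms_residual))
  invisible(x)
}

#' @export
coef.hertz_fit <- function(object, ...) {
  c(E_Pa = object$E_est, contact_point_um = object$contact_point)
}

#' Young's modulus from a uniaxial stress-strain record
#'
#' Slope of the least-squares line through the points inside `window`,
#' forced through the origin when the window contains zero strain (the
#' undeformed reference). The default 0-5% window takes the small-strain
#' slope, which is the modulus definition the ring FEM consumes.
#'
#' @param record a [stress_strain_record()].
#' @param window length-2 strain interval.
#' @return Estimated Young's modulus in Pa.
#' @export
fit_uniaxial_modulus <- function(record, window = c(0, 0.05)) {
  stopifnot(inherits(record, "stress_strain_record"), length(window) == 2L)
  window <- sort(window)
  sel <- record$strain >= window[1] & record$strain <= window[2]
  if (sum(sel) < 2L)
    .err("insufficient-data", "window [%g, %g] contains fewer than 2 points",
         window[1], window[2])
  s <- record$strain[sel]; sig <- record$stress[sel]
  if (window[1] <= 0 && window[2] >= 0) {
    sum(s * sig) / sum(s^2)
  } else {
    unname(coef(lm(sig ~ s))[2])
  }
}
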