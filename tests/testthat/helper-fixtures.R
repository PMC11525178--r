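# Shared fixtures and independent oracles used across test files.

# representative sensor used throughout (mid-range geometry, 80 kPa hydrogel)
rep_geometry <- function() cylinder_geometry(H = 20, D = 180, t = 15)

hydrogel <- function(nu = 0.4995) material_model(80, nu = nu)

# classical diametral ring-bending stiffness (point loads, thin centroidal
# ring of diameter D_mid): k = E H (t/D_mid)^3 * 8 / (12 (pi/4 - 2/pi))
ring_closed_form_k <- function(E_kPa, H, t, D_mid) {
  E_kPa * H * (t / D_mid)^3 * 8 / (12 * (pi / 4 - 2 / pi))
}

# brute-force sliding-window impulse oracle: dense scan over window starts
# of (F(t+w) - F(t)) * w on the piecewise-linear interpolant
impulse_scan_oracle <- function(times, force, window = 60, dt = 0.01) {
  f <- function(t) approx(times, force, xout = t, rule = 2)$y
  starts <- seq(min(times), max(times) - window, by = dt)
  max((f(starts + window) - f(starts)) * window)
}

# analytic through-origin least-squares slope of the incompressible
# neo-Hookean uniaxial record sampled at the given strains
nh_origin_slope_oracle <- function(E_kPa, strains) {
  mu <- E_kPa / 3
  lam <- 1 + strains
  sig <- mu * (lam - lam^(-2))
  sum(sig * strains) / sum(strains^2)
}

# boolean ground-truth sensor footprint (hole-filled ellipse, matching the
# segmentation pipeline's fillHull step) on render_movie's pixel grid
ellipse_disc_mask <- function(npx, pixel_size, a_outer, b_outer) {
  ctr <- (npx + 1) / 2
  xs <- ((1:npx) - ctr) * pixel_size
  X2 <- matrix(xs^2, npx, npx, byrow = TRUE)
  Y2 <- matrix(xs^2, npx, npx)
  X2 / a_outer^2 + Y2 / b_outer^2 <= 1
}
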