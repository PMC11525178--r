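#' Rigid-surface contact configuration for the ring model
#'
#' The apposing tissue folds are modelled as two rigid, frictionless surfaces
#' approaching symmetrically along the mediolateral (x) axis. Three surface
#' shapes are available: `flat_plates` (default), `point_load` (prescribed
#' displacement of the two outermost nodes; the classical diametral-load
#' idealization used for the analytic cross-check) and `conforming_arc`
#' (rigid surfaces shaped like the undeformed outer wall over a given
#' half-angle, emulating distributed tissue contact).
#'
#' @param mode one of `"flat_plates"`, `"point_load"`, `"conforming_arc"`.
#' @param arc_half_angle half-angle of the conforming contact arc, degrees in
#'   (0, 90]; only used by `conforming_arc`.
#' @param penalty contact penalty scale, a dimensionless multiple of the
#'   material Young's modulus (default 1e3).
#' @return An object of class `contact_config`.
#' @export
contact_config <- function(mode = c("flat_plates", "point_load", "conforming_arc"),
                           arc_half_angle = 30, penalty = 1e3) {
  mode <- match.arg(mode)
  if (penalty <= 0) .err("invalid-argument", "penalty must be positive")
  if (mode == "conforming_arc" &&
      (arc_half_angle <= 0 || arc_half_angle > 90))
    .err("invalid-argument", "arc_half_angle must be in (0, 90] degrees")
  structure(list(mode = mode, arc_half_angle = arc_half_angle,
                 penalty = penalty, friction = "frictionless"),
            class = "contact_config")
}

#' Contact-force versus narrowing curve
#'
#' @param narrowing mediolateral outer-diameter reduction, um (>= 0,
#'   strictly increasing, starting at 0).
#' @param force total contact force on one rigid surface, nN (0 at zero
#'   narrowing).
#' @param geometry optional [cylinder_geometry()] the curve belongs to.
#' @return An object of class `fd_curve`.
#' @export
fd_curve <- function(narrowing, force, geometry = NULL) {
  if (length(narrowing) != length(force))
    .err("invalid-input", "narrowing and force must have equal lengths")
  if (any(diff(narrowing) <= 0))
    .err("invalid-input", "narrowing must be strictly increasing")
  if (narrowing[1] != 0 || abs(force[1]) > 1e-9 * max(abs(force), 1))
    .err("invalid-input", "curve must start at (0, 0)")
  structure(list(narrowing = as.numeric(narrowing), force = as.numeric(force),
                 geometry = geometry),
            class = "fd_curve")
}

#' @method print fd_curve
#' @export
print.fd_curve <- function(x, ...) {
  cat(sprintf("fd_curve: %d points, narrowing up to %.3g um, force up to %.4g nN\n",
              length(x$narrowing), max(x$narrowing), max(x$force)))
  invisible(x)
}

#' @export
plot.fd_curve <- function(x, ...) {
  plot(x$narrowing, x$force, type = "b", pch = 16,
       xlab = "mediolateral narrowing (um)", ylab = "contact force (nN)", ...)
  invisible(x)
}

#' @export
as.data.frame.fd_curve <- function(x, ...) {
  data.frame(narrowing_um = x$narrowing, force_nN = x$force)
}

# material constants in kPa for a given 2D formulation
.plane_material <- function(material, formulation) {
  E <- material$E_kPa; nu <- material$nu
  if (formulation == "plane_strain") {
    if (nu >= 0.5 - 1e-9)
      .err("unsupported-configuration",
           "plane strain requires nu < 0.5 (use e.g. nu = 0.4995 for near incompressibility)")
    list(mu = E / (2 * (1 + nu)), lambda = E * nu / ((1 + nu) * (1 - 2 * nu)), form = 0L)
  } else {
    if (abs(nu - 0.5) > 1e-6)
      .err("unsupported-configuration",
           "the plane-stress ring model uses the incompressible closed form and requires nu = 0.5")
    list(mu = E / 3, lambda = 0, form = 1L)
  }
}

#' Diametral compression of the ring between rigid surfaces
#'
#' Displacement-controlled, geometrically nonlinear static solve of the ring
#' cross-section squeezed along the mediolateral axis, using neo-Hookean
#' plane elements (see Details) and frictionless penalty contact. The
#' cross-sectional (per-unit-height) contact force is multiplied by the
#' cylinder height `H` to give the total force in nN.
#'
#' Two plane reductions of the 3D wall are provided. `plane_strain`
#' (default), with the near-incompressible `nu` carried by `material`, treats
#' the wall as constrained along the cylinder axis - the appropriate limit
#' when the height is large compared with the wall thickness, and the setting
#' used for the calibration sweep. `plane_stress` (requires `nu = 0.5`,
#' incompressible closed form) leaves the axial direction free, which is the
#' reduction under which the classical thin-ring bending solution with
#' flexural modulus `E` holds exactly.
#'
#' @param mesh a [build_ring_mesh()] result.
#' @param material a [material_model()].
#' @param contact a [contact_config()].
#' @param max_narrowing total mediolateral narrowing to apply, um
#'   (< 0.4 D).
#' @param n_steps number of equal displacement increments; default takes
#'   steps of 1% of D.
#' @param formulation `"plane_strain"` or `"plane_stress"`.
#' @param newton_tol relative Newton tolerance; convergence is declared when
#'   the free-residual norm falls below `newton_tol * E * t` (the
#'   per-unit-height force scale). Default 1e-8.
#' @param max_iter Newton iteration cap per increment (increments are halved,
#'   up to 5 times, on non-convergence).
#' @param enhanced use incompatible (enhanced) bending modes in the elements
#'   (default TRUE; FALSE gives the plain bilinear element, mainly for
#'   convergence studies).
#' @param fbar apply the centroid-dilatation (F-bar) treatment in plane
#'   strain; default on only for the plain bilinear element, whose bending
#'   response volumetric-locks without it.
#' @return A list with components `solution` (class `ring_solution`: reference
#'   coordinates, final displacement field, per-step plate forces, stored
#'   energy, external work, y-diameter) and `curve` (class `fd_curve`).
#' @export
solve_diametral_compression <- function(mesh, material,
                                        contact = contact_config(),
                                        max_narrowing,
                                        n_steps = NULL,
                                        formulation = c("plane_strain", "plane_stress"),
                                        newton_tol = 1e-8,
                                        max_iter = 30L,
                                        enhanced = TRUE,
                                        fbar = !enhanced) {
  stopifnot(inherits(mesh, "ring_mesh"), inherits(material, "material_model"),
            inherits(contact, "contact_config"))
  formulation <- match.arg(formulation)
  geom <- mesh$geometry
  D <- geom$D; t_wall <- geom$t; H <- geom$H
  if (max_narrowing < 0) .err("invalid-argument", "max_narrowing must be >= 0")
  if (max_narrowing >= 0.4 * D)
    .err("invalid-argument", "max_narrowing must be below 0.4 D")

  mat <- .plane_material(material, formulation)
  E_kPa <- material$E_kPa
  X <- mesh$nodes; conn <- mesh$conn
  nn <- nrow(X); ndof <- 2L * nn
  Ro <- D / 2

  # symmetry/rigid-mode constraints: uy = 0 on the y = 0 plane,
  # ux = 0 on the x = 0 plane (both are true symmetry planes here)
  tolc <- 1e-6 * D
  fix_y <- which(abs(X[, 2]) < tolc)
  fix_x <- which(abs(X[, 1]) < tolc)
  fixed <- c(2L * fix_y, 2L * fix_x - 1L)
  presc <- integer(0)
  if (contact$mode == "point_load") {
    nc <- mesh$resolution[1]
    n_right <- mesh$outer[1]                  # theta = 0, x = +Ro
    n_left  <- mesh$outer[nc / 2 + 1]         # theta = pi, x = -Ro
    presc <- c(2L * n_right - 1L, 2L * n_left - 1L)
  }
  fixed_all <- sort(unique(c(fixed, presc)))
  free <- setdiff(seq_len(ndof), fixed_all)

  # contact bookkeeping on the outer surface
  outer <- mesh$outer
  kappa <- contact$penalty * E_kPa
  right_set <- left_set <- outer
  if (contact$mode == "conforming_arc") {
    phi <- contact$arc_half_angle * pi / 180
    th <- mesh$theta
    ang_dist <- function(a, b) abs(atan2(sin(a - b), cos(a - b)))
    right_set <- outer[ang_dist(th, 0) <= phi]
    left_set <- outer[ang_dist(th, pi) <= phi]
  }

  contact_state <- function(u, delta) {
    if (contact$mode == "point_load")
      return(list(f = numeric(ndof), diag_idx = integer(0),
                  FR = NA_real_, FL = NA_real_, pen = 0, energy = 0))
    f <- numeric(ndof)
    if (contact$mode == "flat_plates") {
      xp <- Ro - delta / 2
      xr <- X[right_set, 1] + u[2L * right_set - 1L]
      gr <- xr - xp
      xl <- X[left_set, 1] + u[2L * left_set - 1L]
      gl <- -xl - xp
    } else {
      xr <- X[right_set, 1] + u[2L * right_set - 1L]
      gr <- xr - (X[right_set, 1] - delta / 2)
      xl <- X[left_set, 1] + u[2L * left_set - 1L]
      gl <- -xl - (-X[left_set, 1] - delta / 2)
    }
    ar <- gr > 0; al <- gl > 0
    f[2L * right_set[ar] - 1L] <- kappa * gr[ar]
    f[2L * left_set[al] - 1L] <- -kappa * gl[al]
    list(f = f,
         diag_idx = c(2L * right_set[ar] - 1L, 2L * left_set[al] - 1L),
         FR = kappa * sum(gr[ar]), FL = kappa * sum(gl[al]),
         pen = max(0, gr[ar], gl[al]),
         energy = 0.5 * kappa * (sum(gr[ar]^2) + sum(gl[al]^2)))
  }

  tol <- newton_tol * E_kPa * t_wall
  u <- numeric(ndof)
  # internal (incompatible-mode) parameters, warm-started across increments
  amat <- matrix(0, nrow(conn), 4)

  newton <- function(u, delta) {
    if (contact$mode == "point_load") {
      u[presc[1]] <- -delta / 2
      u[presc[2]] <- delta / 2
    }
    du_cap <- 0.05 * D  # per-iteration displacement cap guards against overshoot
    # work on a private copy of the internal-mode state: a diverging attempt
    # must not poison the warm start of the retry after bisection
    a_try <- amat * 1
    for (it in seq_len(max_iter)) {
      asm <- tryCatch(fem_assemble(X, conn, u, a_try, mat$mu, mat$lambda,
                                   mat$form, TRUE, enhanced, fbar = fbar),
                      error = function(e) NULL)
      if (is.null(asm)) return(list(u = u, converged = FALSE))
      cs <- contact_state(u, delta)
      r <- asm$residual + cs$f
      rf <- r[free]
      nrm <- sqrt(sum(rf^2))
      if (nrm < tol) {
        amat[] <<- a_try   # commit the converged internal-mode state
        return(list(u = u, iters = it - 1L, energy = asm$energy, cs = cs, r = r,
                    converged = TRUE))
      }
      K <- Matrix::sparseMatrix(i = asm$i, j = asm$j, x = asm$v,
                                dims = c(ndof, ndof))
      if (length(cs$diag_idx))
        K <- K + Matrix::sparseMatrix(i = cs$diag_idx, j = cs$diag_idx,
                                      x = rep(kappa, length(cs$diag_idx)),
                                      dims = c(ndof, ndof))
      du <- as.numeric(Matrix::solve(K[free, free, drop = FALSE], -rf))
      mx <- max(abs(du))
      if (mx > du_cap) du <- du * (du_cap / mx)
      u[free] <- u[free] + du
    }
    list(u = u, converged = FALSE)
  }

  # one increment with up to 5 bisections
  advance <- function(u, d_from, d_to, depth = 0L, step_index = NA_integer_) {
    res <- newton(u, d_to)
    if (res$converged) return(res)
    if (depth >= 5L)
      .err("convergence-failure",
           "Newton failed at step %s (narrowing %.4g um) after 5 bisections",
           step_index, d_to)
    mid <- (d_from + d_to) / 2
    res <- advance(u, d_from, mid, depth + 1L, step_index)
    advance(res$u, mid, d_to, depth + 1L, step_index)
  }

  if (is.null(n_steps)) n_steps <- max(1L, ceiling(max_narrowing / (0.01 * D)))
  deltas <- if (max_narrowing == 0) numeric(0) else
    seq(max_narrowing / n_steps, max_narrowing, length.out = n_steps)

  FR <- FL <- W_store <- y_diam <- iters <- pens <- numeric(length(deltas))
  work_ext <- 0; F_prev <- 0; d_prev <- 0
  final <- NULL

  for (s in seq_along(deltas)) {
    res <- advance(u, d_prev, deltas[s], step_index = s)
    u <- res$u
    if (contact$mode == "point_load") {
      # reactions at the prescribed dofs (per unit height)
      FR[s] <- -res$r[presc[1]]     # force on the ring from the right loader acts in -x
      FL[s] <- res$r[presc[2]]
      pens[s] <- 0
    } else {
      FR[s] <- res$cs$FR; FL[s] <- res$cs$FL
      pens[s] <- res$cs$pen
      if (res$cs$pen > 1e-3 * t_wall)
        .err("contact-resolution-failure",
             "penetration %.3g um exceeds 1e-3 t at step %d", res$cs$pen, s)
    }
    W_store[s] <- (res$energy + res$cs$energy) * H   # fJ (nN um)
    yy <- X[outer, 2] + u[2L * outer]
    y_diam[s] <- max(yy) - min(yy)
    iters[s] <- res$iters
    F_mean <- 0.5 * (abs(FR[s]) + abs(FL[s])) * H    # nN
    work_ext <- work_ext + 0.5 * (F_prev + F_mean) * (deltas[s] - d_prev)
    F_prev <- F_mean; d_prev <- deltas[s]
    final <- res
  }

  force_total <- if (length(deltas)) 0.5 * (abs(FR) + abs(FL)) * H else numeric(0)
  curve <- fd_curve(c(0, deltas), c(0, force_total), geometry = geom)
  solution <- structure(list(
    node_coords = X, u = matrix(u, ncol = 2, byrow = TRUE),
    narrowing = c(0, deltas),
    force_right = c(0, abs(FR) * H), force_left = c(0, abs(FL) * H),
    strain_energy_fJ = c(0, W_store), external_work_fJ = work_ext,
    y_diameter = c(D, y_diam), penetration = pens, newton_iters = iters,
    geometry = geom, contact = contact, formulation = formulation,
    material = material
  ), class = "ring_solution")
  list(solution = solution, curve = curve)
}

#' @method print ring_solution
#' @export
print.ring_solution <- function(x, ...) {
  cat(sprintf(
    "ring_solution: %s/%s, narrowing %.3g um, force %.4g nN, %d steps\n",
    x$contact$mode, x$formulation, max(x$narrowing),
    max(x$force_right), length(x$narrowing) - 1L))
  invisible(x)
}

#' Small-displacement structural stiffness from a force-displacement curve
#'
#' Slope of the least-squares line through the origin over narrowing up to
#' `window * D` (default 2% of the diameter, the small-displacement regime in
#' which the stiffness is treated as a constant).
#'
#' @param curve an [fd_curve()] carrying its geometry (or pass `D`).
#' @param window narrowing window as a fraction of the diameter.
#' @param D diameter override, um, if the curve has no geometry attached.
#' @return Stiffness k in nN/um.
#' @export
extract_stiffness <- function(curve, window = 0.02, D = NULL) {
  stopifnot(inherits(curve, "fd_curve"))
  if (is.null(D)) {
    if (is.null(curve$geometry)) .err("invalid-argument", "curve has no geometry; supply D")
    D <- curve$geometry$D
  }
  sel <- curve$narrowing > 0 & curve$narrowing <= window * D
  if (sum(sel) < 3L)
    .err("insufficient-data",
         "need at least 3 nonzero points with narrowing <= %.3g um", window * D)
  d <- curve$narrowing[sel]; f <- curve$force[sel]
  sum(f * d) / sum(d^2)
}

#' Strain up to which the force-narrowing relationship stays linear
#'
#' Compares the secant stiffness `F/delta` at each point with the initial
#' tangent stiffness (from [extract_stiffness()]) and returns the largest
#' strain (100 * delta / D) reached before the relative deviation first
#' exceeds `tolerance`.
#'
#' @param curve an [fd_curve()].
#' @param geometry a [cylinder_geometry()]; defaults to the curve's.
#' @param tolerance allowed relative secant deviation (default 0.10).
#' @param window tangent-fit window passed to [extract_stiffness()].
#' @return Linearity limit in % strain.
#' @export
linearity_limit <- function(curve, geometry = curve$geometry, tolerance = 0.10,
                            window = 0.02) {
  stopifnot(inherits(curve, "fd_curve"))
  if (is.null(geometry)) .err("invalid-argument", "no geometry available")
  D <- geometry$D
  k0 <- extract_stiffness(curve, window = window, D = D)
  sel <- curve$narrowing > 0
  if (sum(sel) < 3L) .err("insufficient-data", "curve too short")
  d <- curve$narrowing[sel]; f <- curve$force[sel]
  dev <- abs(f / d - k0) / k0
  bad <- which(dev > tolerance)
  last_ok <- if (length(bad)) bad[1] - 1L else length(d)
  if (last_ok == 0L) return(0)
  100 * d[last_ok] / D
}
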