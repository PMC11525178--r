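#' Planar frame (beam) shape
#'
#' Slender printed shapes - straight or initially curved bars, V-springs -
#' are modelled as planar Euler-Bernoulli beams with rectangular cross
#' section: in-plane width `section_width` and out-of-plane `depth`, so
#' `A = width * depth` and `I = depth * width^3 / 12`.
#'
#' @param centerline ordered n x 2 matrix of planar points, um (n >= 2).
#' @param section_width in-plane thickness, um.
#' @param depth out-of-plane extrusion, um.
#' @param ends end constraint, `"pinned"` (default) or `"fixed"`.
#' @return An object of class `frame_shape`.
#' @export
frame_shape <- function(centerline, section_width, depth, ends = c("pinned", "fixed")) {
  ends <- match.arg(ends)
  centerline <- as.matrix(centerline)
  if (nrow(centerline) < 2L || ncol(centerline) != 2L)
    .err("invalid-geometry", "centerline needs at least 2 planar points")
  if (section_width <= 0 || depth <= 0)
    .err("invalid-geometry", "section dimensions must be positive")
  seg <- sqrt(rowSums(diff(centerline)^2))
  if (any(seg == 0)) .err("invalid-geometry", "repeated centerline points")
  L <- sum(seg)
  if (section_width > L / 5)
    warning("section width exceeds length/5; slender-beam theory is stretched here",
            call. = FALSE)
  structure(list(centerline = centerline, section_width = section_width,
                 depth = depth, ends = ends, length = L),
            class = "frame_shape")
}

# internal force (9 or 3n dof) of one corotational beam element.
# dofs per node: (ux, uy, rot). E in kPa, lengths um -> forces nN, moments nN um.
.beam_internal <- function(p1, p2, u1, u2, th1, th2, b0, L0, EA, EI) {
  x1 <- p1 + u1; x2 <- p2 + u2
  dx <- x2 - x1
  L <- sqrt(sum(dx^2))
  b <- atan2(dx[2], dx[1])
  # local rotations relative to the rotated chord, kept in (-pi, pi)
  wrap <- function(a) atan2(sin(a), cos(a))
  t1l <- wrap(th1 - (b - b0))
  t2l <- wrap(th2 - (b - b0))
  ul <- L - L0
  N <- EA * ul / L0
  M1 <- (EI / L0) * (4 * t1l + 2 * t2l)
  M2 <- (EI / L0) * (2 * t1l + 4 * t2l)
  c_ <- dx[1] / L; s_ <- dx[2] / L
  r <- c(-c_, -s_, 0, c_, s_, 0)
  z <- c(s_, -c_, 0, -s_, c_, 0)   # = L * d(beta)/du
  # exact gradient of the element energy:
  # q = N dul/du + M1 dth1l/du + M2 dth2l/du, dthil/du = e_i - z/L
  q <- N * r - ((M1 + M2) / L) * z
  q[3] <- q[3] + M1
  q[6] <- q[6] + M2
  list(q = q, energy = 0.5 * (N * ul + M1 * t1l + M2 * t2l))
}

#' Geometrically nonlinear compression of a planar frame
#'
#' Corotational beam solve under displacement-controlled end shortening along
#' the chord connecting the two ends. Internally the shape is rotated so the
#' chord lies along x; the moving end is driven towards the fixed end and the
#' reaction force along the chord is reported. Element tangents are finite
#' differences of the analytic corotational internal force.
#'
#' A perfectly straight column has no lateral trigger and simply shortens
#' axially; buckling studies should supply a small initial imperfection via
#' the centerline (e.g. a sine with amplitude 0.1% of the length).
#'
#' @param shape a [frame_shape()].
#' @param material a [material_model()].
#' @param end_shortening total chordwise end displacement, um.
#' @param n_steps number of increments (default 40).
#' @param newton_tol relative force tolerance (default 1e-9 of `EA`).
#' @param max_iter Newton cap per increment.
#' @return An [fd_curve()] of reaction force (nN) versus end shortening (um).
#' @export
solve_frame_compression <- function(shape, material, end_shortening,
                                    n_steps = 40L, newton_tol = 1e-9,
                                    max_iter = 50L) {
  stopifnot(inherits(shape, "frame_shape"), inherits(material, "material_model"))
  if (end_shortening < 0) .err("invalid-argument", "end_shortening must be >= 0")
  P <- shape$centerline
  n <- nrow(P)
  # rotate so the chord is along +x
  chord <- P[n, ] - P[1, ]
  ang <- atan2(chord[2], chord[1])
  Rm <- matrix(c(cos(-ang), -sin(-ang), sin(-ang), cos(-ang)), 2, 2, byrow = TRUE)
  P <- t(Rm %*% (t(P) - P[1, ])) # first end at origin, chord on x

  E <- material$E_kPa
  A <- shape$section_width * shape$depth
  I <- shape$depth * shape$section_width^3 / 12
  EA <- E * A; EI <- E * I

  L0 <- sqrt(rowSums(diff(P)^2))
  b0 <- atan2(diff(P)[, 2], diff(P)[, 1])
  ndof <- 3L * n
  dof <- function(i) (3L * (i - 1L) + 1L):(3L * i)

  fixed <- c(1L, 2L)                        # end 1 pinned at origin
  presc <- 3L * (n - 1L) + 1L               # ux of end n, driven
  fixed <- c(fixed, presc, 3L * (n - 1L) + 2L)  # uy of end n
  if (shape$ends == "fixed") fixed <- c(fixed, 3L, 3L * n)
  fixed <- sort(unique(fixed))
  free <- setdiff(seq_len(ndof), fixed)

  internal <- function(u) {
    q <- numeric(ndof); en <- 0
    for (e in seq_len(n - 1L)) {
      i1 <- dof(e); i2 <- dof(e + 1L)
      el <- .beam_internal(P[e, ], P[e + 1L, ],
                           u[i1[1:2]], u[i2[1:2]], u[i1[3]], u[i2[3]],
                           b0[e], L0[e], EA, EI)
      q[c(i1, i2)] <- q[c(i1, i2)] + el$q
      en <- en + el$energy
    }
    list(q = q, energy = en)
  }

  tangent <- function(u, q0) {
    K <- matrix(0, ndof, ndof)
    h <- 1e-6 * shape$length
    for (e in seq_len(n - 1L)) {
      idx <- c(dof(e), dof(e + 1L))
      qe0 <- .beam_internal(P[e, ], P[e + 1L, ], u[idx[1:2]], u[idx[4:5]],
                            u[idx[3]], u[idx[6]], b0[e], L0[e], EA, EI)$q
      for (k in seq_len(6L)) {
        up <- u; hk <- if (k %% 3L == 0L) 1e-6 else h  # rotations are O(1)
        up[idx[k]] <- up[idx[k]] + hk
        qe1 <- .beam_internal(P[e, ], P[e + 1L, ], up[idx[1:2]], up[idx[4:5]],
                              up[idx[3]], up[idx[6]], b0[e], L0[e], EA, EI)$q
        K[idx, idx[k]] <- K[idx, idx[k]] + (qe1 - qe0) / hk
      }
    }
    0.5 * (K + t(K))
  }

  tol <- newton_tol * EA
  u <- numeric(ndof)
  steps <- if (end_shortening == 0) numeric(0) else
    seq(end_shortening / n_steps, end_shortening, length.out = n_steps)
  force <- numeric(length(steps))

  for (s in seq_along(steps)) {
    u[presc] <- -steps[s]
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      res <- internal(u)
      rf <- res$q[free]
      if (sqrt(sum(rf^2)) < tol) { converged <- TRUE; break }
      K <- tangent(u, res$q)
      du <- solve(K[free, free, drop = FALSE], -rf)
      u[free] <- u[free] + du
    }
    if (!converged)
      .err("convergence-failure", "frame Newton failed at step %d", s)
    force[s] <- -internal(u)$q[presc]   # compressive reaction positive
  }
  fd_curve(c(0, steps), c(0, force))
}
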