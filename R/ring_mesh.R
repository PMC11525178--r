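#' Cylinder sensor geometry
#'
#' Thin-walled cylinder of height `H`, outer diameter `D` and wall thickness
#' `t` (all um). A warning (not an error) is issued outside the sweep-validated
#' ranges H 20-100, D 140-220, t 5-25 um, within which the parametric
#' stiffness law was calibrated.
#'
#' @param H cylinder height, um.
#' @param D outer diameter, um.
#' @param t wall thickness, um; must satisfy `0 < t < D/2`.
#' @return An object of class `cylinder_geometry`.
#' @export
cylinder_geometry <- function(H, D, t) {
  if (!all(is.finite(c(H, D, t)))) .err("invalid-geometry", "non-finite dimensions")
  if (H <= 0) .err("invalid-geometry", "H must be positive")
  if (t <= 0 || t >= D / 2)
    .err("invalid-geometry", "wall thickness must satisfy 0 < t < D/2 (t = %g, D = %g)", t, D)
  if (H < 20 || H > 100 || D < 140 || D > 220 || t < 5 || t > 25)
    warning(sprintf(
      "geometry (H=%g, D=%g, t=%g) outside sweep-validated ranges H 20-100, D 140-220, t 5-25 um",
      H, D, t), call. = FALSE)
  structure(list(H = H, D = D, t = t), class = "cylinder_geometry")
}

#' @method print cylinder_geometry
#' @export
print.cylinder_geometry <- function(x, ...) {
  cat(sprintf("cylinder_geometry: H = %g um, D = %g um, t = %g um (t/D = %.4f)\n",
              x$H, x$D, x$t, x$t / x$D))
  invisible(x)
}

#' Quadrilateral annulus mesh of the ring cross-section
#'
#' Builds a conforming structured mesh of the ring section (the cylinder wall
#' seen down its axis): `resolution[1]` elements around the circumference and
#' `resolution[2]` through the thickness. Node ordering is deterministic:
#' radial layers from the inner to the outer surface, each layer ordered by
#' angle from the +x (mediolateral) axis.
#'
#' @param geometry a [cylinder_geometry()].
#' @param resolution integer vector `c(n_circumferential, n_radial)`, at
#'   least `c(96, 4)`; the circumferential count must be divisible by 4 so
#'   that the mediolateral and perpendicular symmetry axes pass through nodes.
#' @return An object of class `ring_mesh` with fields `nodes` (n x 2 um),
#'   `conn` (nel x 4, counterclockwise), `outer` (outer-surface node indices),
#'   `geometry` and `resolution`.
#' @export
build_ring_mesh <- function(geometry, resolution = c(96, 4)) {
  stopifnot(inherits(geometry, "cylinder_geometry"))
  nc <- as.integer(resolution[1]); nr <- as.integer(resolution[2])
  if (nc < 96L || nr < 4L)
    .err("invalid-argument", "resolution must be at least (96, 4)")
  if (nc %% 4L != 0L)
    .err("invalid-argument", "circumferential element count must be divisible by 4")

  Ro <- geometry$D / 2
  Ri <- Ro - geometry$t
  theta <- 2 * pi * (0:(nc - 1)) / nc
  radii <- seq(Ri, Ro, length.out = nr + 1)
  nodes <- cbind(
    x = as.vector(outer(cos(theta), radii)),
    y = as.vector(outer(sin(theta), radii))
  )
  node_id <- function(i, j) j * nc + i + 1L  # i in 0..nc-1, j in 0..nr

  conn <- matrix(0L, nc * nr, 4)
  e <- 1L
  for (j in 0:(nr - 1)) {
    for (i in 0:(nc - 1)) {
      ip <- (i + 1L) %% nc
      conn[e, ] <- c(node_id(i, j), node_id(i, j + 1L), node_id(ip, j + 1L), node_id(ip, j))
      e <- e + 1L
    }
  }

  structure(list(
    nodes = nodes, conn = conn,
    outer = node_id(0:(nc - 1), nr),
    inner = node_id(0:(nc - 1), 0L),
    theta = theta, geometry = geometry, resolution = c(nc, nr)
  ), class = "ring_mesh")
}

#' @method print ring_mesh
#' @export
print.ring_mesh <- function(x, ...) {
  cat(sprintf("ring_mesh: %d x %d elements, %d nodes (D = %g, t = %g um)\n",
              x$resolution[1], x$resolution[2], nrow(x$nodes),
              x$geometry$D, x$geometry$t))
  invisible(x)
}

#' Total area of a ring mesh (um^2)
#'
#' Shoelace sum over elements; converges to the annulus area
#' `pi/4 (D^2 - (D - 2t)^2)` as the circumferential resolution grows.
#'
#' @param mesh a [build_ring_mesh()] result.
#' @return Mesh area in um^2.
#' @export
mesh_area <- function(mesh) {
  stopifnot(inherits(mesh, "ring_mesh"))
  x <- matrix(mesh$nodes[mesh$conn, 1], ncol = 4)
  y <- matrix(mesh$nodes[mesh$conn, 2], ncol = 4)
  a <- 0.5 * abs(
    (x[, 1] * y[, 2] - x[, 2] * y[, 1]) +
    (x[, 2] * y[, 3] - x[, 3] * y[, 2]) +
    (x[, 3] * y[, 4] - x[, 4] * y[, 3]) +
    (x[, 4] * y[, 1] - x[, 1] * y[, 4])
  )
  sum(a)
}
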