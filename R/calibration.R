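#' Stiffness parameter sweep over cylinder geometry and modulus
#'
#' Runs one ring contact solve plus small-displacement stiffness extraction
#' per grid point of (H, D, t, E), the four quantities entering the
#' parametric stiffness law. Failed cells are recorded with `status` and the
#' sweep continues. With `cache_dir` set, completed cells are written to disk
#' keyed by their parameters and re-used on the next call, making long sweeps
#' resumable.
#'
#' @param H,D,t grid values in um (defaults: 3 values spanning the validated
#'   ranges 20-100, 140-220 and 5-25 um).
#' @param E_kPa grid values of Young's modulus in kPa (default 3 values
#'   spanning 5-80 kPa).
#' @param resolution mesh resolution passed to [build_ring_mesh()].
#' @param contact a [contact_config()].
#' @param nu Poisson ratio for the plane-strain wall (default 0.4995).
#' @param formulation plane reduction, see [solve_diametral_compression()].
#' @param window stiffness-fit window as a fraction of D (default 0.02).
#' @param cache_dir optional directory for resumable per-cell caching.
#' @param verbose print one line per cell.
#' @return A data frame of class `sweep_table` with columns `H_um`, `D_um`,
#'   `t_um`, `E_kPa`, `k_nN_per_um`, `status`.
#' @export
run_sweep <- function(H = c(20, 60, 100), D = c(140, 180, 220),
                      t = c(5, 15, 25), E_kPa = c(5, 42.5, 80),
                      resolution = c(96, 4),
                      contact = contact_config("flat_plates"),
                      nu = 0.4995,
                      formulation = "plane_strain",
                      window = 0.02,
                      cache_dir = NULL,
                      verbose = FALSE) {
  grid <- expand.grid(H_um = H, D_um = D, t_um = t, E_kPa = E_kPa,
                      KEEP.OUT.ATTRS = FALSE)
  if (nrow(grid) == 0L) .err("invalid-argument", "empty parameter grid")
  if (!is.null(cache_dir) && !dir.exists(cache_dir))
    dir.create(cache_dir, recursive = TRUE)

  k <- rep(NA_real_, nrow(grid))
  status <- rep("ok", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    key <- sprintf("cell_H%g_D%g_t%g_E%g_r%dx%d_%s_%s.csv",
                   g$H_um, g$D_um, g$t_um, g$E_kPa,
                   resolution[1], resolution[2], contact$mode, formulation)
    cache_file <- if (is.null(cache_dir)) NULL else file.path(cache_dir, key)
    if (!is.null(cache_file) && file.exists(cache_file)) {
      k[i] <- read.csv(cache_file)$k_nN_per_um[1]
      next
    }
    res <- tryCatch({
      geom <- cylinder_geometry(g$H_um, g$D_um, g$t_um)
      mesh <- build_ring_mesh(geom, resolution)
      sol <- solve_diametral_compression(
        mesh, material_model(g$E_kPa, nu = nu),
        contact = contact, max_narrowing = window * g$D_um,
        n_steps = 4L, formulation = formulation)
      extract_stiffness(sol$curve, window = window)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      status[i] <- conditionMessage(res)
    } else {
      k[i] <- res
      if (!is.null(cache_file))
        write.csv(data.frame(k_nN_per_um = res), cache_file, row.names = FALSE)
    }
    if (verbose)
      message(sprintf("[%d/%d] H=%g D=%g t=%g E=%g -> k=%.4g (%s)",
                      i, nrow(grid), g$H_um, g$D_um, g$t_um, g$E_kPa,
                      k[i], status[i]))
  }
  out <- cbind(grid, k_nN_per_um = k, status = status)
  class(out) <- c("sweep_table", "data.frame")
  out
}

#' Least-squares fit of the stiffness-law constant alpha
#'
#' Minimizes `sum_i (k_i - alpha * x_i)^2` with `x_i = H_i (t_i/D_i)^3 E_i`,
#' which has the closed-form solution `alpha = sum(k x) / sum(x^2)`. A
#' relative-error weighting mode (residuals divided by k) is provided but is
#' not the default. Failed sweep cells are dropped.
#'
#' @param records a `sweep_table` from [run_sweep()] or any data frame with
#'   columns `H_um`, `D_um`, `t_um`, `E_kPa`, `k_nN_per_um`.
#' @param weighting `"absolute"` (plain least squares, default) or
#'   `"relative"`.
#' @return An object of class `alpha_fit` with `alpha`, `r_squared`
#'   (uncentered, appropriate for a through-origin law), `max_rel_residual`
#'   and the fitted records.
#' @export
fit_alpha <- function(records, weighting = c("absolute", "relative")) {
  weighting <- match.arg(weighting)
  need <- c("H_um", "D_um", "t_um", "E_kPa", "k_nN_per_um")
  if (!all(need %in% names(records)))
    .err("invalid-record", "records must contain columns %s", paste(need, collapse = ", "))
  rec <- records[is.finite(records$k_nN_per_um), , drop = FALSE]
  if (nrow(rec) < 2L) .err("insufficient-data", "need at least 2 usable records")
  x <- rec$H_um * (rec$t_um / rec$D_um)^3 * rec$E_kPa
  k <- rec$k_nN_per_um
  if (any(x <= 0)) .err("invalid-record", "non-positive predictor in sweep records")
  if (any(k <= 0)) .err("invalid-record", "non-positive stiffness in sweep records")

  alpha <- if (weighting == "absolute") {
    sum(k * x) / sum(x^2)
  } else {
    w <- x / k
    sum(w) / sum(w^2)
  }
  resid <- k - alpha * x
  structure(list(
    alpha = alpha,
    weighting = weighting,
    r_squared = 1 - sum(resid^2) / sum(k^2),
    max_rel_residual = max(abs(resid) / k),
    records = rec
  ), class = "alpha_fit")
}

#' @method print alpha_fit
#' @export
print.alpha_fit <- function(x, ...) {
  cat(sprintf("alpha_fit: alpha = %.4f (%s LS, n = %d), R^2 = %.4f, max rel residual = %.3f\n",
              x$alpha, x$weighting, nrow(x$records), x$r_squared, x$max_rel_residual))
  invisible(x)
}

#' @export
coef.alpha_fit <- function(object, ...) c(alpha = object$alpha)

#' @method summary alpha_fit
#' @export
summary.alpha_fit <- function(object, ...) {
  x <- object$records$H_um * (object$records$t_um / object$records$D_um)^3 *
    object$records$E_kPa
  rel <- (object$records$k_nN_per_um - object$alpha * x) / object$records$k_nN_per_um
  out <- list(alpha = object$alpha, r_squared = object$r_squared,
              n = nrow(object$records),
              rel_residual_quartiles = quantile(rel, c(0, .25, .5, .75, 1)))
  class(out) <- "summary.alpha_fit"
  out
}

#' @method print summary.alpha_fit
#' @export
print.summary.alpha_fit <- function(x, ...) {
  cat(sprintf("alpha = %.4f over %d sweep cells (R^2 = %.4f)\n", x$alpha, x$n, x$r_squared))
  cat("relative residual quartiles:\n"); print(round(x$rel_residual_quartiles, 4))
  invisible(x)
}

#' Predict sensor structural stiffness from the parametric law
#'
#' `k = alpha * H * (t/D)^3 * E`. With H, t, D in um and E in kPa the result
#' is exactly in nN/um (1 kPa = 1 nN/um^2). The shipped default alpha is
#' [alpha_default()]; pass a locally refitted value to compare.
#'
#' @param geometry a [cylinder_geometry()].
#' @param E_kPa hydrogel Young's modulus in kPa.
#' @param alpha stiffness-law constant.
#' @return Stiffness k in nN/um.
#' @export
predict_stiffness <- function(geometry, E_kPa, alpha = alpha_default()) {
  stopifnot(inherits(geometry, "cylinder_geometry"))
  if (E_kPa <= 0) .err("invalid-argument", "E must be positive")
  if (alpha < 0) .err("invalid-argument", "alpha must be non-negative")
  if (E_kPa < 5 || E_kPa > 80)
    warning(sprintf("E = %g kPa outside the calibrated range 5-80 kPa", E_kPa),
            call. = FALSE)
  alpha * geometry$H * (geometry$t / geometry$D)^3 * E_kPa
}

#' @export
predict.alpha_fit <- function(object, geometry, E_kPa, ...) {
  predict_stiffness(geometry, E_kPa, alpha = object$alpha)
}
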