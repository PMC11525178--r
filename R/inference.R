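#' Sensor width-versus-time trace
#'
#' @param times acquisition times in minutes, strictly increasing, starting
#'   at 0.
#' @param width mediolateral sensor width in um; `NA` marks frames without a
#'   detection (gaps are kept explicit, never interpolated here).
#' @param width0 printed (initial) width; defaults to the width at t = 0,
#'   which must be available.
#' @return An object of class `deformation_trace`.
#' @export
deformation_trace <- function(times, width, width0 = width[1]) {
  if (length(times) != length(width))
    .err("invalid-trace", "times and width must have equal lengths")
  if (length(times) < 1L || times[1] != 0)
    .err("invalid-trace", "times must start at 0 minutes")
  if (any(diff(times) <= 0))
    .err("invalid-trace", "times must be strictly increasing")
  if (!is.finite(width0) || width0 <= 0)
    .err("invalid-trace", "width0 must be positive and known")
  if (any(width <= 0, na.rm = TRUE))
    .err("invalid-trace", "widths must be positive")
  structure(list(times = as.numeric(times), width = as.numeric(width),
                 width0 = as.numeric(width0)),
            class = "deformation_trace")
}

#' @method print deformation_trace
#' @export
print.deformation_trace <- function(x, ...) {
  cat(sprintf("deformation_trace: %d timepoints over %g min, width0 = %g um (%d gaps)\n",
              length(x$times), max(x$times), x$width0, sum(is.na(x$width))))
  invisible(x)
}

#' Sensor strain from widths
#'
#' Strain is the percentage change of the mediolateral width relative to the
#' printed width: `100 * (width0 - width) / width0`, positive for narrowing
#' (tissue compression), negative for widening (stretch, as seen under ROCK
#' inhibition).
#'
#' @param trace a [deformation_trace()].
#' @return Strain series in %.
#' @export
widths_to_strain <- function(trace) {
  stopifnot(inherits(trace, "deformation_trace"))
  100 * (trace$width0 - trace$width) / trace$width0
}

#' Force from widths via the linear sensor stiffness
#'
#' `F = k * (width0 - width)`, positive compressive. The linear gauge is
#' reliable up to about 20% strain; beyond that, values are still returned
#' but flagged invalid via the `"valid"` attribute so downstream summaries
#' can exclude them.
#'
#' @param trace a [deformation_trace()].
#' @param k structural stiffness in nN/um (see [predict_stiffness()]).
#' @return Force series in nN with attribute `valid` (|strain| <= 20%).
#' @export
strain_to_force <- function(trace, k) {
  stopifnot(inherits(trace, "deformation_trace"))
  if (!is.numeric(k) || length(k) != 1L || k <= 0)
    .err("invalid-argument", "k must be a positive scalar")
  f <- k * (trace$width0 - trace$width)
  strain <- widths_to_strain(trace)
  structure(f, valid = abs(strain) <= 20)
}

#' Cumulative stored elastic energy from a force-displacement history
#'
#' Trapezoidal integral of F d(delta); nN x um = fJ, reported in pJ.
#'
#' @param force force series, nN.
#' @param narrowing displacement series, um (same length).
#' @return Cumulative energy series in pJ (first element 0).
#' @export
elastic_energy <- function(force, narrowing) {
  if (length(force) != length(narrowing))
    .err("invalid-input", "force and narrowing must have equal lengths")
  n <- length(force)
  if (n == 0L) return(numeric(0))
  inc <- c(0, 0.5 * (force[-1] + force[-n]) * diff(narrowing))
  nn_um_to_pj(cumsum(inc))
}

#' Full force profile of one sensor
#'
#' Bundles the pipeline for a single trace: strain, force, cumulative stored
#' elastic energy and the maximum 60-min impulse, with per-point validity
#' flags (|strain| <= 20%).
#'
#' @param trace a [deformation_trace()].
#' @param k structural stiffness, nN/um.
#' @param impulse_window impulse window in minutes (default 60).
#' @return An object of class `force_profile`.
#' @export
force_profile <- function(trace, k, impulse_window = 60) {
  stopifnot(inherits(trace, "deformation_trace"))
  strain <- widths_to_strain(trace)
  force <- strain_to_force(trace, k)
  valid <- attr(force, "valid")
  narrowing <- trace$width0 - trace$width
  energy <- elastic_energy(as.numeric(force), narrowing)
  p <- structure(list(times = trace$times, strain = strain,
                      force = as.numeric(force), energy = energy,
                      valid = valid, k = k, width0 = trace$width0),
                 class = "force_profile")
  p$max_impulse_60 <- tryCatch(max_impulse(p, window = impulse_window),
                               error = function(e) NA_real_)
  p
}

#' @method print force_profile
#' @export
print.force_profile <- function(x, ...) {
  cat(sprintf(
    "force_profile: %d timepoints, peak |force| %.4g nN, final energy %.3g pJ, max 60-min impulse %.4g nN min\n",
    length(x$times), max(abs(x$force), na.rm = TRUE),
    tail(x$energy, 1), x$max_impulse_60))
  invisible(x)
}

#' @export
plot.force_profile <- function(x, ...) {
  plot(x$times, x$force, type = "b", pch = ifelse(x$valid, 16, 1),
       xlab = "time (min)", ylab = "force (nN)", ...)
  invisible(x)
}

#' @export
as.data.frame.force_profile <- function(x, ...) {
  data.frame(time_min = x$times, strain_pct = x$strain, force_nN = x$force,
             energy_pJ = x$energy, valid = x$valid)
}

#' Maximum impulse over a sliding window
#'
#' Impulse here summarizes the *rate of force generation*: for each window
#' `[t, t + window]` it is the force generated within the window times the
#' window length, `(F(t + window) - F(t)) * window`, and the maximum over all
#' window positions is returned. Under this definition a constant force
#' carries zero impulse. A `mean_force` mode (mean force over the window
#' times the window length) is available behind a flag for comparison.
#'
#' @param profile a [force_profile()].
#' @param window window length in minutes (default 60).
#' @param mode `"delta_force"` (default) or `"mean_force"`.
#' @return Maximum impulse in nN min.
#' @export
max_impulse <- function(profile, window = 60, mode = c("delta_force", "mean_force")) {
  mode <- match.arg(mode)
  stopifnot(inherits(profile, "force_profile"))
  tt <- profile$times; ff <- profile$force
  ok <- is.finite(ff)
  tt <- tt[ok]; ff <- ff[ok]
  if (length(tt) < 2L || max(tt) - min(tt) < window)
    .err("insufficient-data", "trace duration is shorter than the %g-min window", window)
  fint <- function(t) approx(tt, ff, xout = t, rule = 2)$y
  # for piecewise-linear F the extremum has a window edge on a knot
  starts <- sort(unique(c(tt, tt - window)))
  starts <- starts[starts >= min(tt) & starts + window <= max(tt)]
  if (mode == "delta_force") {
    max((fint(starts + window) - fint(starts)) * window)
  } else {
    meanF <- vapply(starts, function(s) {
      grid <- sort(unique(c(s, s + window, tt[tt > s & tt < s + window])))
      fv <- fint(grid)
      sum(0.5 * (fv[-1] + fv[-length(fv)]) * diff(grid)) / window
    }, numeric(1))
    max(meanF) * window
  }
}

#' Stored elastic energy expressed as ATP equivalents
#'
#' Converts pJ to a count of ATP molecules at a free energy of about
#' 60 kJ/mol, i.e. roughly 1e-19 J per molecule - so 1 pJ corresponds to
#' about 1e7 molecules.
#'
#' @param energy stored energy in pJ (>= 0).
#' @param dG_per_molecule hydrolysis free energy per molecule, J.
#' @return Number of ATP molecules.
#' @export
atp_equivalent <- function(energy, dG_per_molecule = 1e-19) {
  if (any(energy < 0, na.rm = TRUE))
    .err("invalid-argument", "energy must be non-negative")
  pj_to_j(energy) / dG_per_molecule
}

#' Cohort mean force profile with 95% confidence band
#'
#' Interpolates each embryo's force profile onto a common time grid (linear
#' in time, no extrapolation beyond a profile's last timepoint) and reports
#' the per-timepoint mean with a t-distribution 95% CI. Timepoints with a
#' single contributing embryo get no CI, with a warning.
#'
#' @param profiles list of [force_profile()] objects.
#' @param times common time grid in minutes; defaults to the first profile's.
#' @return An object of class `cohort_summary` with `times`, `mean`,
#'   `ci_low`, `ci_high`, `n`.
#' @export
cohort_profile <- function(profiles, times = NULL) {
  if (!length(profiles) || !all(vapply(profiles, inherits, TRUE, "force_profile")))
    .err("invalid-input", "profiles must be a non-empty list of force_profile objects")
  if (is.null(times)) times <- profiles[[1]]$times
  vals <- vapply(profiles, function(p) {
    approx(p$times, p$force, xout = times, rule = 1)$y
  }, numeric(length(times)))
  vals <- matrix(vals, nrow = length(times))
  n <- rowSums(is.finite(vals))
  m <- rowMeans(vals, na.rm = TRUE)
  s <- apply(vals, 1, sd, na.rm = TRUE)
  half <- ifelse(n >= 2, qt(0.975, pmax(n - 1, 1)) * s / sqrt(n), NA_real_)
  if (any(n == 1))
    warning("timepoints with a single profile: CI omitted there", call. = FALSE)
  structure(list(times = times, mean = m, ci_low = m - half, ci_high = m + half,
                 n = n),
            class = "cohort_summary")
}

#' @method print cohort_summary
#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("cohort_summary: %d timepoints, n = %d..%d, peak mean force %.4g nN\n",
              length(x$times), min(x$n), max(x$n), max(abs(x$mean), na.rm = TRUE)))
  invisible(x)
}

#' @export
as.data.frame.cohort_summary <- function(x, ...) {
  data.frame(time_min = x$times, mean_force_nN = x$mean,
             ci_low_nN = x$ci_low, ci_high_nN = x$ci_high, n = x$n)
}

#' Two-group comparison
#'
#' Student's t-test with pooled variance by default (for normally distributed
#' data of comparable variance), Mann-Whitney U on request for non-parametric
#' data. P values are two-sided.
#'
#' @param a,b numeric samples (each n >= 2).
#' @param method `"t"` (default) or `"mann-whitney"`.
#' @return The `htest` object from [stats::t.test()] or [stats::wilcox.test()].
#' @export
compare_groups <- function(a, b, method = c("t", "mann-whitney")) {
  method <- match.arg(method)
  if (length(a) < 2L || length(b) < 2L)
    .err("insufficient-data", "each sample needs at least 2 observations")
  if (method == "t") t.test(a, b, var.equal = TRUE) else
    wilcox.test(a, b, exact = FALSE)
}
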