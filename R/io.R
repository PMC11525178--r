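#' Read and write the package's CSV interchange formats
#'
#' Traces: `time_min, width_um`. Profiles: `time_min, strain_pct, force_nN,
#' energy_pJ, valid`. AFM curves: `depth_um, force_nN`. Stress-strain
#' records: `strain, stress_kPa`. Force-displacement curves:
#' `narrowing_um, force_nN`.
#'
#' @param path CSV file path.
#' @param x object to write.
#' @name io
NULL

#' @rdname io
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) .err("unreadable-input", "no such file: %s", path)
  d <- read.csv(path)
  if (!all(c("time_min", "width_um") %in% names(d)))
    .err("invalid-input", "trace CSV needs columns time_min, width_um")
  deformation_trace(d$time_min, d$width_um)
}

#' @rdname io
#' @export
write_trace_csv <- function(x, path) {
  stopifnot(inherits(x, "deformation_trace"))
  write.csv(data.frame(time_min = x$times, width_um = x$width), path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
write_profile_csv <- function(x, path) {
  stopifnot(inherits(x, "force_profile"))
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_afm_csv <- function(path, tip_half_angle = 20, spring_constant = 0.2) {
  if (!file.exists(path)) .err("unreadable-input", "no such file: %s", path)
  d <- read.csv(path)
  if (!all(c("depth_um", "force_nN") %in% names(d)))
    .err("invalid-input", "AFM CSV needs columns depth_um, force_nN")
  afm_curve(d$depth_um, d$force_nN, tip_half_angle = tip_half_angle,
            spring_constant = spring_constant)
}

#' @rdname io
#' @export
read_stress_strain_csv <- function(path) {
  if (!file.exists(path)) .err("unreadable-input", "no such file: %s", path)
  d <- read.csv(path)
  if (!all(c("strain", "stress_kPa") %in% names(d)))
    .err("invalid-input", "record CSV needs columns strain, stress_kPa")
  stress_strain_record(d$strain, d$stress_kPa, units = "kPa")
}

#' @rdname io
#' @export
write_fd_curve_csv <- function(x, path) {
  stopifnot(inherits(x, "fd_curve"))
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @param tip_half_angle,spring_constant AFM metadata when the sidecar is
#'   absent.
#' @export
read_fd_curve_csv <- function(path) {
  if (!file.exists(path)) .err("unreadable-input", "no such file: %s", path)
  d <- read.csv(path)
  if (!all(c("narrowing_um", "force_nN") %in% names(d)))
    .err("invalid-input", "curve CSV needs columns narrowing_um, force_nN")
  fd_curve(d$narrowing_um, d$force_nN)
}
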