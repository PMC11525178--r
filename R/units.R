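#' Unit conversions used at the package boundary
#'
#' All constitutive math runs in SI internally; file and function interfaces
#' use the field's units (um, kPa, nN, pJ, minutes). The conversions are
#' centralized here. Note the convenient identity 1 kPa = 1 nN/um^2, so a
#' stiffness computed as kPa x um is already in nN/um.
#'
#' @param x numeric value(s) to convert.
#' @return Converted numeric value(s).
#' @name units
NULL

#' @rdname units
#' @export
kpa_to_pa <- function(x) x * 1e3

#' @rdname units
#' @export
pa_to_kpa <- function(x) x * 1e-3

#' @rdname units
#' @export
n_per_m_to_nn_per_um <- function(x) x * 1e3

#' @rdname units
#' @export
nn_um_to_pj <- function(x) x / 1e3  # nN*um = fJ; 1000 fJ = 1 pJ

#' @rdname units
#' @export
pj_to_j <- function(x) x * 1e-12

.err <- function(kind, msg, ...) {
  stop(sprintf("%s: %s", kind, sprintf(msg, ...)), call. = FALSE)
}
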