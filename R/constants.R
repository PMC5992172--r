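#' Physical constants and unit helpers
#'
#' All quantities in this package are carried in piconewtons (pN),
#' nanometres (nm), seconds (s) and kelvin (K); conversions happen only at
#' input boundaries (e.g. flexural rigidity supplied in N m^2).
#'
#' @name units
NULL

#' Boltzmann constant in pN nm / K
#' @keywords internal
KB_PN_NM <- 0.0138065

#' Default assay temperature in kelvin
#'
#' The tweezers objective is not actively temperature controlled in the
#' assays this package models, so ambient 298 K is used wherever a
#' temperature is not given explicitly.
#' @keywords internal
T_DEFAULT <- 298

#' Thermal energy kB*T in pN nm
#'
#' @param temperature Temperature in kelvin.
#' @return Thermal energy in pN nm.
#' @examples
#' kbt(298)  # ~4.11 pN nm
#' @export
kbt <- function(temperature = T_DEFAULT) {
  stopifnot(is.numeric(temperature), temperature >= 0)
  KB_PN_NM * temperature
}

# shared argument checks -------------------------------------------------

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single finite positive number", name),
         call. = FALSE)
  }
  invisible(x)
}

check_nonneg_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    stop(sprintf("`%s` must be a single finite non-negative number", name),
         call. = FALSE)
  }
  invisible(x)
}
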