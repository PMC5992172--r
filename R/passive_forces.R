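#' Passive force calculators
#'
#' Closed-form forces used as independent corroborations of the motor-team
#' stopping force: the entropic expansion force of diffusible crosslinkers
#' confined in a shortening microtubule overlap (1-D ideal-gas law), and
#' the buckling force of a constrained microtubule segment.
#'
#' @name passive_forces
NULL

#' Entropic force of confined crosslinkers
#'
#' N diffusible crosslinkers confined to an overlap of length L behave as
#' a 1-D ideal gas and push the overlap apart with F = N kB T / L. The
#' approximation holds for a dilute gas; no density cutoff is enforced.
#'
#' @param n_molecules Number of confined crosslinkers N (>= 0).
#' @param overlap_length Overlap length L, nm (> 0).
#' @param temperature Temperature, K.
#' @return Force in pN; linear in N, inverse in L.
#' @examples
#' entropic_force(10, 100)  # ~0.41 pN at 298 K
#' @export
entropic_force <- function(n_molecules, overlap_length,
                           temperature = T_DEFAULT) {
  if (n_molecules < 0) stop("`n_molecules` must be >= 0", call. = FALSE)
  check_positive_scalar(overlap_length, "overlap_length")
  check_positive_scalar(temperature, "temperature")
  n_molecules * kbt(temperature) / overlap_length
}

#' Default microtubule flexural rigidity, N m^2
#' @keywords internal
EI_MICROTUBULE <- 6e-24

#' Buckling force of a constrained microtubule segment
#'
#' Force associated with the buckling of a filament segment of length L
#' and flexural rigidity EI: `prefactor * EI / L^2`, converted to pN. The
#' default prefactor is 4*pi, the form used in the analyses this package
#' reproduces; the classical Euler clamped-clamped prefactor 4*pi^2 (a
#' factor pi larger) is available via the argument. Shorter segments
#' correspond to higher forces.
#'
#' @param segment_length Length of the buckled segment, um (> 0).
#' @param flexural_rigidity EI in N m^2 (> 0); default `6e-24`, the
#'   standard microtubule value.
#' @param prefactor Dimensionless prefactor; default `4 * pi`.
#' @return Buckling force in pN.
#' @examples
#' buckling_force(8.3)   # ~1.1 pN
#' buckling_force(10)    # ~0.75 pN
#' @export
buckling_force <- function(segment_length,
                           flexural_rigidity = EI_MICROTUBULE,
                           prefactor = 4 * pi) {
  check_positive_scalar(segment_length, "segment_length")
  check_positive_scalar(flexural_rigidity, "flexural_rigidity")
  check_positive_scalar(prefactor, "prefactor")
  L_m <- segment_length * 1e-6            # um -> m
  force_n <- prefactor * flexural_rigidity / L_m^2
  force_n * 1e12                          # N -> pN
}

#' Motor-team force from a stalled overlap series
#'
#' When motors slide a crosslinked microtubule pair apart against confined
#' diffusible crosslinkers, shortening stops where the entropic force
#' balances the sliding force. Given a series that has reached stall, the
#' motor team's stopping force is the entropic force evaluated at the
#' stalled (N, L, T).
#'
#' @param series An `overlap_series` (see [simulate_overlap_series()]) or
#'   any list with `times`, `overlap_lengths`, `n_crosslinkers`,
#'   `temperature`.
#' @param stall_tol Maximum relative shortening rate (fraction of the final
#'   length per unit of the series' mean sampling interval) still accepted
#'   as stalled.
#' @return Motor force in pN.
#' @export
stall_overlap_inversion <- function(series, stall_tol = 1e-3) {
  L <- series$overlap_lengths
  t <- series$times
  n <- length(L)
  if (n < 3L) stop("series too short", call. = FALSE)
  if (series$n_crosslinkers <= 0) {
    stop("no crosslinkers: no force balance is possible", call. = FALSE)
  }
  # stall check: relative length change over the last few samples
  tail_n <- max(3L, round(n / 10))
  i0 <- n - tail_n + 1L
  rel_rate <- abs(L[n] - L[i0]) / L[n] / (t[n] - t[i0]) *
    mean(diff(t))
  if (!is.finite(rel_rate) || rel_rate > stall_tol) {
    stop("overlap series has not reached stall", call. = FALSE)
  }
  entropic_force(series$n_crosslinkers, L[n], series$temperature)
}
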