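#' Velocity statistics and motor counting
#'
#' Per-filament velocities in the three measurement modes (automated
#' tracking, kymograph slopes, hand-marked endpoints), duration-weighted
#' population statistics, boxplot summary statistics with the 1.5 IQR
#' outlier fences, and fluorescence-based motor counting.
#'
#' @name motility_stats
NULL

#' Frame-to-frame velocities of one track
#'
#' The travelled distance between consecutive frames divided by the time
#' difference between frames.
#'
#' @param track A [filament_track()].
#' @return Numeric vector of length `n_frames - 1`, nm/s.
#' @export
instantaneous_velocities <- function(track) {
  stopifnot(inherits(track, "filament_track"))
  dts <- diff(track$frame_times)
  if (any(dts == 0)) stop("duplicate frame timestamps", call. = FALSE)
  diff(track$positions) / dts
}

#' Mean velocity and observation duration of one filament
#'
#' For tracked and manually marked data, the unweighted mean of the
#' instantaneous velocities; for kymograph data carrying a precomputed
#' line slope, that slope unchanged (kymograph velocities are inherently
#' averaged). The duration is the span of the observed frames, used later
#' as the filament's weight in the population statistics.
#'
#' @param track A [filament_track()].
#' @return Named numeric `c(velocity, duration)`: nm/s and s.
#' @export
per_filament_velocity <- function(track) {
  stopifnot(inherits(track, "filament_track"))
  dur <- track$frame_times[length(track$frame_times)] - track$frame_times[1]
  v <- if (!is.null(track$velocity)) {
    track$velocity
  } else {
    mean(instantaneous_velocities(track))
  }
  c(velocity = v, duration = dur)
}

#' Duration-weighted population velocity statistics
#'
#' Population summary in which each filament's mean velocity is weighted
#' by its observation duration, so long-observed filaments count more.
#' The weighted median is the value at 50% of the total weight; the
#' weighted SD uses frequency-weight normalisation
#' (sum(w) - mean(w) in the denominator), reducing to the ordinary sample
#' SD when all weights are equal. Unweighted statistics are emitted
#' alongside.
#'
#' @param velocities Per-filament mean velocities, nm/s.
#' @param durations Observation durations, s (> 0, same length).
#' @return A `velocity_summary`: weighted mean/sd/median, raw mean/sd,
#'   `n_filaments`, total duration.
#' @export
time_weighted_population <- function(velocities, durations) {
  n <- length(velocities)
  if (n < 1L) stop("need at least one filament", call. = FALSE)
  if (length(durations) != n) {
    stop("`durations` must match `velocities` in length", call. = FALSE)
  }
  if (any(!is.finite(durations)) || any(durations <= 0)) {
    stop("durations must be positive and finite", call. = FALSE)
  }
  w <- durations
  W <- sum(w)
  m <- sum(w * velocities) / W
  wsd <- if (n > 1L) {
    sqrt(sum(w * (velocities - m)^2) / (W - mean(w)))
  } else NA_real_
  structure(list(population_mean = m,
                 population_sd = wsd,
                 population_median = weighted_median(velocities, w),
                 raw_mean = mean(velocities),
                 raw_sd = stats::sd(velocities),
                 n_filaments = n,
                 observation_duration = W),
            class = "velocity_summary")
}

# value at 50% of total weight: smallest x with cumulative weight >= W/2;
# averaged with the next value when the split is exact
weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w)
  half <- sum(w) / 2
  i <- which(cw >= half)[1]
  if (abs(cw[i] - half) < 1e-12 * sum(w) && i < length(x)) {
    (x[i] + x[i + 1]) / 2
  } else {
    x[i]
  }
}

#' @export
print.velocity_summary <- function(x, ...) {
  cat(sprintf(
    "<velocity_summary> %.1f +/- %.1f nm/s (weighted mean +/- SD), median %.1f, N = %d\n",
    x$population_mean, x$population_sd, x$population_median, x$n_filaments))
  invisible(x)
}

#' Boxplot summary statistics
#'
#' Median and quartiles with outliers flagged by the 1.5 IQR rule: points
#' greater than q3 + 1.5 (q3 - q1) or less than q1 - 1.5 (q3 - q1) are
#' outliers, and the whiskers extend to the most extreme points not
#' considered outliers. Quartiles interpolate linearly between order
#' statistics at rank (n + 1) p ([stats::quantile()] type 6); for 1..7
#' this gives q1 = 2, q3 = 6.
#'
#' @param values Numeric sample (>= 1 value).
#' @return A `boxplot_stats` list: `median`, `q1`, `q3`, `whisker_low`,
#'   `whisker_high`, `outliers`, `n`.
#' @export
boxplot_stats <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 1L) stop("empty input", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 6, names = FALSE)
  q1 <- q[1]; med <- q[2]; q3 <- q[3]
  iqr <- q3 - q1
  lo_fence <- q1 - 1.5 * iqr
  hi_fence <- q3 + 1.5 * iqr
  out <- values < lo_fence | values > hi_fence
  inliers <- values[!out]
  structure(list(median = med, q1 = q1, q3 = q3,
                 whisker_low = min(inliers), whisker_high = max(inliers),
                 outliers = sort(values[out]), n = length(values)),
            class = "boxplot_stats")
}

#' @export
print.boxplot_stats <- function(x, ...) {
  cat(sprintf(
    "<boxplot_stats> median %.3g [q1 %.3g, q3 %.3g], whiskers [%.3g, %.3g], %d outlier(s), n = %d\n",
    x$median, x$q1, x$q3, x$whisker_low, x$whisker_high,
    length(x$outliers), x$n))
  invisible(x)
}

#' Single-fluorophore intensity calibration
#'
#' Mean background-subtracted intensity of manually selected single
#' molecules, used as the divisor when counting fluorophores in a spot or
#' an overlap.
#'
#' @param single_fluor_intensity Mean single-fluorophore intensity, a.u.
#'   (> 0).
#' @param background Background intensity to subtract from measurements,
#'   a.u. (already integrated over the measured area).
#' @return An `intensity_calibration` object.
#' @export
intensity_calibration <- function(single_fluor_intensity, background = 0) {
  check_positive_scalar(single_fluor_intensity, "single_fluor_intensity")
  check_nonneg_scalar(background, "background")
  structure(list(single_fluor_intensity = single_fluor_intensity,
                 background = background),
            class = "intensity_calibration")
}

#' Count fluorophores from integrated intensity
#'
#' Background-subtracted integrated intensity divided by the
#' single-fluorophore intensity. A negative background-subtracted
#' intensity is clamped to zero with a warning. When a length is supplied,
#' the linear motor density is returned alongside (motors per 100 nm, the
#' field's customary unit for overlap occupancy).
#'
#' @param integrated_intensity Integrated spot/overlap intensity, a.u.
#' @param cal An [intensity_calibration()].
#' @param length_nm Optional length over which the molecules are spread,
#'   nm.
#' @return List with `count` and, when `length_nm` is given,
#'   `density_per_100nm`.
#' @export
count_molecules <- function(integrated_intensity, cal, length_nm = NULL) {
  stopifnot(inherits(cal, "intensity_calibration"))
  net <- integrated_intensity - cal$background
  if (any(net < 0)) {
    warning("background-subtracted intensity below zero; clamped to 0")
    net <- pmax(net, 0)
  }
  count <- net / cal$single_fluor_intensity
  out <- list(count = count)
  if (!is.null(length_nm)) {
    check_positive_scalar(length_nm, "length_nm")
    out$density_per_100nm <- count / (length_nm / 100)
  }
  out
}

#' Motor number engaging a gliding filament
#'
#' Expected number of surface motors able to reach a filament of the given
#' length: filament length x reach-band width x surface density, rounded
#' to the nearest integer. The reach band is the lateral strip of surface
#' within which a motor can contact the filament; the default 50 nm is the
#' motor contour-length scale.
#'
#' @param mt_length Filament length, nm (> 0).
#' @param surface_density Motor surface density, motors per um^2 (> 0).
#' @param reach Reach-band width, nm (> 0).
#' @return Integer motor count.
#' @export
motor_number_from_surface <- function(mt_length, surface_density,
                                      reach = 50) {
  check_nonneg_scalar(mt_length, "mt_length")
  check_positive_scalar(surface_density, "surface_density")
  check_positive_scalar(reach, "reach")
  as.integer(round(mt_length / 1000 * reach / 1000 * surface_density))
}
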