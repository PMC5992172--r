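#' Force trace of one bead-on-filament measurement
#'
#' Synchronised time series of the x/y trap force (pN), with optional stage
#' position channels (nm) and the per-axis trap stiffness (pN/nm) as
#' metadata. This is the raw object of all force analysis.
#'
#' @param time Time stamps, s; strictly increasing, approximately uniform.
#' @param force_x,force_y Trap force channels, pN.
#' @param stage_x,stage_y Optional stage position channels, nm.
#' @param trap_stiffness Trap spring constant, pN/nm (> 0).
#' @param metadata Free-form list (instrument settings, simulation truth).
#' @return A `force_trace` object.
#' @export
force_trace <- function(time, force_x, force_y,
                        stage_x = NULL, stage_y = NULL,
                        trap_stiffness, metadata = list()) {
  n <- length(time)
  if (n < 2L) stop("a force trace needs at least 2 samples", call. = FALSE)
  if (length(force_x) != n || length(force_y) != n) {
    stop("force channels must match the time channel in length", call. = FALSE)
  }
  if (any(diff(time) <= 0)) {
    stop("`time` must be strictly increasing", call. = FALSE)
  }
  if (!all(is.finite(force_x)) || !all(is.finite(force_y))) {
    stop("force channels must be finite", call. = FALSE)
  }
  check_positive_scalar(trap_stiffness, "trap_stiffness")
  structure(list(time = as.numeric(time),
                 force_x = as.numeric(force_x),
                 force_y = as.numeric(force_y),
                 stage_x = if (is.null(stage_x)) NULL else as.numeric(stage_x),
                 stage_y = if (is.null(stage_y)) NULL else as.numeric(stage_y),
                 trap_stiffness = trap_stiffness,
                 metadata = metadata),
            class = "force_trace")
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf("<force_trace> %d samples, %.1f s @ %.0f Hz, k = %.3g pN/nm\n",
              length(x$time), diff(range(x$time)),
              1 / stats::median(diff(x$time)), x$trap_stiffness))
  invisible(x)
}

# sampling interval, checking approximate uniformity
trace_dt <- function(trace, tol = 0.01) {
  dts <- diff(trace$time)
  dt <- stats::median(dts)
  if (any(abs(dts - dt) > tol * dt)) {
    warning("trace sampling is not uniform; using the median interval")
  }
  dt
}

#' Force-velocity scan of one microtubule pair
#'
#' Segments of a force-feedback (constant-force) or constant-velocity scan:
#' each row holds the set-point, the measured response, a quality weight in
#' (0, 1] rating how steady the sliding was, and the segment duration. The
#' unloaded transport velocity is measured independently before or after
#' the scan and carried alongside.
#'
#' @param segments `data.frame` with columns `mode`
#'   (`"constant_force"`/`"constant_velocity"`), `setpoint` (pN or nm/s),
#'   `response` (nm/s or pN), `quality_weight` in (0, 1], `duration` (s).
#' @param unloaded_velocity Independently measured zero-load velocity, nm/s.
#' @param pair_id Identifier of the microtubule pair.
#' @return An `fv_scan` object.
#' @export
fv_scan <- function(segments, unloaded_velocity, pair_id = "pair") {
  need <- c("mode", "setpoint", "response", "quality_weight", "duration")
  if (!is.data.frame(segments) || !all(need %in% names(segments))) {
    stop("`segments` must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (!all(segments$mode %in% c("constant_force", "constant_velocity"))) {
    stop("segment `mode` must be constant_force or constant_velocity",
         call. = FALSE)
  }
  w <- segments$quality_weight
  if (any(!is.finite(w)) || any(w <= 0) || any(w > 1)) {
    stop("quality weights must lie in (0, 1]", call. = FALSE)
  }
  check_nonneg_scalar(unloaded_velocity, "unloaded_velocity")
  structure(list(segments = segments,
                 unloaded_velocity = unloaded_velocity,
                 pair_id = pair_id),
            class = "fv_scan")
}

#' @export
print.fv_scan <- function(x, ...) {
  cat(sprintf("<fv_scan> pair %s: %d segments, v0 = %.1f nm/s\n",
              x$pair_id, nrow(x$segments), x$unloaded_velocity))
  invisible(x)
}

#' Track of one transported filament
#'
#' Per-frame positions (nm, along the transport coordinate) of one
#' filament, with its length and the measurement mode: `"tracked"`
#' (automated tracking giving instantaneous velocities), `"kymograph"`
#' (velocity read as a line slope, inherently averaged) or
#' `"manual_endpoint"` (hand-marked end-to-pivot distances, used when
#' filaments swivel too much for kymograph evaluation).
#'
#' @param frame_times Frame times, s; strictly increasing.
#' @param positions Positions along the transport direction, nm.
#' @param filament_length Filament length, nm (> 0).
#' @param mode One of `"tracked"`, `"kymograph"`, `"manual_endpoint"`.
#' @param filament_id Identifier.
#' @param velocity Optional precomputed velocity (nm/s), e.g. a kymograph
#'   line slope; when present [per_filament_velocity()] returns it as-is.
#' @return A `filament_track` object.
#' @export
filament_track <- function(frame_times, positions, filament_length,
                           mode = c("tracked", "kymograph",
                                    "manual_endpoint"),
                           filament_id = "filament", velocity = NULL) {
  mode <- match.arg(mode)
  n <- length(frame_times)
  if (n < 2L) stop("a track needs at least 2 frames", call. = FALSE)
  if (length(positions) != n) {
    stop("`positions` must match `frame_times` in length", call. = FALSE)
  }
  if (any(diff(frame_times) <= 0)) {
    stop("`frame_times` must be strictly increasing", call. = FALSE)
  }
  check_positive_scalar(filament_length, "filament_length")
  structure(list(frame_times = as.numeric(frame_times),
                 positions = as.numeric(positions),
                 filament_length = filament_length,
                 mode = mode, filament_id = filament_id,
                 velocity = velocity),
            class = "filament_track")
}

#' @export
print.filament_track <- function(x, ...) {
  cat(sprintf("<filament_track> %s (%s): %d frames over %.1f s, L = %.0f nm\n",
              x$filament_id, x$mode, length(x$frame_times),
              diff(range(x$frame_times)), x$filament_length))
  invisible(x)
}
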