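#' Force-trace analysis
#'
#' Processing of raw bead-in-trap force traces: baseline offset estimation
#' from the pre-attachment period, detection of the bead-filament binding
#' event, identification of the force plateau once transport has stalled,
#' and the stopping force as the vector magnitude of the offset-corrected
#' per-axis plateau means.
#'
#' @name trace_forces
NULL

# vector force magnitude, optionally offset-corrected
force_magnitude <- function(trace, offset = c(0, 0)) {
  sqrt((trace$force_x - offset[1])^2 + (trace$force_y - offset[2])^2)
}

window_indices <- function(trace, window, what = "window") {
  if (length(window) != 2L || window[2] <= window[1]) {
    stop(sprintf("`%s` must be (t_start, t_end) with t_end > t_start", what),
         call. = FALSE)
  }
  if (window[1] < trace$time[1] - 1e-9 ||
      window[2] > trace$time[length(trace$time)] + 1e-9) {
    stop(sprintf("`%s` [%.3f, %.3f] s lies outside the trace time range",
                 what, window[1], window[2]), call. = FALSE)
  }
  which(trace$time >= window[1] & trace$time <= window[2])
}

#' Annotation of a force trace
#'
#' Time windows used by the stopping-force evaluation: a baseline window
#' before microsphere attachment, the binding time, and the plateau window
#' after transport has stalled.
#'
#' @param baseline_window `(t_start, t_end)` in s, before `binding_time`.
#' @param binding_time Bead-filament attachment time, s.
#' @param plateau_window `(t_start, t_end)` in s, after `binding_time`.
#' @return A `trace_annotation` object.
#' @export
trace_annotation <- function(baseline_window, binding_time, plateau_window) {
  if (baseline_window[2] > binding_time) {
    stop("baseline window must end before the binding time", call. = FALSE)
  }
  if (plateau_window[1] < binding_time) {
    stop("plateau window must start after the binding time", call. = FALSE)
  }
  if (baseline_window[2] <= baseline_window[1] ||
      plateau_window[2] <= plateau_window[1]) {
    stop("windows must be non-empty", call. = FALSE)
  }
  structure(list(baseline_window = as.numeric(baseline_window),
                 binding_time = binding_time,
                 plateau_window = as.numeric(plateau_window)),
            class = "trace_annotation")
}

#' Estimate the per-axis force offset from a baseline window
#'
#' Averages the x and y force channels over a pre-attachment window
#' (several seconds of free-bead signal) to determine the instrumental
#' force offset that is later subtracted from the plateau means.
#'
#' @param trace A [force_trace()].
#' @param baseline_window `(t_start, t_end)` in s; must contain at least
#'   `min_samples` samples.
#' @param binding_time Optional known attachment time, s; if supplied the
#'   window must end before it (offsets from post-binding samples would be
#'   biased by the motor force).
#' @param min_samples Minimum number of samples in the window.
#' @return Named numeric `c(offset_x, offset_y)` in pN.
#' @export
estimate_offset <- function(trace, baseline_window, binding_time = NULL,
                            min_samples = 10L) {
  stopifnot(inherits(trace, "force_trace"))
  if (!is.null(binding_time) && baseline_window[2] > binding_time) {
    stop("baseline window overlaps post-binding samples", call. = FALSE)
  }
  idx <- window_indices(trace, baseline_window, "baseline_window")
  if (length(idx) < min_samples) {
    stop(sprintf("baseline window holds %d samples; need at least %d",
                 length(idx), min_samples), call. = FALSE)
  }
  c(offset_x = mean(trace$force_x[idx]),
    offset_y = mean(trace$force_y[idx]))
}

# centred moving average over a window of `w` samples (w forced odd)
moving_average <- function(x, w) {
  w <- max(1L, as.integer(w))
  if (w %% 2L == 0L) w <- w + 1L
  if (w == 1L) return(x)
  pad <- (w - 1L) %/% 2L
  xp <- c(rep(x[1], pad), x, rep(x[length(x)], pad))
  as.numeric(stats::filter(xp, rep(1 / w, w), sides = 2))[(pad + 1L):(pad + length(x))]
}

#' Detect bead-filament binding events in a force trace
#'
#' Binding is confirmed by a fast increase in measured force: the smoothed
#' force magnitude's derivative must exceed `rise_threshold` and the force
#' must subsequently rise at least `confirm_force` above the local
#' baseline. After a detachment (force falling back to baseline) later
#' binding events can be detected again.
#'
#' @param trace A [force_trace()].
#' @param rise_threshold Minimum force slope, pN/s.
#' @param confirm_force Required rise above baseline, pN.
#' @param smooth_time Moving-average window for the magnitude, s.
#' @param all If `TRUE` return all detected binding times, else the first.
#' @return Binding time(s) in s, or `NULL` if no event is found (a valid
#'   result for a pure baseline trace).
#' @export
detect_binding <- function(trace, rise_threshold = 2, confirm_force = 1,
                           smooth_time = 0.1, all = FALSE) {
  stopifnot(inherits(trace, "force_trace"))
  dt <- trace_dt(trace)
  n <- length(trace$time)
  w <- max(3L, round(smooth_time / dt))
  if (n <= w + 2L) stop("trace shorter than the smoothing window", call. = FALSE)
  # baseline level from the first smooth_time*10 (>= 0.5 s) of signal
  nb <- max(w, min(n, round(max(10 * smooth_time, 0.5) / dt)))
  fmag <- moving_average(force_magnitude(trace), w)
  base <- stats::median(fmag[seq_len(nb)])
  # derivative of the smoothed magnitude over one smoothing window
  lag <- max(1L, round(smooth_time / dt))
  slope <- c(rep(0, lag), (fmag[(lag + 1L):n] - fmag[1:(n - lag)]) / (lag * dt))
  high <- fmag > base + confirm_force
  candidates <- which(slope > rise_threshold)
  candidates <- candidates[candidates > w + lag]  # skip smoothing edge
  events <- numeric(0)
  i <- 1L
  while (i <= length(candidates)) {
    ci <- candidates[i]
    # confirmation: force rises above baseline + confirm_force after ci
    conf <- which(high[ci:n])[1]
    if (is.na(conf)) break
    events <- c(events, trace$time[ci])
    if (!all) return(events)
    # skip ahead to the next return to baseline (detachment), then rearm
    low_after <- which(!high[(ci + conf):n])[1]
    if (is.na(low_after)) break
    rearm <- ci + conf + low_after - 1L
    candidates <- candidates[candidates > rearm]
    i <- 1L
  }
  if (length(events) == 0L) NULL else events
}

#' Detect the stalled-force plateau after binding
#'
#' Finds the longest post-binding window in which the force magnitude is
#' flat: the trace is binned, local slopes are estimated by linear fits
#' over a rolling window of bins, and the longest contiguous run with
#' |slope| <= `slope_tol` and duration >= `min_duration` is returned. The
#' by-eye plateau selection of a manual analysis can be reproduced by
#' passing an explicit window to [stopping_force_from_plateau()] instead.
#'
#' @param trace A [force_trace()].
#' @param binding_time Attachment time, s (within the trace).
#' @param slope_tol Maximum |slope| of the plateau, pN/s.
#' @param min_duration Minimum plateau duration, s.
#' @param bin_width Bin width for slope estimation, s. Bins (and the slope
#'   window) must span several relaxation times of the bound bead
#'   (`(bead_drag + team_friction) / trap_stiffness`, typically well under
#'   a second) or the correlated force fluctuations masquerade as slope.
#' @param slope_window Width of the rolling slope fit, s.
#' @return `(t_start, t_end)` in s, or `NULL` if no plateau qualifies
#'   (e.g. the attachment broke during the force ramp).
#' @export
detect_plateau <- function(trace, binding_time, slope_tol = 0.15,
                           min_duration = 2, bin_width = 1,
                           slope_window = 6) {
  stopifnot(inherits(trace, "force_trace"))
  tmax <- trace$time[length(trace$time)]
  if (binding_time < trace$time[1] || binding_time >= tmax) {
    stop("`binding_time` must lie within the trace", call. = FALSE)
  }
  post <- trace$time > binding_time
  if (sum(post) < 10L) return(NULL)
  t <- trace$time[post]
  f <- force_magnitude(trace)[post]
  # bin means (bins ordered numerically, not by character level)
  bins <- floor((t - t[1]) / bin_width)
  bt <- tapply(t, bins, mean)
  bf <- tapply(f, bins, mean)
  o <- order(as.numeric(names(bt)))
  bt <- as.numeric(bt[o])
  bf <- as.numeric(bf[o])
  nb <- length(bt)
  half <- max(1L, round(slope_window / bin_width / 2))
  if (nb < 2L * half + 1L) return(NULL)
  slopes <- rep(NA_real_, nb)
  for (i in (half + 1L):(nb - half)) {
    ii <- (i - half):(i + half)
    slopes[i] <- stats::cov(bt[ii], bf[ii]) / stats::var(bt[ii])
  }
  flat <- !is.na(slopes) & abs(slopes) <= slope_tol
  if (!any(flat)) return(NULL)
  r <- rle(flat)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values)
  if (length(ok) == 0L) return(NULL)
  best <- ok[which.max(r$lengths[ok])]
  win <- c(bt[starts[best]] - bin_width / 2, bt[ends[best]] + bin_width / 2)
  win[1] <- max(win[1], binding_time)
  win[2] <- min(win[2], tmax)
  if (diff(win) < min_duration) return(NULL)
  win
}

#' Stopping force from a plateau window
#'
#' Averages the per-axis force over the plateau window, subtracts the
#' baseline offsets, and combines the two axes by Pythagoras into the
#' absolute stopping force in an arbitrary direction. Averaging the signed
#' per-axis values before taking the magnitude means baseline-crossing
#' fluctuations do not bias the result (on a genuine plateau the force is
#' far from zero anyway).
#'
#' @param trace A [force_trace()].
#' @param annotation A [trace_annotation()], or `NULL` to pass windows
#'   directly.
#' @param baseline_window,plateau_window Used when `annotation` is `NULL`.
#' @param min_plateau Minimum plateau duration, s.
#' @return A `stopping_force_result`: offsets, per-axis plateau means,
#'   the absolute `stopping_force` (pN), sample counts and the plateau
#'   magnitude sd.
#' @export
stopping_force_from_plateau <- function(trace, annotation = NULL,
                                        baseline_window = NULL,
                                        plateau_window = NULL,
                                        min_plateau = 0.5) {
  stopifnot(inherits(trace, "force_trace"))
  if (!is.null(annotation)) {
    stopifnot(inherits(annotation, "trace_annotation"))
    baseline_window <- annotation$baseline_window
    plateau_window <- annotation$plateau_window
    binding_time <- annotation$binding_time
  } else {
    if (is.null(baseline_window) || is.null(plateau_window)) {
      stop("supply either `annotation` or both windows", call. = FALSE)
    }
    binding_time <- NULL
  }
  if (diff(plateau_window) < min_plateau) {
    stop(sprintf("plateau window of %.2f s is shorter than the %.2f s minimum",
                 diff(plateau_window), min_plateau), call. = FALSE)
  }
  off <- estimate_offset(trace, baseline_window, binding_time = binding_time)
  pidx <- window_indices(trace, plateau_window, "plateau_window")
  mx <- mean(trace$force_x[pidx])
  my <- mean(trace$force_y[pidx])
  dx <- mx - off[["offset_x"]]
  dy <- my - off[["offset_y"]]
  structure(list(offset_x = off[["offset_x"]], offset_y = off[["offset_y"]],
                 plateau_mean_x = mx, plateau_mean_y = my,
                 stopping_force = sqrt(dx^2 + dy^2),
                 n_baseline = length(window_indices(trace, baseline_window)),
                 n_plateau = length(pidx),
                 plateau_sd = stats::sd(force_magnitude(trace, off)[pidx]),
                 baseline_window = baseline_window,
                 plateau_window = plateau_window),
            class = "stopping_force_result")
}

#' @export
print.stopping_force_result <- function(x, ...) {
  cat(sprintf(
    "<stopping_force_result> F_stop = %.3f pN (plateau %.1f-%.1f s, sd %.3f pN)\n",
    x$stopping_force, x$plateau_window[1], x$plateau_window[2], x$plateau_sd))
  invisible(x)
}

#' Equipartition check of the trap stiffness
#'
#' Diagnostic replacement for a power-spectrum calibration: on a
#' free-bead segment the positional variance must satisfy
#' k = kB T / var(x), equivalently var(F) = k kB T. Returns the implied
#' stiffness per axis for comparison with the nominal value.
#'
#' @param trace A [force_trace()].
#' @param baseline_window Free-bead window, s.
#' @param temperature Temperature, K.
#' @return List with per-axis force variance (pN^2) and implied stiffness
#'   (pN/nm).
#' @export
equipartition_check <- function(trace, baseline_window,
                                temperature = T_DEFAULT) {
  stopifnot(inherits(trace, "force_trace"))
  idx <- window_indices(trace, baseline_window, "baseline_window")
  vx <- stats::var(trace$force_x[idx])
  vy <- stats::var(trace$force_y[idx])
  list(var_force = c(x = vx, y = vy),
       implied_stiffness = c(x = vx, y = vy) / kbt(temperature),
       nominal_stiffness = trace$trap_stiffness)
}

#' One-shot stopping-force analysis of a trace
#'
#' Convenience wrapper: detects binding, detects the plateau, builds the
#' baseline window from the `baseline_duration` seconds preceding binding,
#' and computes the stopping force. Returns `NULL` elements where a stage
#' fails (no binding, no plateau) rather than erroring, so batch drivers
#' can log and skip.
#'
#' @param trace A [force_trace()].
#' @param baseline_duration Baseline length before binding, s.
#' @param ... Passed to [detect_binding()] and [detect_plateau()] by name.
#' @return List with `binding_time`, `plateau_window`, `result`
#'   (a `stopping_force_result` or `NULL`).
#' @export
analyze_trace <- function(trace, baseline_duration = 5, ...) {
  dots <- list(...)
  bind_args <- dots[names(dots) %in% names(formals(detect_binding))]
  plat_args <- dots[names(dots) %in% names(formals(detect_plateau))]
  tb <- do.call(detect_binding, c(list(trace), bind_args))
  if (is.null(tb)) {
    return(list(binding_time = NULL, plateau_window = NULL, result = NULL))
  }
  tb <- tb[1]
  win <- do.call(detect_plateau, c(list(trace, binding_time = tb), plat_args))
  if (is.null(win)) {
    return(list(binding_time = tb, plateau_window = NULL, result = NULL))
  }
  b0 <- max(trace$time[1], tb - baseline_duration)
  guard <- 0.05 * baseline_duration
  res <- stopping_force_from_plateau(
    trace, baseline_window = c(b0, tb - guard), plateau_window = win)
  list(binding_time = tb, plateau_window = win, result = res)
}
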