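#' Weighted force-velocity fits
#'
#' For aligned, crosslinked microtubule pairs the transmitted forces are
#' too small for a visible plateau, so the stopping force is obtained from
#' a force-velocity scan instead: the force-velocity relation is linear,
#' its weighted least-squares slope is the friction coefficient of the
#' motor team, and the stopping force is the force difference between
#' zero-load transport velocity and stop, i.e. |slope| * v0.
#'
#' @name friction_fit
NULL

# pool scan segments into (velocity, force, weight) regardless of mode
scan_points <- function(scan) {
  seg <- scan$segments
  cf <- seg$mode == "constant_force"
  data.frame(velocity = ifelse(cf, seg$response, seg$setpoint),
             force = ifelse(cf, seg$setpoint, seg$response),
             weight = seg$quality_weight)
}

#' Fit the linear force-velocity relation of one pair
#'
#' Weighted least squares of force on velocity, pooling constant-force and
#' constant-velocity segments (both modes give comparable results). The
#' quality weights act multiplicatively on the squared residuals. Standard
#' errors come from the weighted normal equations.
#'
#' @param scan An [fv_scan()] with at least 3 segments.
#' @return A `friction_fit_result`: `slope` (pN s/nm, signed), `intercept`
#'   (pN), their standard errors, `stopping_force` = |slope| * v0 (pN) with
#'   `stopping_force_se`, weighted `r_squared` and `n_segments`.
#' @export
fit_force_velocity <- function(scan) {
  stopifnot(inherits(scan, "fv_scan"))
  pts <- scan_points(scan)
  if (nrow(pts) < 3L) {
    stop("need at least 3 segments to fit", call. = FALSE)
  }
  if (stats::var(pts$velocity) == 0) {
    stop("all segment velocities identical: force-velocity design is rank deficient",
         call. = FALSE)
  }
  fit <- stats::lm(force ~ velocity, data = pts, weights = pts$weight)
  # summary.lm warns on noise-free data ("essentially perfect fit"); such
  # scans are legitimate here (closed-form checks), so silence it
  sm <- suppressWarnings(summary(fit))
  slope <- stats::coef(fit)[["velocity"]]
  intercept <- stats::coef(fit)[["(Intercept)"]]
  sf <- stopping_force_from_fit(
    list(slope = slope, slope_se = sm$coefficients["velocity", "Std. Error"]),
    scan$unloaded_velocity)
  structure(list(slope = slope,
                 intercept = intercept,
                 slope_se = sm$coefficients["velocity", "Std. Error"],
                 intercept_se = sm$coefficients["(Intercept)", "Std. Error"],
                 stopping_force = sf[["stopping_force"]],
                 stopping_force_se = sf[["se"]],
                 r_squared = sm$r.squared,
                 n_segments = nrow(pts),
                 unloaded_velocity = scan$unloaded_velocity,
                 pair_id = scan$pair_id),
            class = "friction_fit_result")
}

#' @export
print.friction_fit_result <- function(x, ...) {
  cat(sprintf(
    "<friction_fit_result> pair %s: slope %.4g pN s/nm, F_stop = %.3f +/- %.3f pN (R2 %.3f, n %d)\n",
    x$pair_id, x$slope, x$stopping_force, x$stopping_force_se,
    x$r_squared, x$n_segments))
  invisible(x)
}

#' Stopping force from a force-velocity fit
#'
#' The stopping force is the force difference along the fitted line between
#' the unloaded transport velocity and stop: |slope| * v0. Uncertainty is
#' propagated from the slope standard error and, when supplied, the
#' unloaded-velocity uncertainty.
#'
#' @param fit A `friction_fit_result`, or any list with `slope` and
#'   optionally `slope_se`.
#' @param unloaded_velocity Independently measured v0, nm/s (>= 0). When
#'   both a pre- and a post-scan measurement exist, pass their mean.
#' @param unloaded_velocity_se Optional uncertainty of v0, nm/s.
#' @return Named numeric `c(stopping_force, se)` in pN (se is `NA` when no
#'   slope_se is available).
#' @export
stopping_force_from_fit <- function(fit, unloaded_velocity,
                                    unloaded_velocity_se = 0) {
  check_nonneg_scalar(unloaded_velocity, "unloaded_velocity")
  slope <- fit$slope
  if (!is.finite(slope)) stop("fit slope is not finite", call. = FALSE)
  se <- if (is.null(fit$slope_se)) NA_real_ else
    sqrt((unloaded_velocity * fit$slope_se)^2 +
         (slope * unloaded_velocity_se)^2)
  c(stopping_force = abs(slope) * unloaded_velocity, se = se)
}

#' Compare transport velocities before and after a measurement
#'
#' Two-sample Kolmogorov-Smirnov test of the unloaded velocities measured
#' before microsphere attachment against those measured after the
#' force-velocity scans, to check that the transport was not degraded by
#' the manipulation. Plumbing around [stats::ks.test()].
#'
#' @param pre,post Velocity samples, nm/s; each of length >= 2.
#' @return List with `statistic` (D), `p_value`, and the sample sizes.
#' @export
compare_pre_post_velocities <- function(pre, post) {
  if (length(pre) < 2L || length(post) < 2L) {
    stop("need at least 2 velocities on each side", call. = FALSE)
  }
  kt <- suppressWarnings(stats::ks.test(pre, post))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       n_pre = length(pre), n_post = length(post))
}
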