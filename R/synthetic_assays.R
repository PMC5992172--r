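#' Synthetic single-molecule assays
#'
#' Generators that emulate the data streams of an optical-tweezers motility
#' experiment: bead-in-trap force traces, force-feedback force-velocity
#' scans, filament tracks with localisation noise, integrated fluorescence
#' intensities, and crosslinker-limited overlap shortening. Every generator
#' is deterministic given its seed, so downstream estimators can be tested
#' by parameter recovery.
#'
#' @name synthetic_assays
NULL

# run code with a locally-set RNG seed, restoring global RNG state after
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

GEOMETRIES <- c("gliding", "sliding", "non_aligned", "mt_anchored")

#' Configuration of a synthetic tweezers assay
#'
#' Bundles every physical and sampling parameter of a simulated
#' bead-on-filament experiment. The defaults describe a 1 um silica
#' microsphere (Stokes drag ~9.4e-6 pN s/nm in water) in a trap of
#' stiffness 0.05 pN/nm, the lower end of the calibrated range used in the
#' experiments this package models.
#'
#' @param geometry Assay geometry, one of `"gliding"`, `"sliding"`,
#'   `"non_aligned"`, `"mt_anchored"`. Metadata only; the physics is set by
#'   the numeric parameters.
#' @param trap_stiffness Trap spring constant per axis, pN/nm.
#' @param bead_drag Bead drag coefficient, pN s/nm.
#' @param temperature Bath temperature, K. `0` gives noise-free traces.
#' @param sample_rate Sampling rate, Hz.
#' @param duration Trace length, s.
#' @param unloaded_velocity Zero-load transport velocity v0, nm/s.
#' @param team_friction Motor-team friction gamma, pN s/nm: magnitude of the
#'   linear force-velocity slope, so the transmitted force at stall is
#'   `team_friction * unloaded_velocity`.
#' @param binding_time Time at which the bead couples to the filament, s.
#' @param detachment_force Load at which the bead-filament link breaks, pN,
#'   or `NA` for an unbreakable link.
#' @param rebind_delay Delay before re-binding after a detachment, s, or
#'   `NA` for no rebinding.
#' @param offset_force Instrumental force offset added to the recorded
#'   channels, pN; length-2 (x, y).
#' @param direction_deg Transport direction in the trap x-y plane, degrees
#'   from the x axis.
#' @param seed RNG seed; mandatory, recorded in trace metadata.
#' @return A `sim_config` object (validated list).
#' @export
sim_config <- function(geometry = "gliding",
                       trap_stiffness = 0.05,
                       bead_drag = 9.4e-6,
                       temperature = T_DEFAULT,
                       sample_rate = 1000,
                       duration = 60,
                       unloaded_velocity = 270,
                       team_friction = 0.037,
                       binding_time = 10,
                       detachment_force = NA_real_,
                       rebind_delay = NA_real_,
                       offset_force = c(0, 0),
                       direction_deg = 0,
                       seed = 1L) {
  geometry <- match.arg(geometry, GEOMETRIES)
  check_positive_scalar(trap_stiffness, "trap_stiffness")
  check_positive_scalar(bead_drag, "bead_drag")
  check_nonneg_scalar(temperature, "temperature")
  check_positive_scalar(sample_rate, "sample_rate")
  check_positive_scalar(duration, "duration")
  check_nonneg_scalar(unloaded_velocity, "unloaded_velocity")
  check_nonneg_scalar(team_friction, "team_friction")
  check_nonneg_scalar(binding_time, "binding_time")
  if (!is.na(detachment_force)) check_positive_scalar(detachment_force, "detachment_force")
  if (!is.na(rebind_delay)) check_nonneg_scalar(rebind_delay, "rebind_delay")
  if (duration <= binding_time) {
    stop("`duration` must exceed `binding_time`", call. = FALSE)
  }
  if (length(offset_force) != 2L || any(!is.finite(offset_force))) {
    stop("`offset_force` must be two finite numbers (x, y)", call. = FALSE)
  }
  structure(
    list(geometry = geometry, trap_stiffness = trap_stiffness,
         bead_drag = bead_drag, temperature = temperature,
         sample_rate = sample_rate, duration = duration,
         unloaded_velocity = unloaded_velocity,
         team_friction = team_friction, binding_time = binding_time,
         detachment_force = detachment_force, rebind_delay = rebind_delay,
         offset_force = as.numeric(offset_force),
         direction_deg = direction_deg, seed = as.integer(seed)),
    class = "sim_config")
}

# Exact discrete-time OU update for position x with relaxation rate lambda,
# stationary mean mu and stationary variance var_x, starting at x0.
# Returns n samples *after* x0 (steps of dt). var_x = 0 gives the
# deterministic exponential relaxation.
ou_path <- function(n, x0, mu, lambda, var_x, dt) {
  if (n <= 0L) return(numeric(0))
  a <- exp(-lambda * dt)
  innov_sd <- sqrt(pmax(var_x * (1 - a^2), 0))
  eps <- if (innov_sd > 0) stats::rnorm(n, 0, innov_sd) else numeric(n)
  # x_i = mu + a^i (x0 - mu) + sum_j a^(i-j) eps_j : recursive AR(1) filter
  x <- stats::filter(eps + (1 - a) * mu, filter = a, method = "recursive",
                     init = x0)
  as.numeric(x)
}

#' Simulate a bead-in-trap force trace
#'
#' Before `binding_time` the bead position follows the exact discrete-time
#' Ornstein-Uhlenbeck process of a free bead in a harmonic trap (relaxation
#' rate `trap_stiffness / bead_drag`, stationary positional variance
#' `kB T / trap_stiffness` per axis). At `binding_time` the bead couples
#' rigidly to a filament transported with the linear force-velocity relation
#' v(F) = v0 - F/gamma, so the trace becomes an OU process with relaxation
#' rate `trap_stiffness / (bead_drag + team_friction)` whose mean force
#' rises to the plateau `team_friction * unloaded_velocity` along the
#' transport direction; the stationary force variance stays at
#' `trap_stiffness * kB * T` (equipartition). If `detachment_force` is set
#' the link breaks when the vector force magnitude exceeds it and the trace
#' reverts to the free-bead process (re-binding after `rebind_delay` if
#' set). The instrumental `offset_force` is added to the recorded channels.
#'
#' @param config A [sim_config()].
#' @return A [force_trace()] whose metadata records the full configuration
#'   and the realised binding/detachment times (ground truth for tests).
#' @export
simulate_trap_trace <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  k <- config$trap_stiffness
  dt <- 1 / config$sample_rate
  n <- floor(config$duration * config$sample_rate) + 1L
  times <- (seq_len(n) - 1L) * dt
  var_x <- kbt(config$temperature) / k              # nm^2, per axis
  lam_free <- k / config$bead_drag
  lam_bound <- k / (config$bead_drag + config$team_friction)
  theta <- config$direction_deg * pi / 180
  u <- c(cos(theta), sin(theta))                    # transport direction
  plateau <- config$team_friction * config$unloaded_velocity  # pN
  mu_bound <- plateau / k * u                       # nm, bound-state mean

  with_seed(config$seed, {
    x <- matrix(NA_real_, n, 2)
    # initial free-bead draw from the stationary distribution
    x[1, ] <- if (var_x > 0) stats::rnorm(2, 0, sqrt(var_x)) else c(0, 0)
    state <- "free"
    i <- 1L
    next_event <- config$binding_time
    events <- data.frame(time = numeric(0), type = character(0))
    while (i < n) {
      if (state == "free") {
        # simulate free until the scheduled binding time (or trace end)
        j <- if (is.finite(next_event)) {
          min(n, 1L + ceiling(next_event / dt))
        } else n
        if (j > i) {
          for (ax in 1:2) {
            x[(i + 1L):j, ax] <- ou_path(j - i, x[i, ax], 0, lam_free,
                                         var_x, dt)
          }
          i <- j
        }
        if (i < n) {
          state <- "bound"
          events <- rbind(events,
                          data.frame(time = times[i], type = "binding"))
        }
      } else {
        # simulate bound to the end, then truncate at detachment if any
        for (ax in 1:2) {
          x[(i + 1L):n, ax] <- ou_path(n - i, x[i, ax], mu_bound[ax],
                                       lam_bound, var_x, dt)
        }
        if (is.na(config$detachment_force)) {
          i <- n
        } else {
          fmag <- k * sqrt(rowSums(x[(i + 1L):n, , drop = FALSE]^2))
          hit <- which(fmag > config$detachment_force)
          if (length(hit) == 0L) {
            i <- n
          } else {
            i <- i + hit[1L]
            events <- rbind(events,
                            data.frame(time = times[i], type = "detachment"))
            state <- "free"
            next_event <- if (is.na(config$rebind_delay)) Inf else
              times[i] + config$rebind_delay
            # bead relaxes freely from the detachment position
          }
        }
      }
    }
    force_trace(
      time = times,
      force_x = k * x[, 1] + config$offset_force[1],
      force_y = k * x[, 2] + config$offset_force[2],
      stage_x = numeric(n), stage_y = numeric(n),
      trap_stiffness = k,
      metadata = list(config = unclass(config), events = events,
                      plateau_force = plateau, seed = config$seed))
  })
}

#' Simulate a force-velocity scan
#'
#' Emulates force-feedback (constant-force) and constant-velocity scans of
#' one crosslinked microtubule pair obeying the linear force-velocity
#' relation v(F) = v0 - F/gamma. In `constant_force` segments the set-point
#' is a force (pN) and the response is the stage velocity (nm/s) plus
#' Gaussian noise of sd `noise_sd`; in `constant_velocity` segments the
#' set-point is a velocity and the response is the held force, with the
#' velocity noise propagated through the slope. Quality weights are drawn
#' uniformly from [0.5, 1] (the by-eye steadiness rating has no defined
#' scale). Set-points should include both signs: load is applied in the
#' forward and backward direction.
#'
#' @param config A [sim_config()]; supplies v0, gamma and the pair seed.
#' @param setpoints Force set-points in pN (or velocities in nm/s for
#'   `mode = "constant_velocity"`). Must be non-empty.
#' @param noise_sd Velocity noise sd, nm/s.
#' @param seed RNG seed; defaults to the config seed.
#' @param mode Segment mode for all segments, or `"mixed"` to alternate.
#' @param segment_duration Nominal duration of each segment, s.
#' @return An [fv_scan()] with one row per segment and the true unloaded
#'   velocity recorded as the independently measured v0.
#' @export
simulate_fv_scan <- function(config, setpoints, noise_sd = 20,
                             seed = config$seed,
                             mode = c("constant_force", "constant_velocity",
                                      "mixed"),
                             segment_duration = 5) {
  stopifnot(inherits(config, "sim_config"))
  mode <- match.arg(mode)
  if (length(setpoints) == 0L) {
    stop("`setpoints` must be non-empty", call. = FALSE)
  }
  check_nonneg_scalar(noise_sd, "noise_sd")
  v0 <- config$unloaded_velocity
  gam <- config$team_friction
  if (gam <= 0) stop("`team_friction` must be positive for a scan", call. = FALSE)
  m <- length(setpoints)
  modes <- switch(mode,
    constant_force = rep("constant_force", m),
    constant_velocity = rep("constant_velocity", m),
    mixed = rep(c("constant_force", "constant_velocity"), length.out = m))
  with_seed(seed, {
    vnoise <- stats::rnorm(m, 0, noise_sd)
    w <- stats::runif(m, 0.5, 1)
    cf <- modes == "constant_force"
    response <- numeric(m)
    # constant force: measure velocity; constant velocity: measure force
    response[cf] <- v0 - setpoints[cf] / gam + vnoise[cf]
    response[!cf] <- gam * (v0 - setpoints[!cf] + vnoise[!cf])
    fv_scan(segments = data.frame(mode = modes, setpoint = setpoints,
                                  response = response, quality_weight = w,
                                  duration = rep(segment_duration, m)),
            unloaded_velocity = v0,
            pair_id = sprintf("sim-%d", seed))
  })
}

#' Simulate a transported-filament track
#'
#' Constant-velocity motion sampled at a fixed frame interval with iid
#' Gaussian localisation noise, emulating the per-frame positions a
#' filament tracker extracts from a movie.
#'
#' @param v_true True transport velocity, nm/s.
#' @param loc_noise_sd Localisation noise sd, nm.
#' @param frame_interval Time between frames, s.
#' @param n_frames Number of frames (>= 2).
#' @param seed RNG seed.
#' @param filament_length Filament length, nm.
#' @param mode Track provenance label, see [filament_track()].
#' @return A [filament_track()].
#' @export
simulate_track <- function(v_true, loc_noise_sd, frame_interval, n_frames,
                           seed = 1L, filament_length = 4000,
                           mode = "tracked") {
  check_nonneg_scalar(loc_noise_sd, "loc_noise_sd")
  check_positive_scalar(frame_interval, "frame_interval")
  if (n_frames < 2L) stop("`n_frames` must be >= 2", call. = FALSE)
  with_seed(seed, {
    t <- (seq_len(n_frames) - 1L) * frame_interval
    pos <- v_true * t +
      if (loc_noise_sd > 0) stats::rnorm(n_frames, 0, loc_noise_sd) else 0
    filament_track(frame_times = t, positions = pos,
                   filament_length = filament_length, mode = mode,
                   filament_id = sprintf("sim-%d", seed))
  })
}

#' Simulate integrated fluorescence intensities
#'
#' Integrated intensity of a diffraction-limited spot containing
#' `n_molecules` fluorophores: the sum of `n_molecules` positive draws
#' (gamma-distributed) with mean `single_mean` and coefficient of variation
#' `single_cv`, emulating a single-fluorophore intensity calibration.
#'
#' @param n_molecules Number of fluorophores in the spot (>= 0).
#' @param single_mean Mean single-fluorophore intensity, a.u.
#' @param single_cv Coefficient of variation of one fluorophore's intensity.
#' @param seed RNG seed.
#' @param n_replicates Number of independent spots to draw.
#' @return Numeric vector of `n_replicates` integrated intensities (a.u.).
#' @export
simulate_intensities <- function(n_molecules, single_mean, single_cv,
                                 seed = 1L, n_replicates = 1L) {
  if (n_molecules < 0) stop("`n_molecules` must be >= 0", call. = FALSE)
  check_positive_scalar(single_mean, "single_mean")
  check_nonneg_scalar(single_cv, "single_cv")
  if (n_molecules == 0L) return(rep(0, n_replicates))
  with_seed(seed, {
    if (single_cv == 0) {
      return(rep(n_molecules * single_mean, n_replicates))
    }
    shape <- 1 / single_cv^2
    scale <- single_mean * single_cv^2
    draws <- matrix(stats::rgamma(n_molecules * n_replicates, shape = shape,
                                  scale = scale),
                    nrow = n_molecules)
    colSums(draws)
  })
}

#' Simulate a crosslinker-limited overlap-shortening series
#'
#' Motors slide a microtubule pair apart, compacting `n_crosslinkers`
#' diffusible crosslinkers into the shrinking overlap. The confined
#' crosslinkers push back with the 1-D ideal-gas entropic force
#' N kB T / L, so shortening follows dL/dt = -rate * (1 - L_stall / L) and
#' stalls at L_stall = N kB T / motor_force. The series is integrated until
#' the recorded length is within 0.5% of L_stall (well inside the 1%
#' contract), or until hitting `floor_nm` when no crosslinkers oppose the
#' motors.
#'
#' @param n_crosslinkers Number of confined crosslinkers N (>= 0).
#' @param motor_force Sliding force of the motor team, pN (> 0).
#' @param L_start Initial overlap length, nm; must exceed the stall length.
#' @param temperature Temperature, K.
#' @param rate Unopposed shortening speed, nm/s.
#' @param seed RNG seed (used only when `noise_sd > 0`).
#' @param n_points Number of recorded samples.
#' @param noise_sd Optional measurement noise on recorded lengths, nm.
#'   Default 0 keeps the series exactly non-increasing.
#' @param floor_nm Smallest recordable overlap, nm.
#' @return An `overlap_series` object: times (s), overlap_lengths (nm),
#'   n_crosslinkers, temperature (K) and the true motor_force (pN).
#' @export
simulate_overlap_series <- function(n_crosslinkers, motor_force, L_start,
                                    temperature = T_DEFAULT, rate = 20,
                                    seed = 1L, n_points = 200L,
                                    noise_sd = 0, floor_nm = 1) {
  if (n_crosslinkers < 0) stop("`n_crosslinkers` must be >= 0", call. = FALSE)
  check_positive_scalar(motor_force, "motor_force")
  check_positive_scalar(L_start, "L_start")
  check_positive_scalar(rate, "rate")
  check_nonneg_scalar(noise_sd, "noise_sd")
  L_stall <- n_crosslinkers * kbt(temperature) / motor_force
  if (L_start <= L_stall) {
    stop(sprintf(
      "`L_start` (%.1f nm) is already at or below the stall length %.1f nm",
      L_start, L_stall), call. = FALSE)
  }
  target <- if (L_stall > 0) L_stall * 1.005 else floor_nm
  # the ODE is separable: t(L) = (L0 - L + a ln((L0-a)/(L-a))) / rate with
  # a = L_stall; sample the exact solution by inverting t(L) per time point
  if (L_stall > 0) {
    a <- L_stall
    time_of <- function(L) (L_start - L + a * log((L_start - a) / (L - a))) / rate
    t_total <- time_of(target)
    ts <- seq(0, t_total, length.out = n_points)
    Ls <- vapply(ts, function(ti) {
      if (ti <= 0) return(L_start)
      stats::uniroot(function(L) time_of(L) - ti,
                     lower = target, upper = L_start,
                     tol = 1e-9 * L_start)$root
    }, numeric(1))
    Ls <- cummin(Ls)                       # guard against root-solver jitter
  } else {
    t_total <- (L_start - floor_nm) / rate
    ts <- seq(0, t_total, length.out = n_points)
    Ls <- pmax(L_start - rate * ts, floor_nm)
  }
  if (noise_sd > 0) {
    Ls <- with_seed(seed, Ls + stats::rnorm(length(Ls), 0, noise_sd))
    Ls <- rev(cummax(rev(Ls)))   # keep the non-increasing invariant
  }
  structure(list(times = ts, overlap_lengths = Ls,
                 n_crosslinkers = n_crosslinkers, temperature = temperature,
                 motor_force = motor_force),
            class = "overlap_series")
}
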