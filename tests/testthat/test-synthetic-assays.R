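test_that("free-bead traces satisfy equipartition and carry the offset", {
  cfg <- sim_config(trap_stiffness = 0.05, temperature = 298,
                    duration = 30, binding_time = 25, sample_rate = 1000,
                    offset_force = c(0.5, 0), seed = 11)
  tr <- simulate_trap_trace(cfg)
  pre <- tr$time < 25
  expect_equal(var(tr$force_x[pre]), 0.05 * kbt(298), tolerance = 0.05)
  expect_equal(var(tr$force_y[pre]), 0.05 * kbt(298), tolerance = 0.05)
  # offset shifts the mean, not the variance; SE of the mean from the OU
  # correlation time tau = drag/k is tiny at these parameters
  expect_equal(mean(tr$force_x[pre]), 0.5, tolerance = 0.02)
  expect_equal(mean(tr$force_y[pre]), 0, tolerance = 0.02)
})

test_that("post-binding force plateaus at team_friction * v0 plus offset", {
  # noise-free limit: temperature 0 makes the trace deterministic
  cfg <- sim_config(unloaded_velocity = 270, team_friction = 0.037,
                    temperature = 0, duration = 30, binding_time = 2,
                    offset_force = c(0.3, -0.2), seed = 1)
  tr <- simulate_trap_trace(cfg)
  late <- tr$time > 25
  expect_equal(mean(tr$force_x[late]), 0.037 * 270 + 0.3, tolerance = 1e-9)
  expect_equal(mean(tr$force_y[late]), -0.2, tolerance = 1e-9)

  # no motor drive: v0 = 0 leaves the post-binding mean at the offset
  cfg0 <- sim_config(unloaded_velocity = 0, team_friction = 0.037,
                     temperature = 0, duration = 10, binding_time = 2,
                     offset_force = c(0.3, -0.2), seed = 1)
  tr0 <- simulate_trap_trace(cfg0)
  expect_equal(mean(tr0$force_x[tr0$time > 8]), 0.3, tolerance = 1e-12)
})

test_that("the transport direction only rotates the plateau vector", {
  mk <- function(deg) {
    simulate_trap_trace(sim_config(temperature = 0, duration = 20,
                                   binding_time = 2, direction_deg = deg,
                                   seed = 1))
  }
  t0 <- mk(0); t35 <- mk(35)
  mag <- function(tr) sqrt(mean(tr$force_x[tr$time > 18])^2 +
                           mean(tr$force_y[tr$time > 18])^2)
  expect_equal(mag(t0), mag(t35), tolerance = 1e-10)
})

test_that("traces are bit-identical under the same config and seed", {
  cfg <- sim_config(duration = 5, binding_time = 1, seed = 42)
  t1 <- simulate_trap_trace(cfg)
  t2 <- simulate_trap_trace(cfg)
  expect_identical(t1, t2)
  t3 <- simulate_trap_trace(sim_config(duration = 5, binding_time = 1,
                                       seed = 43))
  expect_false(identical(t1$force_x, t3$force_x))
})

test_that("detachment reverts the trace to the free-bead baseline", {
  cfg <- sim_config(duration = 30, binding_time = 5, detachment_force = 8,
                    temperature = 0, seed = 3)
  tr <- simulate_trap_trace(cfg)
  ev <- tr$metadata$events
  expect_identical(ev$type[1:2], c("binding", "detachment"))
  # after detachment (no rebinding) the noise-free bead relaxes to zero
  expect_lt(abs(tr$force_x[length(tr$force_x)]), 1e-3)
})

test_that("config invariants are enforced", {
  expect_error(sim_config(trap_stiffness = 0), "trap_stiffness")
  expect_error(sim_config(trap_stiffness = Inf), "trap_stiffness")
  expect_error(sim_config(duration = 5, binding_time = 5), "binding_time")
  expect_error(sim_config(bead_drag = -1), "bead_drag")
})

test_that("noise-free scans lie exactly on the force-velocity line", {
  cfg <- sim_config(geometry = "sliding", unloaded_velocity = 57,
                    team_friction = 0.0123, seed = 5)
  scan <- simulate_fv_scan(cfg, setpoints = c(-5, -2, 0, 2, 5, 0.0123 * 57),
                          noise_sd = 0)
  v <- scan$segments$response
  expect_equal(v[3], 57)                       # F = 0 -> v0
  expect_equal(v[6], 0)                        # F = gamma*v0 -> stall
  expect_equal(range(v), c(57 - 5 / 0.0123, 57 + 5 / 0.0123))
  expect_true(all(scan$segments$quality_weight > 0.5 - 1e-12 &
                  scan$segments$quality_weight <= 1))
  expect_error(simulate_fv_scan(cfg, setpoints = numeric(0)), "non-empty")
})

test_that("constant-velocity segments report the held force", {
  cfg <- sim_config(unloaded_velocity = 100, team_friction = 0.02, seed = 5)
  scan <- simulate_fv_scan(cfg, setpoints = c(0, 50, 100, 150), noise_sd = 0,
                          mode = "constant_velocity")
  expect_equal(scan$segments$response, 0.02 * (100 - c(0, 50, 100, 150)))
})

test_that("synthetic tracks recover the true velocity", {
  tr <- simulate_track(v_true = 100, loc_noise_sd = 0, frame_interval = 1,
                       n_frames = 20, seed = 1)
  expect_equal(instantaneous_velocities(tr), rep(100, 19))

  # v_true = 57, 100 frames, 10 nm noise: mean within 3 SE; for the mean of
  # frame-to-frame velocities the noise telescopes, SE = sd*sqrt(2)/(n-1)/dt
  tr2 <- simulate_track(57, 10, 1, 100, seed = 2)
  se <- 10 * sqrt(2) / 99
  expect_lt(abs(mean(instantaneous_velocities(tr2)) - 57), 3 * se)

  expect_error(simulate_track(57, -1, 1, 10), "loc_noise_sd")
  expect_error(simulate_track(57, 0, 1, 1), "n_frames")
})

test_that("intensity draws have the stated moment structure", {
  expect_identical(simulate_intensities(0, 100, 0.3), 0)
  expect_equal(simulate_intensities(7, 100, 0), 700)
  reps <- simulate_intensities(50, 100, 0.3, seed = 8, n_replicates = 400)
  expect_equal(mean(reps), 5000, tolerance = 0.02)
  expect_equal(sd(reps), 100 * 0.3 * sqrt(50), tolerance = 0.2)
})

test_that("overlap series shorten monotonically to the entropic stall", {
  s <- simulate_overlap_series(20, motor_force = 0.5, L_start = 1000,
                               temperature = 298)
  L_stall <- 20 * kbt(298) / 0.5
  expect_true(all(diff(s$overlap_lengths) <= 0))
  expect_equal(tail(s$overlap_lengths, 1), L_stall, tolerance = 0.01)
  # doubling N doubles the stall length
  s2 <- simulate_overlap_series(40, motor_force = 0.5, L_start = 1000)
  expect_equal(tail(s2$overlap_lengths, 1) / tail(s$overlap_lengths, 1), 2,
               tolerance = 1e-3)
  # no crosslinkers: shortening runs to the floor
  s0 <- simulate_overlap_series(0, motor_force = 0.5, L_start = 500,
                                floor_nm = 2)
  expect_equal(tail(s0$overlap_lengths, 1), 2)
  expect_error(simulate_overlap_series(50, 0.1, L_start = 100),
               "stall length")
})
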