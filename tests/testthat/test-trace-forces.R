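make_trace <- function(fx, fy, dt = 0.01, k = 0.05) {
  n <- length(fx)
  force_trace(time = (seq_len(n) - 1) * dt, force_x = fx, force_y = fy,
              trap_stiffness = k)
}

test_that("offset estimation averages the baseline window", {
  tr <- make_trace(rep(1, 200), rep(-2, 200))
  off <- estimate_offset(tr, c(0, 1))
  expect_equal(unname(off), c(1, -2))
  # simulated free bead with a known offset
  cfg <- sim_config(duration = 20, binding_time = 15,
                    offset_force = c(0.5, 0), seed = 21)
  trs <- simulate_trap_trace(cfg)
  offs <- estimate_offset(trs, c(0, 14))
  se <- sqrt(2 * 0.05 * kbt(298) * (cfg$bead_drag / 0.05) / 14)
  expect_lt(abs(offs[["offset_x"]] - 0.5), 3 * se + 1e-3)
  # precondition violations
  expect_error(estimate_offset(trs, c(0, 16), binding_time = 15),
               "post-binding")
  expect_error(estimate_offset(tr, c(0, 0.05)), "samples")
  expect_error(estimate_offset(tr, c(-5, -1)), "outside")
})

test_that("binding detection finds the force rise, and only real ones", {
  # pure baseline trace: no event
  base <- simulate_trap_trace(sim_config(duration = 20, binding_time = 19.5,
                                         seed = 31))
  short <- force_trace(base$time[base$time < 19], base$force_x[base$time < 19],
                       base$force_y[base$time < 19], trap_stiffness = 0.05)
  expect_null(detect_binding(short))
  # binding at t = 30 s detected within 1 s
  tr <- simulate_trap_trace(gliding_config(seed = 32, duration = 50,
                                           binding_time = 30))
  expect_lt(abs(detect_binding(tr) - 30), 1)
  # detachment and rebinding: first event by default, both with all = TRUE
  tr2 <- simulate_trap_trace(sim_config(duration = 40, binding_time = 10,
                                        detachment_force = 9.5,
                                        rebind_delay = 8, seed = 33))
  ev <- tr2$metadata$events
  truth <- ev$time[ev$type == "binding"]
  expect_gte(length(truth), 2)
  got <- detect_binding(tr2, all = TRUE)
  expect_equal(detect_binding(tr2), got[1])
  expect_gte(length(got), 2)
  expect_lt(abs(got[1] - truth[1]), 1)
  expect_lt(abs(got[2] - truth[2]), 1)
})

test_that("plateau detection finds flat stretches and rejects pure ramps", {
  # noise-free trace: plateau covers essentially the whole post-rise window
  tr0 <- simulate_trap_trace(sim_config(temperature = 0, duration = 40,
                                        binding_time = 5, seed = 1))
  win <- detect_plateau(tr0, binding_time = 5)
  expect_false(is.null(win))
  expect_lt(win[1], 12)          # flat within a few relaxation times
  expect_gt(win[2], 36)          # slope undefined within half a window of the end
  # ramp-only trace (attachment broke before the filament halted)
  ramp <- make_trace(seq(0, 10, length.out = 2000), rep(0, 2000))
  expect_null(detect_plateau(ramp, binding_time = 0.5))
  # piecewise trace with a known 20 s plateau bounded by ramps
  t <- seq(0, 60, by = 0.01)
  f <- ifelse(t < 20, t * 0.5, ifelse(t <= 40, 10, 10 + (t - 40) * 0.5))
  set.seed(5)
  f <- f + rnorm(length(f), 0, 0.05)
  trp <- make_trace(f, rep(0, length(f)))
  winp <- detect_plateau(trp, binding_time = 1)
  expect_lt(abs(winp[1] - 20), 2)
  expect_lt(abs(winp[2] - 40), 2)
})

test_that("stopping force combines offset-corrected axes by Pythagoras", {
  n <- 3000
  fx <- c(rep(0, 1000), rep(3, 2000))
  fy <- c(rep(0, 1000), rep(4, 2000))
  tr <- make_trace(fx, fy)
  res <- stopping_force_from_plateau(tr, baseline_window = c(0, 9),
                                     plateau_window = c(15, 29))
  expect_equal(res$stopping_force, 5)
  # identical offsets and plateau means give zero force
  tr2 <- make_trace(rep(1, n), rep(1, n))
  res2 <- stopping_force_from_plateau(tr2, baseline_window = c(0, 9),
                                      plateau_window = c(15, 29))
  expect_equal(res2$stopping_force, 0)
  expect_true(res2$stopping_force >= 0)
  # plateau window below the duration floor errors
  expect_error(stopping_force_from_plateau(tr, baseline_window = c(0, 9),
                                           plateau_window = c(15, 15.2)),
               "minimum")
})

test_that("stopping force is invariant under axis rotation and offsets", {
  cfg <- gliding_config(seed = 44, duration = 30, binding_time = 5)
  tr <- simulate_trap_trace(cfg)
  res <- stopping_force_from_plateau(tr, baseline_window = c(0, 4.5),
                                     plateau_window = c(15, 30))
  for (ang in c(0.4, 1.2, 2.6)) {
    rx <- cos(ang) * tr$force_x - sin(ang) * tr$force_y
    ry <- sin(ang) * tr$force_x + cos(ang) * tr$force_y
    trr <- make_trace(rx, ry, dt = 0.001)
    resr <- stopping_force_from_plateau(trr, baseline_window = c(0, 4.5),
                                        plateau_window = c(15, 30))
    expect_equal(resr$stopping_force, res$stopping_force, tolerance = 1e-10)
  }
  # adding a constant vector to both channels changes nothing
  tro <- make_trace(tr$force_x + 2.3, tr$force_y - 1.1, dt = 0.001)
  reso <- stopping_force_from_plateau(tro, baseline_window = c(0, 4.5),
                                      plateau_window = c(15, 30))
  expect_equal(reso$stopping_force, res$stopping_force, tolerance = 1e-10)
})

test_that("on noise-free traces the stopping force equals gamma * v0", {
  cfg <- sim_config(temperature = 0, unloaded_velocity = 270,
                    team_friction = 0.037, duration = 60, binding_time = 5,
                    direction_deg = 25, offset_force = c(0.4, -0.1),
                    seed = 1)
  tr <- simulate_trap_trace(cfg)
  res <- stopping_force_from_plateau(tr, baseline_window = c(0, 4.5),
                                     plateau_window = c(40, 60))
  expect_equal(res$stopping_force, 0.037 * 270, tolerance = 1e-8)
})

test_that("the equipartition diagnostic recovers the trap stiffness", {
  tr <- simulate_trap_trace(sim_config(duration = 30, binding_time = 29,
                                       trap_stiffness = 0.08, seed = 55))
  eq <- equipartition_check(tr, c(0, 28))
  expect_equal(unname(eq$implied_stiffness[["x"]]), 0.08, tolerance = 0.05)
  expect_equal(unname(eq$implied_stiffness[["y"]]), 0.08, tolerance = 0.05)
})

test_that("trace annotations enforce window ordering", {
  expect_error(trace_annotation(c(0, 6), 5, c(10, 20)), "baseline")
  expect_error(trace_annotation(c(0, 4), 5, c(4, 20)), "plateau")
  expect_error(trace_annotation(c(4, 4), 5, c(10, 20)), "non-empty")
  ann <- trace_annotation(c(0, 4), 5, c(10, 20))
  tr <- simulate_trap_trace(gliding_config(seed = 7, duration = 21,
                                           binding_time = 5))
  res <- stopping_force_from_plateau(tr, ann)
  expect_s3_class(res, "stopping_force_result")
})
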