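test_that("instantaneous and per-filament velocities are frame quotients", {
  lin <- filament_track(0:9, (0:9) * 100, 5000)
  expect_equal(instantaneous_velocities(lin), rep(100, 9))
  expect_equal(unname(per_filament_velocity(lin)), c(100, 9))
  still <- filament_track(0:9, rep(5, 10), 5000)
  expect_equal(instantaneous_velocities(still), rep(0, 9))
  # noisy simulated track: mean within 3 SE (noise telescopes in the mean)
  tr <- simulate_track(57, 10, 1, 100, seed = 71)
  se <- 10 * sqrt(2) / 99
  expect_lt(abs(per_filament_velocity(tr)[["velocity"]] - 57), 3 * se)
  # kymograph tracks carry an inherently averaged slope, returned as-is
  ky <- filament_track(c(0, 60), c(0, 3420), 5000, mode = "kymograph",
                       velocity = 57)
  expect_equal(per_filament_velocity(ky)[["velocity"]], 57)
  # nonuniform frame times: mean of quotients, checked by direct summation
  t <- c(0, 1, 3, 4.5, 7)
  p <- c(0, 90, 320, 430, 700)
  tr2 <- filament_track(t, p, 5000)
  acc <- 0
  for (i in 2:5) acc <- acc + (p[i] - p[i - 1]) / (t[i] - t[i - 1])
  expect_equal(mean(instantaneous_velocities(tr2)), acc / 4)
})

test_that("uniform-sampling mean velocity telescopes to net displacement over time", {
  set.seed(72)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    pos <- cumsum(rnorm(n, 10, 40))
    tr <- filament_track(seq_len(n), pos, 3000)
    v <- mean(instantaneous_velocities(tr))
    expect_equal(v, (pos[n] - pos[1]) / (n - 1), tolerance = 1e-12)
  }
})

test_that("time weighting weighs filaments by observation duration", {
  s <- time_weighted_population(c(10, 20), c(1, 3))
  expect_equal(s$population_mean, 17.5)
  expect_equal(s$n_filaments, 2)
  # a single filament is its own summary
  s1 <- time_weighted_population(42, 7)
  expect_equal(s1$population_mean, 42)
  expect_equal(s1$population_median, 42)
  # equal durations reduce to the unweighted statistics
  set.seed(73)
  v <- rnorm(31, 269, 95)
  se <- time_weighted_population(v, rep(2.5, 31))
  expect_equal(se$population_mean, mean(v))
  expect_equal(se$population_sd, sd(v))
  expect_equal(se$population_median, median(v))
  expect_error(time_weighted_population(c(1, 2), c(1, 0)), "positive")
})

test_that("weighted statistics match the brute-force oracle on random data", {
  set.seed(74)
  for (i in 1:300) {
    n <- sample(1:30, 1)
    v <- round(rnorm(n, 100, 60), 1)
    w <- round(runif(n, 0.5, 20), 2)
    s <- time_weighted_population(v, w)
    o <- oracle_weighted_stats(v, w)
    expect_equal(s$population_mean, o$mean, tolerance = 1e-12)
    expect_equal(s$population_median, o$median, tolerance = 1e-12)
    if (n > 1) expect_equal(s$population_sd, o$sd, tolerance = 1e-12)
  }
})

test_that("boxplot statistics use hinges and the 1.5 IQR fences", {
  b <- boxplot_stats(1:7)
  expect_equal(b$median, 4)
  expect_equal(b$q1, 2)
  expect_equal(b$q3, 6)
  expect_length(b$outliers, 0)
  expect_equal(b$whisker_low, 1)
  expect_equal(b$whisker_high, 7)
  # constant sample
  bc <- boxplot_stats(rep(3, 5))
  expect_equal(bc$median, 3)
  expect_equal(bc$q1, 3)
  expect_equal(bc$whisker_high, 3)
  expect_length(bc$outliers, 0)
  # an extreme point is an outlier iff it exceeds the fence
  bo <- boxplot_stats(c(1, 2, 3, 100))
  oo <- oracle_boxplot(c(1, 2, 3, 100))
  expect_equal(bo$outliers, oo$outliers)
  expect_error(boxplot_stats(numeric(0)), "empty")
})

test_that("boxplot statistics match the brute-force oracle on random samples", {
  set.seed(75)
  for (i in 1:300) {
    n <- sample(1:40, 1)
    x <- round(rt(n, df = 3) * 10, 2)   # heavy tails provoke outliers
    b <- boxplot_stats(x)
    o <- oracle_boxplot(x)
    expect_equal(b$median, o$median)
    expect_equal(b$q1, o$q1)
    expect_equal(b$q3, o$q3)
    expect_equal(b$whisker_low, o$whisker_low)
    expect_equal(b$whisker_high, o$whisker_high)
    expect_equal(b$outliers, o$outliers)
  }
})

test_that("molecule counting divides net intensity by the calibration", {
  cal <- intensity_calibration(100, background = 50)
  expect_equal(count_molecules(100 * 12 + 50, cal)$count, 12)
  expect_equal(count_molecules(50, cal)$count, 0)
  expect_warning(res <- count_molecules(10, cal), "clamped")
  expect_equal(res$count, 0)
  # linear density in motors per 100 nm
  d <- count_molecules(100 * 12 + 50, cal, length_nm = 1200)
  expect_equal(d$density_per_100nm, 1)
  # recovery on synthetic intensities: 50 molecules at cv 0.3
  ints <- simulate_intensities(50, 100, 0.3, seed = 76, n_replicates = 200)
  counts <- count_molecules(ints, intensity_calibration(100))$count
  se <- 0.3 * sqrt(50) / sqrt(200)
  expect_lt(abs(mean(counts) - 50), 3 * se)
})

test_that("surface motor number scales with length, reach and density", {
  expect_equal(motor_number_from_surface(0, 10), 0L)
  expect_equal(motor_number_from_surface(4000, 10, reach = 50), 2L)
  expect_equal(motor_number_from_surface(4000, 20, reach = 50), 4L)
  expect_error(motor_number_from_surface(4000, -1), "surface_density")
})
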