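# Independent brute-force oracles used to cross-check the package's
# estimators. Deliberately written as plain loops / exhaustive searches,
# sharing no code with the implementations they verify.

# median of a sorted vector by explicit even/odd index arithmetic
oracle_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2L == 1L) s[(n + 1L) / 2L] else (s[n / 2L] + s[n / 2L + 1L]) / 2
}

# quartiles by linear interpolation between order statistics at rank
# (n + 1) p, clamped to the extremes
oracle_quartile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n + 1) * p
  if (h <= 1) return(s[1])
  if (h >= n) return(s[n])
  lo <- floor(h)
  s[lo] + (h - lo) * (s[lo + 1L] - s[lo])
}

oracle_hinges <- function(x) {
  c(q1 = oracle_quartile(x, 0.25), q3 = oracle_quartile(x, 0.75))
}

# full boxplot summary with the 1.5 IQR fences, fences checked per point
oracle_boxplot <- function(x) {
  h <- oracle_hinges(x)
  iqr <- h["q3"] - h["q1"]
  lo <- h["q1"] - 1.5 * iqr
  hi <- h["q3"] + 1.5 * iqr
  out <- logical(length(x))
  for (i in seq_along(x)) out[i] <- x[i] < lo || x[i] > hi
  list(median = oracle_median(x), q1 = unname(h["q1"]), q3 = unname(h["q3"]),
       whisker_low = min(x[!out]), whisker_high = max(x[!out]),
       outliers = sort(x[out]))
}

# duration-weighted population statistics by direct loop summation
oracle_weighted_stats <- function(v, w) {
  W <- 0; S <- 0
  for (i in seq_along(v)) { W <- W + w[i]; S <- S + w[i] * v[i] }
  m <- S / W
  ss <- 0
  for (i in seq_along(v)) ss <- ss + w[i] * (v[i] - m)^2
  sdv <- sqrt(ss / (W - W / length(v)))
  # weighted median: walk the sorted values until half the weight is passed
  o <- order(v)
  acc <- 0
  med <- NA_real_
  for (i in o) {
    acc <- acc + w[i]
    if (acc > W / 2) { med <- v[i]; break }
    if (acc == W / 2) {
      nxt <- o[which(o == i) + 1L]
      med <- (v[i] + v[nxt]) / 2
      break
    }
  }
  list(mean = m, sd = sdv, median = med)
}

# weighted least squares of force on velocity by iterative grid refinement
# of the weighted squared loss; parameterised as (level at the mean
# velocity, slope) so the two grid axes decouple, then mapped back to the
# intercept at v = 0
oracle_wls_grid <- function(v, f, w, n_grid = 25L, n_zoom = 40L) {
  vc <- v - mean(v)
  a_lo <- min(f) - 2 * (diff(range(f)) + 1)
  a_hi <- max(f) + 2 * (diff(range(f)) + 1)
  span_b <- (diff(range(f)) + 1) / max(diff(range(v)), 1e-6)
  b_lo <- -10 * span_b; b_hi <- 10 * span_b
  loss <- function(a, b) sum(w * (f - a - b * vc)^2)
  best <- c(Inf, NA, NA)
  for (it in seq_len(n_zoom)) {
    as <- seq(a_lo, a_hi, length.out = n_grid)
    bs <- seq(b_lo, b_hi, length.out = n_grid)
    best <- c(Inf, NA, NA)
    for (a in as) for (b in bs) {
      l <- loss(a, b)
      if (l < best[1]) best <- c(l, a, b)
    }
    da <- (a_hi - a_lo) / (n_grid - 1L)
    db <- (b_hi - b_lo) / (n_grid - 1L)
    a_lo <- best[2] - 2 * da; a_hi <- best[2] + 2 * da
    b_lo <- best[3] - 2 * db; b_hi <- best[3] + 2 * db
  }
  c(intercept = best[2] - best[3] * mean(v), slope = best[3])
}

# gliding-regime configuration used across recovery tests (plateau 9.99 pN)
gliding_config <- function(seed, duration = 40, binding_time = 8) {
  sim_config(geometry = "gliding", trap_stiffness = 0.05,
             unloaded_velocity = 270, team_friction = 0.037,
             duration = duration, binding_time = binding_time, seed = seed)
}
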