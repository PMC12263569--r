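ramp <- function(f, dur = 10, rate = 100, offset = 0)
  phase_series(2 * pi * f * seq(0, dur, by = 1 / rate) + offset, rate)

test_that("instantaneous phase counts cycles and reflects shifts", {
  rate <- 100
  t <- seq(0, 10, by = 1 / rate)
  mk <- function(x) envelope_series(x, rate, band = c(3.3, 5.7),
                                    source_duration = 10)
  p <- instantaneous_phase(mk(sin(2 * pi * 4.5 * t)))
  expect_equal(p$theta[length(p$theta)] - p$theta[1], 2 * pi * 45,
               tolerance = 0.5)
  # 0.05 s delay of a 4.5 Hz cycle = 0.225 cycles of constant offset
  pd <- instantaneous_phase(mk(sin(2 * pi * 4.5 * (t - 0.05))))
  mid <- 100:900
  offs <- (p$theta[mid] - pd$theta[mid]) %% (2 * pi)  # offset defined mod 2 pi
  expect_equal(mean(offs), 2 * pi * 0.225, tolerance = 0.02)
  expect_lt(stats::sd(offs), 0.02)
  # negation flips the phase by a constant pi
  pn <- instantaneous_phase(mk(-sin(2 * pi * 4.5 * t)))
  expect_equal(abs(mean(p$theta[mid] - pn$theta[mid])) %% (2 * pi), pi,
               tolerance = 0.02)
  expect_error(instantaneous_phase(
    envelope_series(t, rate, source_duration = 10)), "band-limited")
})

test_that("PLV identities: self, constant lag, roots of unity", {
  a <- ramp(4.5)
  expect_equal(plv(a, a), 1.0)
  expect_equal(plv(a, ramp(4.5, offset = 1.23)), 1.0, tolerance = 1e-12)
  # evenly spaced phase differences over [0, 2pi) sum to zero
  T <- 360
  b <- phase_series(numeric(T), 100)
  u <- phase_series(2 * pi * (0:(T - 1)) / T, 100)
  expect_equal(plv(u, b), 0, tolerance = 1e-12)
})

test_that("PLV is bounded, symmetric, and lag-invariant on random phases", {
  for (i in 1:20) {
    th1 <- cumsum(withr::with_seed(i, stats::runif(200, -0.5, 1)))
    th2 <- cumsum(withr::with_seed(i + 100, stats::runif(200, -0.5, 1)))
    a <- phase_series(th1, 100); b <- phase_series(th2, 100)
    v <- plv(a, b)
    expect_gte(v, 0); expect_lte(v, 1)
    expect_equal(plv(b, a), v)
    shifted <- phase_series(th2 + 2.345, 100)
    expect_equal(plv(a, shifted), v, tolerance = 1e-12)
  }
})

test_that("n:m PLV captures subharmonic locking and reduces to 1:1", {
  a <- ramp(2.25, dur = 8)   # exactly 18 cycles
  b <- ramp(4.5, dur = 8)    # exactly 36 cycles
  expect_equal(plv_nm(a, b, 2, 1), 1.0, tolerance = 1e-12)
  expect_lt(plv_nm(a, b, 1, 1), 0.01)
  expect_equal(plv_nm(a, b, 1, 1), plv(a, b))
  expect_error(plv_nm(a, b, 0, 1), "positive")
})

test_that("corrected moving windows tile the signal as expected", {
  a <- ramp(4.5, dur = 10)
  a <- phase_series(a$theta[1:1000], 100)  # exactly 10 s
  rep5 <- moving_window_plv(a, a, win = 5, overlap = 3)
  expect_equal(nrow(rep5$windows), 3L)   # starts 0, 2, 4
  expect_equal(rep5$windows$start, c(0, 2, 4))
  expect_equal(rep5$scalar, 1.0)
  expect_error(moving_window_plv(a, a, win = 3, overlap = 3), "exceed")
  short <- phase_series(a$theta[1:100], 100)
  expect_error(moving_window_plv(short, short), "shorter")
})

test_that("legacy emulation reproduces the (slots-1)/slots self-comparison identity", {
  # 80.14 s at 100 Hz: 40 slots at step 2 s, 39 assigned unit windows
  n <- 8014
  a <- phase_series(2 * pi * 4.5 * (0:(n - 1)) / 100, 100)
  leg <- moving_window_plv(a, a, legacy = TRUE)
  expect_equal(leg$scalar, 39 / 40)
  expect_equal(leg$windows$value[nrow(leg$windows)], 0)
  # generally: legacy = corrected-style unit mean x (slots-1)/slots on self-comparison
  for (dur_s in c(20.5, 33.02, 57.9)) {
    m <- round(dur_s * 100)
    p <- phase_series(2 * pi * 3 * (0:(m - 1)) / 100, 100)
    slots <- m %/% 200
    expect_equal(moving_window_plv(p, p, legacy = TRUE)$scalar,
                 (slots - 1) / slots)
  }
})

test_that("moving-window scalar equals a brute-force window-by-window oracle", {
  for (i in 1:20) {
    n <- withr::with_seed(i, sample(900:2000, 1))
    th1 <- cumsum(withr::with_seed(i + 30, stats::runif(n, 0, 0.6)))
    th2 <- cumsum(withr::with_seed(i + 60, stats::runif(n, 0, 0.6)))
    a <- phase_series(th1, 100); b <- phase_series(th2, 100)
    got <- moving_window_plv(a, b, win = 5, overlap = 3)$scalar
    expect_equal(got, oracle_moving_mean(th1, th2, 100, 5, 3),
                 tolerance = 1e-12)
  }
})

test_that("gap removal drops identical sample indices from both series", {
  a <- ramp(4.5, dur = 30); b <- ramp(3.0, dur = 30)
  g <- gap_set(data.frame(start = 10, end = 14))
  red <- apply_gap_removal(a, b, g)
  expect_equal(length(a$theta) - length(red$a$theta), 400)
  expect_equal(length(red$a$theta), length(red$b$theta))
  # empty gap set is the identity
  red0 <- apply_gap_removal(a, b, gap_set())
  expect_equal(red0$a$theta, a$theta)
  # gaps below the removal rule are kept
  red_short <- apply_gap_removal(a, b, gap_set(data.frame(start = 10, end = 12),
                                               min_len = 2), min_gap = 3)
  expect_equal(length(red_short$a$theta), length(a$theta))
})

test_that("phase-level removal is not equivalent to envelope-level removal", {
  # regression guard: cutting the envelope before phase extraction distorts
  # the phase at the splice; the pipeline removes at the phase level only
  rate <- 100
  t <- seq(0, 30, by = 1 / rate)
  e1 <- sin(2 * pi * 4.5 * t)
  e2 <- sin(2 * pi * 4.5 * t + 0.9) + 0.3 * sin(2 * pi * 3.7 * t)
  keep <- !(t >= 10 & t < 14)
  mk <- function(v, d) envelope_series(v, rate, band = c(3.3, 5.7),
                                       source_duration = d)
  phase_removal <- {
    p1 <- instantaneous_phase(mk(e1, 30)); p2 <- instantaneous_phase(mk(e2, 30))
    plv(phase_series(p1$theta[keep], rate), phase_series(p2$theta[keep], rate))
  }
  envelope_removal <- {
    q1 <- instantaneous_phase(mk(e1[keep], sum(keep) / rate))
    q2 <- instantaneous_phase(mk(e2[keep], sum(keep) / rate))
    plv(q1, q2)
  }
  expect_false(isTRUE(all.equal(phase_removal, envelope_removal,
                                tolerance = 1e-6)))
})

test_that("segmented PLV applies the 50% NaN rule and length weighting", {
  spec <- default_segment_spec()
  n <- round(spec$total_duration * 100)
  a <- phase_series(2 * pi * 4.5 * (0:(n - 1)) / 100, 100)
  rep0 <- segmented_plv(a, a, spec)
  expect_equal(rep0$segment_values, rep(1, 5))
  expect_equal(rep0$weighted_mean, 1.0)
  # 8 s gap inside segment 1 (13.95 s) leaves 43% < 50% -> NaN
  g <- gap_set(data.frame(start = 3, end = 11))
  rep1 <- segmented_plv(a, a, spec, g)
  expect_true(is.nan(rep1$segment_values[1]))
  expect_equal(rep1$segment_values[2:5], rep(1, 4))
  expect_equal(rep1$weighted_mean, 1.0)  # NaN excluded, not poisoning
  # all-NaN propagates a NaN weighted mean
  gall <- gap_set(data.frame(start = 0, end = spec$total_duration))
  expect_true(is.nan(segmented_plv(a, a, spec, gall)$weighted_mean))
  # mismatched duration is rejected
  short <- phase_series(a$theta[1:2000], 100)
  expect_error(segmented_plv(short, short, spec), "duration")
})

test_that("a lagged 1:1 producer keeps all five segment PLVs high", {
  prep <- get_full_prep()
  sim <- simulate_participant(
    participant_sim_config(mode = "1:1", lag_ms = 60, seed = 23),
    prep$timeline)
  env <- env_bandpass(extract_envelope(remove_leakage(sim$audio), 100))
  ph <- instantaneous_phase(env)
  n <- min(length(ph$theta), length(prep$phase$theta))
  rep <- segmented_plv(phase_series(prep$phase$theta[1:n], 100),
                       phase_series(ph$theta[1:n], 100), prep$spec)
  expect_true(all(rep$segment_values > 0.9))
})
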