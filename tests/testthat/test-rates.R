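test_that("the candidate grid and reference phases are as specified", {
  g <- rate_grid()
  expect_length(g, 81)
  expect_equal(range(g), c(1, 5))
  expect_equal(unique(round(diff(g), 10)), 0.05)
  rp <- reference_phase(1, 10, 100)
  expect_equal(rp$theta[length(rp$theta)] - rp$theta[1], 2 * pi * 10)
  expect_error(reference_phase(60, 10, 100), "rate/2")
})

test_that("isochronous pulse trains are recovered within one grid step everywhere", {
  # from ~1.3 Hz up; below that the 1 Hz band edge attenuates the
  # fundamental while its harmonics stay inside the 1-5 Hz analysis band,
  # a documented limitation of the PLV-matching estimator
  spec <- default_segment_spec()
  for (f in c(1.3, 1.5, 2.25, 3.0, 4.5)) {
    env <- pulse_envelope(f, spec$total_duration)
    est <- estimate_rates(env, spec)
    expect_equal(est$per_segment$freq, rep(f, 5), tolerance = 0.051,
                 label = sprintf("recovered rates at %.2f Hz", f))
    expect_equal(est$articulation_rate, f, tolerance = 0.051)
    # weighted-mean property: bounded by the per-segment extremes
    expect_gte(est$articulation_rate, min(est$per_segment$freq) - 1e-9)
    expect_lte(est$articulation_rate, max(est$per_segment$freq) + 1e-9)
  }
})

test_that("a fully gap-removed segment returns NaN with zero phonation", {
  env <- pulse_envelope(3, 30)
  res <- estimate_segment_rate(env, c(5, 10),
                               gap_set(data.frame(start = 4, end = 11),
                                       min_len = 1.5))
  expect_true(is.nan(res$freq))
  expect_equal(res$phonation_time, 0)
})

test_that("phonation time excludes only gaps of at least 1.5 s", {
  env <- pulse_envelope(3, 30)
  gaps <- gap_set(data.frame(start = c(5, 20), end = c(6, 24)), min_len = 1)
  res <- estimate_segment_rate(env, c(0, 30), gaps)
  # the 1 s gap is kept as phonation; the 4 s gap is removed
  expect_equal(res$phonation_time, 26, tolerance = 0.1)
})

test_that("the articulation rate is the phonation-weighted segment mean", {
  mk <- function(freq, phon) {
    structure(list(per_segment = data.frame(
      freq = freq, match_plv = rep(0.9, length(freq)), phonation_time = phon),
      articulation_rate = NA_real_), class = "rate_estimate")
  }
  expect_equal(articulation_rate(mk(rep(2.25, 5), rep(10, 5))), 2.25)
  spec <- default_segment_spec()
  seg_len <- diff(c(0, spec$boundaries))
  # oracle: printed rates weighted by printed segment lengths
  by_hand <- sum(spec$segments$rate * seg_len) / sum(seg_len)
  expect_equal(articulation_rate(mk(spec$segments$rate, seg_len)), by_hand)
  expect_equal(by_hand, 4.53, tolerance = 0.005)
  # NaN segments are excluded from the weighting
  est_nan <- mk(c(NaN, 4.4, 4.5, 4.6, 4.7), seg_len)
  expect_equal(articulation_rate(est_nan),
               sum(c(4.4, 4.5, 4.6, 4.7) * seg_len[2:5]) / sum(seg_len[2:5]))
  expect_warning(r <- articulation_rate(mk(rep(NaN, 5), rep(0, 5))), "NaN")
  expect_true(is.nan(r))
})

test_that("subharmonic producers are flagged with the right subdivision", {
  spec <- default_segment_spec()
  mk <- function(freq) {
    structure(list(per_segment = data.frame(
      freq = freq, match_plv = rep(0.9, 5),
      phonation_time = diff(c(0, spec$boundaries))),
      articulation_rate = NA_real_), class = "rate_estimate")
  }
  f2 <- detect_subharmonic(mk(spec$segments$rate / 2), spec)
  expect_true(f2$is_subharmonic)
  expect_equal(f2$m, 2L)
  expect_equal(f2$segments_flagged, 1:5)
  f3 <- detect_subharmonic(mk(spec$segments$rate / 3), spec)
  expect_equal(f3$m, 3L)
  f1 <- detect_subharmonic(mk(spec$segments$rate), spec)
  expect_false(f1$is_subharmonic)
  expect_true(is.na(f1$m))
  # fewer than 3 agreeing segments is not enough
  fmix <- detect_subharmonic(mk(c(2.15, 2.2, 4.5, 4.6, 4.7)), spec)
  expect_false(fmix$is_subharmonic)
})

test_that("moderate jitter moves the 1:1 rate estimate by at most 0.1 Hz", {
  prep <- get_short_prep()
  est <- lapply(c(0, 15), function(j) {
    sim <- simulate_participant(
      participant_sim_config(mode = "1:1", jitter_sd_ms = j, seed = 31),
      prep$timeline)
    env <- extract_envelope(remove_leakage(sim$audio), 100)
    estimate_rates(env, prep$spec)
  })
  expect_lte(max(abs(est[[1]]$per_segment$freq - est[[2]]$per_segment$freq)),
             0.1 + 1e-9)
  # mode-locked simulations never exceed the stimulus rate by more than 0.1 Hz
  for (e in est)
    expect_true(all(e$per_segment$freq <= prep$spec$segments$rate + 0.1))
})
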