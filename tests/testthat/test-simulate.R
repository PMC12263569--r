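test_that("subharmonic and lagged modes place the expected onsets", {
  tl <- build_timeline(default_segment_spec())
  sim2 <- simulate_participant(
    participant_sim_config(mode = "1:2", seed = 1), tl)
  expect_equal(length(sim2$truth$produced_onsets), ceiling(363 / 2))
  expect_equal(sim2$truth$true_rate_per_segment,
               c(4.3, 4.4, 4.5, 4.6, 4.7) / 2)

  sim1 <- simulate_participant(
    participant_sim_config(mode = "1:1", lag_ms = 60, seed = 1), tl)
  # pure shift; onsets very near the end are clipped from the rendering
  n <- length(sim1$truth$produced_onsets)
  expect_equal(sim1$truth$produced_onsets, (tl$onsets + 0.060)[seq_len(n)])
  expect_gte(n, 362L)

  simf <- simulate_participant(
    participant_sim_config(mode = "free", free_rate = 2, seed = 1), tl)
  expect_equal(simf$truth$true_rate_per_segment, rep(2, 5))
  expect_equal(diff(simf$truth$produced_onsets),
               rep(0.5, length(simf$truth$produced_onsets) - 1))
})

test_that("identical configurations give byte-identical WAV output", {
  tl <- build_timeline(short_spec())
  cfg <- participant_sim_config(mode = "1:2", jitter_sd_ms = 10,
                                lag_ms = 40, seed = 42)
  a1 <- simulate_participant(cfg, tl)$audio
  a2 <- simulate_participant(cfg, tl)$audio
  f1 <- withr::local_tempfile(fileext = ".wav")
  f2 <- withr::local_tempfile(fileext = ".wav")
  write_wav(a1, f1); write_wav(a2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("jitter is truncated so onsets stay ordered", {
  tl <- build_timeline(default_segment_spec())
  sim <- simulate_participant(
    participant_sim_config(mode = "1:1", jitter_sd_ms = 20, seed = 5), tl)
  expect_false(is.unsorted(sim$truth$produced_onsets))
  # each produced onset stays within 3 SD of its nearest stimulus onset
  # (events jittered before t = 0 are dropped, so match by proximity)
  jit <- vapply(sim$truth$produced_onsets,
                function(o) min(abs(o - tl$onsets)), numeric(1))
  expect_true(all(jit <= 3 * 0.020 + 1e-9))
})

test_that("breathing gaps delete onsets and are found by the gap detector", {
  tl <- build_timeline(default_segment_spec())
  sim <- simulate_participant(participant_sim_config(mode = "1:1", seed = 2), tl)
  gt4 <- inject_breathing_gaps(sim$truth, list(c(20, 4)))
  expect_true(all(gt4$produced_onsets < 20 | gt4$produced_onsets >= 24))
  g <- detect_gaps(gt4$produced_onsets, tl$total_duration, min_gap = 3)
  expect_equal(nrow(g$intervals), 1L)
  expect_equal(g$intervals$end - g$intervals$start, 4, tolerance = 0.5)

  gt2 <- inject_breathing_gaps(sim$truth, list(c(20, 2)))
  expect_equal(nrow(detect_gaps(gt2$produced_onsets, tl$total_duration,
                                min_gap = 3)$intervals), 0L)
  # the short-gap refinement picks it up
  expect_equal(nrow(detect_gaps(gt2$produced_onsets, tl$total_duration,
                                min_gap = 1.5)$intervals), 1L)

  expect_identical(inject_breathing_gaps(sim$truth, list()), sim$truth)
})

test_that("simulated gaps produce silent audio inside the gap interval", {
  tl <- build_timeline(short_spec())
  sim <- simulate_participant(
    participant_sim_config(mode = "1:1", gaps = list(c(10, 4)), seed = 3), tl)
  sr <- sim$audio$sample_rate
  inside <- sim$audio$samples[round(10.2 * sr):round(13.8 * sr)]
  expect_lt(max(abs(inside)), 1e-6)
})

test_that("leakage is removed by the bandstop while whisper energy survives", {
  tl <- build_timeline(short_spec())
  sim <- simulate_participant(
    participant_sim_config(mode = "1:1", leakage_gain = 0.1, seed = 8), tl)
  post <- remove_leakage(sim$audio)
  sr <- sim$audio$sample_rate
  binpow <- function(x, f) {
    n <- length(x); X <- Mod(stats::fft(x))^2
    k <- round(f * n / sr) + 1
    sum(X[(k - 2):(k + 2)])
  }
  # 200 Hz leakage fundamental down by >= 40 dB
  drop200 <- 10 * log10(binpow(post$samples, 200) / binpow(sim$audio$samples, 200))
  expect_lt(drop200, -40)
  # whisper band (> 3.5 kHz) changes by < 1 dB
  bandpow <- function(x) {
    n <- length(x); X <- Mod(stats::fft(x))^2
    f <- (seq_len(n) - 1) * sr / n
    sum(X[f > 3500 & f < 7000])
  }
  change <- 10 * log10(bandpow(post$samples) / bandpow(sim$audio$samples))
  expect_lt(abs(change), 1)
})

test_that("simulation configs are validated", {
  expect_error(participant_sim_config(mode = "1:4"), "mode")
  expect_error(participant_sim_config(mode = "free"), "free_rate")
  expect_error(participant_sim_config(jitter_sd_ms = -1), "jitter")
  expect_error(participant_sim_config(gaps = list(c(5, 3), c(6, 3))),
               "non-overlapping")
  tl <- build_timeline(short_spec())
  bad <- participant_sim_config(
    mode = "1:1", mode_switch = data.frame(time = 999, mode = "1:2"))
  expect_error(simulate_participant(bad, tl), "inside the timeline")
})
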