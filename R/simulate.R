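# Simulated participants: whisper-like /ta/ productions with a controlled
# synchronization mode, response lag, onset jitter, breathing gaps and
# optional stimulus leakage. The simulator is what makes every downstream
# claim testable without data collection.

#' Configuration for a simulated participant
#'
#' @param mode `"1:1"` (every stimulus syllable), `"1:2"` / `"1:3"` (every
#'   second / third syllable: subharmonic production), or `"free"`
#'   (self-paced at `free_rate`, ignoring the stimulus).
#' @param free_rate production rate in Hz for `mode = "free"`.
#' @param mode_switch optional data.frame with columns `time` (s) and
#'   `mode`; the mode in force changes at each listed time. Overrides
#'   `mode` from the first listed time onward.
#' @param lag_ms constant response lag in milliseconds.
#' @param jitter_sd_ms SD of Gaussian onset jitter in ms, truncated at
#'   +/- 3 SD so onsets stay ordered.
#' @param gaps list of `c(start, duration)` silent (breathing) intervals in
#'   seconds; must be non-overlapping.
#' @param leakage_gain linear gain of the rendered stimulus mixed into the
#'   recording (0 = no leakage).
#' @param voiced_gain optional gain of a 150-300 Hz harmonic series across
#'   the whole recording, for testing manual exclusion of voiced speech.
#' @param seed integer RNG seed; identical configs give byte-identical audio.
#' @return an object of class `participant_sim_config`.
#' @export
participant_sim_config <- function(mode = "1:1", free_rate = NULL,
                                   mode_switch = NULL,
                                   lag_ms = 0, jitter_sd_ms = 0,
                                   gaps = list(), leakage_gain = 0,
                                   voiced_gain = 0, seed = 1L) {
  if (!mode %in% c("1:1", "1:2", "1:3", "free"))
    stop("mode must be one of \"1:1\", \"1:2\", \"1:3\", \"free\"")
  if (mode == "free" && (is.null(free_rate) || free_rate <= 0))
    stop("free mode requires a positive free_rate")
  if (jitter_sd_ms < 0) stop("jitter_sd_ms must be >= 0")
  if (leakage_gain < 0) stop("leakage_gain must be >= 0")
  if (length(gaps)) {
    m <- do.call(rbind, lapply(gaps, function(g) c(g[1], g[1] + g[2])))
    m <- m[order(m[, 1]), , drop = FALSE]
    if (any(m[, 2] <= m[, 1]) ||
        (nrow(m) > 1 && any(m[-1, 1] < m[-nrow(m), 2])))
      stop("gaps must be valid, non-overlapping intervals")
  }
  structure(list(mode = mode, free_rate = free_rate, mode_switch = mode_switch,
                 lag_ms = lag_ms, jitter_sd_ms = jitter_sd_ms, gaps = gaps,
                 leakage_gain = leakage_gain, voiced_gain = voiced_gain,
                 seed = as.integer(seed)),
            class = "participant_sim_config")
}

mode_subdivision <- function(mode) switch(mode, "1:1" = 1L, "1:2" = 2L,
                                          "1:3" = 3L, NA_integer_)

# intended production onsets (before lag/jitter/gaps) for one mode over a
# time window of the timeline
intended_onsets <- function(mode, free_rate, timeline, from, to) {
  if (mode == "free") {
    on <- seq(from, to, by = 1 / free_rate)
  } else {
    m <- mode_subdivision(mode)
    sel <- timeline$onsets[seq(1L, length(timeline$onsets), by = m)]
    on <- sel[sel >= from & sel < to]
  }
  on
}

#' Simulate a whispering participant
#'
#' Places a whisper-like /ta/ burst (a sharp 3-7 kHz noise transient with a
#' breathy decay; no fundamental, as whispered speech has none) at every
#' m-th stimulus onset (or on a free-running grid), shifted by the response
#' lag plus truncated Gaussian jitter. Events inside silent gaps are
#' deleted. Per-burst gain is drawn uniformly from \[0.7, 1\] to emulate the
#' low but variable intensity of whispering. Optional stimulus leakage (with
#' its 200 Hz fundamental) is mixed in.
#'
#' @param config a [participant_sim_config()].
#' @param timeline a [build_timeline()] result.
#' @param sample_rate output rate in Hz (default 16000).
#' @return list with `audio` (an [audio_signal()]) and `truth` (class
#'   `sim_ground_truth`: `produced_onsets`, `true_rate_per_segment`,
#'   `gap_intervals`, `mode`).
#' @export
simulate_participant <- function(config, timeline, sample_rate = 16000) {
  stopifnot(inherits(config, "participant_sim_config"),
            inherits(timeline, "syllable_timeline"))
  sr <- sample_rate
  total <- timeline$total_duration

  # resolve mode schedule
  sched <- data.frame(time = 0, mode = config$mode,
                      stringsAsFactors = FALSE)
  if (!is.null(config$mode_switch) && nrow(config$mode_switch)) {
    ms <- config$mode_switch
    if (any(ms$time < 0 | ms$time > total))
      stop("mode_switch times must lie inside the timeline")
    ms <- ms[order(ms$time), , drop = FALSE]
    if (ms$time[1] > 0)
      sched <- rbind(sched, ms)
    else
      sched <- ms
  }
  ends <- c(sched$time[-1], total)
  onsets <- numeric(0)
  for (i in seq_len(nrow(sched)))
    onsets <- c(onsets,
                intended_onsets(sched$mode[i], config$free_rate, timeline,
                                sched$time[i], ends[i]))

  with_local_seed(config$seed, {
    # lag + truncated jitter
    if (config$jitter_sd_ms > 0) {
      u <- stats::runif(length(onsets), stats::pnorm(-3), stats::pnorm(3))
      jit <- stats::qnorm(u) * config$jitter_sd_ms / 1000
    } else jit <- numeric(length(onsets))
    onsets <- sort(onsets + config$lag_ms / 1000 + jit)

    # delete events inside gaps
    gap_iv <- if (length(config$gaps))
      do.call(rbind, lapply(config$gaps, function(g) c(g[1], g[1] + g[2])))
    else matrix(numeric(0), ncol = 2)
    if (nrow(gap_iv)) {
      in_gap <- rep(FALSE, length(onsets))
      for (i in seq_len(nrow(gap_iv)))
        in_gap <- in_gap | (onsets >= gap_iv[i, 1] & onsets < gap_iv[i, 2])
      onsets <- onsets[!in_gap]
    }
    onsets <- onsets[onsets >= 0 & onsets <= total - 0.02]

    n <- round(total * sr)
    x <- numeric(n)
    gains <- stats::runif(length(onsets), 0.7, 1.0)
    for (i in seq_along(onsets)) {
      b <- whisper_burst(sr) * gains[i]
      i0 <- round(onsets[i] * sr) + 1L
      i1 <- min(n, i0 + length(b) - 1L)
      if (i0 <= n) x[i0:i1] <- x[i0:i1] + b[seq_len(i1 - i0 + 1L)]
    }
  })

  if (config$leakage_gain > 0) {
    stim <- render_stimulus(timeline, sr)
    m <- min(length(x), length(stim$samples))
    x[seq_len(m)] <- x[seq_len(m)] +
      config$leakage_gain * stim$samples[seq_len(m)]
  }
  if (config$voiced_gain > 0) {
    tt <- (seq_along(x) - 1) / sr
    for (f in c(150, 200, 250, 300))
      x <- x + config$voiced_gain / 4 * sin(2 * pi * f * tt)
  }

  m <- mode_subdivision(sched$mode[nrow(sched)])
  true_rate <- if (!is.na(m)) timeline$segment_rates / m
               else rep(config$free_rate, length(timeline$segment_rates))
  truth <- structure(
    list(produced_onsets = onsets, true_rate_per_segment = true_rate,
         gap_intervals = gap_iv, mode = config$mode),
    class = "sim_ground_truth")
  list(audio = audio_signal(x, sr, label = sprintf("sim %s", config$mode)),
       truth = truth)
}

# whisper /ta/ template: 15 ms sharp 3-7 kHz noise transient + ~80 ms breathy
# decay; drawn from the active RNG stream (per-burst variation)
whisper_burst <- function(sr) {
  n <- round(0.095 * sr)
  noise <- stats::rnorm(n)
  top <- min(7000, 0.45 * sr)
  bp <- signal::butter(4, c(3000, top) / (sr / 2), "pass")
  v <- signal::filtfilt(bp, c(noise, numeric(64)))[seq_len(n)]
  attack_n <- round(0.015 * sr)
  env <- c(rep(1, attack_n),
           0.35 * exp(-(seq_len(n - attack_n)) / (0.030 * sr)))
  v <- v * env
  v / max(abs(v))
}

#' Remove onsets inside breathing-gap intervals from a ground truth
#'
#' @param gt a `sim_ground_truth` from [simulate_participant()].
#' @param schedule list of `c(start, duration)` intervals in seconds.
#' @return the ground truth with the onsets removed and `gap_intervals`
#'   extended.
#' @export
inject_breathing_gaps <- function(gt, schedule) {
  stopifnot(inherits(gt, "sim_ground_truth"))
  if (!length(schedule)) return(gt)
  iv <- do.call(rbind, lapply(schedule, function(g) {
    if (g[2] <= 0) stop("gap duration must be positive")
    c(g[1], g[1] + g[2])
  }))
  keep <- rep(TRUE, length(gt$produced_onsets))
  for (i in seq_len(nrow(iv)))
    keep <- keep & !(gt$produced_onsets >= iv[i, 1] &
                     gt$produced_onsets < iv[i, 2])
  gt$produced_onsets <- gt$produced_onsets[keep]
  gt$gap_intervals <- rbind(gt$gap_intervals, iv)
  gt
}

#' Write a simulation ground truth as a JSON sidecar
#' @param gt a `sim_ground_truth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(gt, path) {
  jsonlite::write_json(
    list(produced_onsets = gt$produced_onsets,
         true_rate_per_segment = gt$true_rate_per_segment,
         gap_intervals = as.data.frame(gt$gap_intervals),
         mode = gt$mode),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
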