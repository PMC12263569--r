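# End-to-end orchestration: leakage filter -> envelope -> rhythm bandpass ->
# phase -> gap detection -> phase-level gap removal -> moving + segmented
# PLV -> rate estimation -> classification.

#' Analysis configuration with the pipeline's defaults
#'
#' Every default mirrors the analysis constants: moving window 5 s with 3 s
#' overlap; rhythm band 3.3-5.7 Hz (5th-order Butterworth); leakage stopband
#' edge 3 kHz (Chebyshev II, order 6, 40 dB); silent-gap rule 3 s; phonation
#' gap rule 1.5 s; rate grid 1-5 Hz in 0.05 Hz steps; the printed
#' classification thresholds.
#'
#' @param env_rate envelope rate in Hz.
#' @param band rhythm passband `c(low, high)` in Hz.
#' @param band_order Butterworth prototype order.
#' @param win,overlap moving-window parameters in seconds.
#' @param min_gap silent-gap rule in seconds.
#' @param min_gap_phonation phonation-time gap rule in seconds.
#' @param remove_short_gaps also remove gaps >= `min_gap_phonation` (the
#'   optional short-gap refinement; default `FALSE`).
#' @param leak_stop_hz,leak_order,leak_atten_db leakage filter parameters.
#' @param rate_win,rate_overlap rate-matching window parameters in seconds.
#' @param thresholds classification thresholds ([plv_thresholds()]).
#' @param second_run_only treat run 1 as a test run and classify on run 2
#'   alone (alternative consistency strategy).
#' @param seed integer seed for any stochastic step.
#' @return a `run_config` list.
#' @export
run_config <- function(env_rate = 100, band = c(3.3, 5.7), band_order = 5,
                       win = 5, overlap = 3, min_gap = 3,
                       min_gap_phonation = 1.5, remove_short_gaps = FALSE,
                       leak_stop_hz = 3000, leak_order = 6, leak_atten_db = 40,
                       rate_win = 2, rate_overlap = 1,
                       thresholds = plv_thresholds(),
                       second_run_only = FALSE, seed = 1L) {
  structure(list(env_rate = env_rate, band = band, band_order = band_order,
                 win = win, overlap = overlap, min_gap = min_gap,
                 min_gap_phonation = min_gap_phonation,
                 remove_short_gaps = remove_short_gaps,
                 leak_stop_hz = leak_stop_hz, leak_order = leak_order,
                 leak_atten_db = leak_atten_db,
                 rate_win = rate_win, rate_overlap = rate_overlap,
                 thresholds = thresholds, second_run_only = second_run_only,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Prepare the stimulus side of the analysis once per configuration
#'
#' @param config a [run_config()].
#' @param spec a [segment_spec()] (default the printed five segments).
#' @param sample_rate stimulus rendering rate in Hz.
#' @return list with the rendered stimulus audio, its broadband envelope,
#'   the band-limited envelope and its phase, the timeline and the spec.
#' @export
prepare_stimulus <- function(config, spec = default_segment_spec(),
                             sample_rate = 16000) {
  timeline <- build_timeline(spec)
  audio <- render_stimulus(timeline, sample_rate)
  env <- extract_envelope(audio, config$env_rate)
  env_bp <- env_bandpass(env, config$band[1], config$band[2],
                         order = config$band_order)
  list(audio = audio, env = env, env_bp = env_bp,
       phase = instantaneous_phase(env_bp), timeline = timeline, spec = spec)
}

#' Analyze one participant run against the stimulus
#'
#' @param config a [run_config()].
#' @param recording the participant [audio_signal()] (its duration must
#'   agree with the stimulus within 1 s).
#' @param stim a [prepare_stimulus()] result.
#' @param manual_exclusions optional data.frame of `start`/`end` intervals
#'   to remove (voiced stretches, undetected gaps).
#' @param id participant/run identifier carried into reports.
#' @return an `analysis_entry`: moving and segmented [plv_report]s, the
#'   rate estimate, subharmonic flag, run classification, gap summary,
#'   spoken rate, and the legacy criteria that would have fired.
#' @export
analyze_run <- function(config, recording, stim, manual_exclusions = NULL,
                        id = recording$label) {
  stopifnot(inherits(config, "run_config"), inherits(recording, "audio_signal"))
  if (abs(duration(recording) - duration(stim$audio)) > 1)
    stop("stimulus and recording durations differ by more than 1 s")

  clean <- remove_leakage(recording, stop_hz = config$leak_stop_hz,
                          attenuation_db = config$leak_atten_db,
                          order = config$leak_order)
  track <- pick_onsets(onset_strength(clean))
  gaps <- detect_gaps(track$onsets, duration(clean),
                      min_gap = if (config$remove_short_gaps)
                        config$min_gap_phonation else config$min_gap)
  if (!is.null(manual_exclusions))
    gaps <- merge_manual_exclusions(gaps, manual_exclusions)

  env <- extract_envelope(clean, config$env_rate)
  env_bp <- env_bandpass(env, config$band[1], config$band[2],
                         order = config$band_order)
  phase <- instantaneous_phase(env_bp)

  n <- min(length(phase$theta), length(stim$phase$theta))
  p_part <- phase_series(phase$theta[seq_len(n)], phase$rate)
  p_stim <- phase_series(stim$phase$theta[seq_len(n)], stim$phase$rate)

  reduced <- apply_gap_removal(p_stim, p_part, gaps, min_gap = config$min_gap)
  moving <- moving_window_plv(reduced$a, reduced$b,
                              win = config$win, overlap = config$overlap)
  segmented <- segmented_plv(p_stim, p_part, stim$spec, gaps,
                             min_gap = config$min_gap)

  rates <- estimate_rates(env, stim$spec, gaps,
                          win = config$rate_win, overlap = config$rate_overlap)
  subharm <- detect_subharmonic(rates, stim$spec)

  scalar <- moving$scalar
  classification <- if (all(is.nan(segmented$segment_values)))
    structure(list(plv = scalar, label = "unreliable"),
              class = "run_classification")
  else classify_run(scalar, config$thresholds)

  spoken_rate <- length(track$onsets) / duration(clean)
  legacy <- legacy_exclusions(list(plv = scalar, spoken_rate = spoken_rate,
                                   gaps = gaps))
  structure(list(id = id, moving = moving, segmented = segmented,
                 rates = rates, subharmonic = subharm,
                 classification = classification, gaps = gaps,
                 onsets = track$onsets, spoken_rate = spoken_rate,
                 legacy_criteria = legacy, leakage_filtered = TRUE),
            class = "analysis_entry")
}

#' Summarize a set of analyzed runs into a cohort table
#'
#' @param entries list of `analysis_entry` objects.
#' @param breaks histogram breaks over \[0, 1\] for the PLV distribution.
#' @return list with `table` (one row per entry) and `histogram`
#'   (data.frame of bin mid-points and counts of the moving-window PLVs).
#' @export
cohort_report <- function(entries, breaks = seq(0, 1, by = 0.05)) {
  if (!length(entries)) stop("need at least one entry")
  rows <- lapply(entries, function(e) {
    data.frame(id = e$id,
               plv_moving = e$moving$scalar,
               plv_segmented = e$segmented$weighted_mean,
               articulation_rate = e$rates$articulation_rate,
               label = e$classification$label,
               is_subharmonic = e$subharmonic$is_subharmonic,
               subharmonic_m = e$subharmonic$m,
               n_gaps = nrow(e$gaps$intervals),
               gap_time = gap_total(e$gaps),
               legacy_criteria = paste(e$legacy_criteria, collapse = ";"))
  })
  tab <- do.call(rbind, rows)
  h <- graphics::hist(pmin(pmax(tab$plv_moving, 0), 1), breaks = breaks,
                      plot = FALSE)
  list(table = tab,
       histogram = data.frame(mid = h$mids, count = h$counts))
}

#' Write an analysis entry as JSON
#' @param entry an `analysis_entry`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_analysis_entry <- function(entry, path) {
  jsonlite::write_json(
    list(id = entry$id,
         plv_moving = entry$moving$scalar,
         plv_windows = entry$moving$windows,
         plv_segments = entry$segmented$segment_values,
         plv_segmented_weighted = entry$segmented$weighted_mean,
         rates = entry$rates$per_segment,
         articulation_rate = entry$rates$articulation_rate,
         subharmonic = entry$subharmonic[c("is_subharmonic", "m")],
         label = entry$classification$label,
         gaps = entry$gaps$intervals,
         spoken_rate = entry$spoken_rate,
         legacy_criteria = entry$legacy_criteria),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
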