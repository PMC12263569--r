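# Syllable and articulation rate estimation. Modulation-spectrum peak
# picking is unreliable per segment, so the PLV is repurposed as a
# similarity metric: the participant envelope (1-5 Hz filtered, silent gaps
# >= 1.5 s removed to approximate phonation time) is compared per segment
# against reference phases for a 1-5 Hz candidate grid in 0.05 Hz steps,
# with small overlapping windows; the argmax frequency is the estimate. A
# second pass re-filters in a narrower band (1-3.3 or 2.7-5 Hz) around the
# first-pass estimate. The articulation rate is the phonation-time-weighted
# mean of the per-segment estimates.

#' Reference phase for a candidate syllable rate
#'
#' @param freq candidate frequency in Hz (must be below `rate`/2).
#' @param dur duration in seconds.
#' @param rate sampling rate in Hz.
#' @return a [phase_series()] whose theta is the unwrapped phase of a unit
#'   sinusoid at `freq`.
#' @export
reference_phase <- function(freq, dur, rate) {
  if (freq <= 0 || freq >= rate / 2)
    stop("freq must lie in (0, rate/2)")
  t <- seq(0, dur, by = 1 / rate)
  phase_series(2 * pi * freq * t, rate)
}

#' The candidate syllable-rate grid (1-5 Hz in 0.05 Hz steps)
#' @return numeric vector of 81 candidate frequencies in Hz.
#' @export
rate_grid <- function() seq(1, 5, by = 0.05)

# mean windowed PLV between an envelope phase (at retained real times
# t_keep) and a pure frequency reference, windows win/overlap seconds on the
# concatenated retained samples
match_plv <- function(theta_env, t_keep, freq, rate, win = 2, overlap = 1) {
  d <- exp(1i * (theta_env - 2 * pi * freq * t_keep))
  N <- length(d)
  nwin <- round(win * rate)
  nstep <- round((win - overlap) * rate)
  if (N < nwin) return(Mod(mean(d)))
  starts <- seq.int(1L, N - nwin + 1L, by = nstep)
  mean(vapply(starts, function(s) Mod(mean(d[s:(s + nwin - 1L)])), numeric(1)))
}

#' Estimate the dominant syllable rate of one stimulus segment
#'
#' Two-pass PLV-matching estimate on the broadband envelope: pass 1 filters
#' 1-5 Hz and scans the full 81-candidate grid; pass 2 re-filters in 1-3.3 Hz
#' (if the first-pass estimate is below 3 Hz) or 2.7-5 Hz (otherwise) and
#' re-scans the grid restricted to that band. Matching uses windows of
#' `win` s with `overlap` s overlap over the gap-removed segment samples.
#' Ties on the grid resolve to the lowest frequency, so harmonic aliases of
#' a slower production cannot win.
#'
#' @param env broadband [envelope_series()] of the whole recording.
#' @param segment_window `c(start, end)` of the segment in seconds.
#' @param gaps a [gap_set()]; gaps of at least `min_gap_phonation` s are
#'   removed to approximate phonation time.
#' @param min_gap_phonation minimum gap length counted as non-phonation
#'   (default 1.5 s).
#' @param win,overlap matching window length and overlap in seconds.
#' @return list `freq` (Hz, NaN if the segment is fully removed),
#'   `match_plv`, `phonation_time` (s).
#' @export
estimate_segment_rate <- function(env, segment_window, gaps = gap_set(),
                                  min_gap_phonation = 1.5,
                                  win = 2, overlap = 1) {
  stopifnot(inherits(env, "envelope_series"))
  phases <- rate_estimation_phases(env)
  estimate_segment_rate_impl(phases, env$rate, segment_window, gaps,
                             min_gap_phonation, win, overlap)
}

# pre-filter the three band variants once per recording
rate_estimation_phases <- function(env) {
  list(wide = instantaneous_phase(env_bandpass(env, 1, 5)),
       low = instantaneous_phase(env_bandpass(env, 1, 3.3)),
       high = instantaneous_phase(env_bandpass(env, 2.7, 5)))
}

estimate_segment_rate_impl <- function(phases, rate, segment_window, gaps,
                                       min_gap_phonation = 1.5,
                                       win = 2, overlap = 1) {
  N <- length(phases$wide$theta)
  t <- (seq_len(N) - 1L) / rate
  in_seg <- t >= segment_window[1] & t < segment_window[2]
  drop <- gap_mask(gaps, t, min_len = min_gap_phonation)
  keep <- in_seg & !drop
  seg_len <- segment_window[2] - segment_window[1]
  phonation <- sum(keep) / rate
  if (!any(keep))
    return(list(freq = NaN, match_plv = NaN, phonation_time = 0))
  t_keep <- t[keep]
  grid <- rate_grid()

  scan <- function(theta, candidates) {
    pl <- vapply(candidates, function(f)
      match_plv(theta[keep], t_keep, f, rate, win, overlap), numeric(1))
    list(freq = candidates[which.max(pl)], plv = max(pl))
  }
  pass1 <- scan(phases$wide$theta, grid)
  band <- if (pass1$freq < 3) c(1, 3.3) else c(2.7, 5)
  theta2 <- if (pass1$freq < 3) phases$low$theta else phases$high$theta
  pass2 <- scan(theta2, grid[grid >= band[1] & grid <= band[2]])
  list(freq = pass2$freq, match_plv = pass2$plv,
       phonation_time = min(phonation, seg_len))
}

#' Estimate per-segment rates and the overall articulation rate
#'
#' @param env broadband [envelope_series()] of the recording.
#' @param spec a [segment_spec()] providing the segment boundaries.
#' @param gaps a [gap_set()] (gaps >= 1.5 s approximate non-phonation time).
#' @param win,overlap matching-window parameters in seconds.
#' @return an object of class `rate_estimate`: `per_segment` (data.frame
#'   with `freq`, `match_plv`, `phonation_time`) and `articulation_rate`
#'   (Hz, phonation-time-weighted mean of non-NaN segment rates).
#' @export
estimate_rates <- function(env, spec, gaps = gap_set(), win = 2, overlap = 1) {
  stopifnot(inherits(spec, "segment_spec"))
  phases <- rate_estimation_phases(env)
  bounds <- c(0, spec$boundaries)
  res <- lapply(seq_along(spec$boundaries), function(k)
    estimate_segment_rate_impl(phases, env$rate,
                               c(bounds[k], bounds[k + 1]), gaps,
                               win = win, overlap = overlap))
  per_segment <- data.frame(
    freq = vapply(res, `[[`, numeric(1), "freq"),
    match_plv = vapply(res, `[[`, numeric(1), "match_plv"),
    phonation_time = vapply(res, `[[`, numeric(1), "phonation_time"))
  est <- structure(list(per_segment = per_segment,
                        articulation_rate = NA_real_),
                   class = "rate_estimate")
  est$articulation_rate <- articulation_rate(est)
  est
}

#' Phonation-time-weighted articulation rate
#'
#' @param est a `rate_estimate` (see [estimate_rates()]).
#' @return sum(freq_i * phonation_i) / sum(phonation_i) over non-NaN
#'   segments, in Hz; NaN (with a warning) if every segment is NaN.
#' @export
articulation_rate <- function(est) {
  ps <- est$per_segment
  ok <- !is.nan(ps$freq) & ps$phonation_time > 0
  if (!any(ok)) {
    warning("all segment rate estimates are NaN")
    return(NaN)
  }
  sum(ps$freq[ok] * ps$phonation_time[ok]) / sum(ps$phonation_time[ok])
}

#' Flag subharmonic synchronizers
#'
#' A segment is flagged with integer m >= 2 when its estimated rate lies
#' within `tol` of the segment's stimulus rate divided by m (a 1:m
#' production). The participant is flagged subharmonic when at least 3 of
#' the 5 segments agree on the same m.
#'
#' @param est a `rate_estimate`.
#' @param spec the driving [segment_spec()].
#' @param tol rate tolerance in Hz (default 0.15).
#' @param max_m largest subdivision considered (default 4).
#' @return object of class `subharmonic_flag`: `is_subharmonic`, `m`
#'   (integer or NA), `segments_flagged` (indices), `per_segment_m`.
#' @export
detect_subharmonic <- function(est, spec, tol = 0.15, max_m = 4L) {
  stopifnot(inherits(spec, "segment_spec"))
  rates <- spec$segments$rate
  freqs <- est$per_segment$freq
  m_per <- rep(NA_integer_, length(freqs))
  for (i in seq_along(freqs)) {
    if (is.nan(freqs[i])) next
    for (m in 2:max_m) {
      if (abs(freqs[i] - rates[i] / m) <= tol) { m_per[i] <- m; break }
    }
  }
  tab <- table(m_per[!is.na(m_per)])
  if (length(tab) && max(tab) >= 3) {
    m <- as.integer(names(tab)[which.max(tab)])
    structure(list(is_subharmonic = TRUE, m = m,
                   segments_flagged = which(m_per == m),
                   per_segment_m = m_per),
              class = "subharmonic_flag")
  } else {
    structure(list(is_subharmonic = FALSE, m = NA_integer_,
                   segments_flagged = integer(0), per_segment_m = m_per),
              class = "subharmonic_flag")
  }
}
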