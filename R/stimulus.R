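# The accelerating /ta/ stimulus: five segments of constant syllable rate
# (4.3 -> 4.7 Hz), each defined by a phoneme count and a per-phoneme duration
# (two phonemes, /t/ + /a/, per syllable). A surrogate audio rendering stands
# in for the original diphone-synthesized file.

#' Construct a stimulus segment specification
#'
#' @param rate syllable rates in Hz, one per segment, strictly increasing.
#' @param phoneme_count phonemes per segment; must be even (two per syllable).
#' @param phoneme_ms per-phoneme duration in milliseconds.
#' @return An object of class `segment_spec`: a list with `segments`
#'   (data.frame with columns `rate`, `phoneme_count`, `phoneme_ms`),
#'   `boundaries` (cumulative segment end times, seconds) and
#'   `total_duration` (seconds).
#' @export
segment_spec <- function(rate, phoneme_count, phoneme_ms) {
  n <- length(rate)
  if (length(phoneme_count) != n || length(phoneme_ms) != n)
    stop("rate, phoneme_count and phoneme_ms must have equal length")
  if (any(phoneme_count %% 2 != 0))
    stop("phoneme_count must be even in every segment (2 phonemes per /ta/)")
  if (n > 1 && any(diff(rate) <= 0))
    stop("syllable rates must be strictly increasing")
  # a syllable (2 phonemes) must span one rate period
  if (any(abs(2 * phoneme_ms - 1000 / rate) > 0.5))
    stop("2 x phoneme_ms must equal 1000/rate within 0.5 ms")
  segments <- data.frame(rate = rate, phoneme_count = as.integer(phoneme_count),
                         phoneme_ms = phoneme_ms)
  boundaries <- cumsum(phoneme_count * phoneme_ms / 1000)
  structure(list(segments = segments, boundaries = boundaries,
                 total_duration = boundaries[n]),
            class = "segment_spec")
}

#' The printed five-segment specification of the 80 s accelerating stimulus
#'
#' Five segments at 4.3, 4.4, 4.5, 4.6 and 4.7 Hz with 120/120/120/120/246
#' phonemes of ca. 116.28/113.64/111.11/108.70/106.38 ms, giving segment
#' boundaries near 13.95, 27.59, 40.92, 53.97 and 80.14 s.
#'
#' @return a [segment_spec()].
#' @export
#' @examples
#' spec <- default_segment_spec()
#' spec$boundaries
default_segment_spec <- function() {
  segment_spec(rate = c(4.3, 4.4, 4.5, 4.6, 4.7),
               phoneme_count = c(120L, 120L, 120L, 120L, 246L),
               phoneme_ms = c(116.28, 113.64, 111.11, 108.70, 106.38))
}

#' @export
print.segment_spec <- function(x, ...) {
  cat("<segment_spec>\n")
  df <- x$segments
  df$end_s <- round(x$boundaries, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Serialize / deserialize a segment specification
#'
#' @param spec a [segment_spec()].
#' @param path file path for the JSON representation.
#' @return `read_segment_spec` returns a [segment_spec()];
#'   `write_segment_spec` returns `path` invisibly.
#' @export
write_segment_spec <- function(spec, path) {
  stopifnot(inherits(spec, "segment_spec"))
  jsonlite::write_json(spec$segments, path, digits = NA)
  invisible(path)
}

#' @rdname write_segment_spec
#' @export
read_segment_spec <- function(path) {
  df <- jsonlite::fromJSON(path)
  segment_spec(df$rate, df$phoneme_count, df$phoneme_ms)
}

#' Lay out syllable onset times from a segment specification
#'
#' Syllables are laid end-to-end: within segment k onsets are spaced by one
#' syllable duration (2 x phoneme duration ~ 1/rate), starting at the end of
#' the previous segment.
#'
#' @param spec a [segment_spec()].
#' @return An object of class `syllable_timeline`: `onsets` (seconds),
#'   `segment_index` (1-based, per onset), `syllable_duration` (seconds, per
#'   onset), `segment_rates` (Hz, per segment) and `total_duration`.
#' @export
build_timeline <- function(spec) {
  stopifnot(inherits(spec, "segment_spec"))
  seg <- spec$segments
  starts <- c(0, spec$boundaries[-nrow(seg)])
  onsets <- numeric(0); idx <- integer(0); dur <- numeric(0)
  for (k in seq_len(nrow(seg))) {
    n_syll <- seg$phoneme_count[k] %/% 2L
    syl <- 2 * seg$phoneme_ms[k] / 1000
    onsets <- c(onsets, starts[k] + (seq_len(n_syll) - 1L) * syl)
    idx <- c(idx, rep(k, n_syll))
    dur <- c(dur, rep(syl, n_syll))
  }
  structure(list(onsets = onsets, segment_index = idx, syllable_duration = dur,
                 segment_rates = seg$rate, total_duration = spec$total_duration),
            class = "syllable_timeline")
}

#' Render a surrogate audio stimulus from a syllable timeline
#'
#' Each syllable is rendered as a brief broadband noise burst (the /t/
#' release, high-pass shaped above 2 kHz) followed by a harmonic complex at
#' `f0` (the voiced /a/, low-pass limited below 1.5 kHz), gated to the
#' phoneme durations. The resulting amplitude envelope carries modulation
#' energy at the segment syllable rates; the rendering is deterministic.
#'
#' @param timeline a [build_timeline()] result.
#' @param sample_rate output rate in Hz, >= 8000.
#' @param f0 fundamental of the vowel complex in Hz (default 200, matching
#'   the fundamental that leaking stimulus audio introduces into recordings).
#' @return an [audio_signal()].
#' @export
render_stimulus <- function(timeline, sample_rate = 16000, f0 = 200) {
  stopifnot(inherits(timeline, "syllable_timeline"))
  if (sample_rate < 8000) stop("sample_rate must be >= 8000 Hz")
  if (f0 >= sample_rate / 2) stop("f0 must be below the Nyquist frequency")
  sr <- sample_rate
  n <- round(timeline$total_duration * sr)
  x <- numeric(n)

  # deterministic /t/ burst template: 15 ms noise, high-pass above 2 kHz
  burst_n <- round(0.015 * sr)
  burst <- with_local_seed(20201L, stats::rnorm(burst_n))
  hp <- signal::butter(4, 2000 / (sr / 2), "high")
  burst <- signal::filtfilt(hp, c(burst, numeric(burst_n)))[seq_len(burst_n)]
  burst <- 0.8 * burst / max(abs(burst))
  burst <- burst * seq(1, 0.2, length.out = burst_n)

  n_harm <- max(1L, floor(1500 / f0))
  amps <- 1 / seq_len(n_harm)

  for (i in seq_along(timeline$onsets)) {
    t0 <- timeline$onsets[i]
    pd <- timeline$syllable_duration[i] / 2
    i0 <- round(t0 * sr) + 1L
    i1 <- min(n, i0 + burst_n - 1L)
    if (i0 <= n)
      x[i0:i1] <- x[i0:i1] + burst[seq_len(i1 - i0 + 1L)]
    # vowel occupies the second phoneme slot
    v0 <- round((t0 + pd) * sr) + 1L
    v_n <- round(pd * sr)
    v1 <- min(n, v0 + v_n - 1L)
    if (v0 <= n && v1 >= v0) {
      tt <- (seq.int(v0, v1) - 1) / sr
      vow <- numeric(length(tt))
      for (k in seq_len(n_harm))
        vow <- vow + amps[k] * sin(2 * pi * k * f0 * tt)
      # gentle gates keep the vowel free of broadband edge transients
      ramp_n <- min(round(0.025 * sr), length(vow) %/% 2L)
      gate <- rep(1, length(vow))
      if (ramp_n > 0) {
        r <- 0.5 * (1 - cos(pi * seq_len(ramp_n) / ramp_n))
        gate[seq_len(ramp_n)] <- r
        gate[length(gate) + 1L - seq_len(ramp_n)] <- r
      }
      x[v0:v1] <- x[v0:v1] + 0.5 * vow * gate / sum(amps)
    }
  }
  audio_signal(x / max(abs(x)), sr, label = "stimulus")
}
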