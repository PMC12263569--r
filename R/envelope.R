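# Signal conditioning: leakage removal, Hilbert amplitude envelope,
# resampling, rhythm-band filtering, and modulation-spectrum diagnostics.

#' Envelope series container
#'
#' @param values amplitude values (may be negative after DC removal or
#'   filtering).
#' @param rate sampling rate of the envelope in Hz.
#' @param band numeric `c(low, high)` in Hz if band-limited, or the string
#'   `"broadband"`.
#' @param source_duration duration of the source audio in seconds.
#' @return an object of class `envelope_series`.
#' @export
envelope_series <- function(values, rate, band = "broadband", source_duration) {
  if (rate <= 0) stop("rate must be positive")
  if (is.numeric(band)) {
    if (length(band) != 2L || band[1] >= band[2]) stop("band must be c(low, high)")
    if (rate <= 2 * band[2])
      stop("envelope rate must exceed twice the band upper edge (Nyquist)")
  } else if (!identical(band, "broadband")) {
    stop("band must be numeric c(low, high) or \"broadband\"")
  }
  structure(list(values = as.numeric(values), rate = rate, band = band,
                 source_duration = source_duration),
            class = "envelope_series")
}

#' @export
duration.envelope_series <- function(x) length(x$values) / x$rate

#' @export
print.envelope_series <- function(x, ...) {
  b <- if (is.numeric(x$band)) sprintf("%g-%g Hz", x$band[1], x$band[2]) else x$band
  cat(sprintf("<envelope_series> %d samples @ %g Hz, band %s\n",
              length(x$values), x$rate, b))
  invisible(x)
}

#' Remove stimulus leakage from a recording
#'
#' Leaking stimulus audio carries energy below 3 kHz (including a 200 Hz
#' fundamental), while whispered /ta/ productions concentrate above 3 kHz.
#' The leakage is removed with a 6th-order Chebyshev type-II filter with
#' 40 dB stopband attenuation; the printed \[0, 3 kHz\] bandstop is realized
#' as its high-pass form (a band-stop whose lower edge is 0 Hz), applied
#' forward and backward (zero phase).
#'
#' @param audio an [audio_signal()] with sample rate above 6 kHz.
#' @param stop_hz stopband edge in Hz (default 3000).
#' @param attenuation_db stopband attenuation in dB (default 40).
#' @param order filter order (default 6).
#' @return filtered [audio_signal()].
#' @export
remove_leakage <- function(audio, stop_hz = 3000, attenuation_db = 40, order = 6) {
  stopifnot(inherits(audio, "audio_signal"))
  if (audio$sample_rate <= 2 * stop_hz)
    stop("sample_rate must exceed ", 2 * stop_hz,
         " Hz so the stopband edge lies below Nyquist")
  hp <- signal::cheby2(order, attenuation_db, stop_hz / (audio$sample_rate / 2),
                       "high")
  audio_signal(signal::filtfilt(hp, audio$samples), audio$sample_rate,
               label = paste0(audio$label, " [leakage removed]"))
}

# staged anti-aliased resampling of a slow series onto a lower rate grid;
# t0 tracks the block-mean center offset so the output grid stays aligned
resample_series <- function(x, fs, target_rate) {
  dur <- (length(x) - 1) / fs
  t0 <- 0
  while (fs > 8 * target_rate) {
    k <- min(8L, max(2L, floor(fs / (2 * target_rate))))
    n <- (length(x) %/% k) * k
    x <- colMeans(matrix(x[seq_len(n)], nrow = k))
    t0 <- t0 + (k - 1) / (2 * fs)
    fs <- fs / k
  }
  lp <- signal::butter(4, (0.9 * target_rate / 2) / (fs / 2))
  x <- signal::filtfilt(lp, x)
  t_old <- t0 + (seq_along(x) - 1) / fs
  t_new <- seq(0, dur, by = 1 / target_rate)
  stats::approx(t_old, x, xout = pmin(pmax(t_new, t_old[1]), max(t_old)))$y
}

#' Extract the amplitude envelope of a recording
#'
#' Computes the magnitude of the analytic signal (Hilbert transform), then
#' downsamples to `target_rate` with anti-aliasing, then removes the DC
#' offset. Band-limiting to the syllable-rate range is a separate step
#' ([env_bandpass()]).
#'
#' @param audio an [audio_signal()].
#' @param target_rate envelope rate in Hz (default 100; must exceed twice
#'   the highest rhythm frequency of interest).
#' @return a broadband [envelope_series()].
#' @export
extract_envelope <- function(audio, target_rate = 100) {
  stopifnot(inherits(audio, "audio_signal"))
  if (target_rate <= 0) stop("target_rate must be positive")
  if (target_rate < 2 * 5.7)
    stop("target_rate must be at least twice the 5.7 Hz band edge")
  env <- Mod(analytic_signal(audio$samples))
  v <- resample_series(env, audio$sample_rate, target_rate)
  envelope_series(v - mean(v), target_rate, band = "broadband",
                  source_duration = duration(audio))
}

#' Band-limit an envelope to a rhythm band
#'
#' Butterworth bandpass applied forward and backward so the net phase
#' response is zero (phase lags then reflect behavior, not filter delay).
#' The default 3.3-5.7 Hz passband brackets the 4.3-4.7 Hz stimulus rates
#' with roughly +/- 1 Hz tolerance.
#'
#' @param env an [envelope_series()].
#' @param low,high passband edges in Hz.
#' @param order Butterworth prototype order (default 5).
#' @param zero_phase apply forward-backward (default); `FALSE` gives a
#'   causal single pass for parity experiments with delay-carrying setups.
#' @return a band-limited [envelope_series()].
#' @export
env_bandpass <- function(env, low = 3.3, high = 5.7, order = 5, zero_phase = TRUE) {
  stopifnot(inherits(env, "envelope_series"))
  if (low >= high) stop("low must be below high")
  if (env$rate <= 2 * high) stop("band violates the envelope Nyquist frequency")
  bp <- signal::butter(order, c(low, high) / (env$rate / 2), "pass")
  v <- if (zero_phase) signal::filtfilt(bp, env$values)
       else as.numeric(signal::filter(bp, env$values))
  envelope_series(v, env$rate, band = c(low, high),
                  source_duration = env$source_duration)
}

#' Modulation spectrum of an envelope
#'
#' FFT magnitude of the (demeaned) envelope on \[0, `fmax`\] Hz, peak-
#' normalized to a maximum of 1 — the diagnostic that makes subharmonic
#' production visible: a 2.25 Hz production pattern shows peaks at 2.25 and
#' 4.5 Hz before rhythm-band filtering, and only the 4.5 Hz peak after.
#'
#' @param env an [envelope_series()].
#' @param fmax upper frequency limit in Hz (default 7).
#' @return data.frame with columns `frequency` (Hz) and `amplitude`
#'   (normalized to max 1).
#' @export
modulation_spectrum <- function(env, fmax = 7) {
  stopifnot(inherits(env, "envelope_series"))
  v <- env$values
  if (length(v) < 2L) stop("envelope too short")
  v <- v - mean(v)
  n <- length(v)
  amp <- Mod(stats::fft(v))
  freq <- (seq_len(n) - 1) * env$rate / n
  keep <- freq <= fmax
  amp <- amp[keep]
  if (max(amp) > 0) amp <- amp / max(amp)
  data.frame(frequency = freq[keep], amplitude = amp)
}

#' Overlay a filtered recording and its envelope for visual validation
#'
#' Sanity plot to check that leakage filtering did not destroy the
#' participant's productions: the post-filter waveform with the amplitude
#' envelope overlaid.
#'
#' @param audio (typically leakage-filtered) [audio_signal()].
#' @param env matching [envelope_series()] (broadband).
#' @param t_range optional `c(from, to)` seconds to restrict the view.
#' @return invisibly, `NULL`; called for the plot side effect.
#' @export
plot_envelope_overlay <- function(audio, env, t_range = NULL) {
  t_a <- (seq_along(audio$samples) - 1) / audio$sample_rate
  t_e <- (seq_along(env$values) - 1) / env$rate
  if (!is.null(t_range)) {
    ka <- t_a >= t_range[1] & t_a <= t_range[2]
    ke <- t_e >= t_range[1] & t_e <= t_range[2]
  } else {
    ka <- rep(TRUE, length(t_a)); ke <- rep(TRUE, length(t_e))
  }
  graphics::plot(t_a[ka], audio$samples[ka], type = "l", col = "grey70",
                 xlab = "time (s)", ylab = "amplitude",
                 main = "post-filter waveform + envelope")
  scale <- max(abs(audio$samples[ka])) / max(abs(env$values[ke]) + 1e-12)
  graphics::lines(t_e[ke], env$values[ke] * scale, col = "firebrick", lwd = 1.5)
  invisible(NULL)
}
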