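# Syllable onset detection for whispered speech. Whispering has no F0 and
# low, highly variable intensity, so onsets are found from the spectral-flux
# onset strength envelope: the half-wave-rectified frame-to-frame increase of
# the magnitude spectrogram, summed over frequency, which peaks at the /t/
# transients. Silent gaps are onset-free spans longer than a minimum length.

#' Spectral-flux onset strength envelope
#'
#' @param audio an [audio_signal()].
#' @param frame analysis frame length in seconds (default 0.046).
#' @param hop hop between frames in seconds (default 0.010).
#' @return an object of class `onset_track`: `strength` (per frame),
#'   `times` (frame reference times, s), `rate` (frame rate, Hz), `duration`
#'   (signal duration, s), `onsets` (empty until [pick_onsets()]), `params`.
#' @export
onset_strength <- function(audio, frame = 0.046, hop = 0.010) {
  stopifnot(inherits(audio, "audio_signal"))
  if (hop > frame) stop("hop must not exceed frame")
  sr <- audio$sample_rate
  win_n <- round(frame * sr)
  hop_n <- max(1L, round(hop * sr))
  if (win_n > length(audio$samples)) stop("frame longer than the signal")
  nfft <- 2^ceiling(log2(win_n))
  sg <- signal::specgram(audio$samples, n = nfft, Fs = sr,
                         window = signal::hanning(win_n),
                         overlap = win_n - hop_n)
  M <- abs(sg$S)
  nt <- ncol(M)
  flux <- c(0, colSums(pmax(M[, -1, drop = FALSE] - M[, -nt, drop = FALSE], 0)))
  # frame-center times: the flux of a transient peaks when it sits under the
  # center of the Hann window
  times <- ((seq_len(nt) - 1L) * hop_n + win_n / 2) / sr
  structure(list(strength = flux, times = times, rate = sr / hop_n,
                 duration = duration(audio), onsets = numeric(0),
                 params = list(frame = frame, hop = hop, threshold = NA_real_)),
            class = "onset_track")
}

#' Pick onset events from an onset strength envelope
#'
#' Local maxima above an adaptive threshold — median + `k_mad` scaled MADs
#' of the strength, with a floor at `rel_floor` of the maximum strength so
#' near-silent stretches cannot collapse the threshold — subject to a
#' refractory minimum inter-onset spacing: even at the fastest stimulus rate
#' (4.7 Hz, ~106 ms phonemes) /ta/ onsets cannot be closer than ~80 ms.
#' Peak times are refined by parabolic interpolation.
#'
#' @param track an [onset_strength()] result.
#' @param k_mad threshold multiplier (default 3).
#' @param rel_floor threshold floor as a fraction of the maximum strength
#'   (default 0.1).
#' @param min_sep refractory spacing in seconds (default 0.08).
#' @return the `onset_track` with `onsets` (event times, s) and the applied
#'   threshold filled in.
#' @export
pick_onsets <- function(track, k_mad = 3, rel_floor = 0.1, min_sep = 0.08) {
  stopifnot(inherits(track, "onset_track"))
  s <- track$strength
  n <- length(s)
  if (n < 3L || all(s == 0)) {
    track$onsets <- numeric(0)
    return(track)
  }
  thr <- max(stats::median(s) + k_mad * stats::mad(s), rel_floor * max(s))
  peaks <- which(s[2:(n - 1)] >= s[1:(n - 2)] & s[2:(n - 1)] > s[3:n]) + 1L
  peaks <- peaks[s[peaks] > thr]
  # refractory rule: strongest peak wins within min_sep
  if (length(peaks) > 1L) {
    ord <- peaks[order(s[peaks], decreasing = TRUE)]
    keep <- logical(0)
    chosen <- numeric(0)
    for (p in ord) {
      if (all(abs(track$times[p] - chosen) >= min_sep))
        chosen <- c(chosen, track$times[p])
    }
    peaks <- sort(peaks[track$times[peaks] %in% chosen])
  }
  # parabolic refinement around each peak
  t_hop <- 1 / track$rate
  onsets <- vapply(peaks, function(p) {
    if (p > 1L && p < n) {
      denom <- s[p - 1L] - 2 * s[p] + s[p + 1L]
      d <- if (denom != 0) 0.5 * (s[p - 1L] - s[p + 1L]) / denom else 0
      d <- max(-0.5, min(0.5, d))
      track$times[p] + d * t_hop
    } else track$times[p]
  }, numeric(1))
  track$onsets <- sort(onsets)
  track$params$threshold <- thr
  track
}

#' Gap set container
#'
#' @param intervals data.frame with columns `start` and `end` (seconds),
#'   disjoint and sorted.
#' @param min_len the minimum-length rule that produced the set (seconds).
#' @return an object of class `gap_set`.
#' @export
gap_set <- function(intervals = data.frame(start = numeric(0), end = numeric(0)),
                    min_len = 3) {
  intervals <- as.data.frame(intervals)
  if (nrow(intervals)) {
    if (any(intervals$end <= intervals$start)) stop("inverted interval in gap set")
    o <- order(intervals$start)
    intervals <- intervals[o, , drop = FALSE]
    if (nrow(intervals) > 1L &&
        any(intervals$start[-1] < intervals$end[-nrow(intervals)]))
      stop("gap intervals must be disjoint")
    rownames(intervals) <- NULL
  }
  structure(list(intervals = intervals, min_len = min_len), class = "gap_set")
}

#' Detect silent gaps from onset times
#'
#' A silent gap is a maximal onset-free time span longer than `min_gap`
#' seconds, including the spans before the first and after the last onset.
#' Interior gap edges are padded inward by `edge_pad` so syllable energy
#' adjacent to a gap is not removed with it; the pad is clamped so a
#' reported gap never falls below `min_gap`.
#'
#' @param onsets sorted onset times in seconds.
#' @param duration signal duration in seconds.
#' @param min_gap minimum onset-free span in seconds (default 3; the
#'   optional short-gap refinement uses e.g. 1.5).
#' @param edge_pad inward padding at gap edges in seconds (default 0.11,
#'   about half a syllable period).
#' @return a [gap_set()].
#' @export
detect_gaps <- function(onsets, duration, min_gap = 3, edge_pad = 0.11) {
  if (is.unsorted(onsets)) stop("onsets must be sorted")
  if (length(onsets) == 0L) {
    if (duration > min_gap)
      return(gap_set(data.frame(start = 0, end = duration), min_len = min_gap))
    return(gap_set(min_len = min_gap))
  }
  edges_start <- c(0, onsets)
  edges_end <- c(onsets, duration)
  span <- edges_end - edges_start
  res <- list()
  for (i in which(span > min_gap)) {
    pad_lo <- if (i == 1L) 0 else edge_pad
    pad_hi <- if (i == length(span)) 0 else edge_pad
    pad_total <- pad_lo + pad_hi
    if (span[i] - pad_total < min_gap) {
      shrink <- (span[i] - min_gap) / max(pad_total, 1e-12)
      pad_lo <- pad_lo * shrink
      pad_hi <- pad_hi * shrink
    }
    res[[length(res) + 1L]] <-
      c(edges_start[i] + pad_lo, edges_end[i] - pad_hi)
  }
  if (!length(res)) return(gap_set(min_len = min_gap))
  m <- do.call(rbind, res)
  gap_set(data.frame(start = m[, 1], end = m[, 2]), min_len = min_gap)
}

#' Merge manually excluded intervals into a gap set
#'
#' Supports manual removal of voiced (non-whispered) stretches or gaps the
#' detector missed: the manual intervals are unioned with the detected ones,
#' overlaps coalesced.
#'
#' @param gaps a [gap_set()].
#' @param manual data.frame with columns `start`, `end` (seconds), or a
#'   list of length-2 vectors.
#' @return a [gap_set()].
#' @export
merge_manual_exclusions <- function(gaps, manual) {
  stopifnot(inherits(gaps, "gap_set"))
  if (is.list(manual) && !is.data.frame(manual) && length(manual))
    manual <- as.data.frame(do.call(rbind, lapply(manual, function(v)
      c(start = v[1], end = v[2]))))
  if (is.null(manual) || NROW(manual) == 0L) return(gaps)
  if (any(manual$end <= manual$start)) stop("inverted manual interval")
  all_iv <- rbind(gaps$intervals[, c("start", "end")],
                  manual[, c("start", "end")])
  all_iv <- all_iv[order(all_iv$start), , drop = FALSE]
  merged <- all_iv[1, , drop = FALSE]
  for (i in seq_len(nrow(all_iv))[-1]) {
    last <- nrow(merged)
    if (all_iv$start[i] <= merged$end[last]) {
      merged$end[last] <- max(merged$end[last], all_iv$end[i])
    } else {
      merged <- rbind(merged, all_iv[i, , drop = FALSE])
    }
  }
  gap_set(merged, min_len = gaps$min_len)
}

#' Total gap time of a gap set
#' @param gaps a [gap_set()].
#' @param min_len optionally consider only gaps at least this long (s).
#' @return total gap duration in seconds.
#' @export
gap_total <- function(gaps, min_len = 0) {
  iv <- gaps$intervals
  if (!nrow(iv)) return(0)
  len <- iv$end - iv$start
  sum(len[len >= min_len])
}
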