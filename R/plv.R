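# Phase extraction and Phase Locking Value variants.
#
# PLV = (1/T) |sum_t exp(i (theta1(t) - theta2(t)))| : the modulus of the
# time-averaged unit phasor of the phase difference. 1 = perfectly stable
# phase difference (including any constant production lag), 0 = none.

#' Phase series container
#'
#' @param theta unwrapped instantaneous phase per sample (radians,
#'   accumulating past 2 pi).
#' @param rate sampling rate in Hz.
#' @param mask logical keep/drop per sample (default all kept).
#' @return object of class `phase_series`.
#' @export
phase_series <- function(theta, rate, mask = rep(TRUE, length(theta))) {
  if (!all(is.finite(theta))) stop("theta must be finite")
  if (length(mask) != length(theta)) stop("mask length must equal theta length")
  structure(list(theta = as.numeric(theta), rate = rate, mask = as.logical(mask)),
            class = "phase_series")
}

#' Instantaneous phase of a band-limited envelope
#'
#' Unwrapped angle of the analytic signal of the envelope. In the filtered
#' stimulus envelope one 2 pi cycle corresponds to one syllable (cycle
#' minima near syllable onsets, maxima near nuclei), so unwrapped phase
#' counts completed syllables. Broadband envelopes are rejected: phase is
#' meaningless without a band limit.
#'
#' @param env a band-limited [envelope_series()].
#' @return a [phase_series()] at the envelope rate.
#' @export
instantaneous_phase <- function(env) {
  stopifnot(inherits(env, "envelope_series"))
  if (!is.numeric(env$band))
    stop("envelope must be band-limited before phase extraction")
  theta <- unwrap_phase(Arg(analytic_signal(env$values)))
  phase_series(theta, env$rate)
}

masked_theta <- function(p) p$theta[p$mask]

#' Phase Locking Value between two phase series
#'
#' @param a,b [phase_series()] objects with equal rates and equal lengths
#'   after mask application (gap removal must have been applied identically
#'   to both).
#' @return a value in \[0, 1\].
#' @export
#' @examples
#' t <- seq(0, 10, by = 0.01)
#' a <- phase_series(2 * pi * 4.5 * t, 100)
#' b <- phase_series(2 * pi * 4.5 * t + 1.2, 100)  # constant lag
#' plv(a, b)  # 1: stable phase difference despite the shift
plv <- function(a, b) {
  stopifnot(inherits(a, "phase_series"), inherits(b, "phase_series"))
  if (a$rate != b$rate) stop("phase series rates differ")
  ta <- masked_theta(a); tb <- masked_theta(b)
  if (length(ta) != length(tb))
    stop("lengths differ after mask application; remove gaps identically")
  if (length(ta) < 1L) stop("need at least one sample")
  Mod(mean(exp(1i * (ta - tb))))
}

#' n:m Phase Locking Value
#'
#' Cross-frequency phase locking: modulus of the mean of
#' exp(i (n theta1 - m theta2)). With (n, m) = (1, 1) this reduces to
#' [plv()]. A producer at half the stimulus rate is perfectly 2:1 locked to
#' the stimulus even though its 1:1 PLV over full cycles vanishes.
#'
#' @param a,b [phase_series()] objects (as for [plv()]).
#' @param n,m positive integer multipliers for `a` and `b`.
#' @return a value in \[0, 1\].
#' @export
plv_nm <- function(a, b, n, m) {
  if (n < 1 || m < 1) stop("n and m must be positive integers")
  stopifnot(inherits(a, "phase_series"), inherits(b, "phase_series"))
  if (a$rate != b$rate) stop("phase series rates differ")
  ta <- masked_theta(a); tb <- masked_theta(b)
  if (length(ta) != length(tb)) stop("lengths differ after mask application")
  Mod(mean(exp(1i * (n * ta - m * tb))))
}

#' PLV report container
#' @keywords internal
plv_report <- function(scalar, windows, segment_values = NULL,
                       weighted_mean = NULL, params = list()) {
  structure(list(scalar = scalar, windows = windows,
                 segment_values = segment_values,
                 weighted_mean = weighted_mean, params = params),
            class = "plv_report")
}

#' @export
print.plv_report <- function(x, ...) {
  cat(sprintf("<plv_report> scalar = %s\n",
              format(x$scalar, digits = 4)))
  if (!is.null(x$segment_values))
    cat("  segments:", paste(format(x$segment_values, digits = 3),
                             collapse = " "),
        " weighted mean:", format(x$weighted_mean, digits = 4), "\n")
  invisible(x)
}

#' Moving-window PLV
#'
#' Windowed PLV between two (gap-removed) phase series, window `win` s with
#' `overlap` s overlap (step = win - overlap). In the corrected mode windows
#' are placed only where a full window fits and the scalar is the mean over
#' those windows. The legacy mode reproduces a documented off-by-one in an
#' earlier analysis script: the slot count is floor(duration / step), the
#' last slot is never assigned (stays 0), assigned windows are truncated at
#' the signal end, and the mean is taken over all slots including the zero —
#' which turns a self-comparison of an ~80 s stimulus into 0.975 (39/40)
#' instead of 1.
#'
#' @param a,b [phase_series()] objects (equal rates; equal masked lengths).
#' @param win window length in seconds (default 5).
#' @param overlap window overlap in seconds (default 3).
#' @param legacy emulate the legacy slot-count bug (default `FALSE`).
#' @return a [plv_report] with `scalar`, per-window values, and params.
#' @export
moving_window_plv <- function(a, b, win = 5, overlap = 3, legacy = FALSE) {
  stopifnot(inherits(a, "phase_series"), inherits(b, "phase_series"))
  if (win <= overlap) stop("win must exceed overlap")
  if (a$rate != b$rate) stop("phase series rates differ")
  ta <- masked_theta(a); tb <- masked_theta(b)
  if (length(ta) != length(tb)) stop("lengths differ after mask application")
  rate <- a$rate
  N <- length(ta)
  nwin <- round(win * rate)
  nstep <- round((win - overlap) * rate)
  d <- exp(1i * (ta - tb))
  win_plv <- function(i0, i1) Mod(mean(d[i0:i1]))

  if (!legacy) {
    if (N < nwin) stop("signal shorter than one window")
    starts <- seq.int(1L, N - nwin + 1L, by = nstep)
    vals <- vapply(starts, function(s) win_plv(s, s + nwin - 1L), numeric(1))
    windows <- data.frame(start = (starts - 1L) / rate, value = vals)
    scalar <- mean(vals)
  } else {
    slots <- N %/% nstep
    if (slots < 2L) stop("signal too short for the legacy slot layout")
    starts <- 1L + (seq_len(slots - 1L) - 1L) * nstep
    vals <- vapply(starts, function(s) win_plv(s, min(N, s + nwin - 1L)),
                   numeric(1))
    windows <- data.frame(start = c((starts - 1L) / rate,
                                    (slots - 1L) * nstep / rate),
                          value = c(vals, 0))
    scalar <- sum(vals) / slots
  }
  plv_report(scalar, windows,
             params = list(win = win, overlap = overlap, legacy = legacy))
}

#' Acceleration-based segmented PLV
#'
#' One PLV per stimulus segment, computed over the segment's samples after
#' removing silent gaps of at least `min_gap` seconds, without overlapping
#' windows. Segments retaining less than half of their samples are assigned
#' NaN. The weighted mean weights each non-NaN segment by its remaining
#' sample count; if all segments are NaN the weighted mean is NaN.
#'
#' @param a,b unmasked full-duration [phase_series()] objects covering the
#'   stimulus.
#' @param spec a [segment_spec()] whose total duration matches the series
#'   within 1 s.
#' @param gaps a [gap_set()]; only gaps of at least `min_gap` s are removed.
#' @param min_gap minimum gap length to remove, in seconds (default 3).
#' @return a [plv_report] with `segment_values` and `weighted_mean`.
#' @export
segmented_plv <- function(a, b, spec, gaps = gap_set(), min_gap = 3) {
  stopifnot(inherits(a, "phase_series"), inherits(b, "phase_series"),
            inherits(spec, "segment_spec"))
  if (a$rate != b$rate) stop("phase series rates differ")
  if (length(a$theta) != length(b$theta)) stop("phase series lengths differ")
  rate <- a$rate
  N <- length(a$theta)
  if (abs(N / rate - spec$total_duration) > 1)
    stop("signal duration does not match the segment specification")
  t <- (seq_len(N) - 1L) / rate
  drop <- gap_mask(gaps, t, min_len = min_gap)
  bounds <- c(0, spec$boundaries)
  n_seg <- length(spec$boundaries)
  seg_vals <- rep(NaN, n_seg)
  seg_kept <- numeric(n_seg)
  d <- exp(1i * (a$theta - b$theta))
  for (k in seq_len(n_seg)) {
    in_seg <- t >= bounds[k] & (t < bounds[k + 1] | (k == n_seg & t <= bounds[k + 1]))
    keep <- in_seg & !drop
    seg_kept[k] <- sum(keep)
    if (sum(in_seg) > 0 && sum(keep) / sum(in_seg) >= 0.5)
      seg_vals[k] <- Mod(mean(d[keep]))
  }
  ok <- !is.nan(seg_vals)
  wm <- if (any(ok)) sum(seg_vals[ok] * seg_kept[ok]) / sum(seg_kept[ok]) else NaN
  plv_report(scalar = wm, windows = NULL, segment_values = seg_vals,
             weighted_mean = wm,
             params = list(min_gap = min_gap, kept = seg_kept))
}

# logical drop mask: TRUE where t falls inside a gap of length >= min_len
gap_mask <- function(gaps, t, min_len = 0) {
  drop <- rep(FALSE, length(t))
  iv <- gaps$intervals
  if (!is.null(iv) && nrow(iv)) {
    for (i in seq_len(nrow(iv))) {
      if (iv$end[i] - iv$start[i] >= min_len)
        drop <- drop | (t >= iv$start[i] & t < iv$end[i])
    }
  }
  drop
}

#' Remove gap samples identically from two phase series
#'
#' Samples falling inside the gap intervals are dropped from both series at
#' the same indices; the remaining samples are concatenated across the cut
#' without re-unwrapping. Removal is performed at the phase level — after
#' phase extraction — never on the envelopes.
#'
#' @param a,b [phase_series()] objects with equal rate and length.
#' @param gaps a [gap_set()].
#' @param min_gap only remove gaps at least this long (s; default 3).
#' @return list of the two reduced [phase_series()] objects.
#' @export
apply_gap_removal <- function(a, b, gaps, min_gap = 3) {
  stopifnot(inherits(a, "phase_series"), inherits(b, "phase_series"))
  if (a$rate != b$rate) stop("phase series rates differ")
  if (length(a$theta) != length(b$theta)) stop("phase series lengths differ")
  t <- (seq_along(a$theta) - 1L) / a$rate
  keep <- !gap_mask(gaps, t, min_len = min_gap)
  list(a = phase_series(a$theta[keep], a$rate, a$mask[keep]),
       b = phase_series(b$theta[keep], b$rate, b$mask[keep]))
}
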