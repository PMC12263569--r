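#' Audio signal container
#'
#' A plain in-memory waveform: the unit all filters and onset detection
#' operate on. Samples are stored as a numeric vector on an arbitrary
#' amplitude scale (typically within \[-1, 1\]).
#'
#' @param samples numeric vector of amplitudes; must be finite.
#' @param sample_rate sampling rate in Hz, > 0.
#' @param label free-text label carried through the pipeline.
#' @return An object of class `audio_signal` with fields `samples`,
#'   `sample_rate` and `label`.
#' @export
#' @examples
#' a <- audio_signal(sin(2 * pi * 5 * seq(0, 1, by = 1 / 100)), 100)
#' duration(a)
audio_signal <- function(samples, sample_rate, label = "") {
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("sample_rate must be a single positive number")
  samples <- as.numeric(samples)
  if (!all(is.finite(samples)))
    stop("samples must be finite")
  structure(
    list(samples = samples, sample_rate = sample_rate, label = as.character(label)),
    class = "audio_signal"
  )
}

#' Duration of an audio signal or envelope in seconds
#' @param x an `audio_signal` or `envelope_series`.
#' @return duration in seconds.
#' @export
duration <- function(x) UseMethod("duration")

#' @export
duration.audio_signal <- function(x) length(x$samples) / x$sample_rate

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal> %s: %.3f s @ %g Hz (%d samples)\n",
              if (nzchar(x$label)) x$label else "unlabelled",
              duration(x), x$sample_rate, length(x$samples)))
  invisible(x)
}
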