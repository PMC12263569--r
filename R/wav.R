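# Minimal RIFF/WAVE reader and writer (16-bit PCM and 32-bit float, mono or
# multi-channel; multi-channel input is averaged to mono on read).

#' Write an audio signal to a WAV file
#'
#' @param audio an [audio_signal()].
#' @param path output file path.
#' @param bit_depth 16 (integer PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(audio, path, bit_depth = 16L) {
  stopifnot(inherits(audio, "audio_signal"))
  if (!bit_depth %in% c(16L, 32L)) stop("bit_depth must be 16 or 32")
  sr <- as.integer(round(audio$sample_rate))
  x <- audio$samples
  n <- length(x)
  bytes_per <- bit_depth %/% 8L
  data_size <- n * bytes_per
  fmt_code <- if (bit_depth == 16L) 1L else 3L  # PCM / IEEE float

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")             # channels
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(as.integer(sr * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bit_depth), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bit_depth == 16L) {
    q <- as.integer(pmax(-32767L, pmin(32767L, round(x * 32767))))
    writeBin(q, con, size = 2, endian = "little")
  } else {
    writeBin(x, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a WAV file into an audio signal
#'
#' Supports 16-bit integer PCM and 32-bit float data. Multi-channel files
#' are averaged down to mono.
#'
#' @param path WAV file path.
#' @param label label for the resulting [audio_signal()]; defaults to the
#'   file name.
#' @return an [audio_signal()] with samples scaled to \[-1, 1\] for PCM input.
#' @export
read_wav <- function(path, label = basename(path)) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt_code <- NA_integer_; channels <- NA_integer_
  sr <- NA_integer_; bit_depth <- NA_integer_
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) stop("no data chunk found in ", path)
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_code <- readBin(con, "integer", size = 2, endian = "little")
      channels <- readBin(con, "integer", size = 2, endian = "little")
      sr <- readBin(con, "integer", size = 4, endian = "little")
      invisible(readBin(con, "integer", size = 4, endian = "little"))
      invisible(readBin(con, "integer", size = 2, endian = "little"))
      bit_depth <- readBin(con, "integer", size = 2, endian = "little")
      extra <- size - 16L
      if (extra > 0) invisible(readBin(con, "raw", n = extra))
    } else if (identical(id, "data")) {
      if (is.na(fmt_code)) stop("data chunk before fmt chunk in ", path)
      if (fmt_code == 1L && bit_depth == 16L) {
        n <- size %/% 2L
        x <- readBin(con, "integer", n = n, size = 2, signed = TRUE,
                     endian = "little") / 32767
      } else if (fmt_code == 3L && bit_depth == 32L) {
        n <- size %/% 4L
        x <- readBin(con, "double", n = n, size = 4, endian = "little")
      } else {
        stop("unsupported WAV format (fmt ", fmt_code, ", ", bit_depth, " bit)")
      }
      if (channels > 1L) {
        n_frames <- length(x) %/% channels
        x <- colMeans(matrix(x[seq_len(n_frames * channels)], nrow = channels))
      }
      return(audio_signal(x, sr, label = label))
    } else {
      invisible(readBin(con, "raw", n = size + (size %% 2L)))
    }
  }
}
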