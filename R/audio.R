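#' Audio clip container
#'
#' The unit all signal processing in the package operates on: a mono waveform
#' of floating-point samples in \[-1, +1\] (digital full scale) plus its
#' sampling rate. Clips are plain lists of class `"audio_clip"` so they can be
#' built cheaply inside simulations.
#'
#' @param samples numeric vector of samples; full scale corresponds to 1.0.
#' @param rate_hz sampling rate in Hz (> 0).
#' @param source_id identifier of the originating recording (optional).
#' @param channel channel identifier, default `"A"` (field recorders in this
#'   workflow are two-channel; only one channel is analysed).
#' @return an object of class `audio_clip`.
#' @export
audio_clip <- function(samples, rate_hz, source_id = NA_character_,
                       channel = "A") {
  stopifnot(is.numeric(samples), length(rate_hz) == 1L, rate_hz > 0)
  structure(
    list(samples = as.numeric(samples), rate_hz = as.numeric(rate_hz),
         source_id = source_id, channel = channel),
    class = "audio_clip"
  )
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip> %d samples @ %g Hz (%.3f s), peak %.4f\n",
              length(x$samples), x$rate_hz,
              length(x$samples) / x$rate_hz,
              if (length(x$samples)) max(abs(x$samples)) else NA_real_))
  invisible(x)
}

#' @export
length.audio_clip <- function(x) length(x$samples)

#' Duration of a clip in seconds
#' @param clip an [audio_clip()].
#' @return numeric scalar, seconds.
#' @export
clip_duration <- function(clip) length(clip$samples) / clip$rate_hz

#' Convert a linear amplitude to decibels relative to full scale
#'
#' 0 dBFS corresponds to amplitude 1.0. Non-positive amplitudes are clamped to
#' the package's dB floor of -120 dBFS.
#'
#' @param a linear amplitude (peak or RMS, caller's choice of convention).
#' @return decibels, `20 * log10(a)`, floored at -120.
#' @export
dbfs <- function(a) {
  out <- rep(-120, length(a))
  ok <- is.finite(a) & a > 0
  out[ok] <- pmax(20 * log10(a[ok]), -120)
  out
}

#' @rdname dbfs
#' @param db decibels relative to full scale.
#' @export
db_to_amp <- function(db) 10^(db / 20)

# ---- RIFF/WAVE I/O -----------------------------------------------------------
# Minimal PCM reader/writer. Field recordings in this workflow are RIFF PCM
# 16-bit; 24-bit read support is included because some recorders emit it.

#' Read a PCM WAV file
#'
#' Reads RIFF/WAVE PCM (16- or 24-bit). Multi-channel files are reduced to a
#' single channel (default the first, "channel A").
#'
#' @param path file path.
#' @param channel 1-based channel index to keep.
#' @return an [audio_clip()] with samples scaled to \[-1, 1\].
#' @export
read_wav <- function(path, channel = 1L) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(fmt_raw[1:2], "integer", 1L, 2L, endian = "little"),
        n_channels   = readBin(fmt_raw[3:4], "integer", 1L, 2L, endian = "little"),
        sample_rate  = readBin(fmt_raw[5:8], "integer", 1L, 4L, endian = "little"),
        bits         = readBin(fmt_raw[15:16], "integer", 1L, 2L, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz + (sz %% 2L)))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("missing fmt/data chunk: ", path)
  if (fmt$audio_format != 1L) stop("only PCM WAV is supported")
  if (!fmt$bits %in% c(16L, 24L)) stop("only 16/24-bit PCM supported, got ", fmt$bits)
  if (fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", length(data_raw) %/% 2L, size = 2L,
                 signed = TRUE, endian = "little") / 32768
  } else {
    n <- length(data_raw) %/% 3L
    b <- matrix(as.integer(data_raw[seq_len(n * 3L)]), nrow = 3L)
    v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    x <- v / 8388608
  }
  nch <- fmt$n_channels
  if (channel > nch) stop("requested channel ", channel, " of ", nch)
  if (nch > 1L) x <- x[seq(channel, length(x), by = nch)]
  audio_clip(x, fmt$sample_rate, source_id = basename(path))
}

#' Write a clip as 16-bit PCM WAV
#'
#' Samples are clipped to \[-1, 1\] before quantization.
#'
#' @param clip an [audio_clip()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path) {
  x <- pmin(1, pmax(-1, clip$samples))
  pcm <- as.integer(round(x * 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")   # PCM
  writeBin(1L, con, size = 2L, endian = "little")   # mono
  writeBin(as.integer(clip$rate_hz), con, size = 4L, endian = "little")
  writeBin(as.integer(clip$rate_hz) * 2L, con, size = 4L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")   # block align
  writeBin(16L, con, size = 2L, endian = "little")  # bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4L, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}
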