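#' Audio recording container
#'
#' A mono sampled waveform. Samples are dimensionless amplitudes, nominally
#' in \[-1, 1\] (values outside are allowed in memory but clip on PCM export).
#'
#' @param samples Numeric vector of amplitudes.
#' @param sample_rate_hz Integer sampling rate (Hz).
#' @return An object of class `audio_recording` with elements `samples` and
#'   `sample_rate_hz`.
#' @export
audio_recording <- function(samples, sample_rate_hz) {
  stopifnot(is.numeric(samples), length(samples) >= 1, all(is.finite(samples)))
  sample_rate_hz <- as.integer(sample_rate_hz)
  stopifnot(sample_rate_hz >= 1)
  structure(list(samples = as.numeric(samples), sample_rate_hz = sample_rate_hz),
            class = "audio_recording")
}

#' @export
print.audio_recording <- function(x, ...) {
  cat(sprintf("<audio_recording: %d samples @ %d Hz (%.3f s)>\n",
              length(x$samples), x$sample_rate_hz,
              length(x$samples) / x$sample_rate_hz))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param audio An `audio_recording`.
#' @return Duration in seconds.
#' @export
audio_duration <- function(audio) {
  length(audio$samples) / audio$sample_rate_hz
}

#' Write a mono 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE writer for mono PCM16. Samples are clipped to
#' \[-1, 1\] and quantised to 16-bit integers.
#'
#' @param audio An `audio_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(audio, path) {
  stopifnot(inherits(audio, "audio_recording"))
  x <- pmin(pmax(audio$samples, -1), 1)
  pcm <- as.integer(round(x * 32767))
  sr <- audio$sample_rate_hz
  n <- length(pcm)
  data_bytes <- 2L * n
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")            # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")             # PCM
  writeBin(1L, con, size = 2, endian = "little")             # mono
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(sr * 2L, con, size = 4, endian = "little")        # byte rate
  writeBin(2L, con, size = 2, endian = "little")             # block align
  writeBin(16L, con, size = 2, endian = "little")            # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE reader; accepts mono PCM16 only and walks chunks until
#' the `data` chunk. Samples are rescaled to \[-1, 1\].
#'
#' @param path WAV file path.
#' @return An `audio_recording`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  sr <- NULL; channels <- NULL; bits <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk in ", path)
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      sr <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
      invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      channels <- fmt[2]
      if (fmt[1] != 1L) stop("only PCM WAV supported")
      extra <- size - 16L
      if (extra > 0) invisible(readBin(con, "raw", extra))
    } else if (identical(id, "data")) {
      if (is.null(sr)) stop("data chunk before fmt chunk in ", path)
      if (channels != 1L) stop("only mono WAV supported (got ", channels, " channels)")
      if (bits != 16L) stop("only 16-bit PCM supported (got ", bits, " bits)")
      pcm <- readBin(con, "integer", size / 2L, size = 2, endian = "little", signed = TRUE)
      return(audio_recording(pcm / 32767, sr))
    } else {
      invisible(readBin(con, "raw", size + (size %% 2L)))
    }
  }
}
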