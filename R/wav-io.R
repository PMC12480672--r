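#' Write a mono waveform to a 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE writer for single-channel 16-bit audio. Samples are
#' expected in \[-1, 1\] and are clipped before quantisation.
#'
#' @param samples numeric vector of amplitudes in \[-1, 1\].
#' @param sample_rate_hz sampling rate in Hz.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate_hz, path) {
  stopifnot(is.numeric(samples), length(samples) > 0, sample_rate_hz > 0)
  pcm <- as.integer(round(clip(samples, -1, 1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(sample_rate_hz), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate_hz * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")            # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' @param path WAV file path.
#' @return list with `samples` (numeric in \[-1, 1\]) and `sample_rate_hz`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    stop("not a RIFF/WAVE file: ", path)
  }
  sr <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L) stop("only mono PCM supported")
      sr <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      invisible(readBin(con, integer(), n = 2, size = 2, endian = "little"))
      if (sz > 16) invisible(readBin(con, raw(), n = sz - 16L))
    } else if (identical(id, "data")) {
      samples <- readBin(con, integer(), n = sz %/% 2L, size = 2,
                         signed = TRUE, endian = "little") / 32767
      break
    } else {
      invisible(readBin(con, raw(), n = sz))
    }
  }
  if (is.null(sr) || is.null(samples)) stop("malformed WAV: ", path)
  list(samples = samples, sample_rate_hz = sr)
}
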