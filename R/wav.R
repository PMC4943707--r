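#' Read a mono PCM WAV file
#'
#' Minimal reader for RIFF/WAVE files containing uncompressed 16-bit PCM
#' audio, the format produced by [write_wav()] and by typical field
#' recorders. Samples are returned rescaled to `[-1, 1]`.
#'
#' @param path Path to a `.wav` file (mono, 16-bit PCM).
#' @return A list with `samples` (numeric vector in `[-1, 1]`) and
#'   `sample_rate_hz`.
#' @seealso [write_wav()]
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stopf("not a RIFF file: %s", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stopf("not a WAVE file: %s", path)
  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(raw[1:2], "integer", 1, 2, endian = "little"),
        n_channels   = readBin(raw[3:4], "integer", 1, 2, endian = "little"),
        sample_rate  = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits         = readBin(raw[15:16], "integer", 1, 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      samples <- readBin(con, "integer", n = size %/% 2L, size = 2,
                         signed = TRUE, endian = "little")
    } else {
      invisible(readBin(con, "raw", size + size %% 2L))
    }
    if (!is.null(fmt) && !is.null(samples)) break
  }
  if (is.null(fmt) || is.null(samples)) stopf("malformed WAV file: %s", path)
  if (fmt$audio_format != 1L || fmt$bits != 16L)
    stopf("only 16-bit PCM WAV supported (got format %d, %d bits)",
          fmt$audio_format, fmt$bits)
  if (fmt$n_channels != 1L) stopf("only mono WAV supported")
  list(samples = samples / 32768, sample_rate_hz = fmt$sample_rate)
}

#' Write a mono PCM WAV file
#'
#' Writes samples in `[-1, 1]` as a mono 16-bit PCM RIFF/WAVE file. Output is
#' byte-stable: the same samples always produce the same file.
#'
#' @param samples Numeric vector in `[-1, 1]`; values outside are clipped.
#' @param path Output path.
#' @param sample_rate_hz Sampling rate in Hz (default 48000).
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, sample_rate_hz = 48000) {
  x <- pmin(pmax(samples, -1), 1)
  pcm <- as.integer(round(x * 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(sample_rate_hz), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate_hz * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")          # block align
  writeBin(16L, con, size = 2, endian = "little")         # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
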