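#' Write a mono 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE writer for the canonical interchange format of this
#' pipeline: mono, 16-bit signed PCM. Samples are clipped to [-1, 1] and
#' quantized with round-to-nearest at a full-scale of 32767.
#'
#' @param samples Numeric vector of samples in [-1, 1].
#' @param path Output file path.
#' @param sample_rate Sampling rate in Hz.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, sample_rate) {
  stopifnot(is.numeric(samples), length(samples) > 0, sample_rate > 0)
  pcm <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' Counterpart of [write_wav()]. Walks the RIFF chunk list, requires a
#' mono 16-bit PCM `fmt ` chunk, and returns samples rescaled to
#' [-1, 1] (division by 32767, so write/read round-trips are exact at
#' the 16-bit grid).
#'
#' @param path Input file path.
#' @return List with `samples` (numeric vector) and `sample_rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(readChar(con, 4), "RIFF")) stopf("not a RIFF file: %s", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  if (!identical(readChar(con, 4), "WAVE")) stopf("not a WAVE file: %s", path)
  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(raw[1:2], "integer", 1, size = 2, endian = "little"),
        channels = readBin(raw[3:4], "integer", 1, size = 2, endian = "little"),
        sample_rate = readBin(raw[5:8], "integer", 1, size = 4, endian = "little"),
        bits = readBin(raw[15:16], "integer", 1, size = 2, endian = "little")
      )
    } else if (id == "data") {
      samples <- readBin(con, "integer", sz %/% 2L, size = 2,
                         signed = TRUE, endian = "little")
    } else {
      readBin(con, "raw", sz)
    }
    if (sz %% 2L == 1L) readBin(con, "raw", 1)  # RIFF chunks are word-aligned
    if (!is.null(fmt) && !is.null(samples)) break
  }
  if (is.null(fmt) || is.null(samples)) stopf("missing fmt/data chunk: %s", path)
  if (fmt$audio_format != 1L || fmt$channels != 1L || fmt$bits != 16L) {
    stopf("only mono 16-bit PCM WAV is supported (got format=%d channels=%d bits=%d)",
          fmt$audio_format, fmt$channels, fmt$bits)
  }
  list(samples = samples / 32767, sample_rate = fmt$sample_rate)
}
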