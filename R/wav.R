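# Minimal RIFF/WAVE PCM16 reader and writer.
#
# The pipeline's on-disk audio interchange format is plain multichannel
# 16-bit PCM WAV at 4000 Hz; no WAV package ships with the target library so
# the (small, fully specified) container is handled here directly.

#' Write a multichannel WAV file (16-bit PCM)
#'
#' @param samples `channels x time` numeric matrix (or a vector for mono),
#'   expected in `[-1, 1]`; values are clipped.
#' @param sample_rate sampling rate in Hz.
#' @param path output file.
#' @export
write_wav <- function(samples, sample_rate, path) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1)
  n_ch <- nrow(samples)
  n <- ncol(samples)
  x <- pmax(pmin(samples, 1), -1)
  ints <- matrix(as.integer(round(x * 32767)), nrow = n_ch)
  interleaved <- as.integer(ints)  # column-major = frame-major = interleaved
  block_align <- n_ch * 2L
  data_bytes <- n * block_align
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                 # PCM
  writeBin(n_ch, con, size = 2, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * block_align), con, size = 4, endian = "little")
  writeBin(block_align, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")                # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(interleaved, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a multichannel WAV file (16-bit PCM)
#'
#' @param path WAV file written by [write_wav()] or any PCM16 RIFF file.
#' @return list with `samples` (`channels x time` matrix in `[-1, 1]`) and
#'   `sample_rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  n_ch <- NULL; fs <- NULL; bits <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stop("only PCM WAV supported")
      n_ch <- fmt[2]
      fs <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      invisible(readBin(con, integer(), size = 2, endian = "little"))
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (bits != 16L) stop("only 16-bit PCM supported")
      extra <- size - 16L
      if (extra > 0) invisible(readBin(con, raw(), n = extra))
    } else if (identical(id, "data")) {
      data <- readBin(con, integer(), n = size %/% 2L, size = 2,
                      endian = "little")
      break
    } else {
      invisible(readBin(con, raw(), n = size))
    }
  }
  if (is.null(data) || is.null(n_ch)) stop("malformed WAV: ", path)
  samples <- matrix(data / 32767, nrow = n_ch)
  list(samples = samples, sample_rate = fs)
}
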