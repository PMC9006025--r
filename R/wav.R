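# Minimal mono RIFF/WAVE reader and writer (16-bit PCM and 32-bit float).
# All analyses are within-recording contrasts, so samples are kept on the
# normalized [-1, 1] full scale.

#' Read a mono WAV file
#'
#' Supports 16-bit PCM and 32-bit IEEE float, single channel.
#'
#' @param path WAV path.
#' @return list with `samples` (numeric, full scale `[-1, 1]`) and
#'   `sample_rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, 2, endian = "little",
                               signed = FALSE),
        channels = readBin(con, "integer", 1, 2, endian = "little",
                           signed = FALSE),
        sample_rate = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate = readBin(con, "integer", 1, 4, endian = "little"),
        block_align = readBin(con, "integer", 1, 2, endian = "little",
                              signed = FALSE),
        bits = readBin(con, "integer", 1, 2, endian = "little",
                       signed = FALSE))
      if (size > 16) invisible(readBin(con, "raw", size - 16))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data before fmt chunk")
      if (fmt$channels != 1L) stop("only mono WAV supported")
      if (fmt$audio_format == 1L && fmt$bits == 16L) {
        n <- size %/% 2L
        samples <- readBin(con, "integer", n, 2, signed = TRUE,
                           endian = "little") / 32768
      } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
        n <- size %/% 4L
        samples <- readBin(con, "numeric", n, 4, endian = "little")
      } else stop("unsupported WAV encoding (need PCM16 or float32)")
    } else {
      invisible(readBin(con, "raw", size))
    }
    if (!is.null(fmt) && !is.null(samples)) break
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  list(samples = samples, sample_rate = fmt$sample_rate)
}

#' Write a mono WAV file
#'
#' @param samples numeric vector on full scale `[-1, 1]` (clipped if
#'   outside).
#' @param sample_rate sampling rate in Hz.
#' @param path output path.
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path, bits = 16L) {
  stopifnot(bits %in% c(16L, 32L))
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(samples)
  bytes_per <- bits %/% 8L
  data_size <- n * bytes_per
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(if (bits == 16L) 1L else 3L, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")
  writeBin(as.integer(sample_rate), con, 4, endian = "little")
  writeBin(as.integer(sample_rate * bytes_per), con, 4, endian = "little")
  writeBin(as.integer(bytes_per), con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  s <- pmin(pmax(samples, -1), 1)
  if (bits == 16L) {
    writeBin(as.integer(round(s * 32767)), con, 2, endian = "little")
  } else {
    writeBin(as.numeric(s), con, 4, endian = "little")
  }
  invisible(path)
}
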