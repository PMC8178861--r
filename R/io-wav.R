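#' Audio signal container
#'
#' @param samples numeric vector of amplitudes in `[-1, 1]`.
#' @param rate sampling rate in Hz.
#' @return object of class `audio_signal`.
#' @export
audio_signal <- function(samples, rate) {
  stopifnot(is.numeric(samples), length(samples) >= 1L, rate > 0)
  structure(list(samples = as.numeric(samples), rate = as.numeric(rate)),
            class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal: %d samples @ %g Hz (%.2f s)>\n",
              length(x$samples), x$rate, length(x$samples) / x$rate))
  invisible(x)
}

#' Read a PCM WAV file
#'
#' Minimal RIFF/WAVE reader for uncompressed integer PCM (8/16/32 bit).
#' Samples are scaled to `[-1, 1]`; stereo input is downmixed by channel mean.
#'
#' @param path WAV file path.
#' @return an [audio_signal()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE),
        channels = readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE),
        rate = readBin(con, "integer", 1, size = 4, endian = "little"),
        byte_rate = readBin(con, "integer", 1, size = 4, endian = "little"),
        block_align = readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE),
        bits = readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE))
      extra <- sz - 16L
      if (extra > 0L) invisible(readBin(con, "raw", extra))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (sz %% 2L == 1L) invisible(readBin(con, "raw", 1))
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2L))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("missing fmt/data chunk in ", path)
  if (fmt$audio_format != 1L) stop("only uncompressed PCM WAV is supported")
  bytes <- fmt$bits %/% 8L
  n <- length(data_raw) %/% bytes
  x <- switch(as.character(fmt$bits),
    "8"  = (as.numeric(readBin(data_raw, "integer", n, size = 1, signed = FALSE)) - 128) / 128,
    "16" = as.numeric(readBin(data_raw, "integer", n, size = 2, endian = "little")) / 32768,
    "32" = as.numeric(readBin(data_raw, "integer", n, size = 4, endian = "little")) / 2147483648,
    stop("unsupported bit depth: ", fmt$bits))
  if (fmt$channels > 1L) {
    x <- colMeans(matrix(x, nrow = fmt$channels))
  }
  audio_signal(x, fmt$rate)
}

#' Write a 16-bit PCM WAV file
#'
#' @param audio an [audio_signal()]; samples are clipped to `[-1, 1]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(audio, path) {
  stopifnot(inherits(audio, "audio_signal"))
  x <- pmin(1, pmax(-1, audio$samples))
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_sz <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_sz), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                  # PCM
  writeBin(1L, con, size = 2, endian = "little")                  # mono
  writeBin(as.integer(audio$rate), con, size = 4, endian = "little")
  writeBin(as.integer(audio$rate) * 2L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_sz, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
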