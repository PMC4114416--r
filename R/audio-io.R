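# Minimal RIFF/WAVE reader and writer (PCM 8/16/24/32-bit and IEEE float),
# sufficient for the monitor's clip exchange formats.

#' Read a WAV file into an AudioRecording
#'
#' Multi-channel files are mean-downmixed to mono; integer PCM is rescaled to
#' \[-1, 1\]. When `targetRate` differs from the file's rate the signal is
#' resampled with an anti-aliasing polyphase filter (via [signal::resample]).
#'
#' @param path path to a PCM or IEEE-float WAV file.
#' @param targetRate optional working sample rate in Hz; NULL keeps the
#'   file's rate.
#' @param startTime optional recording start (seconds since epoch).
#' @return An [AudioRecording-class].
#' @export
readWav <- function(path, targetRate = NULL, startTime = NA_real_) {
  if (!file.exists(path)) stop("cannot read WAV: file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  readBin(con, "integer", 1, 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE"))
    stop("corrupt or non-WAV file: ", path)

  fmt <- NULL; raw_data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      fmt <- list(
        audioFormat = readBin(body[1:2], "integer", 1, 2, endian = "little"),
        nChannels   = readBin(body[3:4], "integer", 1, 2, endian = "little"),
        sampleRate  = readBin(body[5:8], "integer", 1, 4, endian = "little"),
        bits        = readBin(body[15:16], "integer", 1, 2, endian = "little"))
    } else if (identical(id, "data")) {
      raw_data <- readBin(con, "raw", sz)
    } else {
      readBin(con, "raw", sz)
    }
    if (sz %% 2L == 1L) readBin(con, "raw", 1L)  # chunk padding
    if (!is.null(fmt) && !is.null(raw_data)) break
  }
  if (is.null(fmt) || is.null(raw_data))
    stop("corrupt WAV (missing fmt or data chunk): ", path)
  if (length(raw_data) == 0L) stop("zero-length audio in ", path)

  bytes <- fmt$bits %/% 8L
  n <- length(raw_data) %/% bytes
  x <- if (fmt$audioFormat == 3L) {        # IEEE float
    readBin(raw_data, "numeric", n, size = bytes, endian = "little")
  } else if (fmt$bits == 8L) {             # unsigned 8-bit PCM
    (as.numeric(readBin(raw_data, "integer", n, 1, signed = FALSE)) - 128) / 128
  } else if (fmt$bits == 16L) {
    readBin(raw_data, "integer", n, 2, signed = TRUE,
            endian = "little") / 32768
  } else if (fmt$bits == 24L) {
    m <- matrix(as.integer(raw_data), nrow = 3)
    v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
    v[v >= 8388608] <- v[v >= 8388608] - 16777216
    v / 8388608
  } else if (fmt$bits == 32L) {
    readBin(raw_data, "integer", n, 4, signed = TRUE,
            endian = "little") / 2147483648
  } else stop("unsupported WAV bit depth: ", fmt$bits)

  if (fmt$nChannels > 1L) {
    n_use <- (length(x) %/% fmt$nChannels) * fmt$nChannels
    x <- colMeans(matrix(x[seq_len(n_use)], nrow = fmt$nChannels))
  }
  if (length(x) == 0L) stop("zero-length audio in ", path)

  rate <- fmt$sampleRate
  if (!is.null(targetRate) && targetRate != rate) {
    f <- MASSlikeRatio(targetRate, rate)
    x <- as.numeric(signal::resample(x, f[1], f[2]))
    x[x > 1] <- 1; x[x < -1] <- -1
    rate <- targetRate
  }
  audioRecording(x, rate, startTime)
}

# integer resampling ratio p/q in lowest terms
MASSlikeRatio <- function(p, q) {
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  d <- g(round(p), round(q))
  c(round(p) / d, round(q) / d)
}

#' Write an AudioRecording to a WAV file
#'
#' @param rec an [AudioRecording-class].
#' @param path output path.
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
writeWav <- function(rec, path, bits = 16L) {
  x <- samples(rec)
  rate <- as.integer(sampleRate(rec))
  con <- file(path, "wb")
  on.exit(close(con))
  isFloat <- bits == 32L
  bytes <- as.integer(bits %/% 8L)
  dataSize <- length(x) * bytes
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + dataSize), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(as.integer(if (isFloat) 3L else 1L), con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")
  writeBin(rate, con, 4, endian = "little")
  writeBin(as.integer(rate * bytes), con, 4, endian = "little")
  writeBin(bytes, con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(dataSize), con, 4, endian = "little")
  if (isFloat) {
    writeBin(x, con, size = 4, endian = "little")
  } else {
    q <- as.integer(pmax(-32768, pmin(32767, round(x * 32767))))
    writeBin(q, con, size = 2, endian = "little")
  }
  invisible(path)
}
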