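#' Read a mono WAV file
#'
#' Minimal RIFF/WAVE reader covering the formats this pipeline uses:
#' integer PCM (16- or 24-bit) and IEEE float (32- or 64-bit). Multichannel
#' files are reduced to their first channel with a warning. Files sampled at
#' a rate other than `target_rate_hz` are resampled on load
#' (polyphase resampling via [signal::resample()]).
#'
#' @param path Path to a `.wav` file.
#' @param target_rate_hz Rate to resample to, or `NULL` to keep the file's
#'   native rate. Default 44100 Hz, the rate the whole pipeline runs at.
#' @return A [wave] with samples scaled to \[-1, 1\] full scale.
#' @export
read_wav <- function(path, target_rate_hz = 44100) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1L, 4L, endian = "little")  # total size, unused
  wave_id <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave_id, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1L, 2L, endian = "little"),
        n_channels   = readBin(body[3:4], "integer", 1L, 2L, endian = "little"),
        rate_hz      = readBin(body[5:8], "integer", 1L, 4L, endian = "little"),
        bits         = readBin(body[15:16], "integer", 1L, 2L, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      readBin(con, "raw", sz)  # skip unknown chunk
    }
    if (sz %% 2L == 1L) readBin(con, "raw", 1L)  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("missing fmt/data chunk: ", path)

  bytes <- fmt$bits %/% 8L
  n <- length(data_raw) %/% bytes
  x <- switch(
    as.character(fmt$audio_format),
    "1" = {  # integer PCM
      if (fmt$bits == 16L) {
        readBin(data_raw, "integer", n, 2L, signed = TRUE,
                endian = "little") / 32768
      } else if (fmt$bits == 24L) {
        b <- as.integer(data_raw)
        dim(b) <- c(3L, n)
        v <- b[1L, ] + 256L * b[2L, ] + 65536L * b[3L, ]
        ifelse(v >= 8388608L, v - 16777216L, v) / 8388608
      } else stop("unsupported PCM bit depth: ", fmt$bits)
    },
    "3" = {  # IEEE float
      if (!fmt$bits %in% c(32L, 64L))
        stop("unsupported float bit depth: ", fmt$bits)
      readBin(data_raw, "double", n, bytes, endian = "little")
    },
    stop("unsupported WAV audio format code: ", fmt$audio_format)
  )

  if (fmt$n_channels > 1L) {
    warning("multichannel WAV; using channel 1 of ", fmt$n_channels)
    x <- x[seq(1L, length(x), by = fmt$n_channels)]
  }
  rate <- fmt$rate_hz
  if (!is.null(target_rate_hz) && rate != target_rate_hz) {
    x <- signal::resample(x, p = target_rate_hz, q = rate)
    rate <- target_rate_hz
  }
  wave(x, rate)
}

#' Write a mono WAV file
#'
#' @param x A [wave] (or numeric vector with `rate_hz` given).
#' @param path Output path.
#' @param bits 32 (IEEE float, exact round trip, the default) or 16
#'   (integer PCM, clipped to \[-1, 1\]).
#' @param rate_hz Sampling rate, taken from `x` when it is a `wave`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, bits = 32, rate_hz = NULL) {
  rate <- if (inherits(x, "wave")) rate_hz(x) else rate_hz
  if (is.null(rate)) stop("rate_hz required for plain numeric input")
  samples <- as.numeric(x)
  bytes <- bits %/% 8L
  fmt_code <- if (bits == 32) 3L else if (bits == 16) 1L else
    stop("bits must be 16 or 32")
  data_size <- length(samples) * bytes

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(fmt_code, con, 2L, endian = "little")
  writeBin(1L, con, 2L, endian = "little")              # mono
  writeBin(as.integer(rate), con, 4L, endian = "little")
  writeBin(as.integer(rate * bytes), con, 4L, endian = "little")
  writeBin(as.integer(bytes), con, 2L, endian = "little")
  writeBin(as.integer(bits), con, 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4L, endian = "little")
  if (bits == 32) {
    writeBin(samples, con, 4L, endian = "little")
  } else {
    q <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
    writeBin(q, con, 2L, endian = "little")
  }
  invisible(path)
}
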