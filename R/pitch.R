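#' Pitch track constructor
#'
#' A pitch track is a per-frame time series of the fundamental frequency
#' f0(t) of a speech signal, with a voicing flag per frame. f0 is defined
#' exactly on voiced frames; summary statistics (mean, SD) are computed over
#' voiced frames only, since they parameterize the passband of the
#' fundamental-waveform filter (mean f0 +/- 0.5 SD).
#'
#' @param times_s Frame-center times, seconds, strictly increasing.
#' @param f0_hz Fundamental frequency per frame (Hz); `NA` on unvoiced frames.
#' @param f0_range Admissible f0 range in Hz; values outside it are an error.
#' @param require_voiced Error when no frame is voiced (the default; a track
#'   without any voiced frame has no defined passband). [estimate_pitch()]
#'   relaxes this so that e.g. a pure-noise input yields an all-unvoiced
#'   track rather than an error.
#' @return A `pitch_track`: a data.frame with columns `time_s`, `f0_hz`,
#'   `voiced`, and attributes `mean_f0_hz`, `sd_f0_hz`.
#' @export
pitch_track <- function(times_s, f0_hz, f0_range = c(40, 400),
                        require_voiced = TRUE) {
  if (length(times_s) != length(f0_hz))
    stop("times_s and f0_hz must have equal length")
  if (is.unsorted(times_s, strictly = TRUE))
    stop("frame times must be strictly increasing")
  voiced <- is.finite(f0_hz)
  if (require_voiced && !any(voiced)) stop("no voiced frames")
  f0v <- f0_hz[voiced]
  if (any(f0v < f0_range[1] | f0v > f0_range[2]))
    stop("f0 outside the admissible range [", f0_range[1], ", ",
         f0_range[2], "] Hz")
  out <- data.frame(time_s = as.numeric(times_s),
                    f0_hz = ifelse(voiced, as.numeric(f0_hz), NA_real_),
                    voiced = voiced)
  structure(out,
            mean_f0_hz = if (any(voiced)) mean(f0v) else NA_real_,
            sd_f0_hz = if (sum(voiced) > 1L) stats::sd(f0v) else NA_real_,
            class = c("pitch_track", "data.frame"))
}

#' @export
print.pitch_track <- function(x, ...) {
  cat(sprintf("<pitch_track> %d frames (%.0f%% voiced), f0 = %.1f +/- %.1f Hz\n",
              nrow(x), 100 * mean(x$voiced),
              attr(x, "mean_f0_hz"), attr(x, "sd_f0_hz")))
  invisible(x)
}

#' Mean and SD of f0 over voiced frames
#' @param pitch A [pitch_track].
#' @return Named numeric vector `c(mean, sd)` in Hz.
#' @export
f0_stats <- function(pitch) {
  c(mean = attr(pitch, "mean_f0_hz"), sd = attr(pitch, "sd_f0_hz"))
}

#' Read a pitch track from CSV
#'
#' Expects a header `time_s,f0_hz`; empty or NaN f0 entries mark unvoiced
#' frames. This is the import path for pitch tracks produced by external
#' speech-analysis tools.
#'
#' @param path CSV file path.
#' @return A [pitch_track].
#' @export
load_pitch_track <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "f0_hz")
  if (!all(need %in% names(df)))
    stop("pitch CSV must have columns time_s, f0_hz (got: ",
         paste(names(df), collapse = ", "), ")")
  f0 <- suppressWarnings(as.numeric(df$f0_hz))
  pitch_track(df$time_s, f0)
}

#' Write a pitch track to CSV
#' @param pitch A [pitch_track].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pitch_track <- function(pitch, path) {
  out <- data.frame(time_s = pitch$time_s,
                    f0_hz = ifelse(pitch$voiced, pitch$f0_hz, NA_real_))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Estimate the fundamental frequency of speech
#'
#' Frame-wise pitch tracker based on the peak of the normalized
#' autocorrelation within the lag range corresponding to `search_hz`.
#' Frames whose peak normalized autocorrelation falls below
#' `voicing_threshold` are marked unvoiced. The peak lag is refined by
#' parabolic interpolation around the autocorrelation maximum.
#'
#' @param speech A [wave] with the speech signal.
#' @param frame_s Analysis frame length, seconds (default 40 ms).
#' @param hop_s Frame hop, seconds (default 10 ms).
#' @param search_hz Two-element f0 search range in Hz (default 40-400).
#' @param voicing_threshold Minimum normalized autocorrelation for a frame
#'   to count as voiced (default 0.45).
#' @return A [pitch_track] on the frame-center grid.
#' @export
estimate_pitch <- function(speech, frame_s = 0.040, hop_s = 0.010,
                           search_hz = c(40, 400),
                           voicing_threshold = 0.45) {
  fs <- rate_hz(speech)
  x <- as.numeric(speech)
  frame_n <- round(frame_s * fs)
  hop_n <- max(1L, round(hop_s * fs))
  if (frame_n > length(x)) stop("frame longer than the signal")
  lag_min <- max(2L, floor(fs / search_hz[2]))
  lag_max <- ceiling(fs / search_hz[1])
  if (lag_max >= frame_n)
    stop("frame too short for the lower f0 search bound")

  starts <- seq(1L, length(x) - frame_n + 1L, by = hop_n)
  times <- (starts - 1L + frame_n / 2) / fs
  f0 <- rep(NA_real_, length(starts))

  for (k in seq_along(starts)) {
    seg <- x[starts[k]:(starts[k] + frame_n - 1L)]
    seg <- seg - mean(seg)
    e0 <- sum(seg^2)
    if (e0 <= 0) next
    # normalized autocorrelation over the candidate lag range, via FFT
    nfft <- stats::nextn(2L * frame_n, 2L)
    sp <- stats::fft(c(seg, numeric(nfft - frame_n)))
    ac <- Re(stats::fft(sp * Conj(sp), inverse = TRUE)) / nfft
    r <- ac[(lag_min:lag_max) + 1L] / ac[1L]
    i <- which.max(r)
    if (r[i] < voicing_threshold) next
    lag <- lag_min + i - 1L
    # parabolic refinement of the peak lag
    if (i > 1L && i < length(r)) {
      d <- (r[i - 1L] - r[i + 1L]) / (2 * (r[i - 1L] - 2 * r[i] + r[i + 1L]))
      if (is.finite(d) && abs(d) < 1) lag <- lag + d
    }
    cand <- fs / lag
    if (cand >= search_hz[1] && cand <= search_hz[2]) f0[k] <- cand
  }
  pitch_track(times, f0, f0_range = search_hz, require_voiced = FALSE)
}
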