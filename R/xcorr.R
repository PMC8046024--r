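# Detection of the speech-DPOAE in an ear-canal recording: normalized
# complex cross-correlation of the recording with the distortion-product
# template, envelope smoothing, noise floor from off-peak lags, and peak
# extraction in the physiological 0-7 ms latency window.

#' Microphone recording container
#'
#' @param samples Numeric amplitude vector r(t).
#' @param rate_hz Sampling frequency, Hz.
#' @return A `mic_recording` (subclass of [wave]).
#' @export
mic_recording <- function(samples, rate_hz) {
  wave(samples, rate_hz, class = "mic_recording")
}

#' Normalized complex cross-correlation of a recording with a template
#'
#' Computes
#'   C(tau) = N * sum_t r(t + tau) * (w(t) + i H\[w(t)\])
#' on an integer-sample lag grid covering `-max_lag_s .. +max_lag_s`.
#' Positive lag means the recording's matching content FOLLOWS the template.
#' The normalization N = 1 / (||r|| ||w||), with the energy of the real
#' template, makes the auto cross-correlation equal exactly 1 at zero lag
#' (`r = w` gives `C(0) = 1`), and bounds |C| by 1.
#'
#' @param r A `mic_recording` (or any [wave]).
#' @param template A `harmonic_wave` template (or any [wave]).
#' @param max_lag_s Half-width of the lag axis, seconds (default 0.75 s,
#'   wide enough for the off-peak noise windows).
#' @return A `correlogram`: list with `lags_s`, complex `values`,
#'   `normalization_n`, `rate_hz`, and (after [smooth_envelope()])
#'   `smoothed_amplitude`, `smoothing_len`.
#' @export
complex_xcorr <- function(r, template, max_lag_s = 0.75) {
  stopifnot_same_rate(r, template)
  fs <- rate_hz(r)
  w <- as.numeric(template)
  x <- as.numeric(r)
  if (all(w == 0)) stop("all-zero template: normalization undefined")
  if (all(x == 0)) stop("all-zero recording: normalization undefined")
  a <- as.complex(analytic(template))
  nr <- length(x); nw <- length(w)
  lag_n <- round(max_lag_s * fs)
  if (lag_n > min(nr, nw) - 1L)
    stop("signals too short for a ", max_lag_s, " s lag range")

  # c[tau] = sum_t a[t] x[t + tau] via FFT convolution of x with rev(a)
  m <- stats::nextn(nr + nw - 1L, 2L)
  z <- stats::fft(stats::fft(c(x, numeric(m - nr))) *
                  stats::fft(c(rev(a), complex(m - nw))),
                  inverse = TRUE) / m
  taus <- (-lag_n):lag_n
  values <- z[taus + nw]          # conv index k = tau + nw
  nrm <- 1 / (sqrt(sum(x^2)) * sqrt(sum(w^2)))
  structure(list(lags_s = taus / fs,
                 values = values * nrm,
                 normalization_n = nrm,
                 rate_hz = fs,
                 smoothed_amplitude = NULL,
                 smoothing_len = NULL),
            class = "correlogram")
}

#' @export
print.correlogram <- function(x, ...) {
  cat(sprintf("<correlogram> lags %.0f..%.0f ms (%d), %s\n",
              1000 * min(x$lags_s), 1000 * max(x$lags_s), length(x$lags_s),
              if (is.null(x$smoothed_amplitude)) "unsmoothed"
              else sprintf("smoothed (%d samples)", x$smoothing_len)))
  invisible(x)
}

# centered moving average with reflect padding
moving_average_reflect <- function(x, len) {
  h <- (len - 1L) %/% 2L
  n <- length(x)
  if (h == 0L) return(x)
  if (h > n - 1L) stop("smoothing window longer than the signal")
  padded <- c(x[(h + 1L):2L], x, x[(n - 1L):(n - h)])
  cs <- cumsum(c(0, padded))
  (cs[(len + 1L):(len + n)] - cs[1L:n]) / len
}

#' Smooth the envelope of a complex correlogram
#'
#' Applies a centered moving average (reflect padding at the ends) to the
#' amplitude |C(tau)|. The complex values themselves are untouched; phase is
#' always read from the unsmoothed correlogram.
#'
#' @param c A `correlogram`.
#' @param len_samples Odd moving-average length in samples (default 199).
#' @return The correlogram with `smoothed_amplitude` and `smoothing_len` set.
#' @export
smooth_envelope <- function(c, len_samples = 199L) {
  if (len_samples %% 2L != 1L) stop("smoothing length must be odd")
  c$smoothed_amplitude <- moving_average_reflect(Mod(c$values),
                                                 as.integer(len_samples))
  c$smoothing_len <- as.integer(len_samples)
  c
}

#' Noise floor of a correlogram
#'
#' The 95th percentile of the smoothed correlation amplitude over the
#' off-peak lag windows -750..-70 ms and +70..+750 ms, where no
#' short-latency emission can contribute.
#'
#' @param c A smoothed `correlogram` (see [smooth_envelope()]).
#' @param window_s Inner and outer edge of the two symmetric noise windows,
#'   seconds (default `c(0.07, 0.75)`).
#' @param probs Percentile used (default 0.95).
#' @return The noise floor (unitless normalized correlation amplitude).
#' @export
noise_floor <- function(c, window_s = c(0.07, 0.75), probs = 0.95) {
  if (is.null(c$smoothed_amplitude))
    stop("smooth the correlogram first (smooth_envelope)")
  lag <- abs(c$lags_s)
  if (max(c$lags_s) < window_s[2] - 1e-9 || min(c$lags_s) > -window_s[2] + 1e-9)
    stop("lag axis does not cover the +/-", window_s[2], " s noise windows")
  sel <- lag >= window_s[1] & lag <= window_s[2]
  stats::quantile(c$smoothed_amplitude[sel], probs, names = FALSE)
}

#' Locate the emission peak in a correlogram
#'
#' Finds the maximum of the smoothed correlation amplitude within the
#' latency search window (default 0-7 ms). The latency is the lag of the
#' maximum (earliest lag on exact ties), the phase is taken from the
#' unsmoothed complex correlation at that lag, and the result is flagged
#' significant when the peak amplitude exceeds the noise floor.
#'
#' @param c A smoothed `correlogram`.
#' @param floor Noise floor from [noise_floor()].
#' @param window_s Latency search window, seconds (default `c(0, 0.007)`).
#' @return A `dpoae_result`: list with `peak_amplitude`, `latency_s`,
#'   `phase_rad`, `noise_floor`, `significant`, `search_window_s`.
#' @export
find_peak <- function(c, floor, window_s = c(0, 0.007)) {
  if (is.null(c$smoothed_amplitude))
    stop("smooth the correlogram first (smooth_envelope)")
  sel <- which(c$lags_s >= window_s[1] - 1e-12 &
               c$lags_s <= window_s[2] + 1e-12)
  if (length(sel) == 0L) stop("empty latency search window")
  amp <- c$smoothed_amplitude[sel]
  i <- sel[which.max(amp)]          # which.max: first (earliest) on ties
  structure(list(peak_amplitude = c$smoothed_amplitude[i],
                 latency_s = c$lags_s[i],
                 phase_rad = Arg(c$values[i]),
                 noise_floor = floor,
                 significant = c$smoothed_amplitude[i] > floor,
                 search_window_s = window_s),
            class = "dpoae_result")
}

#' @export
print.dpoae_result <- function(x, ...) {
  cat(sprintf(paste0("<dpoae_result> amplitude %.3g at %.2f ms, ",
                     "phase %.2f rad, floor %.3g -> %s\n"),
              x$peak_amplitude, 1000 * x$latency_s, x$phase_rad,
              x$noise_floor, if (x$significant) "significant"
              else "not significant"))
  invisible(x)
}

#' Estimate the equipment (probe/system) delay
#'
#' Cross-correlates the recording with each of the two eliciting harmonic
#' waveforms; the lag of the maximum smoothed correlation amplitude is the
#' per-waveform delay, and the equipment delay is the mean of the two. A
#' warning is issued when the two delays differ by more than 0.5 ms, and an
#' error when either waveform's correlation peak does not rise above the
#' off-peak noise floor (the eliciting stimuli are then not present in the
#' recording).
#'
#' @param r A `mic_recording`.
#' @param eliciting List of the two eliciting `harmonic_wave`s.
#' @param search_s Lag window searched for the stimulus peak, seconds.
#' @param max_lag_s Lag range of the underlying correlograms.
#' @return Equipment delay in seconds.
#' @export
estimate_equipment_delay <- function(r, eliciting,
                                     search_s = c(-0.005, 0.02),
                                     max_lag_s = 0.75) {
  if (length(eliciting) != 2L) stop("need exactly two eliciting waveforms")
  delays <- vapply(eliciting, function(w) {
    cg <- smooth_envelope(complex_xcorr(r, w, max_lag_s = max_lag_s))
    fl <- noise_floor(cg)
    pk <- find_peak(cg, fl, window_s = search_s)
    if (!pk$significant)
      stop("eliciting stimuli not found in the recording ",
           "(no correlation peak above the noise floor)")
    pk$latency_s
  }, numeric(1))
  if (abs(delays[1] - delays[2]) > 5e-4)
    warning(sprintf("per-waveform equipment delays differ by %.2f ms",
                    1000 * abs(delays[1] - delays[2])))
  mean(delays)
}

# trim a wave by n samples at each end, keeping voiced-run bookkeeping valid
trim_wave <- function(x, n_head, n_tail = n_head) {
  n <- length(x)
  keep <- (n_head + 1L):(n - n_tail)
  out <- wave_like(as.numeric(x)[keep], x)
  runs <- attr(out, "voiced_runs")
  if (!is.null(runs)) {
    runs[, "start"] <- pmax(1L, runs[, "start"] - n_head)
    runs[, "end"] <- pmin(length(out), runs[, "end"] - n_head)
    attr(out, "voiced_runs") <- runs[runs[, "end"] >= runs[, "start"], ,
                                     drop = FALSE]
  }
  out
}

#' Trim and delay-compensate a recording
#'
#' Removes `trim_s` seconds from each end of the recording (transient
#' activity at recording onset/offset) and compensates the equipment delay
#' by advancing the content by `delay_s`, so that a subsequent
#' [estimate_equipment_delay()] reads zero. Works on templates too (pass
#' `delay_s = 0`), so recording and template stay sample-aligned.
#'
#' @param r A [wave] or `mic_recording`.
#' @param trim_s Seconds removed from each end (default 3).
#' @param delay_s Equipment delay to compensate, seconds (default 0).
#' @return The trimmed, delay-compensated wave; attribute
#'   `compensated_delay_s` records the shift.
#' @export
preprocess <- function(r, trim_s = 3, delay_s = 0) {
  fs <- rate_hz(r)
  trim_n <- round(trim_s * fs)
  delay_n <- round(delay_s * fs)
  if (length(r) <= 2L * trim_n + delay_n)
    stop("recording too short for trimming (", length(r) / fs, " s)")
  out <- trim_wave(r, trim_n + delay_n, trim_n)
  attr(out, "compensated_delay_s") <- delay_n / fs
  attr(out, "trim_s") <- trim_s
  out
}
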