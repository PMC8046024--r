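# Fundamental waveform w0(t): the speech signal bandpass filtered around its
# fundamental frequency, gated to zero on unvoiced stretches.

# Zero-phase Butterworth bandpass, applied in the frequency domain.
#
# A forward-backward pass of a Butterworth bandpass H applies the real,
# non-negative gain |H(f)|^2 with exactly zero phase. We apply that gain
# directly to the FFT of the signal, using the closed-form magnitude of the
# bilinear-transformed Butterworth bandpass (bilinear prewarping
# w = tan(pi f / fs)). For an order-`order` bandpass (order/2 lowpass
# prototype poles mapped to the band), |H|^2 = 1 / (1 + Q^order) with
# Q = (w^2 - wl*wh) / ((wh - wl) * w). This realization is numerically
# robust at narrow low-frequency passbands where the (b, a) transfer-function
# form of the same filter is ill-conditioned, and is exactly equivariant
# under time reversal.
zerophase_butter_bandpass <- function(x, fs, low_hz, high_hz, order = 6) {
  n <- length(x)
  if (n == 0L) return(x)
  # pad by 1 s so the narrowband impulse response cannot wrap around
  nfft <- stats::nextn(n + round(fs), 2L)
  f <- seq(0L, nfft - 1L) / nfft          # normalized frequency, cycles/sample
  f <- pmin(f, 1 - f)                      # fold to [0, 1/2]
  w <- tan(pi * f)
  wl <- tan(pi * low_hz / fs)
  wh <- tan(pi * high_hz / fs)
  q <- (w^2 - wl * wh) / ((wh - wl) * w)
  gain <- 1 / (1 + q^order)
  gain[!is.finite(gain)] <- 0              # DC (w = 0) and any overflow
  spec <- stats::fft(c(x, numeric(nfft - n)))
  y <- Re(stats::fft(spec * gain, inverse = TRUE)) / nfft
  y[seq_len(n)]
}

# Sample-wise voicing mask from a frame-wise pitch track: nearest-frame
# (piecewise-constant) interpolation of the voiced flags.
voiced_sample_mask <- function(pitch, n, fs) {
  t <- (seq_len(n) - 0.5) / fs
  v <- stats::approx(pitch$time_s, as.numeric(pitch$voiced), xout = t,
                     method = "constant", rule = 2, f = 0.5)$y
  v >= 0.5
}

# Start/end indices of runs of TRUE in a logical vector (matrix, 2 columns).
logical_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Extract the fundamental waveform w0(t) from speech
#'
#' Bandpass filters the speech around its fundamental frequency with a
#' zero-phase sixth-order Butterworth filter whose passband is the mean f0
#' plus/minus half the f0 standard deviation (both over voiced frames), then
#' gates the result so that unvoiced stretches are exactly zero. Short
#' raised-cosine ramps (default 5 ms) at the inner edges of each voiced
#' stretch avoid discontinuities; all samples outside voiced stretches are 0.
#' The filter introduces no group delay.
#'
#' @param speech A [wave] with the speech signal.
#' @param pitch A [pitch_track] covering the speech duration.
#' @param order Designed order of the Butterworth bandpass (default 6).
#' @param ramp_s Raised-cosine ramp length at voiced-stretch edges, seconds.
#' @return A `fundamental_wave` (subclass of [wave]) with attributes
#'   `passband_hz` (low, high) and `voiced_runs` (sample-index run matrix).
#' @export
extract_fundamental <- function(speech, pitch, order = 6, ramp_s = 0.005) {
  fs <- rate_hz(speech)
  if (!any(pitch$voiced)) {
    # nothing voiced: the fundamental waveform is identically zero
    return(wave(numeric(length(speech)), fs, class = "fundamental_wave",
                passband_hz = c(low = NA_real_, high = NA_real_),
                voiced_runs = cbind(start = integer(0), end = integer(0))))
  }
  st <- f0_stats(pitch)
  if (!is.finite(st["sd"]) || st["sd"] <= 0)
    stop("degenerate passband: f0 SD over voiced frames is zero or undefined")
  band <- c(st["mean"] - 0.5 * st["sd"], st["mean"] + 0.5 * st["sd"])
  names(band) <- c("low", "high")
  if (band["low"] < 20)
    stop("passband low edge below 20 Hz (", round(band["low"], 1), " Hz)")

  y <- zerophase_butter_bandpass(as.numeric(speech), fs,
                                 band["low"], band["high"], order = order)

  mask <- voiced_sample_mask(pitch, length(y), fs)
  runs <- logical_runs(mask)
  gate <- numeric(length(y))
  ramp_n <- round(ramp_s * fs)
  for (k in seq_len(nrow(runs))) {
    a <- runs[k, 1L]; b <- runs[k, 2L]
    len <- b - a + 1L
    g <- rep(1, len)
    m <- min(ramp_n, len %/% 2L)
    if (m > 0L) {
      ramp <- 0.5 * (1 - cos(pi * seq_len(m) / (m + 1L)))
      g[seq_len(m)] <- ramp
      g[len - m + seq_len(m)] <- rev(ramp)
    }
    gate[a:b] <- g
  }
  wave(y * gate, fs, class = "fundamental_wave",
       passband_hz = band, voiced_runs = runs)
}

#' Passband of a fundamental waveform
#' @param w0 A `fundamental_wave`.
#' @return Numeric `c(low, high)` in Hz.
#' @export
passband_hz <- function(w0) attr(w0, "passband_hz")

#' Voiced-stretch sample runs of a fundamental waveform
#' @param w0 A `fundamental_wave`.
#' @return Two-column integer matrix (`start`, `end`) of voiced runs.
#' @export
voiced_runs <- function(w0) attr(w0, "voiced_runs")
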