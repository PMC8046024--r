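# Conventional two-tone DPOAE analysis: power spectrum of the ear-canal
# recording, plus the same complex cross-correlation machinery the speech
# pipeline uses, applied to a fixed-frequency sinusoidal template. Serves as
# the cross-validation anchor for the speech method.

#' Pure-tone DPOAE measurement configuration
#'
#' @param f1_hz,f2_hz Primary frequencies, Hz, `f1 < f2`
#'   (defaults 1000 and 1200 Hz, primary ratio 1.2).
#' @param duration_s Stimulus duration, seconds (default 30).
#' @param level_rel Relative digital gain of each primary (default 1).
#' @return A `puretone_config` list.
#' @export
puretone_config <- function(f1_hz = 1000, f2_hz = 1200, duration_s = 30,
                            level_rel = 1) {
  if (f1_hz >= f2_hz) stop("need f1 < f2")
  structure(list(f1_hz = f1_hz, f2_hz = f2_hz,
                 duration_s = duration_s, level_rel = level_rel),
            class = "puretone_config")
}

#' Cubic distortion-product frequencies of a primary pair
#'
#' @param cfg A [puretone_config] (or anything with `f1_hz`, `f2_hz`).
#' @return Named numeric `c(lower, upper)` = (2 f1 - f2, 2 f2 - f1) in Hz.
#' @export
dp_frequencies <- function(cfg) {
  lower <- 2 * cfg$f1_hz - cfg$f2_hz
  upper <- 2 * cfg$f2_hz - cfg$f1_hz
  if (lower <= 0)
    stop("lower sideband 2 f1 - f2 = ", lower, " Hz is not positive")
  c(lower = lower, upper = upper)
}

# Hann-windowed single-periodogram amplitude spectrum
amplitude_spectrum <- function(x, fs) {
  n <- length(x)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
  sp <- stats::fft(x * win)
  half <- seq_len(n %/% 2L + 1L)
  list(freq_hz = (half - 1L) * fs / n,
       amplitude = Mod(sp[half]) * 2 / sum(win))
}

#' Pure-tone DPOAE by power spectrum
#'
#' Computes the amplitude spectrum of the recording (single full-length
#' Hann-windowed periodogram) and reads the distortion-product level at the
#' chosen sideband frequency. The noise level is the 95th percentile of the
#' spectral amplitudes in the two flanking bands 30-70 Hz below and above
#' the DP frequency; the DP is significant when its level exceeds that.
#'
#' @param r A `mic_recording`.
#' @param cfg A [puretone_config].
#' @param sideband `"lower"` (2 f1 - f2, default) or `"upper"` (2 f2 - f1).
#' @return A `puretone_result`: `dp_freq_hz`, `spectral_level`,
#'   `noise_level`, `significant` (relative amplitude units, dBFS-style).
#' @export
spectrum_analysis <- function(r, cfg, sideband = c("lower", "upper")) {
  sideband <- match.arg(sideband)
  fs <- rate_hz(r)
  if (fs / length(r) > 10)
    stop("frequency resolution coarser than 10 Hz; use a longer recording")
  fdp <- dp_frequencies(cfg)[[sideband]]
  sp <- amplitude_spectrum(as.numeric(r), fs)
  df <- sp$freq_hz[2L]
  # DP level: maximum over bins within half a bin plus 2 Hz of the nominal
  # frequency, tolerating spectral straddle
  near <- abs(sp$freq_hz - fdp) <= df / 2 + 2
  level <- max(sp$amplitude[near])
  flank <- (sp$freq_hz >= fdp - 70 & sp$freq_hz <= fdp - 30) |
           (sp$freq_hz >= fdp + 30 & sp$freq_hz <= fdp + 70)
  noise <- stats::quantile(sp$amplitude[flank], 0.95, names = FALSE)
  structure(list(dp_freq_hz = fdp, spectral_level = level,
                 noise_level = noise, significant = level > noise,
                 method = "spectrum"),
            class = "puretone_result")
}

#' Pure-tone DPOAE by complex cross-correlation
#'
#' Processes a two-tone recording with the same machinery as the speech
#' pipeline: the recording is cross-correlated with a sinusoid at the
#' lower-sideband DP frequency, the envelope smoothed (199 samples), and the
#' peak amplitude read in the 0-7 ms latency window. The noise level follows
#' the identical procedure with a sinusoid at an unrelated nearby reference
#' frequency (default 900 Hz), taking the 95th percentile of its smoothed
#' amplitude over the off-peak noise windows.
#'
#' @param r A `mic_recording`.
#' @param cfg A [puretone_config].
#' @param noise_ref_hz Reference frequency for the noise estimate; must not
#'   coincide with a primary or DP frequency (default 900 Hz).
#' @param smoothing_len Envelope moving-average length (default 199).
#' @return A `puretone_result` with `xcorr_amplitude`, `xcorr_latency_s`,
#'   `noise_level`, `significant`.
#' @export
xcorr_analysis <- function(r, cfg, noise_ref_hz = 900,
                           smoothing_len = 199L) {
  fs <- rate_hz(r)
  fdp <- dp_frequencies(cfg)[["lower"]]
  reserved <- c(cfg$f1_hz, cfg$f2_hz, dp_frequencies(cfg))
  if (any(abs(noise_ref_hz - reserved) < 1))
    stop("noise reference frequency coincides with a primary or DP tone")
  t <- (seq_along(r) - 1L) / fs
  dp_tmpl <- wave(sin(2 * pi * fdp * t), fs)
  ref_tmpl <- wave(sin(2 * pi * noise_ref_hz * t), fs)

  cg <- smooth_envelope(complex_xcorr(r, dp_tmpl), smoothing_len)
  cg_ref <- smooth_envelope(complex_xcorr(r, ref_tmpl), smoothing_len)
  noise <- noise_floor(cg_ref)
  pk <- find_peak(cg, noise)
  structure(list(dp_freq_hz = fdp, xcorr_amplitude = pk$peak_amplitude,
                 xcorr_latency_s = pk$latency_s, phase_rad = pk$phase_rad,
                 noise_level = noise, significant = pk$significant,
                 method = "xcorr"),
            class = "puretone_result")
}

#' @export
print.puretone_result <- function(x, ...) {
  lvl <- if (x$method == "spectrum") x$spectral_level else x$xcorr_amplitude
  cat(sprintf("<puretone_result:%s> DP %g Hz, level %.3g vs noise %.3g -> %s\n",
              x$method, x$dp_freq_hz, lvl, x$noise_level,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}
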