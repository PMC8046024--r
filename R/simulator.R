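# Virtual ear and stimulus generator. Produces speech-like harmonic stimuli
# with a known f0 trajectory and ear-canal recordings with known distortion
# amplitude, latency and phase, so that the pitch tracker, the harmonic
# shifter, the correlation detector and the attention statistics can all be
# validated against ground truth without hardware.

#' Specification of a synthetic speech-like signal
#'
#' @param f0_trajectory Either a constant f0 in Hz or a function of time
#'   (seconds) returning f0 in Hz; must stay within (40, 400) Hz. The
#'   default is a slow meander reproducing the male-voice statistics
#'   (f0 = 105 +/- 6 Hz over full cycles).
#' @param n_harmonics Number of harmonics (amplitude rolloff 1/k).
#' @param voiced_fraction Fraction of the duration that is voiced, 0-1.
#' @param duration_s Total duration, seconds.
#' @param rate_hz Sampling rate (default 44100).
#' @param seed Integer seed for the unvoiced noise.
#' @return A `speechlike_spec` list.
#' @export
speechlike_spec <- function(f0_trajectory = function(t)
                              105 + 6 * sqrt(2) * sin(2 * pi * 0.4 * t),
                            n_harmonics = 12L,
                            voiced_fraction = 0.8, duration_s = 10,
                            rate_hz = 44100, seed = 1L) {
  structure(list(f0_trajectory = f0_trajectory,
                 n_harmonics = as.integer(n_harmonics),
                 voiced_fraction = voiced_fraction,
                 duration_s = duration_s, rate_hz = rate_hz,
                 seed = as.integer(seed)),
            class = "speechlike_spec")
}

#' Synthesize a speech-like harmonic signal with known pitch
#'
#' Builds a sum of `n_harmonics` harmonics with common phase path
#' 2 pi * integral of f0(t) dt and 1/k amplitude rolloff, interrupted by
#' unvoiced gaps of low-level white noise so that `voiced_fraction` of the
#' duration is voiced (voiced stretches of about 1.5 s). Returns the signal
#' together with its ground-truth pitch track on a 10 ms frame grid.
#'
#' @param spec A [speechlike_spec].
#' @return List with `speech` (a [wave]), `pitch` (ground-truth
#'   [pitch_track]), `f0_hz` (sample-wise f0, NA in gaps).
#' @export
synth_speechlike <- function(spec) {
  fs <- spec$rate_hz
  n <- round(spec$duration_s * fs)
  t <- (seq_len(n) - 0.5) / fs
  f0 <- if (is.function(spec$f0_trajectory)) spec$f0_trajectory(t)
        else rep(spec$f0_trajectory, n)
  if (any(f0 <= 40) || any(f0 >= 400))
    stop("f0 trajectory must stay within (40, 400) Hz")
  if (spec$n_harmonics * max(f0) >= fs / 2)
    stop("top harmonic exceeds Nyquist")

  # voicing pattern: voiced stretches of ~1.5 s separated by unvoiced gaps
  vf <- spec$voiced_fraction
  mask <- if (vf >= 1) rep(TRUE, n)
          else if (vf <= 0) rep(FALSE, n)
          else {
            cyc <- round(1.5 / vf * fs)
            von <- round(1.5 * fs)
            ((seq_len(n) - 1L) %% cyc) < von
          }

  phase <- 2 * pi * cumsum(f0) / fs
  x <- numeric(n)
  for (k in seq_len(spec$n_harmonics)) x <- x + cos(k * phase) / k
  x <- x / max(abs(x))

  # gate with 5 ms raised-cosine ramps; low-level noise in the gaps
  runs <- logical_runs(mask)
  gate <- numeric(n)
  ramp_n <- round(0.005 * fs)
  if (!is.null(runs) && nrow(runs) > 0L) {
    for (j in seq_len(nrow(runs))) {
      a <- runs[j, 1L]; b <- runs[j, 2L]
      len <- b - a + 1L
      g <- rep(1, len)
      m <- min(ramp_n, len %/% 2L)
      if (m > 0L) {
        rmp <- 0.5 * (1 - cos(pi * seq_len(m) / (m + 1L)))
        g[seq_len(m)] <- rmp
        g[len - m + seq_len(m)] <- rev(rmp)
      }
      gate[a:b] <- g
    }
  }
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(spec$seed)
  noise <- stats::rnorm(n, 0, 0.03)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  x <- x * gate + noise * (1 - gate)

  # ground-truth pitch on a 10 ms frame grid (frame voiced iff its center is)
  hop <- round(0.010 * fs)
  centers <- seq(hop %/% 2L, n - 1L, by = hop) + 1L
  pt <- pitch_track(t[centers],
                    ifelse(mask[centers], f0[centers], NA_real_),
                    require_voiced = FALSE)
  list(speech = wave(x, fs), pitch = pt,
       f0_hz = ifelse(mask, f0, NA_real_))
}

#' Virtual-ear model
#'
#' Describes how a simulated ear turns the two eliciting harmonic waveforms
#' into an ear-canal recording: a linear passthrough of the stimuli, a
#' distortion component, and white Gaussian noise. In `"cubic"` mode the
#' distortion is a memoryless cubic channel applied to the stimulus sum
#' (band-limited below Nyquist/2 to keep templates alias-free); in
#' `"inject"` mode a scaled, delayed, phase-shifted copy of the
#' distortion-product template is added, giving exact amplitude/latency/
#' phase ground truth.
#'
#' @param distortion_gain Gain of the distortion component.
#' @param latency_s Delay of the distortion component, seconds
#'   (default 2.2 ms, a typical short-latency emission).
#' @param phase_rad Phase shift of the injected emission (inject mode);
#'   the detector should report this value.
#' @param mode `"inject"` (default) or `"cubic"`.
#' @param passthrough_gain Linear gain of the eliciting stimuli.
#' @param noise_rms RMS of the additive white Gaussian noise.
#' @param seed Integer seed for the noise.
#' @param template `harmonic_wave` to inject (required in inject mode).
#' @return An `ear_model` list.
#' @export
ear_model <- function(distortion_gain = 0.01, latency_s = 0.0022,
                      phase_rad = 0, mode = c("inject", "cubic"),
                      passthrough_gain = 1, noise_rms = 0.005,
                      seed = 1L, template = NULL) {
  mode <- match.arg(mode)
  if (latency_s < 0) stop("latency must be non-negative")
  if (noise_rms < 0) stop("noise_rms must be non-negative")
  if (mode == "inject" && is.null(template))
    stop("inject mode needs the distortion-product template")
  structure(list(distortion_gain = distortion_gain, latency_s = latency_s,
                 phase_rad = phase_rad, mode = mode,
                 passthrough_gain = passthrough_gain,
                 noise_rms = noise_rms, seed = as.integer(seed),
                 template = template),
            class = "ear_model")
}

# integer-sample delay: shift content later by n samples, keep length
delay_samples <- function(x, n) {
  if (n == 0L) return(x)
  c(numeric(n), x[seq_len(length(x) - n)])
}

# brickwall lowpass below cutoff_hz via FFT
brickwall_lowpass <- function(x, fs, cutoff_hz) {
  n <- length(x)
  nfft <- stats::nextn(n, 2L)
  f <- seq(0L, nfft - 1L) / nfft
  f <- pmin(f, 1 - f) * fs
  sp <- stats::fft(c(x, numeric(nfft - n)))
  Re(stats::fft(sp * (f < cutoff_hz), inverse = TRUE))[seq_len(n)] / nfft
}

#' Simulate an ear-canal recording
#'
#' @param stimuli List of the two eliciting `harmonic_wave`s (equal rate
#'   and duration).
#' @param ear An [ear_model].
#' @return A `mic_recording` with attribute `ground_truth`: the injected
#'   gain, latency, phase, mode, and (inject mode) the template's harmonic
#'   number.
#' @export
simulate_recording <- function(stimuli, ear) {
  if (length(stimuli) != 2L) stop("need exactly two eliciting waveforms")
  stopifnot_same_rate(stimuli[[1L]], stimuli[[2L]])
  if (length(stimuli[[1L]]) != length(stimuli[[2L]]))
    stop("stimuli must share duration")
  fs <- rate_hz(stimuli[[1L]])
  s <- as.numeric(stimuli[[1L]]) + as.numeric(stimuli[[2L]])
  lag_n <- round(ear$latency_s * fs)

  dist <- if (ear$mode == "cubic") {
    delay_samples(brickwall_lowpass(s^3, fs, fs / 4), lag_n)
  } else {
    a <- analytic(ear$template)
    emission <- Re(a) * cos(ear$phase_rad) + Im(a) * sin(ear$phase_rad)
    delay_samples(emission, lag_n)
  }

  old <- get0(".Random.seed", envir = globalenv())
  set.seed(ear$seed)
  noise <- stats::rnorm(length(s), 0, ear$noise_rms)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())

  r <- ear$passthrough_gain * s + ear$distortion_gain * dist + noise
  out <- mic_recording(r, fs)
  attr(out, "ground_truth") <- list(
    mode = ear$mode, distortion_gain = ear$distortion_gain,
    latency_s = lag_n / fs, phase_rad = ear$phase_rad,
    noise_rms = ear$noise_rms,
    template_harmonic_n = if (ear$mode == "inject")
      harmonic_n(ear$template) else NA_integer_)
  out
}

#' Simulate a paired attended/ignored recording
#'
#' The ignored recording uses the ear's distortion gain; the attended one
#' multiplies it by `attended_gain_ratio`. Noise draws are independent
#' (seeds derived from the ear's seed). With peak amplitudes linear in
#' gain, the expected modulation coefficient is
#' A = 2 (ratio - 1) / (ratio + 1).
#'
#' @param stimuli List of the two eliciting `harmonic_wave`s.
#' @param ear An [ear_model].
#' @param attended_gain_ratio Positive gain ratio attended / ignored.
#' @return List with `attended` and `ignored` `mic_recording`s and
#'   `expected_A`.
#' @export
simulate_attention_pair <- function(stimuli, ear, attended_gain_ratio) {
  if (attended_gain_ratio <= 0) stop("gain ratio must be positive")
  ear_ign <- ear
  ear_att <- ear
  ear_att$distortion_gain <- ear$distortion_gain * attended_gain_ratio
  ear_ign$seed <- ear$seed * 2L + 1L
  ear_att$seed <- ear$seed * 2L + 2L
  list(attended = simulate_recording(stimuli, ear_att),
       ignored = simulate_recording(stimuli, ear_ign),
       expected_A = 2 * (attended_gain_ratio - 1) / (attended_gain_ratio + 1))
}
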