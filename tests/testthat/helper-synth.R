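# Shared synthetic fixtures, built once per test run and cached by key.
# Everything is generated in code; no binary fixtures.

.bench_cache <- new.env(parent = emptyenv())

# Speech-like stimulus plus derived waveforms for the male harmonic pair
# (9/11, template 7). Returns list(syn, pitch, w0, elic, tmpl).
bench <- function(duration_s = 8, voiced_fraction = 0.8, seed = 3) {
  key <- paste(duration_s, voiced_fraction, seed, sep = "_")
  if (!is.null(.bench_cache[[key]])) return(.bench_cache[[key]])
  syn <- synth_speechlike(speechlike_spec(duration_s = duration_s,
                                          voiced_fraction = voiced_fraction,
                                          seed = seed))
  pitch <- estimate_pitch(syn$speech)
  w0 <- extract_fundamental(syn$speech, pitch)
  out <- list(syn = syn, pitch = pitch, w0 = w0,
              elic = list(harmonic(w0, 9), harmonic(w0, 11)),
              tmpl = distortion_template(9, 11, w0))
  .bench_cache[[key]] <- out
  out
}

# A fully voiced constant-envelope tone as a fundamental_wave stand-in:
# amplitude A at frequency f_hz, with explicit passband metadata so that
# harmonic() can check aliasing.
tone_fundamental <- function(f_hz, duration_s = 1, amp = 1, fs = 44100,
                             band_halfwidth_hz = 3) {
  n <- round(duration_s * fs)
  x <- amp * cos(2 * pi * f_hz * (0:(n - 1)) / fs)
  wave(x, fs, class = "fundamental_wave",
       passband_hz = c(low = f_hz - band_halfwidth_hz,
                       high = f_hz + band_halfwidth_hz),
       voiced_runs = cbind(start = 1L, end = n))
}

unwrap_phase <- function(p) signal::unwrap(p)

# interior index range excluding `edge_s` seconds at each end
interior <- function(x, edge_s = 0.02, fs = rate_hz(x)) {
  n <- length(x)
  e <- round(edge_s * fs)
  (e + 1L):(n - e)
}
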