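# Complex cross-correlation detector: oracle equivalence, normalization,
# smoothing, noise floor, peak extraction, equipment delay, preprocessing.

# independent brute-force evaluation of the complex cross-correlation:
# direct lag loop over C(tau) = N * sum_t r(t+tau) (w(t) + i H[w(t)])
brute_xcorr <- function(r, w, a, lags) {
  nr <- length(r); nw <- length(w)
  nrm <- 1 / (sqrt(sum(r^2)) * sqrt(sum(w^2)))
  vapply(lags, function(tau) {
    tt <- seq_len(nw)
    ok <- tt + tau >= 1 & tt + tau <= nr
    sum(r[tt[ok] + tau] * a[tt[ok]]) * nrm
  }, complex(1))
}

test_that("FFT cross-correlation equals the brute-force lag loop", {
  set.seed(42)
  fs <- 44100
  r <- wave(rnorm(1000), fs)
  w <- wave(rnorm(1000), fs)
  lag_n <- 300
  cg <- complex_xcorr(r, w, max_lag_s = lag_n / fs)
  a <- as.complex(analytic(w))
  ref <- brute_xcorr(as.numeric(r), as.numeric(w), a, (-lag_n):lag_n)
  expect_lt(max(Mod(cg$values - ref)) / max(Mod(ref)), 1e-10)
})

test_that("auto cross-correlation is 1 at zero lag with zero phase", {
  b <- bench()
  tmpl <- b$tmpl
  cg <- complex_xcorr(mic_recording(as.numeric(tmpl), rate_hz(tmpl)), tmpl,
                      max_lag_s = 0.01)
  i0 <- which(cg$lags_s == 0)
  expect_equal(Mod(cg$values[i0]), 1, tolerance = 1e-12)
  expect_equal(Arg(cg$values[i0]), 0, tolerance = 1e-9)
})

test_that("the Hilbert transform of the template correlates at +pi/2", {
  w0 <- tone_fundamental(150, duration_s = 1)
  W <- analytic(w0)
  r <- mic_recording(Im(W), rate_hz(w0))
  cg <- complex_xcorr(r, w0, max_lag_s = 0.01)
  i0 <- which(cg$lags_s == 0)
  expect_equal(Mod(cg$values[i0]), 1, tolerance = 1e-3)
  expect_equal(Arg(cg$values[i0]), pi / 2, tolerance = 1e-3)
})

test_that("a delayed template is located to within one sample in noise", {
  # wide-band template: its correlation peak is one sample sharp, so the
  # lag convention and argmax can be checked exactly even at 10x noise
  set.seed(7)
  fs <- 44100
  tmpl <- wave(rnorm(30000), fs)
  d <- round(0.002 * fs)
  r <- c(numeric(d), as.numeric(tmpl))[seq_along(tmpl)]
  r <- r + rnorm(length(r), 0, 10 * rms(tmpl))
  cg <- complex_xcorr(mic_recording(r, fs), tmpl, max_lag_s = 0.01)
  lat <- cg$lags_s[which.max(Mod(cg$values))]
  expect_lt(abs(lat - 0.002), 1.5 / fs)
})

test_that("normalized correlation amplitude never exceeds 1", {
  set.seed(9)
  fs <- 44100
  for (i in 1:5) {
    r <- wave(rnorm(2000), fs)
    w <- wave(rnorm(2000), fs)
    cg <- complex_xcorr(r, w, max_lag_s = 500 / fs)
    expect_lte(max(Mod(cg$values)), 1 + 1e-9)
  }
  expect_error(complex_xcorr(wave(rnorm(10), fs), wave(numeric(10), fs),
                             max_lag_s = 2 / fs), "all-zero")
})

test_that("envelope smoothing is a centered moving average", {
  fs <- 44100
  mk <- function(amp) {
    structure(list(lags_s = seq_along(amp) / fs, values = amp + 0i,
                   normalization_n = 1, rate_hz = fs,
                   smoothed_amplitude = NULL, smoothing_len = NULL),
              class = "correlogram")
  }
  # constant amplitude is unchanged
  cg <- smooth_envelope(mk(rep(0.3, 1000)), 199)
  expect_equal(cg$smoothed_amplitude, rep(0.3, 1000))
  # unit impulse becomes a 199-wide rectangle of height 1/199
  imp <- numeric(1001); imp[501] <- 1
  cg <- smooth_envelope(mk(imp), 199)
  expect_equal(sort(unique(round(cg$smoothed_amplitude, 12))), c(0, 1 / 199))
  expect_equal(sum(cg$smoothed_amplitude > 0), 199)
  # complex values untouched; even window refused
  expect_equal(cg$values, imp + 0i)
  expect_error(smooth_envelope(mk(imp), 200), "odd")
  # white-noise variance is reduced about 199-fold
  set.seed(3)
  x <- abs(rnorm(2e5))
  cg <- smooth_envelope(mk(x), 199)
  mid <- 1000:199000
  expect_equal(stats::var(x[mid]) / stats::var(cg$smoothed_amplitude[mid]),
               199, tolerance = 0.15)
})

test_that("noise floor is the 95th percentile of off-peak amplitudes", {
  fs <- 44100
  lag_n <- round(0.76 * fs)
  lags <- (-lag_n):lag_n / fs
  mk <- function(amp) {
    structure(list(lags_s = lags, values = amp + 0i, normalization_n = 1,
                   rate_hz = fs, smoothed_amplitude = amp,
                   smoothing_len = 199L),
              class = "correlogram")
  }
  # constant 0.2 in the noise windows
  amp <- rep(0.2, length(lags))
  expect_equal(noise_floor(mk(amp)), 0.2)
  # a large peak inside +/-70 ms does not move the floor
  amp2 <- amp
  amp2[abs(lags) < 0.06] <- 5
  expect_equal(noise_floor(mk(amp2)), 0.2)
  # Rayleigh-distributed noise matches the analytic 95th percentile
  set.seed(21)
  sigma <- 0.01
  ray <- sigma * sqrt(-2 * log(stats::runif(length(lags))))
  q95 <- sigma * sqrt(-2 * log(0.05))
  expect_equal(noise_floor(mk(ray)), q95, tolerance = 0.02)
  # insufficient lag range
  short <- structure(list(lags_s = seq(-0.1, 0.1, by = 1 / fs),
                          values = 0i, normalization_n = 1, rate_hz = fs,
                          smoothed_amplitude = rep(0.1,
                            length(seq(-0.1, 0.1, by = 1 / fs))),
                          smoothing_len = 199L),
                     class = "correlogram")
  expect_error(noise_floor(short), "noise windows")
})

test_that("an injected emission is found at its latency and significant", {
  b <- bench()
  ear <- ear_model(template = b$tmpl, passthrough_gain = 0, seed = 5)
  rec <- simulate_recording(b$elic, ear)
  cg <- smooth_envelope(complex_xcorr(rec, b$tmpl))
  pk <- find_peak(cg, noise_floor(cg))
  expect_true(pk$significant)
  expect_lt(abs(pk$latency_s - 0.0022), 0.00025)
})

test_that("pure-noise recordings are mostly flagged insignificant", {
  b <- bench(duration_s = 4)
  fs <- rate_hz(b$tmpl)
  hits <- vapply(1:12, function(s) {
    set.seed(100 + s)
    rec <- mic_recording(rnorm(length(b$tmpl)), fs)
    cg <- smooth_envelope(complex_xcorr(rec, b$tmpl))
    find_peak(cg, noise_floor(cg))$significant
  }, logical(1))
  expect_lte(sum(hits), 3)
})

test_that("doubling the injected gain doubles the peak amplitude", {
  # the stimulus passthrough dominates the recording norm, so the
  # normalized peak amplitude is proportional to the injected gain
  b <- bench()
  amp_at <- function(g) {
    ear <- ear_model(distortion_gain = g, noise_rms = 0,
                     passthrough_gain = 1, template = b$tmpl)
    rec <- simulate_recording(b$elic, ear)
    cg <- smooth_envelope(complex_xcorr(rec, b$tmpl))
    find_peak(cg, noise_floor(cg))$peak_amplitude
  }
  expect_equal(amp_at(0.02) / amp_at(0.01), 2, tolerance = 0.05)
})

test_that("equipment delay is read from the eliciting correlations", {
  b <- bench()
  fs <- rate_hz(b$tmpl)
  mix <- as.numeric(b$elic[[1]]) + as.numeric(b$elic[[2]])
  # passed through at zero delay
  set.seed(2)
  r0 <- mic_recording(mix + rnorm(length(mix), 0, 0.005), fs)
  expect_lt(abs(estimate_equipment_delay(r0, b$elic)), 2.5 / fs)
  # both delayed by 1 ms
  d <- round(0.001 * fs)
  r1 <- mic_recording(c(numeric(d), mix)[seq_along(mix)] +
                        rnorm(length(mix), 0, 0.005), fs)
  expect_lt(abs(estimate_equipment_delay(r1, b$elic) - 0.001), 2.5 / fs)
  # differing per-waveform delays: mean, with a warning
  r2 <- mic_recording(c(numeric(d), as.numeric(b$elic[[1]]))[seq_along(mix)] +
                      c(numeric(2 * d), as.numeric(b$elic[[2]]))[seq_along(mix)],
                      fs)
  expect_warning(d12 <- estimate_equipment_delay(r2, b$elic), "differ")
  expect_equal(d12, 0.0015, tolerance = 0.15)
  # stimuli absent
  set.seed(3)
  rn <- mic_recording(rnorm(length(mix)), fs)
  expect_error(estimate_equipment_delay(rn, b$elic), "not found")
})

test_that("preprocess trims and compensates the equipment delay", {
  fs <- 44100
  r <- mic_recording(rnorm(120 * 1000), 1000)
  out <- preprocess(r, trim_s = 3)
  expect_equal(duration(out), 114)
  # identity when nothing to do
  r2 <- mic_recording(rnorm(2000), 1000)
  expect_equal(as.numeric(preprocess(r2, 0, 0)), as.numeric(r2))
  expect_error(preprocess(r2, trim_s = 2), "too short")
  # round trip: compensating a 1 ms delay brings the estimate to ~0
  b <- bench()
  mix <- as.numeric(b$elic[[1]]) + as.numeric(b$elic[[2]])
  d <- round(0.001 * rate_hz(b$tmpl))
  set.seed(4)
  r3 <- mic_recording(c(numeric(d), mix)[seq_along(mix)] +
                        rnorm(length(mix), 0, 0.005), rate_hz(b$tmpl))
  r3c <- preprocess(r3, trim_s = 0, delay_s = 0.001)
  expect_lt(abs(estimate_equipment_delay(r3c, b$elic)), 2.5 / rate_hz(b$tmpl))
})

test_that("injected phase shifts are recovered mod 2 pi", {
  b <- bench()
  for (ph in c(0, pi / 2, pi, 3 * pi / 2)) {
    ear <- ear_model(phase_rad = ph, noise_rms = 0, passthrough_gain = 0,
                     template = b$tmpl)
    rec <- simulate_recording(b$elic, ear)
    cg <- smooth_envelope(complex_xcorr(rec, b$tmpl))
    pk <- find_peak(cg, noise_floor(cg))
    d <- Arg(exp(1i * (pk$phase_rad - ph)))
    expect_lt(abs(d), 0.1)
  }
})
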