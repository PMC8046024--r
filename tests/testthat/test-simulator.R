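# Virtual ear and stimulus generator: ground-truth pitch, cubic-channel
# spectrum, injection ground truth, linearity, reproducibility.

test_that("single-harmonic constant-f0 synthesis is a pure tone", {
  syn <- synth_speechlike(speechlike_spec(f0_trajectory = 150,
                                          n_harmonics = 1,
                                          voiced_fraction = 1,
                                          duration_s = 1, seed = 2))
  sp <- Mod(stats::fft(as.numeric(syn$speech)))
  half <- 1:(length(sp) %/% 2)
  peak_hz <- (which.max(sp[half]) - 1) * 44100 / length(sp)
  expect_lt(abs(peak_hz - 150), 2)
  expect_true(all(syn$pitch$voiced))
})

test_that("voiced_fraction 0 yields noise with an all-unvoiced track", {
  syn <- synth_speechlike(speechlike_spec(voiced_fraction = 0,
                                          duration_s = 1, seed = 2))
  expect_true(all(!syn$pitch$voiced))
  expect_lt(rms(syn$speech), 0.05)
})

test_that("the built-in tracker recovers the generated f0 trajectory", {
  syn <- synth_speechlike(speechlike_spec(duration_s = 6, seed = 13))
  pt <- estimate_pitch(syn$speech)
  truth <- stats::approx(syn$pitch$time_s, syn$pitch$f0_hz,
                         xout = pt$time_s)$y
  ok <- pt$voiced & !is.na(truth)
  expect_gt(mean(ok), 0.6)
  expect_lt(sqrt(mean((pt$f0_hz[ok] - truth[ok])^2)), 2)
})

test_that("a top harmonic beyond Nyquist is refused", {
  expect_error(synth_speechlike(speechlike_spec(f0_trajectory = 390,
                                                n_harmonics = 60,
                                                duration_s = 0.5)),
               "Nyquist")
})

test_that("cubic channel reproduces the trigonometric expansion", {
  fs <- 44100
  t <- (0:(fs - 1)) / fs
  f1 <- 1000; f2 <- 1200
  stim <- list(wave(cos(2 * pi * f1 * t), fs), wave(cos(2 * pi * f2 * t), fs))
  ear <- ear_model(distortion_gain = 1, latency_s = 0, mode = "cubic",
                   passthrough_gain = 0, noise_rms = 0)
  rec <- simulate_recording(stim, ear)
  # oracle: (cos a + cos b)^3 expanded into its seven cosine lines
  coef_at <- function(x, f) 2 * Mod(sum(x * exp(-2i * pi * f * t))) / length(x)
  expected <- rbind(c(f1, 9 / 4), c(f2, 9 / 4), c(3 * f1, 1 / 4),
                    c(3 * f2, 1 / 4), c(2 * f1 - f2, 3 / 4),
                    c(2 * f1 + f2, 3 / 4), c(2 * f2 - f1, 3 / 4),
                    c(2 * f2 + f1, 3 / 4))
  for (i in seq_len(nrow(expected)))
    expect_equal(coef_at(as.numeric(rec), expected[i, 1]), expected[i, 2],
                 tolerance = 0.01)
  # no energy at frequencies outside the predicted set
  expect_lt(coef_at(as.numeric(rec), 2 * f2 - 2 * f1), 0.01)
  expect_lt(coef_at(as.numeric(rec), f2 - f1), 0.01)
})

test_that("gain 0 and noise 0 passes the stimuli through unchanged", {
  b <- bench(duration_s = 4)
  ear <- ear_model(distortion_gain = 0, noise_rms = 0,
                   passthrough_gain = 0.5, template = b$tmpl)
  rec <- simulate_recording(b$elic, ear)
  expect_equal(as.numeric(rec),
               0.5 * (as.numeric(b$elic[[1]]) + as.numeric(b$elic[[2]])))
})

test_that("full pipeline recovers an injected 2.2 ms emission", {
  b <- bench()
  rec <- simulate_recording(b$elic, ear_model(template = b$tmpl, seed = 9))
  out <- run_detect(b$syn$speech, rec, pitch = b$pitch,
                    cfg = run_config(trim_s = 0))
  expect_true(out$result$significant)
  # broad flat-topped envelope: recovery within half a smoothing window
  half_win <- 0.5 * 199 / 44100
  expect_lt(abs(out$result$latency_s - 0.0022), half_win)
})

test_that("detected amplitude is linear in injected gain", {
  b <- bench()
  gains <- c(0.005, 0.01, 0.02, 0.04, 0.08)
  amps <- vapply(gains, function(g) {
    ear <- ear_model(distortion_gain = g, noise_rms = 0,
                     passthrough_gain = 1, template = b$tmpl)
    rec <- simulate_recording(b$elic, ear)
    cg <- smooth_envelope(complex_xcorr(rec, b$tmpl))
    find_peak(cg, noise_floor(cg))$peak_amplitude
  }, numeric(1))
  fit <- stats::lm(amps ~ gains)
  expect_gt(summary(fit)$r.squared, 0.99)
})

test_that("attention pairs embody the expected modulation", {
  b <- bench(duration_s = 6)
  amp_of <- function(rec) {
    cg <- smooth_envelope(complex_xcorr(rec, b$tmpl))
    find_peak(cg, noise_floor(cg))$peak_amplitude
  }
  # ratio 2, noise-free: A approaches the closed form 2/3; the residual
  # error comes from deterministic finite-duration spectral leakage of the
  # passthrough stimuli into the template band, which perturbs both
  # normalized amplitudes by a common vector
  pr <- simulate_attention_pair(b$elic,
          ear_model(template = b$tmpl, noise_rms = 0, passthrough_gain = 1),
          2)
  A <- modulation(amp_of(pr$attended), amp_of(pr$ignored))
  expect_equal(A, 2 / 3, tolerance = 0.08)
  expect_equal(pr$expected_A, 2 / 3)
  # ratio 1 at default noise: near-zero coefficients over seeds
  As <- vapply(1:8, function(s) {
    pr1 <- simulate_attention_pair(b$elic,
             ear_model(template = b$tmpl, seed = s), 1)
    modulation(amp_of(pr1$attended), amp_of(pr1$ignored))
  }, numeric(1))
  expect_lt(abs(mean(As)), 0.02)
  expect_error(simulate_attention_pair(b$elic,
                 ear_model(template = b$tmpl), -1), "positive")
})

test_that("identical seeds give bit-identical recordings", {
  b <- bench(duration_s = 4)
  ear <- ear_model(template = b$tmpl, seed = 77)
  r1 <- simulate_recording(b$elic, ear)
  r2 <- simulate_recording(b$elic, ear)
  expect_identical(as.numeric(r1), as.numeric(r2))
  r3 <- simulate_recording(b$elic, ear_model(template = b$tmpl, seed = 78))
  expect_false(identical(as.numeric(r1), as.numeric(r3)))
})
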