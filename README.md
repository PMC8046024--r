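# speechdpoae

Detection and analysis of distortion-product otoacoustic emissions
(DPOAEs) elicited by the harmonics of running speech.

The cochlea's active amplifier is nonlinear: two simultaneous tones at
f1 < f2 generate a cubic distortion product at 2·f1 − f2 that radiates
back into the ear canal and can be recorded there. This package implements
a speech-locked generalization for auditory researchers: two eliciting
waveforms are synthesized that track the m-th and n-th harmonics of the
time-varying fundamental frequency f0(t) of a speech signal, the cochlea's
cubic nonlinearity produces an emission tracking the (2m − n)-th harmonic,
and the emission is detected by normalized complex cross-correlation of
the ear-canal recording with the expected distortion waveform. On top of
the detector sit the statistics used to ask whether selective attention to
one of two competing voices modulates the emission.

## Method at a glance

- Fundamental waveform: `w0(t)` = speech bandpassed around f0 with a
  zero-phase 6th-order Butterworth (passband mean(f0) ± 0.5·SD(f0), voiced
  frames only); zero on unvoiced stretches.
- Harmonic shifting via the analytic signal
  `W0 = w0 + i·H[w0]`, `wn = |W0|·cos(n·arg W0)`: envelope preserved,
  instantaneous frequency multiplied by n. Eliciting pairs: harmonics 9/11
  (male voice, emission at the 7th harmonic), 6/8 (female voice, emission
  at the 4th).
- Detection: `C(τ) = N ∫ r(t+τ)·{w(t) + i·H[w(t)]} dt` with
  `N = 1/(‖r‖·‖w‖)`; envelope smoothed (199 samples), noise floor = 95th
  percentile over lags ±(70–750) ms, peak searched in 0–7 ms; phase read
  from the unsmoothed correlation at the peak.
- Attention: relative modulation `A = 2(r_att − r_ign)/(r_att + r_ign)`
  per segment pair, per-subject means, 10-interval one-sided t tests,
  group Wilcoxon signed-rank, percentile bootstrap (10,000 resamples).
- A virtual ear (`simulate_recording()`) with known distortion gain,
  latency and phase — in cubic (memoryless x³) or inject mode — makes
  every stage testable without hardware.

## Worked example

Synthesize a speech-like stimulus, run a virtual ear with a known emission
(gain 0.01, latency 2.2 ms), and detect it:

```r
library(speechdpoae)

syn   <- synth_speechlike(speechlike_spec(duration_s = 10, seed = 42))
pitch <- estimate_pitch(syn$speech)
pitch
#> <pitch_track> 997 frames (81% voiced), f0 = 105.5 +/- 5.9 Hz

w0   <- extract_fundamental(syn$speech, pitch)   # passband 102.5-108.4 Hz
elic <- list(harmonic(w0, 9), harmonic(w0, 11))  # eliciting pair
tmpl <- distortion_template(9, 11, w0)           # emission template (7th)

ear <- ear_model(distortion_gain = 0.01, latency_s = 0.0022,
                 template = tmpl, seed = 42)
rec <- simulate_recording(elic, ear)

out <- run_detect(syn$speech, rec, pitch = pitch,
                  cfg = run_config(trim_s = 0), verbose = TRUE)
#> fundamental: passband 102.5-108.4 Hz
#> harmonics: eliciting 9/11, template 7
#> equipment delay: 0.000 ms
#> detection: amplitude 0.00781 at 3.06 ms vs floor 0.000501 (significant)
```

The emission is found well above the noise floor (~16×) at 3.06 ms —
the injected 2.2 ms plus the ~1 ms scatter that the flat-topped
narrowband correlation envelope imposes on any single latency read-out
(see the methods vignette). The peak amplitude is a normalized
correlation: a unitless fraction of the total recording energy. An
attentional modulation of `A = 0.064` corresponds to
`db_of_modulation(0.064)` ≈ 0.54 dB.

A thin command-line wrapper over the same functions ships in
`inst/cli/speechdpoae` with `synth`, `simulate`, `detect`, `puretone` and
`attention` subcommands.

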