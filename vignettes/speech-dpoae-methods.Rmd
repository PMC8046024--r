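---
title: "Measuring speech-elicited distortion-product otoacoustic emissions"
author: "speechdpoae"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring speech-elicited distortion-product otoacoustic emissions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

The healthy cochlea is an active, nonlinear amplifier. When two tones at
frequencies $f_1 < f_2$ are played into the ear canal, the compressive
nonlinearity of outer-hair-cell amplification generates intermodulation
products, the strongest of which, in humans, is the lower-sideband cubic
distortion product at $2f_1 - f_2$. These distortion-product otoacoustic
emissions (DPOAEs) travel back out through the middle ear and can be picked
up by a sensitive microphone in the ear canal. They are a standard
non-invasive window onto cochlear amplification — and, because the
cochlear amplifier is under descending (medial olivocochlear) control, a
candidate readout for top-down effects such as selective attention.

Classical DPOAE measurement needs stationary primaries, so it cannot track
cochlear activity at the time-varying harmonic structure of natural speech.
This package implements a speech-locked variant. Two *eliciting waveforms*
are synthesized that follow the $m$-th and $n$-th harmonics of the
instantaneous fundamental frequency $f_0(t)$ of a running-speech signal.
Their cubic interaction in the cochlea produces distortion at the
instantaneous frequencies $(2m-n)f_0(t)$ and $(2n-m)f_0(t)$. Because
neither the stimuli nor the emission are stationary, the emission cannot be
read from a power spectrum; it is detected by cross-correlating the
ear-canal recording against the *expected* distortion waveform, computed
from the speech itself.

## From speech to eliciting waveforms

**Fundamental waveform.** A pitch track $f_0(t)$ (from the built-in
normalized-autocorrelation tracker, or imported as CSV from any external
pitch analyzer) defines voiced and unvoiced stretches and the statistics of
the fundamental. The *fundamental waveform* $w_0(t)$ is the speech signal
bandpass filtered around the fundamental: the passband runs from
$\bar{f_0} - \tfrac12\,\mathrm{SD}(f_0)$ to
$\bar{f_0} + \tfrac12\,\mathrm{SD}(f_0)$, both computed over voiced frames
only. Unvoiced stretches are set exactly to zero, with 5-ms raised-cosine
ramps just inside each voiced stretch so that gating introduces no clicks.

The filter is a zero-phase sixth-order Butterworth bandpass. Zero phase
matters: any group delay in $w_0$ would masquerade as emission latency.
We realize the zero-phase pass in the frequency domain, multiplying the
FFT of the signal by the closed-form magnitude-squared response of the
bilinear-transformed Butterworth design (frequency prewarping
$w = \tan(\pi f / f_s)$). This is mathematically the response of a
forward–backward pass of the same filter, but it is numerically robust
where the direct transfer-function form is not — a ~6-Hz-wide passband
near 105 Hz at $f_s = 44.1$ kHz puts all twelve poles of the `(b, a)` form
close to $z = 1$, where forward–backward filtering in coefficient form is
ill-conditioned. The frequency-domain pass is also *exactly* zero-phase and
exactly equivariant under time reversal, which the test suite asserts at
$10^{-9}$ of full scale. "Sixth order" counts the designed bandpass (six
poles); the zero-phase pass doubles the effective rolloff, as it would in
any forward–backward implementation.

**Harmonic shifting.** From $w_0$ the analytic representation
$W_0(t) = w_0(t) + i\,\mathcal{H}[w_0(t)]$ is formed with an FFT-based
Hilbert transform, computed separately on each voiced stretch so that no
phase information leaks across silent gaps. The waveform tracking the
$n$-th harmonic is

$$ w_n(t) = |W_0(t)|\,\cos\!\big(n \cdot \arg W_0(t)\big), $$

which preserves the amplitude envelope and multiplies the instantaneous
phase — hence instantaneous frequency — by $n$. No phase unwrapping is
needed: the expression uses only the wrapped angle. $n = 1$ reproduces
$w_0$ exactly.

**Pair selection.** DPOAEs are strongest near a primary ratio of 1.2 and
primaries of about 1 kHz and above. For a male voice
($f_0 \approx 105$ Hz) the pair $m{=}9$, $n{=}11$ puts the eliciting
waveforms near 0.95/1.16 kHz (ratio $11/9 \approx 1.22$) and the
lower-sideband emission at the 7th harmonic (~0.74 kHz); for a female voice
($f_0 \approx 172$ Hz), $m{=}6$, $n{=}8$ gives the emission at the 4th
harmonic (~0.69 kHz). These two pairs are the package defaults
(`run_config()$harmonic_pair`); both are overridable.

## Detection by normalized complex cross-correlation

The recording $r(t)$ is compared against the lower-sideband template
$w_{2m-n}(t)$ through

$$ C(\tau) \;=\; N \int r(t+\tau)\,
   \big\{ w_{2m-n}(t) + i\,\mathcal{H}[w_{2m-n}(t)] \big\}\, dt . $$

The complex form matters because the emission may carry an arbitrary phase
shift relative to the template; $|C(\tau)|$ is phase-invariant and
$\arg C(\tau)$ recovers the shift. Positive lag means the recording's
matching content *follows* the template.

Choices fixed by this implementation (each has an alternative reading):

* **Normalization.** $N = 1 / (\lVert r \rVert\,\lVert w \rVert)$ with the
  energy of the *real* template, so the auto cross-correlation of the
  template with itself is exactly 1 at zero lag, and $|C| \le 1$ always
  (the test suite checks both). Normalizing by the analytic template's
  energy instead would scale all amplitudes by $1/\sqrt{2}$; comparisons
  across recordings are unaffected either way.
* **Amplitudes are relative.** Because $N$ contains $\lVert r \rVert$,
  the reported peak amplitude is a fraction of the total recording energy
  (stimulus passthrough + noise + emission). A consequence worth knowing:
  if a simulated recording contains *only* the emission, its normalized
  peak is 1 regardless of gain. Gain linearity of the detector is
  therefore only meaningful when the recording norm is dominated by
  something else (stimuli or noise), as it always is in practice.
* **Processing chain.** The first and last 3 s of each recording are
  trimmed (onset/offset transients). The equipment delay — probe and
  system latency — is estimated by cross-correlating the recording with
  each of the two eliciting waveforms; the mean of the two peak delays is
  compensated, with a warning if they disagree by more than 0.5 ms. The
  envelope $|C(\tau)|$ is smoothed with a 199-sample moving average
  (reflect padding; ~4.5 ms at 44.1 kHz). The noise floor is the 95th
  percentile of the smoothed envelope over the off-peak windows
  $\pm(70\ldots750)$ ms, where no short-latency emission can contribute;
  we compute the floor on the smoothed envelope so that signal and noise
  regions receive identical processing (computing it unsmoothed changes
  the false-positive behaviour by well under a percentage point). The
  emission is the peak of the smoothed envelope in the 0–7 ms window
  (earliest lag on ties); its phase is read from the *unsmoothed* $C$ at
  that lag; it is significant if the peak exceeds the floor.

### What the correlogram can and cannot resolve

The template is narrowband: its bandwidth is $(2m-n)$ times the ~6-Hz-wide
fundamental band, i.e. ~40 Hz. The envelope $|C(\tau)|$ therefore
decorrelates over ~15–25 ms and is nearly flat across the whole 0–7 ms
search window. Three practical consequences, all reproduced by the
simulator and quantified in the test suite:

1. **Latency is soft.** With the emission alone, the argmax recovers an
   injected latency to ~0.01 ms. With the eliciting stimuli passed through
   at realistic levels, deterministic finite-duration spectral leakage of
   the stimuli into the template band (~$10^{-3}$ normalized units) tilts
   the flat top and displaces the argmax by up to ~1 ms. Per-recording
   latencies should be read with that scatter in mind.
2. **The significance rule is less specific than its percentile suggests.**
   The rule compares a *maximum over the window* against a *per-sample*
   95th percentile. The 7-ms window holds roughly 1.5 independent envelope
   samples, and the off-peak windows hold only ~90, so on pure noise the
   flag fires in roughly 9–12% of runs, not 5%. The rate is
   duration-independent (both sides of the comparison scale together); it
   approaches 5% only when the window is much shorter than the envelope
   decorrelation time, i.e. for broader-band fundamentals. The acceptance
   suite measures this rate rather than assuming it.
3. **Steady tones have no envelope latency at all.** In the pure-tone
   cross-correlation path the template is a sinusoid; its correlation
   envelope is an overlap tent peaked at lag 0 whatever the physical
   delay. The delay is encoded in the phase, modulo one cycle (1.25 ms at
   800 Hz). The pure-tone path therefore reports amplitude, significance
   and phase as its robust outputs.

## Pure-tone cross-validation

The conventional measurement uses primaries $f_1 = 1$ kHz,
$f_2 = 1.2$ kHz, emission at $2f_1 - f_2 = 800$ Hz. Two analyses are
provided. The spectral path reads the 800-Hz line from a full-length
Hann-windowed periodogram against the 95th percentile of the spectral
amplitudes in the flanks 30–70 Hz on either side of the emission
frequency. The correlation path processes the same recording exactly like
a speech recording, with a sinusoidal 800-Hz template; its noise level
follows the identical procedure with a template at the unrelated nearby
frequency of 900 Hz (95th percentile over the same off-peak windows —
the text this procedure derives from does not pin down the window, but for
a sinusoid template the envelope is nearly lag-independent, so the choice
is immaterial). Across simulated ears with log-spaced distortion gains the
two read-outs agree in rank (Spearman $\ge 0.9$ in the test suite).
Spectral levels are reported in relative (full-scale) units; absolute
dB SPL would require a hardware calibration that is out of scope.

## Attentional modulation

For one stimulus segment recorded once with the target voice attended and
once with it ignored, with peak amplitudes $r_A$ and $r_I$, the relative
attentional modulation is

$$ A \;=\; \frac{2\,(r_A - r_I)}{r_A + r_I}, $$

the amplitude difference divided by the mean — antisymmetric under
swapping conditions, bounded in $(-2, 2)$, and convertible to decibels as
$20\log_{10}(1+A)$ (so $A = 0.064$ is ~0.54 dB, the scale of the medial
olivocochlear reflex). Per-subject values average $A$ over that subject's
segment pairs. Subject-level inference splits each segment pair into 10
consecutive intervals, reads each interval's amplitude at the fixed
segment-level peak latency, and applies a one-sided one-sample $t$ test to
the 10 interval coefficients. Group-level inference uses the two-tailed
one-sample Wilcoxon signed-rank test (with an optional rerun after
removing outliers by the 1.5×IQR rule — the rule is our choice; any
outlier definition could be configured) and a percentile bootstrap of the
mean: 10,000 resamples with replacement, 95% CI from the 2.5th/97.5th
percentiles, one-sided $p$ as the fraction of resampled means at or below
zero. The percentile CI (rather than BCa) is a deliberate simplicity
choice; for these sample sizes the difference is well inside the
inter-subject variability. Exclusion criteria (non-significant pure-tone
DPOAE, non-significant speech-DPOAE, chance-level comprehension) are
configurable filters on the subject table, not hard-coded rules.

Two properties of this estimator worth stating precisely: the bootstrap
mean estimate tracks its own sample's mean (to well within 0.01 for
$n = 17$); and with $n = 17$ subjects of inter-subject SD 0.12, *any*
estimator of the population mean carries a standard error of ~0.03 — the
bootstrap CI makes that uncertainty explicit rather than removing it.

## The virtual ear

The simulator exists so that every stage is testable against ground truth
without hardware or human subjects.

* `synth_speechlike()` builds a harmonic complex with a common phase path
  $2\pi \int f_0\,dt$, $1/k$ amplitude rolloff, and unvoiced gaps of
  low-level noise; it returns the exact pitch track it used. The default
  trajectory is a slow meander with $f_0 = 105 \pm 6$ Hz, the male-voice
  statistics; the default voiced fraction is 0.8 in ~1.5-s stretches.
* `simulate_recording()` mixes (i) a linear passthrough of the two
  eliciting waveforms, (ii) a distortion component, and (iii) white
  Gaussian noise, with a reproducible seed. In **inject** mode the
  distortion is the template itself, delayed by a known latency (default
  2.2 ms, a typical short-latency emission), phase-shifted by a known
  angle, and scaled by a known gain — exact ground truth for the
  detector. In **cubic** mode it is a memoryless $x^3$ channel applied to
  the stimulus sum (band-limited below Nyquist/2), whose two-tone response
  carries the $2f_1-f_2$ line at exactly $3/4$ of the cubed unit
  amplitude — the closed-form anchor for the pure-tone path.
* `simulate_attention_pair()` doubles the recording with the distortion
  gain multiplied by a ratio $g$ in the attended copy and independent
  noise draws; amplitudes linear in gain give the closed-form expectation
  $A = 2(g-1)/(g+1)$, so the study-scale ratio $g = 1.066$ corresponds to
  $A \approx 0.064$.

**Default operating point.** The defaults (inject gain 0.01, passthrough
1, noise RMS 0.005) put the emission ~40–60× above the correlogram noise
floor for 10-s segments. That is deliberately *cleaner* than typical human
recordings: at this operating point, ground-truth recovery errors measure
the pipeline, not the noise. The noise-limited regime the human data live
in (emission a few-fold above floor) is exercised separately — the
significance and false-positive analyses use pure-noise recordings and
elevated noise levels. What the simulator does **not** emulate: the
colored spectrum of real ear-canal noise, probe/middle-ear transfer
functions, emission fine structure, or the dynamics of the efferent
reflex (the attention effect is a static gain ratio). Passing tests
therefore validate the signal-processing chain and its statistics, not
the biology.

## Numerical choices

* FFTs for filtering and cross-correlation are zero-padded (the filter by
  1 s, so the narrowband impulse response cannot wrap around; the
  correlation to the next power of two past full overlap).
* The analytic signal forces its real part to equal the input exactly and
  is computed per voiced stretch; the first/last 20 ms of each stretch are
  excluded from envelope and instantaneous-frequency assertions
  (transform edge effects).
* Envelope smoothing uses reflect padding; peak ties resolve to the
  earliest lag; quantiles use R's default type.
* Equipment-delay compensation shifts by an integer number of samples.
* Degenerate inputs error early and explicitly: all-zero templates
  (undefined normalization), zero f0 variance (empty passband),
  all-unvoiced pitch tracks on load, sub-second attention intervals,
  all-tied rank tests. An all-unvoiced track passed to
  `extract_fundamental()` yields the identically-zero waveform rather
  than an error, matching the definition of $w_0$.

## Problem sizes

The test and acceptance runs use 10-s stimuli (8 s for some unit tests),
51 simulated attended/ignored pairs (17 subjects × 3 segments, the study
design), 200 pure-noise recordings for the false-positive rate, and
10,000 bootstrap resamples (fewer in micro-benchmarks). These sizes are
the package's own desk-scale choices; all of them are parameters.

## Known limitations

* Latency estimates inherit ~1 ms scatter from the flat-topped narrowband
  correlation envelope; treat per-recording latencies as soft.
* The significance rule's false-positive rate is ~10%, not 5%, for
  speech-like templates (see above); interpret single-recording
  significance accordingly, or recalibrate the threshold by simulation
  for a specific template bandwidth.
* Normalized amplitudes are relative to total recording energy and so
  depend on stimulus level and noise; they are comparable within a
  session, not across hardware.
* The pitch tracker is a plain normalized-autocorrelation design intended
  for clean single-speaker material; for adverse recordings, import a
  track from a dedicated pitch analyzer instead.
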