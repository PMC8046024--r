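# Harmonic waveforms wn(t): frequency-shifted copies of the fundamental
# waveform, built from its analytic (Hilbert) representation
#   W0(t) = w0(t) + i H[w0(t)],     wn(t) = |W0(t)| cos(n * arg W0(t)).
# The amplitude envelope |W0| is preserved; the instantaneous frequency is
# n-fold that of w0.

# FFT-based analytic signal of a real vector. The real part is forced to be
# the input exactly; the imaginary part is the Hilbert transform.
analytic_core <- function(x) {
  n <- length(x)
  if (n == 0L) return(complex(0))
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2L + 1L] <- 1; h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1; h[2:((n + 1L) / 2L)] <- 2
  }
  a <- stats::fft(stats::fft(x) * h, inverse = TRUE) / n
  complex(real = x, imaginary = Im(a))
}

#' Analytic representation of a waveform
#'
#' Returns the complex analytic signal whose real part is the
#' input and whose imaginary part is its Hilbert transform. For a
#' fundamental waveform the transform is computed separately on each voiced
#' stretch (the signal is exactly zero in between), which prevents phase
#' leakage across silent gaps; for a plain [wave] the whole signal is
#' transformed at once.
#'
#' @param w0 A [wave] or `fundamental_wave`.
#' @return An `analytic_wave`: complex vector with attribute `rate_hz` (and
#'   the source's `passband_hz`/`voiced_runs` when present).
#' @export
analytic <- function(w0) {
  if (length(w0) == 0L) stop("empty input")
  x <- as.numeric(w0)
  runs <- attr(w0, "voiced_runs")
  if (is.null(runs)) {
    values <- analytic_core(x)
  } else {
    values <- complex(real = x, imaginary = numeric(length(x)))
    for (k in seq_len(nrow(runs))) {
      idx <- runs[k, 1L]:runs[k, 2L]
      values[idx] <- analytic_core(x[idx])
    }
  }
  structure(values, rate_hz = rate_hz(w0),
            passband_hz = attr(w0, "passband_hz"),
            voiced_runs = runs,
            class = "analytic_wave")
}

#' @export
print.analytic_wave <- function(x, ...) {
  cat(sprintf("<analytic_wave> %d samples @ %g Hz\n",
              length(x), attr(x, "rate_hz")))
  invisible(x)
}

#' Harmonic waveform at n times the instantaneous frequency
#'
#' Shifts a fundamental waveform to its n-th harmonic through the analytic
#' signal: the amplitude envelope is kept and the instantaneous phase is
#' multiplied by `n`. `n = 1` reproduces the input exactly.
#'
#' @param w0 A `fundamental_wave` (or any [wave]).
#' @param n Positive integer harmonic number.
#' @return A `harmonic_wave` (subclass of [wave]) with attribute
#'   `harmonic_n`; `passband_hz`/`voiced_runs` are carried over from the
#'   source (the passband scaled by `n`).
#' @export
harmonic <- function(w0, n) {
  if (length(n) != 1L || n < 1 || n != round(n))
    stop("n must be a positive integer")
  n <- as.integer(n)
  fs <- rate_hz(w0)
  band <- attr(w0, "passband_hz")
  if (!is.null(band) && n * band[2] >= fs / 2)
    stop("aliasing: harmonic ", n, " of the passband reaches ",
         round(n * band[2]), " Hz, beyond Nyquist (", fs / 2, " Hz)")
  W <- analytic(w0)
  samples <- if (n == 1L) as.numeric(w0) else Mod(W) * cos(Arg(W) * n)
  wave(samples, fs, class = "harmonic_wave",
       harmonic_n = n,
       passband_hz = if (is.null(band)) NULL else n * band,
       voiced_runs = attr(w0, "voiced_runs"))
}

#' Harmonic number of a harmonic waveform
#' @param w A `harmonic_wave`.
#' @return Integer harmonic number n.
#' @export
harmonic_n <- function(w) attr(w, "harmonic_n")

#' Cubic-distortion template waveform
#'
#' Two eliciting waveforms tracking the m-th and n-th harmonics of the
#' fundamental produce cubic distortion at the instantaneous frequencies
#' (2m - n) f0(t) and (2n - m) f0(t). This returns the matching template:
#' the harmonic waveform at `2m - n` (lower sideband, the stronger one in
#' human ears and the one the detection pipeline uses) or `2n - m` (upper).
#'
#' @param m,n Harmonic numbers of the eliciting pair, `m < n`.
#' @param w0 The `fundamental_wave` the pair was derived from.
#' @param sideband `"lower"` (default) or `"upper"`.
#' @return A `harmonic_wave` at harmonic `2m - n` or `2n - m`.
#' @export
distortion_template <- function(m, n, w0, sideband = c("lower", "upper")) {
  sideband <- match.arg(sideband)
  if (m >= n) stop("need m < n")
  k <- if (sideband == "lower") 2L * m - n else 2L * n - m
  if (k < 1L)
    stop("lower sideband harmonic 2m - n = ", k, " is below 1")
  harmonic(w0, k)
}
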