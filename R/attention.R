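# Attentional modulation of speech-DPOAE amplitudes: the relative
# modulation coefficient A = 2 (r_attended - r_ignored) / (r_attended +
# r_ignored), per-subject aggregation, per-interval subject-level t tests,
# and group-level rank and bootstrap inference.

#' Relative attentional modulation coefficient
#'
#' A = 2 (r_attended - r_ignored) / (r_attended + r_ignored): the
#' difference between the two peak amplitudes divided by their average.
#' Positive when the emission is larger with the corresponding voice
#' attended; antisymmetric under swapping the two conditions; bounded in
#' (-2, 2) for positive amplitudes.
#'
#' @param r_attended,r_ignored Non-negative peak correlation amplitudes of
#'   the same stimulus segment under the two attention conditions.
#' @return The unitless modulation coefficient A.
#' @export
modulation <- function(r_attended, r_ignored) {
  if (any(r_attended < 0) || any(r_ignored < 0))
    stop("amplitudes must be non-negative")
  s <- r_attended + r_ignored
  if (any(s == 0)) stop("both amplitudes are zero")
  2 * (r_attended - r_ignored) / s
}

#' Per-subject attentional modulation
#'
#' Computes the modulation coefficient for each paired segment of one
#' subject and one voice, and averages them into a single per-subject
#' value. Latency differences (attended minus ignored), when provided, are
#' averaged the same way.
#'
#' @param pairs data.frame with columns `r_attended`, `r_ignored`,
#'   optionally `voice`, `segment_id`, `latency_attended_s`,
#'   `latency_ignored_s`.
#' @return A `modulation_result`: `A` (subject mean), `per_segment_A`,
#'   `voice`, `latency_diff_s` (mean attended - ignored latency, or NA).
#' @export
subject_modulation <- function(pairs) {
  if (!is.null(pairs$voice) && length(unique(pairs$voice)) > 1L)
    stop("pairs mix voices; call once per voice")
  a <- modulation(pairs$r_attended, pairs$r_ignored)
  lat <- if (all(c("latency_attended_s", "latency_ignored_s") %in%
                 names(pairs)))
    mean(pairs$latency_attended_s - pairs$latency_ignored_s)
  else NA_real_
  structure(list(A = mean(a), per_segment_A = a,
                 voice = if (is.null(pairs$voice)) NA_character_
                         else pairs$voice[1L],
                 latency_diff_s = lat),
            class = "modulation_result")
}

#' @export
print.modulation_result <- function(x, ...) {
  cat(sprintf("<modulation_result> A = %.4f over %d segment pair(s)\n",
              x$A, length(x$per_segment_A)))
  invisible(x)
}

#' Per-interval modulation coefficients of one segment pair
#'
#' Splits the attended and ignored recordings of one stimulus segment (and
#' the matching template) into `k` consecutive equal intervals, reads the
#' smoothed correlation amplitude of each interval at the fixed
#' segment-level peak latency, and returns the `k` paired modulation
#' coefficients. These feed the per-subject one-sided t test.
#'
#' @param rec_attended,rec_ignored Equal-length `mic_recording`s of the
#'   same segment under the two attention conditions.
#' @param template The distortion-product `harmonic_wave` of the segment.
#' @param k Number of intervals (default 10).
#' @param segment_latency_s Peak latency of the full segment, seconds; the
#'   per-interval amplitudes are read at this lag.
#' @param smoothing_len Envelope moving-average length (default 199).
#' @return Numeric vector of `k` modulation coefficients.
#' @export
interval_modulations <- function(rec_attended, rec_ignored, template,
                                 k = 10L, segment_latency_s,
                                 smoothing_len = 199L) {
  if (length(rec_attended) != length(rec_ignored))
    stop("recordings must have equal length")
  if (k < 2L) stop("need k >= 2 intervals")
  fs <- rate_hz(rec_attended)
  n <- length(rec_attended)
  edges <- floor(seq(0L, n, length.out = k + 1L))
  if (min(diff(edges)) < fs)
    stop("intervals shorter than 1 s; reduce k or use longer recordings")
  max_lag <- max(0.02, segment_latency_s + 0.01)

  amp_at <- function(rec, i0, i1) {
    seg_t <- trim_wave(template, i0 - 1L, n - i1)
    seg_r <- wave_like(as.numeric(rec)[i0:i1], rec)
    cg <- smooth_envelope(complex_xcorr(seg_r, seg_t, max_lag_s = max_lag),
                          smoothing_len)
    cg$smoothed_amplitude[which.min(abs(cg$lags_s - segment_latency_s))]
  }
  vapply(seq_len(k), function(i) {
    i0 <- edges[i] + 1L; i1 <- edges[i + 1L]
    modulation(amp_at(rec_attended, i0, i1), amp_at(rec_ignored, i0, i1))
  }, numeric(1))
}

#' Subject-level one-sided t test of modulation coefficients
#'
#' One-sample t test of the per-interval modulation coefficients against
#' zero, alternative "greater": is the emission amplitude modulation with
#' attention significantly positive for this subject?
#'
#' @param per_interval_A Numeric vector of modulation coefficients.
#' @return One-sided p-value.
#' @export
subject_test <- function(per_interval_A) {
  if (length(per_interval_A) < 2L) stop("need at least two coefficients")
  if (stats::sd(per_interval_A) == 0)
    stop("degenerate sample: zero variance")
  stats::t.test(per_interval_A, alternative = "greater")$p.value
}

#' Bootstrap inference for a mean
#'
#' Percentile bootstrap of the sample mean: `n_resamples` resamples with
#' replacement; 95% confidence interval from the 2.5th and 97.5th
#' percentiles of the resampled means; one-sided p as the fraction of
#' resampled means at or below zero.
#'
#' @param values Numeric sample (e.g. per-subject modulation coefficients).
#' @param n_resamples Number of bootstrap resamples (default 10000).
#' @param seed Integer seed for the resampling; `NULL` leaves the RNG state
#'   alone.
#' @return A `bootstrap_result`: `mean_estimate` (mean of resampled means),
#'   `ci95`, `p_one_sided`, `n_resamples`, `seed`.
#' @export
bootstrap_mean <- function(values, n_resamples = 10000L, seed = NULL) {
  if (length(values) < 2L) stop("need at least two values")
  if (!is.null(seed)) set.seed(seed)
  draws <- matrix(sample(values, length(values) * n_resamples,
                         replace = TRUE),
                  nrow = n_resamples)
  means <- rowMeans(draws)
  structure(list(mean_estimate = mean(means),
                 ci95 = stats::quantile(means, c(0.025, 0.975),
                                        names = FALSE),
                 p_one_sided = mean(means <= 0),
                 n_resamples = as.integer(n_resamples),
                 seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_result> mean %.4f, 95%% CI [%.4f, %.4f], p(one-sided) %.3g\n",
    x$mean_estimate, x$ci95[1], x$ci95[2], x$p_one_sided))
  invisible(x)
}

#' Modulation coefficient expressed in decibels
#'
#' Converts the relative modulation A to the equivalent amplitude change in
#' dB, 20 log10(1 + A); e.g. A = 0.064 corresponds to about 0.54 dB.
#'
#' @param A Modulation coefficient, must exceed -1.
#' @return Amplitude change in dB.
#' @export
db_of_modulation <- function(A) {
  if (any(A <= -1)) stop("A must exceed -1 for a positive amplitude ratio")
  20 * log10(1 + A)
}

#' Group-level tests of per-subject modulation coefficients
#'
#' Two-tailed one-sample Wilcoxon signed-rank test of the per-subject
#' coefficients against zero, with an optional rerun after removing
#' outliers (1.5 x IQR rule).
#'
#' @param subject_values Numeric vector, one coefficient per subject
#'   (at least 5).
#' @param rerun_without_outliers Also report the test with outliers removed
#'   (default TRUE).
#' @return A `group_test_result`: `n`, `p_wilcoxon`, `outliers`
#'   (values flagged by the IQR rule), `p_wilcoxon_no_outliers` (NA when
#'   nothing was removed or the rerun was disabled).
#' @export
group_tests <- function(subject_values, rerun_without_outliers = TRUE) {
  n <- length(subject_values)
  if (n < 5L) stop("too few subjects (need at least 5)")
  if (length(unique(subject_values)) == 1L)
    stop("all values tied; signed-rank test undefined")
  p <- suppressWarnings(
    stats::wilcox.test(subject_values, mu = 0)$p.value)
  qs <- stats::quantile(subject_values, c(0.25, 0.75), names = FALSE)
  iqr <- qs[2] - qs[1]
  out_mask <- subject_values < qs[1] - 1.5 * iqr |
              subject_values > qs[2] + 1.5 * iqr
  p_no_out <- NA_real_
  if (rerun_without_outliers && any(out_mask) && sum(!out_mask) >= 5L)
    p_no_out <- suppressWarnings(
      stats::wilcox.test(subject_values[!out_mask], mu = 0)$p.value)
  structure(list(n = n, p_wilcoxon = p,
                 outliers = subject_values[out_mask],
                 p_wilcoxon_no_outliers = p_no_out),
            class = "group_test_result")
}

#' @export
print.group_test_result <- function(x, ...) {
  cat(sprintf("<group_test_result> n = %d, Wilcoxon p = %.3g (%d outliers)\n",
              x$n, x$p_wilcoxon, length(x$outliers)))
  invisible(x)
}
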