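#' Mono waveform container
#'
#' Light-weight container for a single-channel, uniformly sampled signal.
#' All pipeline stages (speech, eliciting harmonics, microphone recordings)
#' use this representation; subclasses add stage-specific metadata.
#'
#' @param samples Numeric vector of amplitudes (digital full scale).
#' @param rate_hz Sampling frequency in Hz.
#' @param class Extra S3 classes prepended to `"wave"`.
#' @param ... Additional attributes stored on the object.
#' @return An object of class `wave`: the numeric sample vector with
#'   attributes `rate_hz` and any extras.
#' @export
wave <- function(samples, rate_hz, class = character(), ...) {
  if (!is.numeric(samples)) stop("samples must be numeric")
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0)
    stop("rate_hz must be a single positive number")
  structure(as.numeric(samples), rate_hz = as.numeric(rate_hz), ...,
            class = c(class, "wave"))
}

#' @export
print.wave <- function(x, ...) {
  cat(sprintf("<%s> %d samples @ %g Hz (%.3f s)\n",
              class(x)[1L], length(x), rate_hz(x), duration(x)))
  invisible(x)
}

#' Sampling rate of a waveform
#' @param x A `wave` object.
#' @return Sampling frequency in Hz.
#' @export
rate_hz <- function(x) attr(x, "rate_hz")

#' Duration of a waveform in seconds
#' @param x A `wave` object.
#' @return Length divided by sampling rate, in seconds.
#' @export
duration <- function(x) length(x) / rate_hz(x)

#' Root-mean-square amplitude
#' @param x Numeric vector or `wave`.
#' @return RMS value.
#' @export
rms <- function(x) sqrt(mean(as.numeric(x)^2))

# keep wave attributes when replacing samples
wave_like <- function(samples, template) {
  a <- attributes(template)
  a$names <- NULL
  out <- as.numeric(samples)
  attributes(out) <- c(attributes(out), a)
  out
}

stopifnot_same_rate <- function(a, b) {
  if (!isTRUE(all.equal(rate_hz(a), rate_hz(b))))
    stop("sampling rates differ (", rate_hz(a), " vs ", rate_hz(b), " Hz)")
}
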